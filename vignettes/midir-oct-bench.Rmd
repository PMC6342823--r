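---
title: "A virtual bench for mid-infrared spectral-domain OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual bench for mid-infrared spectral-domain OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miroct)
```

## What the bench models

`miroct` is a simulation bench for a spectral-domain optical coherence
tomography (SD-OCT) system operating around 4 µm, in which the mid-infrared
interference spectrum is shifted into the near-infrared by sum-frequency
mixing with a strong 1064 nm pump so that an ordinary silicon line-scan
spectrometer can record it. The package covers four linked layers:

1. **Upconversion band mapping.** Energy conservation,
   $1/\lambda_P + 1/\lambda_{IR} = 1/\lambda_{UP}$, sends the mid-IR band
   3576–4625 nm to 820–865 nm; a 1049 nm mid-IR bandwidth collapses into
   45 nm of near-IR bandwidth. `upconvert_wavelength()`, `map_band()` and
   `remap_spectrum()` implement the map, its band book-keeping and a
   Jacobian-correct spectral-density transport that conserves photon count
   up to the scalar quantum efficiency. A collinear quasi-phase-matching
   mismatch, $\Delta k = 2\pi(n_{UP}/\lambda_{UP} - n_P/\lambda_P -
   n_{IR}/\lambda_{IR} - 1/\Lambda)$, is provided as a scalar diagnostic;
   refractive indices are caller-supplied, since no Sellmeier data is
   bundled.

2. **Interferogram forward model.** `synth_interferogram()` builds the
   spectral intensity
   $S(k)\,[\rho + \sum_j r_j^2 + \sum_j 2\sqrt{\rho}\, r_j
   \cos(2 k z_j + \phi_j(k))]$
   on a dense uniform wavenumber grid, convolves it with a Gaussian
   spectral-resolution kernel, samples it through the (possibly nonlinear)
   pixel-to-wavelength map, scales by integration time and quantizes to the
   ADC bit depth, optionally with Poisson shot noise and Gaussian dark
   noise. Depths $z_j$ are always one-way optical path differences (OPD) in
   air; the fringe phase is $2 k z$.

3. **Reconstruction chain.** `preprocess_frames()` performs dark
   subtraction and reference normalization; `build_calibration()` recovers
   the pixel-to-wavenumber map and the interferometer dispersion phase from
   two single-mirror interferograms; `reconstruct_ascan()` resamples to
   uniform wavenumber, multiplies by $e^{-i\phi_{disp}(k)}$, applies a
   Hanning window over the occupied spectral support, zero-pads and Fourier
   transforms to a reflectivity profile. `assemble_scan()` stacks A-scans
   into B-scans and volumes with stage metadata.

4. **Monte Carlo transport.** A compiled voxel photon-transport engine
   (`mc_simulate()`) emulates time-domain detection in turbid phantoms:
   exponential free paths, Henyey–Greenstein scattering, unpolarized
   Fresnel splitting at refractive-index steps, optical time
   $\sum n\,ds/c$, and NA-gated extraction of the returning flux per time
   gate (`extract_mc_ascan()`), with the depth axis $dz = c\,dt/2$ in air.
   `apply_corrections()` multiplies in the sensitivity roll-off and the
   closed-form confocal overlap factor
   $C(z) = \frac{4 w_0^4 \pi^2\,(4 (z-z_F)^2 \lambda^2 + \pi^2 w_0^4)}
   {(4 (z-z_F)^2 \lambda^2 + 2 \pi^2 w_0^4)^2}$.

## Key parameters and defaults

| parameter | default | unit | meaning |
|---|---|---|---|
| pump wavelength | 1064 | nm | upconversion mixing field |
| mid-IR band | 3576–4625 | nm | detected band before upconversion |
| quantum efficiency | 0.01 | – | flat conversion efficiency over the band |
| spectrometer pixels | 4096 | – | line camera, 796–879 nm |
| spectral resolution | 2.7 | nm (mid-IR) | Gaussian kernel FWHM |
| bit depth | 10 | bit | ADC quantization |
| integration time | 3 | ms | per line; 80 % full well anchor |
| MC time grid | 14.4 / 24 | ps / fs | total / gate; dz = 3.6 µm |
| numerical aperture | 0.1 | – | collection cone for MC gating |
| MC source width | 15 (5) | µm | Gaussian e⁻² radius at the 4 (1.3) µm tag |

The geometric mean of the band edges, $\lambda_0 = \sqrt{3576 \times 4625}
= 4066.8$ nm, is the package's centre-wavelength convention. The roll-off
model is $A(z) = \exp(-z^2 \delta k^2 / (4 \ln 2))$ with $\delta k = 2\pi
\delta\lambda/\lambda_0^2$; the arithmetic-mean alternative would change
the inferred spectral resolution by under 2 %.

## The calibration method

The processing chain needs per-pixel wavenumbers and the interferometer's
unbalanced dispersion. Both come from two noiseless single-mirror frames at
known OPDs $z_a, z_b$: the fringe phase is extracted as the analytic signal
(one-sided spectral filtering with a low-frequency guard below the fringe
carrier), unwrapped, and differenced, giving
$k(p) = (\phi_a - \phi_b)/(2(z_a - z_b))$ up to a constant. Three choices
here were genuinely open and are worth recording:

* **Anchoring the constant.** A single-pixel anchor at the array edge sits
  exactly where the analytic-signal phase is least accurate (edge leakage),
  so the offset is instead chosen to match the mean of the nominal
  linear-in-wavelength map over the usable band. This is exact for
  distortions with zero mean over the band and bounded by the distortion
  mean otherwise; the injected-cubic round-trip test covers it at 1e-3
  relative.
* **Calibration OPDs.** The defaults are ¼ and ¾ of the *calibration-safe*
  range — half the unambiguous (Nyquist) range — so that the fringes keep at
  least four samples per period everywhere, which the phase-unwrap step
  needs headroom for.
* **Calibration frame envelope.** The frames omit the spectral-resolution
  attenuation: they exist to carry phase, and attenuating the deeper-OPD
  fringe would only degrade the phase estimate.

The recovered dispersion phase is defined up to a constant and a linear
term in $k$; both are benign (a fixed sub-bin depth shift), which is why
round-trip tests compare after removing a fitted line.

## Numerical choices

* **Spectral support and masking.** Dividing by a near-zero reference
  amplifies out-of-band leakage into spurious bandwidth, so
  `preprocess_frames()` masks pixels where the dark-subtracted reference is
  below 5 % of its maximum, and the same contiguous range defines the
  Hanning window's support in `reconstruct_ascan()`.
* **Resampling.** Cubic spline on fractional pixel positions (linear
  available for tests); zero-pad factor 4 by default; the depth bin is
  $\pi/(K \cdot \text{pad})$ with $K$ the uniform-wavenumber span.
* **dB conventions.** A-scan dB values are $20\log_{10}$ of magnitude over
  the magnitude median (a robust noise-floor proxy); MC flux, being a
  power-like quantity, uses $10\log_{10}$, and roll-off corrections enter
  MC A-scans squared.
* **Count scaling.** An ideal reference frame reaches 80 % of full scale at
  the nominal integration time, so counts stay linear in integration time
  until clipping; strongly reflecting stacks are therefore synthesized at
  reduced integration time (the bench's equivalent of not saturating the
  camera), and saturated pixels are masked, not silently used.
* **Roll-off metrology.** `simulate_rolloff()` reconstructs its mirror
  probes with the Hanning window; peak ratios are window-independent
  because the support is fixed by the reference arm rather than re-detected
  per frame.
* **Axial resolution.** `axial_resolution()` fits a Gaussian
  (Levenberg–Marquardt) over ±3 nominal widths — appropriate for smooth
  apodized peaks — and refuses ambiguous double-peak windows; for the
  unapodized flat-band response, whose shape is a sinc, the `"halfmax"`
  method measures the FWHM directly (the analytic mainlobe width is
  $3.791/\Delta k$, i.e. ≈ 9.5 µm for this band, which an ideal rectangular
  spectrum would give; the measured instrument figure of 8.6 µm depends on
  the true, untabulated source envelope and is deliberately not forced).

## Monte Carlo design

The engine tracks voxel indices explicitly and steps exactly to ray–voxel
boundaries (Siddon-style), so interface timing — the acceptance surface of a
time-gated detector — is exact rather than sub-stepped. Fresnel splitting
is deterministic above a weight of 1e-3 (the reflected packet goes on a
stack) and stochastic below; Russian roulette below 1e-4 keeps the
simulation unbiased, and its net weight (killed minus boosted) is carried
as an explicit ledger term so that
absorbed + exited + residual + roulette = launched closes to floating-point
precision, which the conservation tests assert at 1e-6. The NA gate is
evaluated in air after refraction at the top surface, because the
instrument collects in air. Each B-scan line runs on an independent
counter-based RNG stream keyed by (seed, line), so runs are bit-reproducible
and lines are embarrassingly parallel; detected flux is normalized by the
number of launched photons, which affects only the absolute scale.

## Phantoms

The packaged samples are the bench's reference geometries:

* `ceramic_stack_*()`: a 375 µm zirconia plate (n 2.138) over a 475 µm
  alumina plate (n 1.675) carrying 60 µm deep valleys of widths 5–180 µm in
  5 µm steps (the physical sample spans 5–300 µm; both options exist), over
  a 300 µm alumina plate — 1400 × 9 × 230 voxels at 5 µm, i.e.
  7000 × 45 × 1150 µm³. The two alumina plates share an index, so their
  interface has zero Fresnel reflectivity and is dropped from the reflector
  stack; physically stacked plates touch across a thin air film, so an
  optional `gap_c2_c3_um` carves an air gap out of the top of C3 (outer
  dimensions preserved), which restores the deep interface for penetration
  studies.
* `wafer_reflectors()`: a 255 µm silicon wafer whose back reflection
  carries the double-pass group-delay dispersion 2 × 0.255 mm × GVD, with
  GVD 1576 fs²/mm at 1.3 µm and 385 fs²/mm at 4 µm; the group index is a
  required user input.
* `tape_on_foil_domain()`: alumina green tape (n ≈ 1.68) on a 62 µm
  cellulose acetate foil (n 1.48), for multiple-scattering comparisons.

The zirconia/alumina and tape/foil absorption and scattering coefficients
are **not** published with the samples. The shipped values are placeholders
chosen once to reproduce the qualitative ordering — alumina scatters
strongly at 1.3 µm (sub-µm pores comparable to the wavelength) and weakly
at 4 µm, absorption negligible for both ceramics — and they are plainly
labelled as such; quantitative work must supply measured coefficients.

## What the synthetic data does and does not show

The generators reproduce the *structure* of the real measurements: fringe
formation and roll-off, pixel-map nonlinearity, dispersion mismatch,
quantization, shot noise, time-gated multiple scattering. They do not
reproduce the measured source envelope (a flat or Gaussian stand-in is
used — hence analytic rather than instrument axial resolutions), the
wavelength-dependent quantum-efficiency curve (flat scalar, optional user
table), the upconverted beam's radially varying spatial mode (represented
only through the scalar spectral-resolution kernel), speckle, or
polarization. Passing tests therefore demonstrate the correctness of the
processing and transport machinery under controlled conditions, not
instrument-level agreement with hardware figures such as absolute
sensitivity in dB.

## Problem sizes

The test-suite and verification runs use: 4096-pixel frames on a 32768-point
spectral grid; 10–13 roll-off probe depths over 0.1–2.5 mm; MC blocks of
10³–10⁶ voxels with 10³–10⁵ photons for invariants, and two 1400 × 9 × 230
ceramic runs at 10⁶ photons for the penetration-ordering comparison. These
sizes were chosen so each check is statistically decisive at its stated
tolerance.

## A worked example

```{r example, eval = FALSE}
spec <- spectrometer_model()                      # 4096 px, 2.7 nm, 10 bit
cal  <- build_calibration(generate_calibration_frames(spec))
src  <- make_source_spectrum(c(3576, 4625), "flat")

fr <- synth_interferogram(reflector_stack(300, 0.05), src, spec)
a  <- reconstruct_ascan(preprocess_frames(fr$sample, fr$dark, fr$reference),
                        cal)
print(a)
axial_resolution(a, 300)

ro <- simulate_rolloff(spec)                      # 10 mirror probes
print(ro$curve)
spectral_resolution_from_rolloff(ro$curve$z6db_um, sqrt(3576 * 4625))
```

## Known limitations

Geometrical-optics MC carries no wave nature: axial and lateral resolution
in the MC branch are set by the digital sampling alone, and speckle is
absent. The noncollinear angle-dependent phase matching of the upconversion
stage is reduced to a collinear scalar mismatch. GPU-scale photon counts
and instrument-rate streaming are out of scope; the engine is sized for
verification and phantom studies on one CPU.
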