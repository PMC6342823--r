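# Reference configuration for the mid-IR SD-OCT virtual bench.
# Units: wavelengths nm, lengths/depths um (one-way OPD in air), time
# total ps / step fs, mua & mus mm^-1, speed mm/s, integration ms.
seed: 1
upconversion:
  pump_nm: 1064            # CW solid-state pump line
  band_nm: [3576, 4625]    # mid-IR detection band
  qe: 0.01                 # flat scalar quantum efficiency
  poling_um: 23            # QPM poling period
source:
  shape: flat
spectrometer:
  n_pixels: 4096
  lambda_range_nm: [796, 879]
  resolution_fwhm_nm: 2.7  # mid-IR scale, Gaussian kernel
  bit_depth: 10
  line_rate_hz: 45000
  distortion: [0, 0]       # pixel-map quadratic/cubic coefficients
phantom:
  type: mirror             # mirror | ceramic_stack | wafer | tape_on_foil
  opd_um: 300
  r: 0.05
  # wafer needs: thickness_um, probe ("1.3"/"4.0"), n_group (required)
scan:
  speed_mm_s: 3
  integration_ms: 3
  n_lines: 2
  step_um: 10
mc:
  t_total_ps: 14.4
  dt_fs: 24                # dz = c*dt/2 = 3.6 um in air
  na: 0.1
  nphoton: 2000
  width_um: 15             # Gaussian e^-2 radius (5 at the 1.3 um tag)
  lateral_step_um: 10
  wavelength_tag: "4.0"
characterize:
  n_probes: 10
  max_opd_um: 2500
output:
  format: tiff
  dynamic_range_db: 40
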