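Package: miroct
Title: Virtual Mid-Infrared Spectral-Domain OCT Bench
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual bench for mid-infrared spectral-domain optical coherence
    tomography (SD-OCT) built around frequency-upconversion detection. The package
    synthesizes raw spectrometer interferograms from layered reflector phantoms
    (fringe formation, dispersion mismatch, finite spectral resolution, pixel-map
    nonlinearity, shot noise and quantization), implements the full reconstruction
    chain (dark subtraction, reference normalization, two-interferogram
    pixel-to-wavenumber calibration, spectral resampling, numerical dispersion
    compensation, Hanning apodization and zero-padded Fourier transformation to
    A-, B- and volume scans), provides a time-resolved voxel Monte Carlo photon
    transport engine with numerical-aperture-gated signal extraction, sensitivity
    roll-off and confocal Gaussian-beam overlap corrections, and supplies
    characterization operators (axial resolution by Gaussian fit, sensitivity
    roll-off and 6 dB depth, spectral-resolution inversion, sampling resolutions,
    thickness from optical path difference) together with the sum-frequency
    wavelength mapping that defines the detected band.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    signal,
    stats,
    tiff,
    png,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
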