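# Shared fixtures. The default-geometry spectrometer model and its
# wavenumber calibration are expensive enough to build once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

tst_spec <- function() cached("spec", function() spectrometer_model())

tst_cal <- function() cached("cal", function()
  build_calibration(generate_calibration_frames(tst_spec())))

tst_source <- function() cached("source", function() make_source_spectrum())

# Reconstruct a single noiseless mirror frame through the standard chain.
tst_mirror_ascan <- function(opd_um, r = 0.05, window = "none",
                             spec = tst_spec(), cal = tst_cal(), ...) {
  fr <- synth_interferogram(reflector_stack(opd_um, r), tst_source(), spec)
  reconstruct_ascan(preprocess_frames(fr$sample, fr$dark, fr$reference),
                    cal, window = window, ...)
}

# Analytic sinc mainlobe FWHM for a flat band (um), band edges in nm.
sinc_fwhm_um <- function(band_nm = c(3576, 4625)) {
  3.791 / (2 * pi * (1 / (band_nm[1] / 1000) - 1 / (band_nm[2] / 1000)))
}

# Small uniform test block for MC runs (explicit formals: a literal `n =`
# argument must bind to the refractive index, not partially match `nxy`).
tst_block <- function(nxy = 5, nz = 60, voxel_um = 5, mua = 0, mus = 0,
                      g = 0, n = 1) {
  voxel_domain(c(nxy, nxy, nz), voxel_um, mua = mua, mus = mus, g = g, n = n)
}
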