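#' Write / read a raw frame as CSV (pixel, counts)
#'
#' @param frame an `oct_raw_frame`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_frame_csv <- function(frame, path) {
  stopifnot(inherits(frame, "oct_raw_frame"))
  write.csv(data.frame(pixel = seq_along(frame$counts),
                       counts = frame$counts),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_csv
#' @param spec a [spectrometer_model()] to attach to the frame (required by
#'   downstream processing; CSV stores counts only).
#' @param kind frame kind label.
#' @param integration_ms integration time to attach.
#' @export
read_frame_csv <- function(path, spec, kind = "sample", integration_ms = NA) {
  df <- read.csv(path)
  raw_frame(df$counts, kind, spec, integration_ms)
}

#' Write / read a raw frame as a binary container with a JSON header
#'
#' Format: one JSON text line (n_pixels, bit_depth, kind, seed,
#' integration_ms) followed by little-endian 32-bit integer counts.
#'
#' @param frame an `oct_raw_frame`.
#' @param path output file.
#' @return the path (write) or an `oct_raw_frame` (read), invisibly/visibly.
#' @export
write_frame_bin <- function(frame, path) {
  stopifnot(inherits(frame, "oct_raw_frame"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(n_pixels = length(frame$counts),
                               bit_depth = frame$spec$bit_depth,
                               kind = frame$kind,
                               seed = frame$seed,
                               integration_ms = frame$integration_ms),
                          auto_unbox = TRUE, null = "null")
  writeLines(as.character(hdr), con)
  writeBin(as.integer(round(frame$counts)), con, size = 4L,
           endian = "little")
  invisible(path)
}

#' @rdname write_frame_bin
#' @param spec optional [spectrometer_model()]; default: a model with the
#'   header's pixel count and bit depth and package defaults otherwise.
#' @export
read_frame_bin <- function(path, spec = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(readLines(con, n = 1L))
  counts <- readBin(con, "integer", n = hdr$n_pixels, size = 4L,
                    endian = "little")
  if (is.null(spec))
    spec <- spectrometer_model(n_pixels = hdr$n_pixels,
                               bit_depth = hdr$bit_depth)
  raw_frame(counts, hdr$kind, spec,
            if (is.null(hdr$integration_ms)) NA_real_ else hdr$integration_ms,
            seed = hdr$seed)
}

#' Write an A-scan as CSV (depth_um, magnitude, db)
#'
#' @param ascan an `oct_ascan`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ascan_csv <- function(ascan, path) {
  stopifnot(inherits(ascan, "oct_ascan"))
  write.csv(data.frame(depth_um = ascan$depth_um,
                       magnitude = ascan$magnitude, db = ascan$db),
            path, row.names = FALSE)
  invisible(path)
}

#' Export a B-scan as a 16-bit grayscale image with a JSON sidecar
#'
#' Maps the dB image into `[0, 1]` over `[max - dynamic_range_db, max]`
#' (row = depth, column = lateral position) and writes 16-bit grayscale
#' TIFF (quantization `dynamic_range_db / 65535`) or 8-bit grayscale PNG
#' (`/ 255`; the PNG writer does not support 16-bit samples), plus a
#' `<path>.json` sidecar with the axes, depth bin and the dB mapping so
#' values can be recovered on re-import.
#'
#' @param scan an `oct_bscan` or `mc_bscan` (or a bare matrix of dB values).
#' @param path output file.
#' @param dynamic_range_db displayed dynamic range (default 40).
#' @param format `"tiff"` or `"png"`.
#' @return the path, invisibly.
#' @export
export_image <- function(scan, path, dynamic_range_db = 40,
                         format = c("tiff", "png")) {
  format <- match.arg(format)
  if (inherits(scan, "oct_bscan")) {
    img_db <- scan$db
    depth <- scan$depth_um; lateral <- scan$lateral_um
  } else if (inherits(scan, "mc_bscan")) {
    fl <- scan$flux[scan$flux > 0]
    ref <- if (length(fl)) median(fl) else 1
    img_db <- 10 * log10(pmax(scan$flux, ref * 1e-9) / ref)
    depth <- scan$depth_um; lateral <- scan$lateral_um
  } else if (is.matrix(scan)) {
    img_db <- scan
    depth <- seq_len(nrow(scan)); lateral <- seq_len(ncol(scan))
  } else stop_domain("unsupported scan object")
  if (!length(img_db)) stop_domain("scan is empty")
  top <- max(img_db)
  img <- (img_db - (top - dynamic_range_db)) / dynamic_range_db
  img <- pmin(pmax(img, 0), 1)
  if (format == "tiff") {
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else {
    png::writePNG(img, path)
  }
  sidecar <- list(rows = nrow(img), cols = ncol(img),
                  row_axis = "one-way OPD in air (um)",
                  col_axis = "lateral position (um)",
                  depth_um = range(depth), lateral_um = range(lateral),
                  depth_bin_um = if (length(depth) > 1)
                    depth[2] - depth[1] else NA,
                  db_max = top, dynamic_range_db = dynamic_range_db,
                  format = format)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Re-import an exported B-scan image to dB values
#'
#' @param path image written by [export_image()] (its `.json` sidecar must
#'   sit next to it).
#' @return matrix of dB values.
#' @export
import_image_db <- function(path) {
  sc <- jsonlite::fromJSON(paste0(path, ".json"))
  img <- if (sc$format == "tiff") tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * sc$dynamic_range_db + (sc$db_max - sc$dynamic_range_db)
}

#' Write / read a voxel domain as binary + JSON sidecar
#'
#' `<path>` holds the four per-voxel arrays (mua, mus, g, n) as
#' little-endian doubles in R array order; `<path>.json` holds dims and
#' voxel pitch.
#'
#' @param domain a [voxel_domain()].
#' @param path output file.
#' @return the path (write) / a `voxel_domain` (read).
#' @export
write_domain <- function(domain, path) {
  stopifnot(inherits(domain, "voxel_domain"))
  con <- file(path, "wb")
  on.exit(close(con))
  for (f in c("mua", "mus", "g", "n"))
    writeBin(as.numeric(domain[[f]]), con, size = 8L, endian = "little")
  jsonlite::write_json(list(dims = domain$dims, voxel_um = domain$voxel_um,
                            fields = c("mua", "mus", "g", "n"),
                            units = "mua/mus mm^-1; pitch um"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_domain
#' @export
read_domain <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  n <- prod(meta$dims)
  con <- file(path, "rb")
  on.exit(close(con))
  arrs <- lapply(1:4, function(i)
    array(readBin(con, "numeric", n = n, size = 8L, endian = "little"),
          dim = meta$dims))
  voxel_domain(meta$dims, meta$voxel_um, mua = arrs[[1]], mus = arrs[[2]],
               g = arrs[[3]], n = arrs[[4]])
}

#' Dump Monte Carlo exit records to CSV (debugging aid)
#' @param sim an [mc_simulate()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_mc_exits_csv <- function(sim, path) {
  stopifnot(inherits(sim, "mc_result"))
  write.csv(as.data.frame(sim$exits), path, row.names = FALSE)
  invisible(path)
}
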