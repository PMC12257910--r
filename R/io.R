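# Serialization: volumes as NIfTI (voxel size in the header), projection
# sets as a raw float64 container with a JSON sidecar carrying the full
# scan geometry, domain tag and I0.

#' Read and write volumes as NIfTI
#'
#' @param volume an [att_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param geom optional [scan_geometry()] supplying the voxel size.
#' @return `write_volume()` returns the path invisibly; `read_volume()`
#'   returns an [att_volume()] (unit from the sidecar-free convention:
#'   pass `unit`).
#' @export
write_volume <- function(volume, path, geom = NULL) {
  arr <- unclass_vol(volume)
  pixdim <- if (!is.null(geom)) geom$voxel_size_mm else c(1, 1, 1)
  img <- RNifti::asNifti(arr, pixdim = pixdim)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param unit unit tag to attach on read.
#' @export
read_volume <- function(path, unit = "HU") {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  new_att_volume(arr, unit)
}

#' Read and write projection containers
#'
#' A projection set is stored as `<prefix>.json` (geometry, domain, I0,
#' array shape, optional metal trace run-length encoding) plus
#' `<prefix>.bin` (float64, little-endian, R column-major order).
#'
#' @param projections a [projection_set()].
#' @param prefix path prefix without extension.
#' @param trace optional `metal_trace` serialized alongside.
#' @return `write_projections()` the prefix, invisibly;
#'   `read_projections()` a list `projections` + `trace` (or `NULL`).
#' @export
write_projections <- function(projections, prefix, trace = NULL) {
  stopifnot(inherits(projections, "projection_set"))
  g <- projections$geometry
  hdr <- list(domain = projections$domain, I0 = projections$I0,
              shape = dim(projections$data),
              geometry = if (!is.null(g)) unclass(g))
  if (!is.null(trace)) {
    r <- rle(as.logical(trace$mask))
    hdr$trace_rle <- list(lengths = r$lengths, values = r$values)
  }
  jsonlite::write_json(hdr, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.double(projections$data), con, size = 8, endian = "little")
  invisible(prefix)
}

#' @rdname write_projections
#' @export
read_projections <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(hdr$shape)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  dim(x) <- hdr$shape
  geom <- NULL
  if (!is.null(hdr$geometry)) {
    ga <- hdr$geometry
    geom <- scan_geometry(ga$mode, ga$source_to_iso_mm,
                          ga$source_to_detector_mm, ga$n_views,
                          ga$angle_start, ga$angle_span, ga$detector_cols,
                          ga$detector_rows, ga$pixel_pitch_mm,
                          ga$volume_shape, ga$voxel_size_mm)
  }
  ps <- projection_set(x, hdr$domain, I0 = if (is.null(hdr$I0)) NA_real_ else hdr$I0,
                       geometry = geom)
  trace <- NULL
  if (!is.null(hdr$trace_rle)) {
    m <- inverse.rle(structure(list(lengths = hdr$trace_rle$lengths,
                                    values = hdr$trace_rle$values),
                               class = "rle"))
    dim(m) <- hdr$shape
    trace <- structure(list(mask = m, geometry = geom), class = "metal_trace")
  }
  list(projections = ps, trace = trace)
}
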