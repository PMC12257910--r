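# Filtered backprojection: cosine pre-weighting, row-wise ramp filtering via
# FFT, and weighted backprojection (fan-beam FBP; FDK for cone-beam).
# Detector coordinates are rescaled to the iso-center plane (u * SO/SD), the
# standard flat-panel formulation, so the same filter serves both modes.

# discrete Ramachandran-Lakshminarayanan kernel, frequency response on an
# FFT grid of length npad for detector spacing du
ramp_response <- function(npad, du, kernel = c("ram-lak", "hann", "cosine")) {
  kernel <- match.arg(kernel)
  h <- numeric(npad)
  h[1] <- 1 / (4 * du^2)
  k <- seq_len(npad %/% 2)
  odd <- k[k %% 2 == 1]
  h[1 + odd] <- -1 / (pi^2 * odd^2 * du^2)
  h[npad + 1 - odd] <- -1 / (pi^2 * odd^2 * du^2)
  H <- Re(stats::fft(h))
  if (kernel != "ram-lak") {
    f <- seq(0, npad - 1) / npad
    f <- pmin(f, 1 - f) * 2  # 0..1, 1 at Nyquist
    w <- switch(kernel,
                hann = 0.5 * (1 + cos(pi * f)),
                cosine = cos(pi * f / 2))
    H <- H * w
  }
  H
}

filter_rows <- function(p, du, kernel) {
  # p: (n_views, n_rows, n_cols); filter along the column (u) axis
  d <- dim(p)
  ncols <- d[3]
  npad <- 2^ceiling(log2(max(2 * ncols, 64)))
  H <- ramp_response(npad, du, kernel)
  m <- matrix(0, npad, d[1] * d[2])
  m[seq_len(ncols), ] <- t(matrix(p, nrow = d[1] * d[2], ncol = ncols))
  q <- Re(stats::mvfft(stats::mvfft(m) * H, inverse = TRUE)) / npad
  q <- t(q[seq_len(ncols), , drop = FALSE]) * du
  array(q, dim = d)
}

#' Filtered backprojection / FDK reconstruction
#'
#' Reconstructs an attenuation volume from line-integral projections:
#' cosine pre-weighting, ramp filtering of each detector row, and weighted
#' backprojection. In `"fanbeam2d"` mode this is flat-detector fan-beam FBP;
#' in `"conebeam3d"` mode it is the FDK algorithm. A full angular turn is
#' assumed (no short-scan weighting).
#'
#' @param projections a [projection_set()] in the line-integral domain.
#' @param geom the [scan_geometry()]; defaults to the one stored in
#'   `projections`.
#' @param kernel reconstruction kernel: `"ram-lak"` (default), `"hann"` or
#'   `"cosine"` (apodized variants).
#' @return An [att_volume()] in mm^-1 (values may ring slightly negative).
#' @export
fbp_reconstruct <- function(projections, geom = projections$geometry,
                            kernel = "ram-lak") {
  stopifnot(inherits(projections, "projection_set"))
  if (projections$domain != "line_integral")
    stop("fbp_reconstruct expects line-integral projections; see log_transform()")
  if (is.null(geom)) stop("no geometry supplied")
  want <- c(geom$n_views, geom$detector_rows, geom$detector_cols)
  if (!identical(as.integer(dim(projections$data)), as.integer(want)))
    stop("projection shape does not match geometry")
  SO <- geom$source_to_iso_mm
  SD <- geom$source_to_detector_mm
  mag <- SO / SD
  du <- geom$pixel_pitch_mm * mag
  # cosine weighting on iso-plane coordinates
  u <- (seq_len(geom$detector_cols) - 0.5 - geom$detector_cols / 2) * du
  v <- (seq_len(geom$detector_rows) - 0.5 - geom$detector_rows / 2) * du
  wuv <- outer(v, u, function(vv, uu) SO / sqrt(SO^2 + uu^2 + vv^2))
  p <- projections$data *
    aperm(array(wuv, c(dim(wuv), geom$n_views)), c(3, 1, 2))
  q <- filter_rows(p, du, kernel)
  vol <- cpp_backproject(q, as_geom_list(geom))
  new_att_volume(vol, "mm^-1")
}
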