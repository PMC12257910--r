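# Masked image-quality metrics. Both metrics exclude the metal voxels
# (mask) from every statistic, so edits inside the implants never move a
# score, and both are computed on a declared HU display window.

#' Peak signal-to-noise ratio over unmasked voxels
#'
#' `PSNR = 10 log10(MAX_y^2 / MSE)` with the mean squared error and the
#' reference maximum `MAX_y` both taken over the voxels outside
#' `exclude_mask`. Identical inputs return `Inf`.
#'
#' @param x,y test and reference arrays (same shape).
#' @param exclude_mask optional logical array of voxels to ignore
#'   (typically the metal mask).
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, exclude_mask = NULL) {
  if (!identical(dim(x), dim(y)) && !(is.null(dim(x)) && is.null(dim(y))))
    stop("shape mismatch")
  keep <- if (is.null(exclude_mask)) TRUE else !exclude_mask
  xv <- x[keep]; yv <- y[keep]
  if (!length(yv)) stop("mask excludes every voxel")
  mse <- mean((xv - yv)^2)
  if (mse == 0) return(Inf)
  maxy <- max(yv)
  10 * log10(maxy^2 / mse)
}

#' Structural similarity over unmasked voxels
#'
#' The global-statistics form of SSIM:
#' `(2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`
#' computed from the means, variances and covariance of the unmasked
#' voxels, with `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for a dynamic range
#' `L`. A windowed variant (mean of per-voxel SSIM over a sliding box along
#' the first two dimensions) is available behind `windowed = TRUE`.
#'
#' @param x,y test and reference arrays.
#' @param exclude_mask optional logical array of voxels to ignore.
#' @param L dynamic range; defaults to the range of the unmasked reference.
#' @param windowed use the sliding-window variant.
#' @param window_size box half-width for the windowed variant.
#' @return SSIM in \[-1, 1\].
#' @export
ssim <- function(x, y, exclude_mask = NULL, L = NULL, windowed = FALSE,
                 window_size = 5L) {
  if (!identical(dim(x), dim(y)) && !(is.null(dim(x)) && is.null(dim(y))))
    stop("shape mismatch")
  keep <- if (is.null(exclude_mask)) rep(TRUE, length(x)) else !exclude_mask
  if (is.null(L)) {
    L <- diff(range(y[keep]))
    if (L == 0) L <- 1
  }
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  if (!windowed) {
    xv <- x[keep]; yv <- y[keep]
    n <- length(xv)
    mx <- mean(xv); my <- mean(yv)
    vx <- sum((xv - mx)^2) / (n - 1)
    vy <- sum((yv - my)^2) / (n - 1)
    cxy <- sum((xv - mx) * (yv - my)) / (n - 1)
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
           ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  dx <- dim(x)
  if (is.null(dx)) stop("windowed SSIM needs an array")
  # sliding box mean along both image axes via cumulative sums
  box1 <- function(m, k) {
    n <- nrow(m)
    S <- rbind(0, apply(m, 2, cumsum))
    hi <- pmin(n, seq_len(n) + k); lo <- pmax(1L, seq_len(n) - k)
    (S[hi + 1L, , drop = FALSE] - S[lo, , drop = FALSE]) / (hi - lo + 1)
  }
  box <- function(m, k) t(box1(t(box1(m, k)), k))
  x2 <- array(x, dx); y2 <- array(y, dx)
  smap <- array(NA_real_, dx)
  for (k3 in seq_len(if (length(dx) >= 3) dx[3] else 1L)) {
    xs <- if (length(dx) >= 3) x2[, , k3] else x2
    ys <- if (length(dx) >= 3) y2[, , k3] else y2
    mx <- box(xs, window_size); my <- box(ys, window_size)
    vx <- box(xs^2, window_size) - mx^2
    vy <- box(ys^2, window_size) - my^2
    cxy <- box(xs * ys, window_size) - mx * my
    sm <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
          ((mx^2 + my^2 + C1) * (vx + vy + C2))
    if (length(dx) >= 3) smap[, , k3] <- sm else smap[] <- sm
  }
  mean(smap[keep])
}

#' Evaluate a reconstruction against its reference
#'
#' Clips both volumes to a declared HU display window, masks out the metal
#' voxels, and reports masked PSNR and SSIM (volume-wise, and per slice for
#' 3D volumes).
#'
#' @param x reconstruction (HU volume or array).
#' @param y reference (same shape).
#' @param metal_mask logical array excluded from all statistics.
#' @param window HU display window used for clipping and as the SSIM
#'   dynamic range.
#' @return A list of class `metrics_report`.
#' @export
evaluate_mar <- function(x, y, metal_mask = NULL, window = c(-1000, 1500)) {
  xv <- pmin(pmax(as.array(unclass_vol(x)), window[1]), window[2])
  yv <- pmin(pmax(as.array(unclass_vol(y)), window[1]), window[2])
  L <- diff(window)
  rep <- list(psnr = psnr(xv, yv, metal_mask),
              ssim = ssim(xv, yv, metal_mask, L = L),
              window = window,
              n = if (is.null(metal_mask)) length(yv) else sum(!metal_mask))
  if (length(dim(xv)) == 3L && dim(xv)[3] > 1L) {
    rep$per_slice <- data.frame(
      slice = seq_len(dim(xv)[3]),
      psnr = vapply(seq_len(dim(xv)[3]), function(k)
        psnr(xv[, , k], yv[, , k],
             if (is.null(metal_mask)) NULL else metal_mask[, , k]), 0),
      ssim = vapply(seq_len(dim(xv)[3]), function(k)
        ssim(xv[, , k], yv[, , k],
             if (is.null(metal_mask)) NULL else metal_mask[, , k], L = L), 0))
  }
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("PSNR %.2f dB, SSIM %.4f (window [%g, %g] HU, %d voxels)\n",
              x$psnr, x$ssim, x$window[1], x$window[2], x$n))
  invisible(x)
}
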