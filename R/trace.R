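# Metal trace identification and the ray bookkeeping that drives
# self-supervised field optimization: reliable rays (off-trace), the
# metal-aware subset near the trace with exponential distance weights, and
# the area-balanced batch sampler.

#' Segment metal from a reconstructed volume
#'
#' Thresholding of the uncorrected reconstruction: every voxel at or above
#' `threshold_hu` is metal. The default 2000 HU is the clinical
#' metal-segmentation threshold.
#'
#' @param volume a HU [att_volume()].
#' @param threshold_hu segmentation threshold (inclusive).
#' @return A logical array of the volume's shape.
#' @export
segment_metal_volume <- function(volume, threshold_hu = 2000) {
  if (vol_unit(volume) != "HU") stop("expects a HU volume")
  unclass_vol(volume) >= threshold_hu
}

#' Compute the metal trace
#'
#' Forward-projects the metal-only mask and flags every detector pixel whose
#' metal path length is strictly positive. These pixels are the corrupted
#' (missing-data) region of the sinogram.
#'
#' @param metal_mask logical array matching the geometry's volume grid.
#' @param geom a [scan_geometry()].
#' @param step_frac projector step, see [forward_project()].
#' @return An object of class `metal_trace`: logical array `mask` of shape
#'   `(n_views, detector_rows, detector_cols)` plus the geometry.
#' @export
compute_metal_trace <- function(metal_mask, geom, step_frac = 0.5) {
  if (!is.logical(metal_mask)) stop("metal_mask must be logical")
  if (is.matrix(metal_mask)) dim(metal_mask) <- c(dim(metal_mask), 1L)
  if (!identical(as.integer(dim(metal_mask)), geom$volume_shape))
    stop("metal mask shape does not match geometry")
  p <- forward_project(att_volume(ifelse(metal_mask, 1, 0), "mm^-1"),
                       geom, step_frac)
  structure(list(mask = p$data > 0, geometry = geom), class = "metal_trace")
}

empty_trace <- function(geom) {
  structure(list(mask = array(FALSE, c(geom$n_views, geom$detector_rows,
                                       geom$detector_cols)),
                 geometry = geom),
            class = "metal_trace")
}

#' @export
print.metal_trace <- function(x, ...) {
  cat(sprintf("<metal_trace: %d of %d detector pixels (%.2f%%)>\n",
              sum(x$mask), length(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Reliable rays: the complement of the metal trace
#'
#' @param trace a [compute_metal_trace()] result.
#' @return Integer vector of 1-based linear indices into the projection
#'   array for all rays outside the trace. Empty (with a warning) when the
#'   trace covers the whole detector, which is fatal for training.
#' @export
reliable_rays <- function(trace) {
  stopifnot(inherits(trace, "metal_trace"))
  idx <- which(!trace$mask)
  if (length(idx) == 0L)
    warning("metal trace covers every ray; no reliable data to fit")
  idx
}

#' Distance-to-trace map for one view
#'
#' Exact Euclidean distance transform (in detector pixel units) from every
#' detector pixel of a view to its nearest trace pixel. Zero on the trace;
#' `Inf` when the view contains no trace at all.
#'
#' @param trace a `metal_trace`.
#' @param view 0-based view index.
#' @return A `detector_rows x detector_cols` matrix of distances.
#' @export
detector_distance <- function(trace, view) {
  stopifnot(inherits(trace, "metal_trace"))
  g <- trace$geometry
  if (view < 0 || view >= g$n_views) stop("view out of range")
  sl <- matrix(trace$mask[view + 1L, , ], g$detector_rows, g$detector_cols)
  if (!any(sl))
    return(matrix(Inf, g$detector_rows, g$detector_cols))
  cpp_edt(sl)
}

#' Metal-aware ray set with distance-decay weights
#'
#' Off-trace rays whose detector distance to the trace is strictly below
#' `d_th` form the metal-aware set. Each member gets weight
#' `w = exp(-lambda * d)`; the normalized weights `w_hat = w / max(w)` are
#' computed once over the whole set so the loss scale is stationary across
#' training batches. Views without any trace contribute no members.
#'
#' @param trace a `metal_trace`.
#' @param d_th distance threshold in detector pixels (default 20; strict
#'   inequality, so `d = d_th` is excluded).
#' @param lambda decay factor per pixel (default 0.01).
#' @return A list of class `metal_aware_set`: `idx` (1-based linear indices
#'   into the projection array), `d`, `w`, `w_hat`, `d_th`, `lambda`. The
#'   set may be empty.
#' @export
metal_aware_set <- function(trace, d_th = 20, lambda = 0.01) {
  stopifnot(inherits(trace, "metal_trace"))
  if (d_th <= 0) stop("d_th must be positive")
  if (lambda < 0) stop("lambda must be non-negative")
  g <- trace$geometry
  d_all <- array(Inf, dim(trace$mask))
  for (v in seq_len(g$n_views) - 1L) {
    sl <- matrix(trace$mask[v + 1L, , ], g$detector_rows, g$detector_cols)
    if (any(sl)) d_all[v + 1L, , ] <- cpp_edt(sl)
  }
  member <- !trace$mask & is.finite(d_all) & d_all < d_th
  idx <- which(member)
  d <- d_all[idx]
  w <- exp(-lambda * d)
  w_hat <- if (length(w)) w / max(w) else w
  structure(list(idx = idx, d = d, w = w, w_hat = w_hat,
                 d_th = d_th, lambda = lambda),
            class = "metal_aware_set")
}

#' Area-balanced batch sampling
#'
#' Splits a training batch between the reliable set and the metal-aware set
#' in proportion to their sizes (the sets' detector areas):
#' `n_m = round(batch_size * |R_m| / (|R_m| + |R_r \\ R_m|))`, the rest from
#' `R_r \\ R_m`. Sampling is uniform without replacement within the batch,
#' and metal-aware rays are excluded from the reliable draw, so a batch
#' never contains duplicates.
#'
#' @param r_r integer indices of the reliable rays.
#' @param r_m integer indices of the metal-aware subset (must be contained
#'   in `r_r`); may be empty.
#' @param batch_size total rays per batch (at least 2).
#' @param seed integer seed.
#' @return A list with integer vectors `rays_r` and `rays_m`.
#' @export
area_balanced_batch <- function(r_r, r_m, batch_size, seed) {
  if (batch_size < 2) stop("batch_size must be at least 2")
  if (length(setdiff(r_m, r_r))) stop("r_m must be a subset of r_r")
  r_excl <- setdiff(r_r, r_m)
  n_m <- round(batch_size * length(r_m) / (length(r_m) + length(r_excl)))
  n_m <- min(n_m, length(r_m))
  n_r <- batch_size - n_m
  if (n_r > length(r_excl))
    stop("batch_size exceeds the available rays")
  with_seed(seed, list(
    rays_r = if (n_r) r_excl[sample.int(length(r_excl), n_r)] else integer(0),
    rays_m = if (n_m) r_m[sample.int(length(r_m), n_m)] else integer(0)))
}
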