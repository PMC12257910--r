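# Prior-based sinogram inpainting: reduce the rendered field to a 3-class
# prior image, normalize the measured sinogram by the prior's projections,
# bridge the metal trace by per-row linear interpolation in the normalized
# domain, denormalize, reconstruct, and put the original metal back.

#' Three-class k-means prior image
#'
#' Clusters the voxel intensities of a (rendered) HU volume into three
#' classes, ordered by centroid as air / soft tissue / bone. Air voxels are
#' set to -1000 HU and soft tissue to 0 HU exactly; bone voxels keep their
#' original values. If the volume carries fewer than three distinct values,
#' fixed HU thresholds (-500 and 376) are used instead and a message is
#' emitted.
#'
#' @param volume a HU [att_volume()], typically the rendered NAF image.
#' @param seed seed for the k-means starts.
#' @return A list of class `prior_image`: `hu` (the prior volume), `labels`
#'   (1 = air, 2 = soft, 3 = bone), `centers`, `seed`.
#' @export
kmeans_prior <- function(volume, seed = 1L) {
  if (vol_unit(volume) != "HU") stop("kmeans_prior expects a HU volume")
  v <- as.numeric(unclass_vol(volume))
  uniq <- unique(v)
  if (length(uniq) < 3L) {
    message("fewer than 3 distinct intensities; falling back to fixed thresholds")
    lab <- ifelse(v < -500, 1L, ifelse(v < 376, 2L, 3L))
    centers <- c(-1000, 0, 1000)
  } else {
    km <- with_seed(seed,
      stats::kmeans(v, centers = 3L, nstart = 5L, iter.max = 100L))
    ord <- order(km$centers)
    lab <- match(km$cluster, ord)
    centers <- sort(as.numeric(km$centers))
  }
  hu <- v
  hu[lab == 1L] <- -1000
  hu[lab == 2L] <- 0
  dim(hu) <- dim(unclass_vol(volume))
  dim(lab) <- dim(hu)
  structure(list(hu = new_att_volume(hu, "HU"), labels = lab,
                 centers = centers, seed = seed),
            class = "prior_image")
}

#' @export
print.prior_image <- function(x, ...) {
  cat(sprintf("<prior_image: centers %s HU; air/soft/bone = %s voxels>\n",
              paste(signif(x$centers, 4), collapse = "/"),
              paste(tabulate(x$labels, 3L), collapse = "/")))
  invisible(x)
}

#' Forward-project a prior image
#'
#' Monochromatic projection of the prior at the HU reference energy:
#' HU-to-attenuation conversion followed by [forward_project()].
#'
#' @param prior a [kmeans_prior()] result (or any HU volume).
#' @param geom a [scan_geometry()].
#' @param mu_water_ref HU conversion reference.
#' @return A [projection_set()] in the line-integral domain.
#' @export
project_prior <- function(prior, geom, mu_water_ref = 0.0206) {
  vol <- if (inherits(prior, "prior_image")) prior$hu else prior
  forward_project(hu_to_mu(vol, mu_water_ref), geom)
}

#' Normalize projections by prior projections
#'
#' Pixel-wise division `q = p / max(p_prior, eps)`; the floor `eps`
#' (default 1e-7) avoids division by zero where the prior projects to
#' nothing. [denormalize_projections()] is the reverse product with the
#' same floor, so the round trip is exact wherever `p_prior >= eps`.
#'
#' @param p,p_prior line-integral arrays or [projection_set()]s of the same
#'   shape.
#' @param q the normalized array.
#' @param eps positive floor.
#' @return A numeric array of the common shape.
#' @export
normalize_projections <- function(p, p_prior, eps = 1e-7) {
  pa <- if (inherits(p, "projection_set")) p$data else p
  pb <- if (inherits(p_prior, "projection_set")) p_prior$data else p_prior
  if (!identical(dim(pa), dim(pb))) stop("shape mismatch")
  pa / pmax(pb, eps)
}

#' @rdname normalize_projections
#' @export
denormalize_projections <- function(q, p_prior, eps = 1e-7) {
  pb <- if (inherits(p_prior, "projection_set")) p_prior$data else p_prior
  if (!identical(dim(q), dim(pb))) stop("shape mismatch")
  q * pmax(pb, eps)
}

# linear bridge across one run of masked columns given the flanking values;
# runs touching an edge extend the nearest valid value
bridge_run <- function(vals, mask) {
  n <- length(vals)
  out <- vals
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    a <- starts[k]; b <- ends[k]
    left <- if (a > 1L) vals[a - 1L] else NA_real_
    right <- if (b < n) vals[b + 1L] else NA_real_
    if (is.na(left) && is.na(right)) return(rep(NA_real_, n))  # full row
    if (is.na(left)) left <- right
    if (is.na(right)) right <- left
    idx <- a:b
    out[idx] <- left + (right - left) * (idx - (a - 1L)) / ((b + 1L) - (a - 1L))
  }
  out
}

#' Inpaint the metal trace of a sinogram
#'
#' Per view and per detector row, every maximal run of trace pixels is
#' replaced by 1D linear interpolation between its nearest off-trace
#' neighbors along the detector columns; runs touching a row edge extend
#' the nearest valid value. Pixels outside the trace are untouched. A row
#' that lies entirely inside the trace is filled with the mean of the
#' nearest rows (same view) that have off-trace data; in single-row
#' geometries, with the mean of the neighboring views' rows.
#'
#' @param q array `(n_views, rows, cols)` — usually normalized projections,
#'   or raw line integrals for the LI baseline.
#' @param trace a `metal_trace` (or a logical array of the same shape).
#' @return The inpainted array.
#' @export
interpolate_trace <- function(q, trace) {
  tm <- if (inherits(trace, "metal_trace")) trace$mask else trace
  if (!identical(dim(q), dim(tm))) stop("trace shape mismatch")
  d <- dim(q)
  out <- q
  full_rows <- 0L
  for (v in seq_len(d[1])) {
    fullrow <- logical(d[2])
    for (r in seq_len(d[2])) {
      m <- tm[v, r, ]
      if (!any(m)) next
      br <- bridge_run(q[v, r, ], m)
      if (all(is.na(br))) fullrow[r] <- TRUE else out[v, r, ] <- br
    }
    for (r in which(fullrow)) {
      full_rows <- full_rows + 1L
      near <- which(!fullrow)
      near <- near[order(abs(near - r))]
      near <- near[seq_len(min(2L, length(near)))]
      if (length(near)) {
        out[v, r, ] <- colMeans(matrix(out[v, near, ], nrow = length(near)))
      } else {
        # single-row geometry: borrow the neighboring views
        vprev <- if (v > 1) v - 1L else d[1]
        vnext <- if (v < d[1]) v + 1L else 1L
        out[v, r, ] <- (q[vprev, r, ] + q[vnext, r, ]) / 2
      }
    }
  }
  if (full_rows > 0L)
    message(full_rows, " detector row(s) entirely inside the trace were filled from neighbors")
  out
}

#' Denormalize, reconstruct and reinsert metal
#'
#' Final stage of the inpainting pipeline: the interpolated normalized
#' sinogram is multiplied back by the (floored) prior projections; outside
#' the metal trace the corrected sinogram is copied bit-for-bit from the
#' original measurements (sinogram consistency); the result is
#' reconstructed by FBP, converted to HU, and the voxels of the metal mask
#' are overwritten with the uncorrected reconstruction's values so the
#' implants stay visible.
#'
#' @param q_star inpainted normalized projections (array).
#' @param p_prior prior line integrals ([projection_set()] or array).
#' @param trace the `metal_trace` used for inpainting.
#' @param original the measured line-integral [projection_set()].
#' @param geom a [scan_geometry()].
#' @param metal_mask logical volume of metal voxels to reinsert.
#' @param uncorrected_hu the uncorrected FBP volume in HU.
#' @param eps normalization floor, must match [normalize_projections()].
#' @param kernel reconstruction kernel.
#' @return A list: `volume` (final HU [att_volume()]) and `projections`
#'   (corrected line-integral [projection_set()]).
#' @export
denormalize_and_reconstruct <- function(q_star, p_prior, trace, original,
                                        geom, metal_mask, uncorrected_hu,
                                        eps = 1e-7, kernel = "ram-lak") {
  stopifnot(inherits(original, "projection_set"),
            original$domain == "line_integral")
  tm <- if (inherits(trace, "metal_trace")) trace$mask else trace
  p_corr <- denormalize_projections(q_star, p_prior, eps)
  p_corr[!tm] <- original$data[!tm]   # exact off-trace consistency
  ps <- projection_set(p_corr, "line_integral", I0 = original$I0,
                       geometry = geom)
  vol <- mu_to_hu(fbp_reconstruct(ps, geom, kernel))
  if (!is.null(metal_mask)) {
    stopifnot(identical(dim(metal_mask), dim(unclass_vol(vol))))
    vol[metal_mask] <- unclass_vol(uncorrected_hu)[metal_mask]
  }
  list(volume = vol, projections = ps)
}
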