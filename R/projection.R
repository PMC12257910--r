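#' Attenuation volumes
#'
#' A thin wrapper tagging a numeric array with its unit: `"mm^-1"` for linear
#' attenuation coefficients or `"HU"` for Hounsfield units. The array always
#' has three dimensions `(nx, ny, nz)`; fan-beam slices use `nz = 1`.
#'
#' @param values numeric array (2D arrays are promoted to `nz = 1`).
#' @param unit `"mm^-1"` or `"HU"`.
#' @return The array with a `unit` attribute, class `att_volume`.
#' @export
att_volume <- function(values, unit = c("mm^-1", "HU")) {
  unit <- match.arg(unit)
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) stop("values must be a 2D or 3D array")
  if (any(!is.finite(values))) stop("attenuation values must be finite")
  if (unit == "mm^-1" && any(values < 0))
    stop("attenuation in mm^-1 must be non-negative")
  if (unit == "HU" && any(values < -1000))
    stop("HU values below -1000 (air floor) are not allowed")
  structure(values, unit = unit, class = c("att_volume", "array"))
}

# unchecked constructor for reconstruction outputs, which may carry small
# negative filter ringing in mm^-1
new_att_volume <- function(values, unit) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  structure(values, unit = unit, class = c("att_volume", "array"))
}

vol_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) "mm^-1" else u
}

#' @export
print.att_volume <- function(x, ...) {
  cat(sprintf("<att_volume %s [%s], range %.4g..%.4g>\n",
              paste(dim(x), collapse = "x"), vol_unit(x), min(x), max(x)))
  invisible(x)
}

#' Projection sets
#'
#' Per-view detector measurements in either the intensity domain (`I`,
#' photons) or the line-integral domain (`p = -ln(I / I0)`). The data array
#' has dimensions `(n_views, detector_rows, detector_cols)`.
#'
#' @param data numeric array of that shape.
#' @param domain `"intensity"` or `"line_integral"`.
#' @param I0 initial (unattenuated) intensity; may be `NA` in the
#'   line-integral domain.
#' @param geometry the [scan_geometry()] the data belong to.
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(data, domain = c("line_integral", "intensity"),
                           I0 = NA_real_, geometry = NULL) {
  domain <- match.arg(domain)
  if (!is.null(geometry)) {
    want <- c(geometry$n_views, geometry$detector_rows, geometry$detector_cols)
    if (!identical(as.integer(dim(data)), as.integer(want)))
      stop("projection array shape does not match geometry")
  }
  if (domain == "intensity" && any(data < 0))
    stop("intensities must be non-negative")
  structure(list(data = data, domain = domain, I0 = I0, geometry = geometry),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set %s [%s], I0 = %s, range %.4g..%.4g>\n",
              paste(dim(x$data), collapse = "x"), x$domain,
              format(x$I0), min(x$data), max(x$data)))
  invisible(x)
}

#' Discrete Beer-Lambert line integral
#'
#' The discrete attenuation model along one ray:
#' `I = I0 * exp(-sum(mu * delta))`, with per-sample attenuation coefficients
#' `mu` (mm^-1) and path steps `delta` (mm).
#'
#' @param mu_samples,deltas equal-length numeric vectors.
#' @param I0 initial intensity.
#' @return The transmitted intensity.
#' @examples
#' discrete_line_integral(0.02, 50, 1)  # exp(-1)
#' @export
discrete_line_integral <- function(mu_samples, deltas, I0 = 1) {
  if (length(mu_samples) != length(deltas))
    stop("mu_samples and deltas must have equal length")
  if (any(!is.finite(mu_samples)) || any(!is.finite(deltas)))
    stop("inputs must be finite")
  if (any(deltas < 0)) stop("negative path steps are not allowed")
  I0 * exp(-sum(mu_samples * deltas))
}

#' Forward projection
#'
#' Ray-driven line integrals of an attenuation volume over all views of a
#' scan geometry: each detector pixel gets `p = sum(mu_i * delta_i)` along
#' its ray, with trilinear in-volume sampling at a uniform step of
#' `step_frac * min(voxel_size)` and zero contribution outside the volume.
#'
#' @param volume an [att_volume()] in mm^-1 (HU volumes must be converted
#'   with [hu_to_mu()] first) or a plain array taken to be mm^-1.
#' @param geom a [scan_geometry()] whose `volume_shape` matches the volume.
#' @param step_frac ray-sampling step as a fraction of the smallest voxel
#'   edge (default 0.5).
#' @return A [projection_set()] in the line-integral domain.
#' @export
forward_project <- function(volume, geom, step_frac = 0.5) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (vol_unit(volume) == "HU")
    stop("volume is in HU; convert with hu_to_mu() before projecting")
  if (is.matrix(volume)) dim(volume) <- c(dim(volume), 1L)
  if (!identical(as.integer(dim(volume)), geom$volume_shape))
    stop("volume shape does not match geometry$volume_shape")
  step <- step_frac * min(geom$voxel_size_mm)
  p <- cpp_forward_project(as.double(volume), as_geom_list(geom), step)
  projection_set(p, "line_integral", I0 = NA_real_, geometry = geom)
}

#' Log and exponential transforms between projection domains
#'
#' `log_transform()` maps intensities to line integrals,
#' `p = -ln(max(I, floor) / I0)`; the floor (default 1 count) guards the
#' logarithm against photon starvation (zero detected counts behind dense
#' metal). `exp_transform()` is the inverse, `I = I0 * exp(-p)`, and the two
#' compose to the identity wherever `I >= floor`.
#'
#' @param projections a [projection_set()] in the matching domain.
#' @param floor smallest count admitted into the log (default 1).
#' @param I0 initial intensity; taken from the projection set if present.
#' @return A [projection_set()] in the other domain.
#' @export
log_transform <- function(projections, floor = 1, I0 = projections$I0) {
  stopifnot(inherits(projections, "projection_set"))
  if (projections$domain != "intensity")
    stop("log_transform expects intensity-domain projections")
  if (!is.finite(I0) || I0 <= 0) stop("I0 must be positive")
  p <- -log(pmax(projections$data, floor) / I0)
  projection_set(p, "line_integral", I0 = I0, geometry = projections$geometry)
}

#' @rdname log_transform
#' @export
exp_transform <- function(projections, I0 = projections$I0) {
  stopifnot(inherits(projections, "projection_set"))
  if (projections$domain != "line_integral")
    stop("exp_transform expects line-integral projections")
  if (!is.finite(I0) || I0 <= 0) stop("I0 must be positive")
  projection_set(I0 * exp(-projections$data), "intensity", I0 = I0,
                 geometry = projections$geometry)
}

#' Convert between Hounsfield units and linear attenuation
#'
#' `mu = mu_water_ref * (1 + HU / 1000)`, so water maps to `mu_water_ref`
#' and air (-1000 HU) to zero. The default reference
#' `mu_water_ref = 0.0206` mm^-1 corresponds to water at roughly 60-70 keV
#' effective energy, the scale on which the simulator's ground-truth HU
#' values are defined.
#'
#' @param volume an [att_volume()] (or plain array) in the source unit.
#' @param mu_water_ref water attenuation reference in mm^-1.
#' @return An [att_volume()] in the target unit.
#' @export
hu_to_mu <- function(volume, mu_water_ref = 0.0206) {
  if (vol_unit(volume) != "HU" && inherits(volume, "att_volume"))
    stop("volume is not tagged HU")
  mu <- mu_water_ref * (1 + unclass_vol(volume) / 1000)
  att_volume(pmax(mu, 0), "mm^-1")
}

#' @rdname hu_to_mu
#' @export
mu_to_hu <- function(volume, mu_water_ref = 0.0206) {
  if (vol_unit(volume) == "HU") stop("volume is already HU")
  hu <- 1000 * (unclass_vol(volume) / mu_water_ref - 1)
  att_volume(pmax(hu, -1000), "HU")
}

unclass_vol <- function(x) {
  a <- unclass(x)
  attr(a, "unit") <- NULL
  if (is.matrix(a)) dim(a) <- c(dim(a), 1L)
  a
}
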