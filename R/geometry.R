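#' Describe a CT acquisition geometry
#'
#' A scan geometry ties together the source trajectory (circular, fan-beam in
#' 2D or cone-beam in 3D), the flat-panel detector grid and the reconstruction
#' volume grid. The iso-center sits at the volume center; voxel and detector
#' pixel centers are at half-integer positions (0-based indexing); view `i` is
#' acquired at angle `angle_start + i * angle_span / n_views`.
#'
#' @param mode `"fanbeam2d"` (single detector row, single slice) or
#'   `"conebeam3d"`.
#' @param source_to_iso_mm,source_to_detector_mm source-to-iso-center and
#'   source-to-detector distances in mm; the latter must be the larger.
#' @param n_views number of projection views over `angle_span`.
#' @param angle_start,angle_span start angle and angular coverage in radians.
#'   A full turn (the default) is assumed by the reconstruction weighting.
#' @param detector_cols,detector_rows detector grid size (u = columns,
#'   v = rows). `detector_rows` must be 1 in fan-beam mode.
#' @param pixel_pitch_mm detector pixel pitch in mm (square pixels).
#' @param volume_shape integer vector `c(nx, ny, nz)`; `nz = 1` in fan-beam
#'   mode.
#' @param voxel_size_mm voxel edge lengths in mm, recycled to length 3.
#' @return An object of class `scan_geometry`.
#' @seealso [geom_preset()] for ready-made configurations.
#' @export
scan_geometry <- function(mode = c("fanbeam2d", "conebeam3d"),
                          source_to_iso_mm, source_to_detector_mm,
                          n_views, angle_start = 0, angle_span = 2 * pi,
                          detector_cols, detector_rows = 1L,
                          pixel_pitch_mm, volume_shape, voxel_size_mm) {
  mode <- match.arg(mode)
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  volume_shape <- as.integer(rep_len(volume_shape, 3L))
  g <- list(mode = mode,
            source_to_iso_mm = as.numeric(source_to_iso_mm),
            source_to_detector_mm = as.numeric(source_to_detector_mm),
            n_views = as.integer(n_views),
            angle_start = as.numeric(angle_start),
            angle_span = as.numeric(angle_span),
            detector_cols = as.integer(detector_cols),
            detector_rows = as.integer(detector_rows),
            pixel_pitch_mm = as.numeric(pixel_pitch_mm),
            volume_shape = volume_shape,
            voxel_size_mm = voxel_size_mm)
  if (!(g$source_to_detector_mm > g$source_to_iso_mm) ||
      !(g$source_to_iso_mm > 0))
    stop("need source_to_detector_mm > source_to_iso_mm > 0")
  if (g$pixel_pitch_mm <= 0) stop("pixel_pitch_mm must be positive")
  if (g$n_views < 1L) stop("n_views must be at least 1")
  if (any(c(g$detector_cols, g$detector_rows, g$volume_shape) < 1L))
    stop("all counts must be at least 1")
  if (mode == "fanbeam2d" && (g$detector_rows != 1L || g$volume_shape[3] != 1L))
    stop("fanbeam2d requires detector_rows = 1 and volume_shape[3] = 1")
  if (any(g$voxel_size_mm <= 0)) stop("voxel_size_mm must be positive")
  class(g) <- "scan_geometry"
  g
}

#' Preset scan geometries
#'
#' `"paper"` is a dental CBCT setup: 560/1000 mm source distances, a 512 x 64
#' detector at 1.286 mm pitch, 512 views over a full turn and a
#' 512 x 512 x 100 volume at 0.4 mm voxels. `"desk"` is the reduced 2D
#' fan-beam configuration used throughout the test suite and examples:
#' 300/500 mm, a 192-column single-row detector at 1.2 mm pitch, 180 views
#' and a 128 x 128 slice at 1 mm voxels.
#'
#' @param name `"desk"` or `"paper"`.
#' @param ... overrides passed on to [scan_geometry()].
#' @return A `scan_geometry`.
#' @export
geom_preset <- function(name = c("desk", "paper"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    desk = list(mode = "fanbeam2d", source_to_iso_mm = 300,
                source_to_detector_mm = 500, n_views = 180L,
                detector_cols = 192L, detector_rows = 1L,
                pixel_pitch_mm = 1.2, volume_shape = c(128L, 128L, 1L),
                voxel_size_mm = 1.0),
    paper = list(mode = "conebeam3d", source_to_iso_mm = 560,
                 source_to_detector_mm = 1000, n_views = 512L,
                 detector_cols = 512L, detector_rows = 64L,
                 pixel_pitch_mm = 1.286, volume_shape = c(512L, 512L, 100L),
                 voxel_size_mm = 0.4))
  args[names(list(...))] <- list(...)
  do.call(scan_geometry, args)
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry: %s>\n", x$mode))
  cat(sprintf("  source-iso %.1f mm, source-detector %.1f mm\n",
              x$source_to_iso_mm, x$source_to_detector_mm))
  cat(sprintf("  %d views over %.1f deg from %.1f deg\n", x$n_views,
              x$angle_span * 180 / pi, x$angle_start * 180 / pi))
  cat(sprintf("  detector %d x %d @ %.3f mm\n", x$detector_rows,
              x$detector_cols, x$pixel_pitch_mm))
  cat(sprintf("  volume %s @ %s mm\n",
              paste(x$volume_shape, collapse = "x"),
              paste(signif(x$voxel_size_mm, 3), collapse = "x")))
  invisible(x)
}

as_geom_list <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  unclass(geom)
}

geom_half_extent <- function(geom) {
  geom$volume_shape * geom$voxel_size_mm / 2
}

#' Generate detector rays for one view
#'
#' One ray per detector pixel, from the source through the pixel center, with
#' entry/exit parameters (`t_near`, `t_far`, mm from the source) against the
#' reconstruction volume's bounding box. `t_near = t_far = 0` marks a ray
#' that misses the volume.
#'
#' @param geom a [scan_geometry()].
#' @param view 0-based view index, `0 <= view < n_views`.
#' @return A list with matrices `origin`, `direction` (n x 3, unit rows) and
#'   vectors `t_near`, `t_far`, `view`, `row`, `col` (0-based), ordered to
#'   match the projection array layout.
#' @export
generate_rays <- function(geom, view) {
  stopifnot(inherits(geom, "scan_geometry"))
  view <- as.integer(view)
  if (view < 0L || view >= geom$n_views)
    stop("view out of range [0, n_views)")
  cpp_rays(as_geom_list(geom), view)
}

all_rays <- function(geom) cpp_rays(as_geom_list(geom), -1L)
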