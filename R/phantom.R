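# Procedural dental-like phantoms: a soft-tissue head ellipse, a U-shaped
# jaw arch of bone carrying a row of teeth, and 2-5 gold inserts placed in
# randomly chosen teeth. Units: HU for the ground-truth volume, fractional
# densities (relative to the material table's nominal density) for the
# simulator's material weights.

#' Specify a dental phantom
#'
#' Parameters of the procedural phantom used by the simulator in place of
#' patient data. All lengths are in mm in the iso-centered world frame; the
#' volume grid comes from the scan geometry at generation time.
#'
#' @param n_metal number of metal (gold) inserts, 2 to 5.
#' @param head_semiaxes_mm semi-axes of the soft-tissue head ellipse.
#' @param arch_center_mm,arch_radius_mm,arch_halfwidth_mm,arch_angles_deg
#'   jaw arch: center offset, mid radius, half thickness and angular range
#'   (degrees, measured from +x, the arch opening away from this range).
#' @param n_teeth number of teeth along the arch.
#' @param tooth_radius_mm tooth disk radius.
#' @param metal_radius_mm range of insert radii; each insert draws its size
#'   (and a disk or square shape) from this range.
#' @param jaw_density,teeth_density fractional bone density of jaw and teeth
#'   relative to cortical bone.
#' @param texture_amp_hu,texture_freq_cpmm amplitude (HU) and maximum
#'   spatial frequency (cycles/mm) of the seeded soft-tissue texture field
#'   (a sum of oriented cosine waves; gives the tissue the kind of detail a
#'   coordinate network blurs but filtered backprojection preserves).
#' @param seed integer seed making the phantom deterministic.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_metal = 3L,
                         head_semiaxes_mm = c(52, 44),
                         arch_center_mm = c(0, 2),
                         arch_radius_mm = 30,
                         arch_halfwidth_mm = 5,
                         arch_angles_deg = c(200, 340),
                         n_teeth = 9L,
                         tooth_radius_mm = 3.4,
                         metal_radius_mm = c(1.2, 2.2),
                         jaw_density = 0.65,
                         teeth_density = 0.80,
                         texture_amp_hu = 18,
                         texture_freq_cpmm = 0.18,
                         seed = 1L) {
  n_metal <- as.integer(n_metal)
  if (n_metal < 2L || n_metal > 5L)
    stop("n_metal must be between 2 and 5")
  if (n_metal > n_teeth) stop("more metal inserts than teeth")
  spec <- list(n_metal = n_metal, head_semiaxes_mm = head_semiaxes_mm,
               arch_center_mm = arch_center_mm, arch_radius_mm = arch_radius_mm,
               arch_halfwidth_mm = arch_halfwidth_mm,
               arch_angles_deg = arch_angles_deg, n_teeth = as.integer(n_teeth),
               tooth_radius_mm = tooth_radius_mm,
               metal_radius_mm = metal_radius_mm,
               jaw_density = jaw_density, teeth_density = teeth_density,
               texture_amp_hu = texture_amp_hu,
               texture_freq_cpmm = texture_freq_cpmm,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# HU values implied by the material table at the reference energy
phantom_hu_values <- function(jaw_density = 0.65, teeth_density = 0.80) {
  tab <- material_attenuation()
  ref <- which(tab$energy_keV == 60)
  list(soft = 1000 * (tab$soft_tissue[ref] / tab$water[ref] - 1),
       jaw = 1000 * (jaw_density * tab$bone[ref] / tab$water[ref] - 1),
       teeth = 1000 * (teeth_density * tab$bone[ref] / tab$water[ref] - 1),
       metal = 1000 * (tab$gold[ref] / tab$water[ref] - 1))
}

#' Generate a dental-like phantom on a scan geometry's grid
#'
#' Builds the ground-truth metal-free HU volume together with disjoint
#' material masks and the metal-insert mask. HU classes: air -1000, soft
#' tissue about +43, jaw bone about +880, teeth about +1350, and gold
#' inserts (when painted in) far above 3000 HU. In 3D geometries the slice
#' pattern is extruded along z. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param geom a [scan_geometry()] supplying the volume grid.
#' @return A list with `hu` (ground-truth metal-free [att_volume()]),
#'   `hu_metal` (the same volume with inserts painted in), logical
#'   majority-vote arrays `soft`, `bone`, `metal`, the density-weight arrays
#'   `soft_w`, `bone_w` and the metal coverage `metal_frac` used by the
#'   polychromatic projector, `hu_values`, and the spec.
#' @export
make_dental_phantom <- function(spec, geom) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(geom, "scan_geometry"))
  nx <- geom$volume_shape[1]; ny <- geom$volume_shape[2]
  nz <- geom$volume_shape[3]
  vx <- geom$voxel_size_mm[1]; vy <- geom$voxel_size_mm[2]
  x <- (seq_len(nx) - 0.5 - nx / 2) * vx
  y <- (seq_len(ny) - 0.5 - ny / 2) * vy
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)
  # structures are rasterized with 3x3 sub-voxel supersampling so that class
  # coverage fractions give band-limited (partial-volume) edges, as a real
  # scanner's PSF would; sharp binary masks would add Gibbs ringing that no
  # reconstruction could be fairly scored against
  ss <- 3L
  xf <- (seq_len(nx * ss) - 0.5 - nx * ss / 2) * (vx / ss)
  yf <- (seq_len(ny * ss) - 0.5 - ny * ss / 2) * (vy / ss)
  Xf <- matrix(xf, nx * ss, ny * ss)
  Yf <- matrix(yf, nx * ss, ny * ss, byrow = TRUE)
  blockmean <- function(m) {
    s1 <- colSums(array(m, c(ss, nx, ss * ny)))      # collapse sub-rows
    a <- array(s1, c(nx, ss, ny))
    out <- a[, 1, ]
    for (k in 2:ss) out <- out + a[, k, ]
    out / (ss * ss)
  }

  a <- spec$head_semiaxes_mm[1]; b <- spec$head_semiaxes_mm[2]
  half_ext <- geom_half_extent(geom)
  if (a >= half_ext[1] || b >= half_ext[2])
    stop("head ellipse does not fit inside the volume")
  head_f <- (Xf / a)^2 + (Yf / b)^2 <= 1

  cc <- spec$arch_center_mm
  R <- spec$arch_radius_mm
  hw <- spec$arch_halfwidth_mm
  ang <- atan2(Yf - cc[2], Xf - cc[1]) * 180 / pi
  ang <- (ang + 360) %% 360
  rr <- sqrt((Xf - cc[1])^2 + (Yf - cc[2])^2)
  a0 <- spec$arch_angles_deg[1]; a1 <- spec$arch_angles_deg[2]
  jaw_f <- rr >= R - hw & rr <= R + hw & ang >= a0 & ang <= a1 & head_f

  tooth_ang <- seq(a0 + 6, a1 - 6, length.out = spec$n_teeth)
  tcx <- cc[1] + R * cos(tooth_ang * pi / 180)
  tcy <- cc[2] + R * sin(tooth_ang * pi / 180)
  if (any((tcx / a)^2 + (tcy / b)^2 > 1))
    stop("tooth centers fall outside the head ellipse")
  teeth_f <- matrix(FALSE, nx * ss, ny * ss)
  for (k in seq_len(spec$n_teeth))
    teeth_f <- teeth_f |
      (Xf - tcx[k])^2 + (Yf - tcy[k])^2 <= spec$tooth_radius_mm^2

  rng_draws <- with_seed(spec$seed, {
    picks <- sample(spec$n_teeth, spec$n_metal)
    info <- lapply(picks, function(k) {
      r <- stats::runif(1, spec$metal_radius_mm[1], spec$metal_radius_mm[2])
      shape <- sample(c("disk", "square"), 1)
      jit <- stats::runif(2, -0.8, 0.8)
      list(center = c(tcx[k] + jit[1], tcy[k] + jit[2]), radius = r,
           shape = shape)
    })
    # soft-tissue texture: a few smooth waves plus finer detail the field
    # tends to blur (spectral bias), which the inpainting stage preserves
    ntex <- 8L
    tex <- list(freq = matrix(stats::runif(2 * ntex, -spec$texture_freq_cpmm,
                                           spec$texture_freq_cpmm), 2),
                phase = stats::runif(ntex, 0, 2 * pi),
                amp = spec$texture_amp_hu *
                  stats::runif(ntex, 0.4, 1) / sqrt(ntex / 2))
    list(info = info, tex = tex)
  })
  metal_info <- rng_draws$info
  tex <- rng_draws$tex
  metal_f <- matrix(FALSE, nx * ss, ny * ss)
  for (m in metal_info) {
    inside <- if (m$shape == "disk")
      (Xf - m$center[1])^2 + (Yf - m$center[2])^2 <= m$radius^2
    else
      abs(Xf - m$center[1]) <= m$radius & abs(Yf - m$center[2]) <= m$radius
    metal_f <- metal_f | inside
  }
  metal_f <- metal_f & teeth_f  # implants sit inside teeth (fillings/crowns)

  # exclusive class hierarchy on the fine grid, then coverage fractions
  teeth_f <- teeth_f & !metal_f
  jaw_f <- jaw_f & !teeth_f & !metal_f
  soft_f <- head_f & !jaw_f & !teeth_f & !metal_f
  f_metal <- blockmean(metal_f)
  f_teeth <- blockmean(teeth_f)
  f_jaw <- blockmean(jaw_f)
  f_soft <- blockmean(soft_f)
  f_air <- pmax(1 - f_metal - f_teeth - f_jaw - f_soft, 0)

  huv <- phantom_hu_values(spec$jaw_density, spec$teeth_density)
  texture <- matrix(0, nx, ny)
  for (k in seq_along(tex$phase))
    texture <- texture + tex$amp[k] *
      cos(2 * pi * (tex$freq[1, k] * X + tex$freq[2, k] * Y) + tex$phase[k])
  hu_soft_val <- huv$soft + texture

  # partial-volume blended HU; the metal-free ground truth treats the
  # implant volume as tooth material
  hu2 <- f_air * (-1000) + f_soft * hu_soft_val + f_jaw * huv$jaw +
    (f_teeth + f_metal) * huv$teeth
  humet2 <- f_air * (-1000) + f_soft * hu_soft_val + f_jaw * huv$jaw +
    f_teeth * huv$teeth + f_metal * huv$metal

  # majority-vote logical masks (disjoint by construction)
  metal <- f_metal >= 0.5
  bone <- (f_jaw + f_teeth) >= 0.5 & !metal
  soft <- f_soft >= 0.5 & !bone & !metal

  # textured soft tissue projects as water-like material with a density
  # weight matching its HU at the reference energy
  tab <- material_attenuation()
  ref <- which(tab$energy_keV == 60)
  soft_w2 <- f_soft * (1 + hu_soft_val / 1000) * tab$water[ref] /
    tab$soft_tissue[ref]
  bone_w2 <- f_jaw * spec$jaw_density + f_teeth * spec$teeth_density

  rep3 <- function(m) array(m, dim = c(nx, ny, nz))
  out <- list(hu = att_volume(rep3(hu2), "HU"),
              hu_metal = att_volume(rep3(humet2), "HU"),
              soft = rep3(soft), bone = rep3(bone), metal = rep3(metal),
              soft_w = rep3(soft_w2), bone_w = rep3(bone_w2),
              metal_frac = rep3(f_metal),
              hu_values = huv, metal_info = metal_info, spec = spec)
  if (!any(out$metal)) stop("phantom has an empty metal mask")
  class(out) <- "dental_phantom"
  out
}

#' Threshold a HU volume into material classes
#'
#' Partitions the non-air voxels of a HU volume into soft tissue, bone and
#' metal with fixed thresholds; air is everything below `air_hu`. The three
#' returned masks are pairwise disjoint and, together with air, cover the
#' volume.
#'
#' @param volume a HU [att_volume()].
#' @param soft_bone_hu soft-tissue/bone threshold (default 376 HU, a common
#'   choice in polychromatic artifact simulation).
#' @param metal_hu bone/metal threshold (default 2000 HU, the clinical
#'   metal-segmentation threshold).
#' @param air_hu air/soft-tissue threshold (default -500 HU).
#' @return A list of logical arrays `soft`, `bone`, `metal` (and `air`).
#' @export
segment_materials <- function(volume, soft_bone_hu = 376, metal_hu = 2000,
                              air_hu = -500) {
  if (vol_unit(volume) != "HU") stop("segment_materials expects a HU volume")
  v <- unclass_vol(volume)
  air <- v < air_hu
  metal <- v >= metal_hu
  bone <- v >= soft_bone_hu & !metal
  soft <- !air & !bone & !metal
  list(soft = soft, bone = bone, metal = metal, air = air)
}
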