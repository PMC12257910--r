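# Shared fixtures. Everything is generated in code; the heavier pipeline
# runs used by several acceptance checks are computed once per session and
# memoized here.

tiny_geom <- function(n_views = 24L, cols = 48L, n = 32L, vox = 2) {
  scan_geometry("fanbeam2d", 300, 500, n_views = n_views,
                detector_cols = cols, pixel_pitch_mm = 3.2,
                volume_shape = c(n, n, 1L), voxel_size_mm = vox)
}

small_geom <- function() {
  scan_geometry("fanbeam2d", 300, 500, n_views = 60L, detector_cols = 96L,
                pixel_pitch_mm = 2.4, volume_shape = c(64L, 64L, 1L),
                voxel_size_mm = 2)
}

# geometry used for the seeded MAR cases (reduced desk scale)
case_geom <- function() {
  scan_geometry("fanbeam2d", 300, 500, n_views = 120L, detector_cols = 144L,
                pixel_pitch_mm = 1.5, volume_shape = c(128L, 128L, 1L),
                voxel_size_mm = 1)
}

# a tiny field configuration for gradient checks and determinism tests
tiny_naf_config <- function(epochs = 2L, ...) {
  naf_config("desk-fast", n_levels = 4L, features_per_level = 2L,
             hash_log2 = 8L, base_resolution = 4L, finest_resolution = 16L,
             width = 16L, n_samples = 16L, batch_rays = 32L, epochs = epochs,
             seed = 42L, ...)
}

# anti-aliased uniform disk on an n^2 grid (mm^-1)
disk_volume <- function(n, vox, radius, mu = 0.02, ss = 4L) {
  xs <- (seq_len(n * ss) - 0.5 - n * ss / 2) * (vox / ss)
  X <- matrix(xs, n * ss, n * ss)
  Y <- t(X)
  cov <- (X^2 + Y^2 <= radius^2) * 1
  s1 <- colSums(array(cov, c(ss, n, ss * n)))
  a <- array(s1, c(n, ss, n))
  out <- a[, 1, ]
  for (k in 2:ss) out <- out + a[, k, ]
  att_volume(mu * out / (ss * ss), "mm^-1")
}

# simple connected-component labeling (4-connectivity) for mask checks
label_components <- function(mask) {
  m <- which(mask, arr.ind = TRUE)[, 1:2, drop = FALSE]
  if (!nrow(m)) return(0L)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(m))) {
    r <- m[i, 1]; c <- m[i, 2]
    if (lab[r, c] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r, c)); lab[r, c] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
            q[2] <= ncol(mask) && mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue <- c(queue, list(q))
        }
      }
    }
  }
  cur
}

# strip the att_volume class/unit so identical() compares raw arrays
unclass_v <- function(x) {
  a <- unclass(x); attributes(a) <- list(dim = dim(x)); a
}

.acc_cache <- new.env(parent = emptyenv())

# a small shared simulated case for cheap cross-module tests
shared_case <- function() {
  if (is.null(.acc_cache$shared_case)) {
    g <- case_geom()
    .acc_cache$shared_case <- simulate_case(phantom_spec(n_metal = 3, seed = 7),
                                            g, seed = 7)
  }
  .acc_cache$shared_case
}

# the three seeded MAR cases behind the scaled-down method comparison:
# full pipeline, no-metal-aware ablation and LI baseline per case
mar_cases <- function() {
  if (is.null(.acc_cache$mar_cases)) {
    g <- case_geom()
    .acc_cache$mar_cases <- lapply(c(101L, 102L, 103L), function(sd) {
      case <- simulate_case(phantom_spec(n_metal = 3, seed = sd), g, seed = sd)
      cfg <- naf_config("desk-fast", seed = sd)
      mar <- mar_correct(case$proj_corrupted, g, cfg,
                         metal_mask = case$metal_mask)
      cfg0 <- naf_config("desk-fast", seed = sd, lambda_m = 0)
      mar0 <- mar_correct(case$proj_corrupted, g, cfg0,
                          metal_mask = case$metal_mask)
      li <- li_baseline(case$proj_corrupted, mar$trace, g,
                        metal_mask = case$metal_mask,
                        uncorrected_hu = case$fbp_uncorrected)
      gt <- case$gt_hu; msk <- case$metal_mask
      list(seed = sd, case = case, mar = mar, mar_noma = mar0, li = li,
           m_unc = evaluate_mar(case$fbp_uncorrected, gt, msk),
           m_li = evaluate_mar(li$volume, gt, msk),
           m_naf = evaluate_mar(mar$volume, gt, msk),
           m_noma = evaluate_mar(mar0$volume, gt, msk),
           m_nafimg = evaluate_mar(mar$naf_image, gt, msk))
    })
  }
  .acc_cache$mar_cases
}

# clean-recovery experiment: field trained on uncorrupted projections of a
# desk-scale phantom, rendered and scored against the phantom
clean_recovery <- function() {
  if (is.null(.acc_cache$clean_recovery)) {
    g <- geom_preset("desk")
    ph <- make_dental_phantom(phantom_spec(n_metal = 3, seed = 7), g)
    ps <- forward_project(hu_to_mu(ph$hu), g)
    fit <- naf_fit(ps, g, trace = NULL, config = naf_config("desk", seed = 1))
    vol <- render_volume(fit)
    .acc_cache$clean_recovery <-
      list(fit = fit, volume = vol, phantom = ph,
           metrics = evaluate_mar(vol, ph$hu, NULL))
  }
  .acc_cache$clean_recovery
}
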