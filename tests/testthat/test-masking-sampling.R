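# Metal trace identification, distance transforms, metal-aware weights and
# the area-balanced batch sampler.

test_that("metal segmentation uses an inclusive threshold", {
  v <- att_volume(array(c(1500, 1999.9, 2000, 2500), c(4, 1, 1)), "HU")
  m <- segment_metal_volume(v, 2000)
  expect_equal(as.logical(m), c(FALSE, FALSE, TRUE, TRUE))
  low <- att_volume(array(1500, c(3, 3, 1)), "HU")
  expect_false(any(segment_metal_volume(low, 2000)))
})

test_that("segmented metal overlaps the ground-truth mask on simulated data", {
  # thresholded metal blooms outward (photon starvation saturates the
  # projections, FBP smears the excess), so the clinical 2000 HU mask is a
  # dilated superset of the true insert: recall is what MAR needs — a
  # trace that covers every corrupted ray — while Dice is bounded by the
  # bloom at this voxel size (measured ~0.5 at 1 mm, ~0.7 at 0.5 mm)
  case <- shared_case()
  seg <- segment_metal_volume(case$fbp_uncorrected, 2000)
  recall <- sum(seg & case$metal_mask) / sum(case$metal_mask)
  expect_gte(recall, 0.9)
  dice <- 2 * sum(seg & case$metal_mask) / (sum(seg) + sum(case$metal_mask))
  expect_gte(dice, 0.45)
})

test_that("the metal trace is the strict support of projected metal", {
  g <- tiny_geom()
  empty <- array(FALSE, c(32, 32, 1))
  expect_false(any(compute_metal_trace(empty, g)$mask))
  # single metal voxel: trace pixels agree with a geometric oracle away
  # from grazing incidence
  vox <- empty; vox[20, 14, 1] <- TRUE
  tr <- compute_metal_trace(vox, g)
  center <- c((20 - 0.5 - 16) * 2, (14 - 0.5 - 16) * 2)
  for (v in c(0L, 7L, 15L)) {
    r <- generate_rays(g, v)
    dist <- abs((center[1] - r$origin[, 1]) * r$direction[, 2] -
                (center[2] - r$origin[, 2]) * r$direction[, 1])
    sure_hit <- dist < 0.3 * 2
    sure_miss <- dist > 0.9 * sqrt(2) * 2
    got <- tr$mask[v + 1, 1, ]
    expect_true(all(got[sure_hit]))
    expect_false(any(got[sure_miss]))
  }
  # monotone growth: a larger metal volume traces a superset
  bigger <- vox; bigger[21:22, 14:15, 1] <- TRUE
  tr2 <- compute_metal_trace(bigger, g)
  expect_true(all(tr2$mask[tr$mask]))
  expect_gte(sum(tr2$mask), sum(tr$mask))
})

test_that("reliable rays complement the trace exactly", {
  g <- tiny_geom()
  vox <- array(FALSE, c(32, 32, 1)); vox[14:18, 14:18, 1] <- TRUE
  tr <- compute_metal_trace(vox, g)
  rr <- reliable_rays(tr)
  expect_equal(length(rr) + sum(tr$mask), length(tr$mask))
  expect_false(any(tr$mask[rr]))
  full <- tr; full$mask[] <- TRUE
  expect_warning(out <- reliable_rays(full), "every ray")
  expect_length(out, 0L)
  none <- tr; none$mask[] <- FALSE
  expect_length(reliable_rays(none), length(tr$mask))
})

test_that("detector distances equal the brute-force minimum", {
  g <- scan_geometry("conebeam3d", 300, 500, n_views = 2L,
                     detector_cols = 32L, detector_rows = 32L,
                     pixel_pitch_mm = 2, volume_shape = c(16L, 16L, 16L),
                     voxel_size_mm = 4)
  mk_trace <- function(mask) {
    m <- array(FALSE, c(2, 32, 32)); m[1, , ] <- mask
    structure(list(mask = m, geometry = g), class = "metal_trace")
  }
  # closed cases: neighbors and a 3-4-5 triangle
  m <- matrix(FALSE, 32, 32); m[10, 10] <- TRUE
  d <- detector_distance(mk_trace(m), 0L)
  expect_equal(d[10, 11], 1)
  expect_equal(d[13, 14], 5)
  expect_equal(d[10, 10], 0)
  expect_true(all(is.infinite(detector_distance(mk_trace(m), 1L))))
  # exhaustive oracle on random masks
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(runif(32 * 32) < 0.05, 32, 32)
    if (!any(m)) m[7, 9] <- TRUE
    d <- detector_distance(mk_trace(m), 0L)
    pts <- which(m, arr.ind = TRUE)
    idx <- cbind(sample(32, 25, replace = TRUE), sample(32, 25, replace = TRUE))
    for (i in seq_len(nrow(idx))) {
      brute <- min(sqrt((idx[i, 1] - pts[, 1])^2 + (idx[i, 2] - pts[, 2])^2))
      expect_equal(d[idx[i, 1], idx[i, 2]], brute, tolerance = 1e-12)
    }
  }
})

test_that("metal-aware weights follow the exponential distance law", {
  g <- tiny_geom(n_views = 2L, cols = 48L)
  m <- array(FALSE, c(2, 1, 48)); m[1, 1, 24] <- TRUE
  tr <- structure(list(mask = m, geometry = g), class = "metal_trace")
  mas <- metal_aware_set(tr, d_th = 20, lambda = 0.01)
  # membership is strict: d = 20 excluded, d = 19 included (view 1 only)
  expect_true(all(mas$d < 20))
  expect_true(any(mas$d == 19))
  expect_false(any(mas$d == 20))
  # closed-form weights at the default decay factor
  expect_equal(mas$w[mas$d == 1][1], exp(-0.01), tolerance = 1e-12)
  expect_equal(mas$w[mas$d == 10][1], exp(-0.1), tolerance = 1e-12)
  expect_equal(sort(unique(round(mas$w[mas$d == 10] / exp(-0.1), 12))), 1)
  # normalization: max exactly 1, monotone non-increasing in d
  expect_equal(max(mas$w_hat), 1)
  ord <- order(mas$d)
  expect_true(all(diff(mas$w_hat[ord]) <= 1e-15))
  # the trace-free view contributes no members
  views <- ((mas$idx - 1) %% 2) + 1
  expect_true(all(views == 1))
  # empty set allowed
  none <- tr; none$mask[] <- FALSE
  expect_length(metal_aware_set(none)$idx, 0L)
})

test_that("area-balanced batches split proportionally without duplicates", {
  r_m <- 1:100
  r_r <- 1:500   # so R_r \ R_m has 400 = 4 x |R_m| rays
  b <- area_balanced_batch(r_r, r_m, 100L, seed = 1)
  expect_length(b$rays_r, 80L)
  expect_length(b$rays_m, 20L)
  expect_false(any(b$rays_r %in% r_m))
  expect_false(anyDuplicated(c(b$rays_r, b$rays_m)) > 0)
  # empty metal-aware set: the whole batch of 256 comes from R_r
  b2 <- area_balanced_batch(1:1000, integer(0), 256L, seed = 2)
  expect_length(b2$rays_r, 256L)
  expect_length(b2$rays_m, 0L)
  expect_error(area_balanced_batch(1:10, integer(0), 50L, seed = 1),
               "exceeds")
  expect_error(area_balanced_batch(1:10, 99L, 4L, seed = 1), "subset")
})

test_that("batch sampling frequencies match the uniform design", {
  r_m <- 1:60
  r_r <- 1:300
  nrep <- 1500L
  counts <- numeric(300)
  for (k in seq_len(nrep)) {
    b <- area_balanced_batch(r_r, r_m, 50L, seed = k)
    counts[c(b$rays_r, b$rays_m)] <- counts[c(b$rays_r, b$rays_m)] + 1
  }
  # each excluded-reliable ray: p = 40/240; each metal-aware ray: p = 10/60
  p_r <- (50 - 10) / 240; p_m <- 10 / 60
  z_r <- (counts[61:300] / nrep - p_r) / sqrt(p_r * (1 - p_r) / nrep)
  z_m <- (counts[1:60] / nrep - p_m) / sqrt(p_m * (1 - p_m) / nrep)
  expect_lt(mean(abs(c(z_r, z_m))), 1.5)
  expect_lt(max(abs(c(z_r, z_m))), 4.5)
})
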