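# Physics substrate: ray generation, Beer-Lambert line integrals, the
# forward projector and filtered backprojection.

test_that("ray generation covers the detector and hits the iso-center", {
  g <- scan_geometry("fanbeam2d", 300, 500, n_views = 8L,
                     detector_cols = 9L, pixel_pitch_mm = 2,
                     volume_shape = c(16L, 16L, 1L), voxel_size_mm = 2)
  r <- generate_rays(g, 0L)
  expect_equal(nrow(r$origin), 9L)
  expect_equal(sqrt(rowSums(r$direction^2)), rep(1, 9), tolerance = 1e-9)
  # the central pixel's ray passes through the iso-center
  o <- r$origin[5, ]; d <- r$direction[5, ]
  perp <- abs(o[1] * d[2] - o[2] * d[1])
  expect_lt(perp, 1e-9)
  # one ray per detector pixel in 3D too
  g3 <- scan_geometry("conebeam3d", 300, 500, n_views = 4L,
                      detector_cols = 12L, detector_rows = 5L,
                      pixel_pitch_mm = 2, volume_shape = c(16L, 16L, 8L),
                      voxel_size_mm = 2)
  expect_equal(nrow(generate_rays(g3, 1L)$origin), 12L * 5L)
  expect_error(generate_rays(g, 8L), "out of range")
})

test_that("ray/box entry and exit match a dense marching oracle", {
  g <- tiny_geom()
  r <- generate_rays(g, 3L)
  he <- g$volume_shape * g$voxel_size_mm / 2
  step <- 0.01
  for (i in seq(1, nrow(r$origin), by = 7)) {
    o <- r$origin[i, ]; d <- r$direction[i, ]
    ts <- seq(0, 2 * g$source_to_detector_mm, by = step)
    px <- outer(ts, d[1]) + o[1]
    py <- outer(ts, d[2]) + o[2]
    inside <- abs(px) <= he[1] & abs(py) <= he[2]
    if (!any(inside)) {
      expect_equal(r$t_near[i], 0)
      expect_equal(r$t_far[i], 0)
    } else {
      expect_equal(r$t_near[i], min(ts[inside]), tolerance = 2 * step)
      expect_equal(r$t_far[i], max(ts[inside]), tolerance = 2 * step)
      expect_gt(r$t_far[i], r$t_near[i])
    }
  }
})

test_that("discrete Beer-Lambert line integral matches closed forms", {
  expect_equal(discrete_line_integral(rep(0, 5), rep(1, 5), 1e6), 1e6)
  expect_equal(discrete_line_integral(0.02, 50, 1), exp(-1), tolerance = 1e-12)
  # independent summation oracle on a long random sample vector
  set.seed(3)
  mu <- runif(576, 0, 0.05)
  dl <- runif(576, 0.1, 1)
  oracle <- 1e6
  for (i in seq_along(mu)) oracle <- oracle * exp(-mu[i] * dl[i])
  expect_equal(discrete_line_integral(mu, dl, 1e6), oracle,
               tolerance = 1e-12)
  expect_error(discrete_line_integral(0.1, -1), "negative")
  expect_error(discrete_line_integral(c(1, 2), 1), "equal length")
})

test_that("Beer-Lambert transmission never increases when adding attenuation", {
  set.seed(4)
  for (rep in 1:20) {
    mu <- runif(30, 0, 0.1)
    dl <- runif(30, 0.1, 2)
    I1 <- discrete_line_integral(mu, dl)
    extra <- mu + c(runif(29, 0, 0.05), 0)
    expect_lte(discrete_line_integral(extra, dl), I1)
  }
})

test_that("forward projection reproduces analytic chords through a disk", {
  n <- 128L
  g <- scan_geometry("fanbeam2d", 300, 500, n_views = 2L,
                     detector_cols = 160L, pixel_pitch_mm = 1.2,
                     volume_shape = c(n, n, 1L), voxel_size_mm = 1)
  vol <- disk_volume(n, 1, radius = 40)
  expect_equal(max(abs(forward_project(att_volume(array(0, c(n, n, 1)),
                                                  "mm^-1"), g)$data)), 0)
  p <- forward_project(vol, g)$data[1, 1, ]
  r <- generate_rays(g, 0L)
  s <- abs(r$origin[, 1] * r$direction[, 2] - r$origin[, 2] * r$direction[, 1])
  sel <- s < 0.8 * 40
  analytic <- 0.02 * 2 * sqrt(40^2 - s[sel]^2)
  expect_lt(max(abs(p[sel] - analytic) / analytic), 0.01)
})

test_that("the projector is linear in the volume", {
  g <- tiny_geom()
  set.seed(5)
  v1 <- array(runif(32 * 32), c(32, 32, 1))
  v2 <- array(runif(32 * 32), c(32, 32, 1))
  p1 <- forward_project(att_volume(v1, "mm^-1"), g)$data
  p2 <- forward_project(att_volume(v2, "mm^-1"), g)$data
  p12 <- forward_project(att_volume(2.5 * v1 + 0.3 * v2, "mm^-1"), g)$data
  expect_equal(p12, 2.5 * p1 + 0.3 * p2, tolerance = 1e-10)
})

test_that("single-row cone-beam agrees with the fan-beam path", {
  g2 <- tiny_geom()
  g3 <- scan_geometry("conebeam3d", 300, 500, n_views = 24L,
                      detector_cols = 48L, detector_rows = 1L,
                      pixel_pitch_mm = 3.2, volume_shape = c(32L, 32L, 3L),
                      voxel_size_mm = 2)
  set.seed(6)
  sl <- matrix(runif(32 * 32), 32, 32)
  p2 <- forward_project(att_volume(array(sl, c(32, 32, 1)), "mm^-1"), g2)$data
  p3 <- forward_project(att_volume(array(rep(sl, 3), c(32, 32, 3)), "mm^-1"),
                        g3)$data
  expect_equal(as.numeric(p3), as.numeric(p2), tolerance = 1e-8)
})

test_that("log and exponential transforms invert each other with a floor", {
  g <- tiny_geom()
  set.seed(7)
  I0 <- 1e6
  I <- array(runif(prod(c(24, 1, 48)), 1, I0), c(24, 1, 48))
  ps <- projection_set(I, "intensity", I0 = I0, geometry = g)
  p <- log_transform(ps)
  expect_equal(exp_transform(p)$data, I, tolerance = 1e-12)
  expect_equal(log_transform(projection_set(array(I0, c(24, 1, 48)),
                                            "intensity", I0, g))$data[1], 0)
  expect_equal(log_transform(projection_set(array(I0 * exp(-2), c(24, 1, 48)),
                                            "intensity", I0, g))$data[1], 2)
  # photon starvation: zero counts clamp at the floor
  zero <- projection_set(array(0, c(24, 1, 48)), "intensity", I0, g)
  expect_equal(log_transform(zero, floor = 1)$data[1], log(I0))
  expect_error(log_transform(ps, I0 = 0), "I0")
})

test_that("HU and attenuation conversions are exact inverses", {
  expect_equal(as.numeric(hu_to_mu(att_volume(array(0, c(2, 2, 1)), "HU"))[1]),
               0.0206)
  expect_equal(as.numeric(hu_to_mu(att_volume(array(-1000, c(2, 2, 1)),
                                              "HU"))[1]), 0)
  set.seed(8)
  hu <- att_volume(array(runif(64, -1000, 3000), c(4, 4, 4)), "HU")
  back <- mu_to_hu(hu_to_mu(hu))
  expect_equal(as.numeric(back), as.numeric(hu), tolerance = 1e-12)
})

test_that("FBP round trip recovers a smooth phantom and a disk's value", {
  g <- geom_preset("desk")
  zero <- projection_set(array(0, c(180, 1, 192)), "line_integral",
                         geometry = g)
  expect_equal(max(abs(fbp_reconstruct(zero, g))), 0)
  n <- 128
  xs <- (seq_len(n) - 0.5 - n / 2)
  X <- matrix(xs, n, n); Y <- t(X)
  sm <- 0.02 * exp(-(X^2 + Y^2) / (2 * 20^2)) +
    0.008 * exp(-((X - 12)^2 + (Y + 8)^2) / (2 * 6^2))
  rec <- fbp_reconstruct(forward_project(att_volume(sm, "mm^-1"), g), g)
  rmse <- sqrt(mean((rec[, , 1] - sm)^2))
  rng <- diff(range(sm))
  expect_lt(rmse / rng, 0.03)
  expect_gt(20 * log10(rng / rmse), 35)  # round-trip PSNR
  disk <- disk_volume(n, 1, radius = 40)
  recd <- fbp_reconstruct(forward_project(disk, g), g)
  expect_lt(abs(recd[n / 2, n / 2, 1] - 0.02) / 0.02, 0.02)
})

test_that("FDK reconstructs a small cone-beam volume", {
  g3 <- scan_geometry("conebeam3d", 300, 500, n_views = 90L,
                      detector_cols = 64L, detector_rows = 24L,
                      pixel_pitch_mm = 2.4, volume_shape = c(48L, 48L, 12L),
                      voxel_size_mm = 1.6)
  n <- 48
  xs <- (seq_len(n) - 0.5 - n / 2) * 1.6
  X <- matrix(xs, n, n); Y <- t(X)
  sl <- 0.02 * exp(-(X^2 + Y^2) / (2 * 14^2))
  vol <- att_volume(array(rep(sl, 12), c(48, 48, 12)), "mm^-1")
  rec <- fbp_reconstruct(forward_project(vol, g3), g3)
  mid <- rec[, , 6]
  rmse <- sqrt(mean((mid - sl)^2))
  expect_lt(rmse / diff(range(sl)), 0.05)
})
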