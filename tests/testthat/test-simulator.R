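# Polychromatic acquisition simulator: spectrum, material table, procedural
# phantom, noise, beam-hardening correction and the end-to-end paired case.

test_that("the source spectrum satisfies its contract", {
  sp <- xray_spectrum(1e6)
  expect_length(sp$energies_keV, 12L)
  expect_true(all(diff(sp$energies_keV) > 0))
  expect_true(all(sp$energies_keV >= 10 & sp$energies_keV <= 120))
  expect_true(all(sp$photon_counts >= 0))
  expect_equal(sum(sp$photon_counts), 1e6)
})

test_that("material attenuation decreases with energy and gold dominates", {
  tab <- material_attenuation()
  for (m in c("water", "soft_tissue", "bone", "gold")) {
    expect_true(all(tab[[m]] > 0))
    expect_true(all(diff(tab[[m]]) <= 0))
  }
  expect_true(all(tab$gold > 3 * tab$bone))
})

test_that("the dental phantom is deterministic with ordered tissue classes", {
  g <- case_geom()
  spec <- phantom_spec(n_metal = 5, seed = 3)
  ph1 <- make_dental_phantom(spec, g)
  ph2 <- make_dental_phantom(spec, g)
  expect_identical(unclass_v(ph1$hu_metal), unclass_v(ph2$hu_metal))
  # exactly the requested number of connected metal components
  expect_equal(label_components(ph1$metal[, , 1]), 5L)
  # masks disjoint
  expect_false(any(ph1$soft & ph1$bone))
  expect_false(any(ph1$soft & ph1$metal))
  expect_false(any(ph1$bone & ph1$metal))
  # class medians ordered air < soft < bone < metal
  hu <- unclass_v(ph1$hu_metal)
  air <- !ph1$soft & !ph1$bone & !ph1$metal
  meds <- c(stats::median(hu[air]), stats::median(hu[ph1$soft]),
            stats::median(hu[ph1$bone]), stats::median(hu[ph1$metal]))
  expect_true(all(diff(meds) > 0))
  expect_gt(min(hu[ph1$metal]), 3000)
  expect_error(phantom_spec(n_metal = 6), "between 2 and 5")
})

test_that("threshold segmentation partitions every volume", {
  v <- att_volume(array(c(2500, 100, -1000, 500), c(2, 2, 1)), "HU")
  s <- segment_materials(v)
  expect_true(s$metal[1, 1, 1])   # 2500 HU at the 2000 threshold is metal
  expect_true(s$bone[2, 2, 1])
  expect_true(s$soft[2, 1, 1])
  allair <- segment_materials(att_volume(array(-1000, c(3, 3, 1)), "HU"))
  expect_equal(sum(allair$soft) + sum(allair$bone) + sum(allair$metal), 0L)
  set.seed(9)
  rnd <- att_volume(array(runif(500, -1000, 4000), c(10, 10, 5)), "HU")
  s <- segment_materials(rnd)
  total <- s$soft + s$bone + s$metal + s$air
  expect_true(all(total == 1L))  # pairwise disjoint and covering
})

test_that("a single-bin spectrum degenerates to monochromatic Beer-Lambert", {
  g <- tiny_geom()
  tab <- material_attenuation()
  w <- array(0, c(32, 32, 1)); w[10:20, 10:20, 1] <- 1
  sp1 <- xray_spectrum(1e6)
  sp1$energies_keV <- 60
  sp1$photon_counts <- 1e6
  I <- polychromatic_project(list(water = w), sp1, tab, g)
  L <- forward_project(att_volume(w, "mm^-1"), g)$data
  mono <- 1e6 * exp(-tab$water[tab$energy_keV == 60] * L)
  expect_equal(I$data, mono, tolerance = 1e-10)
})

test_that("a two-bin spectrum matches a hand-computed per-bin sum", {
  g <- tiny_geom()
  tab <- material_attenuation()
  w <- array(0, c(32, 32, 1)); w[8:24, 8:24, 1] <- 1
  sp <- xray_spectrum(1000)
  sp$energies_keV <- c(60, 80)
  sp$photon_counts <- c(600, 400)
  I <- polychromatic_project(list(water = w), sp, tab, g)$data
  L <- forward_project(att_volume(w, "mm^-1"), g)$data
  mu60 <- tab$water[tab$energy_keV == 60]
  mu80 <- tab$water[tab$energy_keV == 80]
  byhand <- 600 * exp(-mu60 * L) + 400 * exp(-mu80 * L)
  expect_equal(I, byhand, tolerance = 1e-12)
  # air-only rays keep the full intensity
  expect_equal(max(I), 1000, tolerance = 1e-12)
  expect_true(all(I <= 1000 + 1e-9) && all(I >= 0))
})

test_that("Poisson noise has the right mean and is seed-reproducible", {
  g <- tiny_geom(n_views = 1L, cols = 100L)
  I <- projection_set(array(100, c(1, 1, 100)), "intensity", I0 = 1e6,
                      geometry = g)
  big <- projection_set(array(100, c(1, 1, 100 * 1000)), "intensity", 1e6)
  draws <- add_poisson_noise(big, seed = 21)$data
  expect_lt(abs(mean(draws) - 100), 1)   # 1e5 draws at mean 100
  zero <- add_poisson_noise(projection_set(array(0, c(1, 1, 100)),
                                           "intensity", 1e6, g), seed = 1)
  expect_equal(max(zero$data), 0)
  expect_identical(add_poisson_noise(I, 5)$data, add_poisson_noise(I, 5)$data)
  expect_false(identical(add_poisson_noise(I, 5)$data,
                         add_poisson_noise(I, 6)$data))
})

test_that("water beam-hardening correction linearizes water paths", {
  g <- tiny_geom()
  tab <- material_attenuation()
  sp <- xray_spectrum()
  # monochromatic spectrum: the correction must be the identity
  sp1 <- sp; sp1$energies_keV <- 60; sp1$photon_counts <- 1e6
  w <- array(0, c(32, 32, 1)); w[8:24, 8:24, 1] <- 1
  I1 <- polychromatic_project(list(water = w), sp1, tab, g)
  p1 <- water_bhc(I1, sp1, tab)
  pref <- forward_project(att_volume(0.0206 * w, "mm^-1"), g)
  expect_equal(p1$data, pref$data, tolerance = 1e-6)
  # a 100 mm water slab maps to mu_ref * 100 within 1%
  Islab <- sum(sp$photon_counts * exp(-tab$water * 100))
  pslab <- -log(Islab / sum(sp$photon_counts))
  co <- attr(water_bhc(I1, sp, tab), "bhc_coefs")
  corrected <- sum(co * pslab^(1:3))
  expect_lt(abs(corrected - 0.0206 * 100) / (0.0206 * 100), 0.01)
  # monotone over the full working range of log projections
  pg <- seq(0, 12, by = 0.05)
  vals <- co[1] * pg + co[2] * pg^2 + co[3] * pg^3
  expect_true(all(diff(vals) > 0))
})

test_that("BHC leaves a water cylinder flat", {
  g <- geom_preset("desk")
  n <- 128
  xs <- seq_len(n) - 0.5 - n / 2
  X <- matrix(xs, n, n); Y <- t(X)
  w <- array((X^2 + Y^2 <= 45^2) * 1.0, c(n, n, 1))
  sp <- xray_spectrum(); tab <- material_attenuation()
  rec <- mu_to_hu(fbp_reconstruct(water_bhc(
    polychromatic_project(list(water = w), sp, tab, g), sp, tab), g))
  center <- rec[n / 2, n / 2, 1]
  edge <- rec[n / 2 + 38, n / 2, 1]
  expect_lt(abs(center - edge), 30)
})

test_that("simulated cases pair a streaked and a clean chain deterministically", {
  case <- shared_case()
  e_unc <- evaluate_mar(case$fbp_uncorrected, case$gt_hu, case$metal_mask)
  e_cln <- evaluate_mar(case$fbp_clean, case$gt_hu, case$metal_mask)
  expect_lt(e_unc$ssim, e_cln$ssim)  # metal streaks degrade the image
  expect_true(any(case$metal_mask))
  # determinism under the same seed
  g <- case_geom()
  again <- simulate_case(phantom_spec(n_metal = 3, seed = 7), g, seed = 7)
  expect_identical(again$proj_corrupted$data, case$proj_corrupted$data)
  # with gold in the beam the trace line integrals leave the range that
  # any water-like anatomy produces (beam hardening + photon starvation):
  # the artifact source
  tr <- compute_metal_trace(case$metal_mask, g)
  expect_gt(max(case$proj_corrupted$data[tr$mask]),
            max(case$proj_corrupted$data[!tr$mask]) + 1)
})

test_that("the noise-free metal-free chain reconstructs the phantom faithfully", {
  # derived bound from the round-trip oracle at this discretization: the
  # residual is bone beam hardening (water-only BHC) plus finite-resolution
  # FBP; the purely monochromatic round trip sits near 33 dB
  g <- scan_geometry("fanbeam2d", 300, 500, n_views = 360L,
                     detector_cols = 384L, pixel_pitch_mm = 0.65,
                     volume_shape = c(256L, 256L, 1L), voxel_size_mm = 0.5)
  case <- simulate_case(phantom_spec(n_metal = 3, seed = 5), g, seed = 5,
                        noise = FALSE)
  e <- evaluate_mar(case$fbp_clean, case$gt_hu, case$metal_mask)
  expect_gt(e$psnr, 27)
  expect_gt(e$ssim, 0.99)
  ph <- case$phantom
  mono <- mu_to_hu(fbp_reconstruct(forward_project(hu_to_mu(ph$hu), g), g))
  expect_gt(evaluate_mar(mono, ph$hu, ph$metal)$psnr, 32)
})
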