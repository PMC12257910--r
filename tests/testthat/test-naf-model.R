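# The neural attenuation field: encoding, field evaluation, projection
# synthesis, losses, optimization and rendering.

test_that("a freshly initialized field is finite, small and pure", {
  g <- small_geom()
  ps <- projection_set(array(0, c(60, 1, 96)), "line_integral", geometry = g)
  fit <- naf_fit(ps, g, config = tiny_naf_config(epochs = 0L))
  # encoder output width = levels x features
  expect_equal(nrow(fit$params$W1), 4L * 2L)
  expect_equal(fit$params$param_count, length(coef(fit)))
  set.seed(12)
  coords <- matrix(runif(60), 30, 2)
  mu1 <- cpp_naf_eval(fit$params, coords)
  mu2 <- cpp_naf_eval(fit$params, coords)
  expect_identical(as.numeric(mu1), as.numeric(mu2))
  expect_true(all(is.finite(mu1)))
  expect_true(all(mu1 >= 0))       # softplus output
  expect_true(all(mu1 < 0.1))      # starts near water scale
})

test_that("paper-scale configuration lands near the stated parameter count", {
  g <- small_geom()
  ps <- projection_set(array(0, c(60, 1, 96)), "line_integral", geometry = g)
  fit <- naf_fit(ps, g, config = naf_config("paper", epochs = 0L))
  # 16 levels x 2^16 x 4 features + MLP: about 4.2M, within 15% of 4.5M
  expect_lt(abs(fit$params$param_count - 4.5e6) / 4.5e6, 0.15)
  expect_equal(nrow(fit$params$W1), 64L)
  expect_equal(ncol(fit$params$W1), 64L)
})

test_that("analytic gradients match finite differences", {
  g <- tiny_geom()
  ps <- projection_set(array(0.5, c(24, 1, 48)), "line_integral", geometry = g)
  fit <- naf_fit(ps, g, config = tiny_naf_config(epochs = 0L))
  params <- fit$params
  # move the tables off their tiny initialization scale: finite differences
  # at h = 1e-6 would otherwise step across ReLU kinks, since freshly
  # initialized pre-activations sit at the 1e-4 scale
  set.seed(99)
  params$tables <- lapply(params$tables, function(t) {
    t[] <- runif(length(t), -0.3, 0.3); t
  })
  rays <- generate_rays(g, 2L)
  sel <- seq(10, 40, by = 6)
  o <- rays$origin[sel, , drop = FALSE]
  d <- rays$direction[sel, , drop = FALSE]
  tn <- rays$t_near[sel]; tf <- rays$t_far[sel]
  y <- rep(0.4, length(sel))
  coefv <- runif(length(sel), 0.5, 1)
  he <- g$volume_shape * g$voxel_size_mm / 2
  gr <- cpp_naf_grad(params, o, d, tn, tf, y, coefv, 16L, he)
  loss_at <- function(p) cpp_naf_grad(p, o, d, tn, tf, y, coefv, 16L, he)$loss
  h <- 1e-6
  set.seed(13)
  # ten random touched table entries
  checked <- 0L
  for (l in sample(4L, 10L, replace = TRUE)) {
    gt <- gr$g_tables[[l]]
    nz <- which(gt != 0)
    if (!length(nz)) next
    i <- sample(nz, 1L)
    p2 <- params; p2$tables[[l]][i] <- p2$tables[[l]][i] + h
    p3 <- params; p3$tables[[l]][i] <- p3$tables[[l]][i] - h
    fd <- (loss_at(p2) - loss_at(p3)) / (2 * h)
    expect_equal(gt[i], fd, tolerance = 1e-3)
    checked <- checked + 1L
  }
  expect_gte(checked, 5L)
  # and a few MLP weights
  for (nm in c("W1", "W4", "b4")) {
    i <- 1L
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + h
    p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - h
    fd <- (loss_at(p2) - loss_at(p3)) / (2 * h)
    expect_equal(gr[[paste0("g_", nm)]][i], fd, tolerance = 1e-3)
  }
})

test_that("projection synthesis equals the shared Beer-Lambert oracle", {
  g <- tiny_geom()
  ps <- projection_set(array(0.5, c(24, 1, 48)), "line_integral", geometry = g)
  fit <- naf_fit(ps, g, config = tiny_naf_config(epochs = 1L))
  rays <- generate_rays(g, 5L)
  he <- g$volume_shape * g$voxel_size_mm / 2
  N <- 16L
  pred <- cpp_naf_predict(fit$params, rays$origin, rays$direction,
                          rays$t_near, rays$t_far, N, he)
  for (i in c(1L, 17L, 33L)) {
    if (rays$t_far[i] <= rays$t_near[i]) next
    dl <- (rays$t_far[i] - rays$t_near[i]) / N
    tsamp <- rays$t_near[i] + (seq_len(N) - 0.5) * dl
    pts <- cbind((rays$origin[i, 1] + tsamp * rays$direction[i, 1] + he[1]) /
                   (2 * he[1]),
                 (rays$origin[i, 2] + tsamp * rays$direction[i, 2] + he[2]) /
                   (2 * he[2]))
    mu <- as.numeric(cpp_naf_eval(fit$params, pts))
    expect_equal(pred$intensity[i],
                 discrete_line_integral(mu, rep(dl, N), 1),
                 tolerance = 1e-10)
  }
  # a ray that misses the volume transmits everything
  expect_true(all(pred$intensity[rays$t_far <= rays$t_near] == 1))
  expect_true(all(pred$intensity > 0 & pred$intensity <= 1))
})

test_that("loss functions reduce as specified", {
  expect_equal(recon_loss(c(1, 1), c(1, 1)), 0)
  expect_equal(recon_loss(0.6, 0.5), 0.01, tolerance = 1e-15)
  expect_equal(metal_aware_loss(3, 1, w_hat = 0.5), 2)
  set.seed(14)
  a <- runif(50); b <- runif(50); w <- runif(50)
  oracle <- 0
  for (i in 1:50) oracle <- oracle + (a[i] - b[i])^2
  expect_equal(recon_loss(a, b), oracle, tolerance = 1e-12)
  oracle_w <- sum(w * (a - b)^2)
  expect_equal(metal_aware_loss(a, b, w), oracle_w, tolerance = 1e-12)
  expect_equal(metal_aware_loss(a, b, rep(1, 50)), recon_loss(a, b))
  expect_equal(total_loss(1.5, 2, lambda_m = 1), 3.5)
  expect_equal(total_loss(1.5, 2, lambda_m = 0), 1.5)
  expect_error(recon_loss(a, b, in_trace = c(TRUE, rep(FALSE, 49))),
               "trace")
  expect_error(metal_aware_loss(a, b, w[1:3]), "weights")
})

test_that("short optimization runs descend and are seed-reproducible", {
  g <- small_geom()
  vol <- disk_volume(64, 2, radius = 30, mu = 0.02)
  ps <- forward_project(vol, g)
  cfg <- naf_config("desk-fast", hash_log2 = 12L, finest_resolution = 64L,
                    n_samples = 64L, epochs = 14L, seed = 9L)
  fit <- naf_fit(ps, g, config = cfg)
  # about 15 steps/epoch: compare the first ~3 epochs with the last ~3
  lg <- fit$log$recon_loss
  expect_lt(mean(utils::tail(lg, 3)), mean(utils::head(lg, 3)))
  # overfit sanity: constant-mu disk recovered within 5% in the interior
  mu_hat <- predict(fit, type = "volume")
  n <- 64
  xs <- (seq_len(n) - 0.5 - n / 2) * 2
  inside <- outer(xs, xs, function(a, b) a^2 + b^2) <= 24^2
  expect_lt(mean(abs(mu_hat[, , 1][inside] - 0.02)) / 0.02, 0.05)
  # determinism: identical seeds give identical fits
  fit2 <- naf_fit(ps, g, config = cfg)
  expect_identical(utils::tail(fit$log$recon_loss, 1),
                   utils::tail(fit2$log$recon_loss, 1))
  expect_identical(coef(fit), coef(fit2))
  fit3 <- naf_fit(ps, g, config = naf_config("desk-fast", hash_log2 = 12L,
                                             finest_resolution = 64L,
                                             n_samples = 64L, epochs = 14L,
                                             seed = 10L))
  expect_false(identical(utils::tail(fit$log$recon_loss, 1),
                         utils::tail(fit3$log$recon_loss, 1)))
})

test_that("rendering matches the geometry grid and repeats exactly", {
  g <- small_geom()
  ps <- projection_set(array(0.2, c(60, 1, 96)), "line_integral", geometry = g)
  fit <- naf_fit(ps, g, config = tiny_naf_config(epochs = 1L))
  v1 <- predict(fit, type = "volume")
  expect_equal(dim(v1), g$volume_shape)
  v2 <- predict(fit, type = "volume")
  expect_identical(as.numeric(v1), as.numeric(v2))
  hu <- render_volume(fit)
  expect_equal(attr(hu, "unit"), "HU")
  # fitted/residuals line up with the measured normalized intensities
  r <- residuals(fit)
  expect_equal(dim(r), dim(ps$data))
  expect_true(all(is.finite(r)))
})

test_that("model object methods print and summarize", {
  g <- small_geom()
  ps <- projection_set(array(0.2, c(60, 1, 96)), "line_integral", geometry = g)
  fit <- naf_fit(ps, g, config = tiny_naf_config(epochs = 1L))
  expect_output(print(fit), "naf")
  expect_output(print(summary(fit)), "parameters")
  expect_s3_class(fit, "naf")
})
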