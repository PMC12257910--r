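# The neural attenuation field model: configuration, the fitting function
# naf_fit() (the package's core estimator) and the usual S3 methods on the
# fitted object. The field f_theta maps normalized spatial coordinates to a
# non-negative attenuation coefficient through a multi-resolution hash
# encoding and a 4-layer ReLU MLP; it is optimized by Adam so that
# synthesized normalized intensities exp(-sum mu_i delta_i) match the
# measured ones on metal-trace-masked rays.

#' Configure a neural attenuation field
#'
#' Defaults follow the full-scale training recipe: a 4-layer, 64-channel
#' ReLU MLP on top of a 16-level hash encoding with 2^16-entry tables and 4
#' features per level (about 4.2 million trainable parameters), 576 samples
#' per ray, batches of 256 rays, Adam at learning rate 1e-3 decaying by 0.5
#' every 50 epochs for 150 epochs, metal-aware loss weight `lambda_m = 1`
#' with distance threshold `d_th = 20` detector pixels and decay factor
#' `lambda_w = 0.01`. The `"desk"` preset shrinks the recipe for CPU-scale
#' 2D experiments (2^14 tables, finest resolution 128, 192 samples per ray,
#' 10 epochs — the desk-scale loss plateaus around epoch 8); `"desk-fast"`
#' shrinks it further for repeated pipeline runs (96 samples, 5 epochs —
#' enough field quality for a stable 3-class prior).
#'
#' @param preset `"paper"`, `"desk"` or `"desk-fast"`.
#' @param n_levels,features_per_level,hash_log2,base_resolution,finest_resolution
#'   hash-encoding geometry.
#' @param width,layers MLP width and layer count (the architecture is fixed
#'   at 4 layers; the argument is kept for clarity).
#' @param n_samples samples per ray (uniform spacing between the ray's
#'   volume entry and exit).
#' @param batch_rays rays per optimization step.
#' @param lr,lr_decay,decay_every,epochs Adam schedule.
#' @param lambda_m weight of the metal-aware loss term (0 disables it).
#' @param d_th,lambda_w metal-aware set threshold and weight decay factor.
#' @param seed integer seed controlling initialization and ray sampling.
#' @param verbose print per-epoch losses during fitting.
#' @return A list of class `naf_config`.
#' @export
naf_config <- function(preset = c("paper", "desk", "desk-fast"),
                       n_levels = 16L, features_per_level = 4L,
                       hash_log2 = 16L, base_resolution = 16L,
                       finest_resolution = 512L,
                       width = 64L, layers = 4L,
                       n_samples = 576L, batch_rays = 256L,
                       lr = 1e-3, lr_decay = 0.5, decay_every = 50L,
                       epochs = 150L, lambda_m = 1,
                       d_th = 20, lambda_w = 0.01,
                       seed = 1L, verbose = FALSE) {
  preset <- match.arg(preset)
  cfg <- as.list(environment())
  supplied <- names(match.call())[-1]
  override <- function(field, value)
    if (!field %in% supplied) cfg[[field]] <<- value
  if (preset %in% c("desk", "desk-fast")) {
    override("hash_log2", 14L)
    override("finest_resolution", 128L)
    override("n_samples", 192L)
    override("epochs", 10L)
  }
  if (preset == "desk-fast") {
    override("n_samples", 96L)
    override("epochs", 5L)
  }
  ints <- c("n_levels", "features_per_level", "hash_log2", "base_resolution",
            "finest_resolution", "width", "layers", "n_samples", "batch_rays",
            "decay_every", "epochs", "seed")
  for (f in ints) cfg[[f]] <- as.integer(cfg[[f]])
  if (cfg$layers != 4L) stop("the field architecture is fixed at 4 layers")
  num_pos <- c("n_levels", "features_per_level", "hash_log2", "width",
               "batch_rays", "lr", "lr_decay", "decay_every", "d_th")
  for (f in num_pos) if (cfg[[f]] <= 0) stop(f, " must be positive")
  if (cfg$epochs < 0L) stop("epochs must be non-negative")
  if (cfg$n_samples < 2L) stop("n_samples must be at least 2")
  if (cfg$lambda_m < 0 || cfg$lambda_w < 0)
    stop("lambda_m and lambda_w must be non-negative")
  class(cfg) <- "naf_config"
  cfg
}

#' @export
print.naf_config <- function(x, ...) {
  cat(sprintf(paste0("<naf_config '%s': %d levels x %d feat, tables 2^%d, ",
                     "finest %d, width %d, N = %d, batch %d, %d epochs>\n"),
              x$preset, x$n_levels, x$features_per_level, x$hash_log2,
              x$finest_resolution, x$width, x$n_samples, x$batch_rays,
              x$epochs))
  invisible(x)
}

cfg_to_cpp <- function(cfg, dim) {
  list(dim = as.integer(dim), n_levels = cfg$n_levels,
       features_per_level = cfg$features_per_level,
       hash_log2 = cfg$hash_log2, base_resolution = cfg$base_resolution,
       finest_resolution = cfg$finest_resolution, width = cfg$width,
       n_samples = cfg$n_samples, batch_rays = cfg$batch_rays,
       lr = cfg$lr, lr_decay = cfg$lr_decay, decay_every = cfg$decay_every,
       epochs = cfg$epochs, lambda_m = cfg$lambda_m,
       seed = as.double(cfg$seed), verbose = isTRUE(cfg$verbose))
}

#' Fit a neural attenuation field to masked projections
#'
#' The core estimator. Measured projections are converted to normalized
#' intensities `I/I0 = exp(-p)`; rays inside the metal trace are excluded
#' from sampling entirely; remaining rays split into the plain reliable set
#' and the metal-aware set (within `d_th` detector pixels of the trace),
#' which contributes a squared error weighted by `lambda_m * w_hat(d)` with
#' `w_hat` the globally normalized `exp(-lambda_w * d)` weights. Each Adam
#' step draws an area-balanced batch without replacement. The total loss is
#' the reliable-ray squared error plus `lambda_m` times the metal-aware
#' term.
#'
#' @param projections a [projection_set()] (line-integral or intensity
#'   domain; intensities require `I0`).
#' @param geom the [scan_geometry()]; defaults to the set's geometry.
#' @param trace optional [compute_metal_trace()] result; `NULL` means no
#'   masking (all rays reliable).
#' @param config a [naf_config()].
#' @return An object of class `naf` with components `params` (encoder
#'   tables and MLP weights), `config`, `geometry`, `log` (per-epoch mean
#'   losses), `trace`, `sets` (ray bookkeeping) and `elapsed` (seconds).
#' @seealso [predict.naf()], [render_volume()], [mar_correct()]
#' @export
naf_fit <- function(projections, geom = projections$geometry, trace = NULL,
                    config = naf_config("desk")) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(config, "naf_config"))
  if (is.null(geom)) stop("no geometry supplied")
  y <- switch(projections$domain,
              line_integral = exp(-projections$data),
              intensity = {
                if (!is.finite(projections$I0) || projections$I0 <= 0)
                  stop("intensity projections need a positive I0")
                projections$data / projections$I0
              })
  if (is.null(trace)) trace <- empty_trace(geom)
  stopifnot(inherits(trace, "metal_trace"))
  if (!identical(dim(trace$mask), dim(projections$data)))
    stop("trace shape does not match projections")

  dim_field <- if (geom$mode == "fanbeam2d") 2L else 3L
  rays <- all_rays(geom)
  n <- length(y)
  ray_class <- integer(n)          # 0 = trace
  ray_class[!trace$mask] <- 1L     # reliable
  mas <- NULL
  if (config$lambda_m > 0 && any(trace$mask)) {
    mas <- metal_aware_set(trace, config$d_th, config$lambda_w)
    ray_class[mas$idx] <- 2L
  }
  if (!any(ray_class > 0L))
    stop("metal trace covers every ray; fitting is impossible")
  w_hat <- numeric(n)
  if (!is.null(mas)) w_hat[mas$idx] <- mas$w_hat

  t0 <- proc.time()[3]
  res <- cpp_naf_train(rays$origin, rays$direction, rays$t_near, rays$t_far,
                       as.double(y), ray_class, w_hat,
                       geom_half_extent(geom), cfg_to_cpp(config, dim_field))
  elapsed <- proc.time()[3] - t0

  log <- as.data.frame(res$log)
  names(log) <- c("epoch", "recon_loss", "metal_aware_loss")
  params <- res[c("dim", "n_levels", "features_per_level", "hash_log2",
                  "width", "resolutions", "table_rows", "tables",
                  "W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4",
                  "param_count")]
  structure(list(params = params, config = config, geometry = geom,
                 log = log, trace = trace,
                 measured = y,
                 sets = list(n_reliable = res$n_reliable,
                             n_metal_aware = res$n_metal_aware,
                             batch_reliable = res$batch_reliable,
                             batch_metal_aware = res$batch_metal_aware,
                             trace_sampled = res$trace_sampled),
                 n_steps = res$n_steps, elapsed = elapsed),
            class = "naf")
}

#' @export
print.naf <- function(x, ...) {
  cat(sprintf("<naf: %dD field, %.3g parameters, %d epochs (%d steps)>\n",
              x$params$dim, x$params$param_count, x$config$epochs,
              as.integer(x$n_steps)))
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  final mean losses: recon %.3g, metal-aware %s\n",
                last$recon_loss,
                if (is.na(last$metal_aware_loss)) "-" else
                  sprintf("%.3g", last$metal_aware_loss)))
  }
  invisible(x)
}

#' @export
summary.naf <- function(object, ...) {
  s <- list(param_count = object$params$param_count,
            dim = object$params$dim,
            resolutions = object$params$resolutions,
            epochs = object$config$epochs,
            n_steps = object$n_steps,
            sets = object$sets,
            elapsed = object$elapsed,
            log = object$log)
  class(s) <- "summary.naf"
  s
}

#' @export
print.summary.naf <- function(x, ...) {
  cat(sprintf("Neural attenuation field (%dD), %.4g trainable parameters\n",
              x$dim, x$param_count))
  cat(sprintf("Hash levels at resolutions: %s\n",
              paste(x$resolutions, collapse = " ")))
  cat(sprintf("Rays: %d reliable (%d metal-aware); batch %d + %d\n",
              as.integer(x$sets$n_reliable),
              as.integer(x$sets$n_metal_aware),
              x$sets$batch_reliable, x$sets$batch_metal_aware))
  cat(sprintf("Trained %d steps in %.1f s; trace rays sampled: %d\n",
              as.integer(x$n_steps), x$elapsed,
              as.integer(x$sets$trace_sampled)))
  if (nrow(x$log)) {
    cat("Loss trajectory (first/last epochs):\n")
    show <- unique(c(1, nrow(x$log)))
    print(x$log[show, ], row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.naf <- function(object, ...) {
  p <- object$params
  c(unlist(lapply(p$tables, as.numeric)),
    unlist(p[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")]))
}

#' Evaluate a fitted attenuation field
#'
#' `type = "volume"` renders the field on the geometry's voxel grid (the
#' "NAF image"); `type = "projection"` synthesizes normalized intensities
#' for every detector ray of the geometry.
#'
#' @param object a fitted [naf_fit()] model.
#' @param type `"volume"` or `"projection"`.
#' @param geom geometry to render on (defaults to the training geometry).
#' @param unit `"mm^-1"` or `"HU"` for volume rendering.
#' @param mu_water_ref HU conversion reference.
#' @param ... unused.
#' @return An [att_volume()] or a [projection_set()] (intensity domain,
#'   `I0 = 1`).
#' @export
predict.naf <- function(object, type = c("volume", "projection"),
                        geom = object$geometry, unit = c("mm^-1", "HU"),
                        mu_water_ref = 0.0206, ...) {
  type <- match.arg(type)
  unit <- match.arg(unit)
  if (type == "volume") {
    vs <- geom$volume_shape; vox <- geom$voxel_size_mm
    he <- geom_half_extent(geom)
    ax <- lapply(1:3, function(a)
      (((seq_len(vs[a]) - 0.5 - vs[a] / 2) * vox[a]) + he[a]) / (2 * he[a]))
    d <- object$params$dim
    grid <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE)
    coords <- as.matrix(grid[, seq_len(d), drop = FALSE])
    mu <- cpp_naf_eval(object$params, coords)
    vol <- array(as.numeric(mu), vs)
    vol <- new_att_volume(vol, "mm^-1")
    if (unit == "HU") vol <- mu_to_hu(vol, mu_water_ref)
    vol
  } else {
    rays <- all_rays(geom)
    pred <- cpp_naf_predict(object$params, rays$origin, rays$direction,
                            rays$t_near, rays$t_far, object$config$n_samples,
                            geom_half_extent(geom))
    I <- array(pred$intensity,
               c(geom$n_views, geom$detector_rows, geom$detector_cols))
    projection_set(I, "intensity", I0 = 1, geometry = geom)
  }
}

#' Render the fitted field as a volume (the NAF image)
#'
#' Convenience wrapper for `predict(object, type = "volume", unit = "HU")`.
#'
#' @inheritParams predict.naf
#' @return A HU [att_volume()].
#' @export
render_volume <- function(object, geom = object$geometry) {
  predict(object, type = "volume", geom = geom, unit = "HU")
}

#' @export
fitted.naf <- function(object, ...) {
  predict(object, type = "projection")$data
}

#' Residuals of a fitted attenuation field
#'
#' Predicted minus measured normalized intensities; rays inside the metal
#' trace, which the model never saw, are returned as `NA`.
#'
#' @param object a fitted `naf` model.
#' @param ... unused.
#' @export
residuals.naf <- function(object, ...) {
  r <- fitted(object) - object$measured
  r[object$trace$mask] <- NA_real_
  r
}

#' Plot a fitted attenuation field
#'
#' Left: per-epoch training losses on a log scale. Right: the rendered
#' central slice in HU.
#'
#' @param x a fitted `naf` model.
#' @param ... passed to [graphics::image()].
#' @export
plot.naf <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lg <- x$log
  graphics::plot(lg$epoch, lg$recon_loss, type = "l", log = "y",
                 xlab = "epoch", ylab = "mean loss per ray",
                 main = "training loss")
  if (!all(is.na(lg$metal_aware_loss)))
    graphics::lines(lg$epoch, lg$metal_aware_loss, lty = 2)
  vol <- predict(x, type = "volume", unit = "HU")
  k <- ceiling(dim(vol)[3] / 2)
  graphics::image(vol[, , k], col = grDevices::gray.colors(256),
                  axes = FALSE, main = "rendered slice (HU)", ...)
  invisible(x)
}

#' Projection-domain losses
#'
#' The squared-error objectives on normalized intensities:
#' `recon_loss()` sums `(I_pred - I_real)^2` over reliable rays;
#' `metal_aware_loss()` weights each term by `w_hat`;
#' `total_loss()` combines them with weight `lambda_m`.
#'
#' @param I_pred,I_real predicted and measured normalized intensities.
#' @param in_trace optional logical flags; any `TRUE` is an error, as
#'   trace rays must never enter the loss.
#' @param w_hat normalized metal-aware weights.
#' @param recon,ma the two loss values.
#' @param lambda_m metal-aware weight.
#' @return A non-negative scalar.
#' @export
recon_loss <- function(I_pred, I_real, in_trace = NULL) {
  if (!is.null(in_trace) && any(in_trace))
    stop("metal-trace rays must not enter the reconstruction loss")
  sum((I_pred - I_real)^2)
}

#' @rdname recon_loss
#' @export
metal_aware_loss <- function(I_pred, I_real, w_hat) {
  if (length(w_hat) != length(I_pred)) stop("missing or mismatched weights")
  sum(w_hat * (I_pred - I_real)^2)
}

#' @rdname recon_loss
#' @export
total_loss <- function(recon, ma, lambda_m = 1) recon + lambda_m * ma
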