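#' Train the inverse stiffness/contractility network
#'
#' Task II: from (geometry, traction map) recover the hidden substrate
#' properties. A U-Net regressor takes the 3-channel stack (indicator,
#' normalized traction x, normalized traction y) and emits the normalized
#' stiffness map `E_s(x)`; a global-average-pooled scalar head on the
#' bottleneck emits the normalized contractility. Supervision is pixelwise
#' squared error on the stiffness map restricted to the footprint (traction
#' carries no stiffness information elsewhere) plus squared error on the
#' contractility scalar. Optimizer settings follow [train_config()].
#'
#' @param corpus A [build_corpus()] result; for full-field recovery it
#'   should mix uniform, linear and circular stiffness modes.
#' @param split Optional [split_corpus()] result.
#' @param gspec U-Net spec; defaults to depth 3, base 8, 3 in / 1 out
#'   channels with the scalar head.
#' @param config A [train_config()] (the adversarial-only fields are
#'   ignored).
#' @param scalar_weight Weight of the contractility term (default 1).
#' @param verbose Print one line per epoch.
#' @return Object of class `dtfm_inverse`.
#' @export
train_inverse <- function(corpus, split = NULL,
                          gspec = generator_spec(depth = 4L, base_channels = 8L,
                                                 in_channels = 3L,
                                                 out_channels = 1L,
                                                 scalar_head = TRUE),
                          config = train_config(epochs = 50L, augment = TRUE,
                                                ema = 0.998),
                          scalar_weight = 1, verbose = FALSE) {
  stopifnot(inherits(corpus, "tfm_corpus"))
  if (!gspec$scalar_head || gspec$out_ch != 1L) {
    stop("train_inverse: spec must have 1 output channel and the scalar head")
  }
  if (is.null(split)) split <- split_corpus(corpus, seed = config$seed)
  n <- corpus$n
  ns <- length(corpus$samples)

  x <- array(0, c(n, n, 3, ns))
  es_t <- array(0, c(n, n, 1, ns))
  mask <- array(0, c(n, n, 1, ns))
  sig_t <- numeric(ns)
  for (i in seq_len(ns)) {
    s <- corpus$samples[[i]]
    x[, , 1, i] <- s$geometry$indicator
    x[, , 2:3, i] <-
      normalize_traction(s$traction, corpus$traction_scale)$values
    es_t[, , 1, i] <- norm_scalar(s$properties$stiffness_field$values,
                                  corpus$ranges$e_s)
    mask[, , 1, i] <- s$geometry$indicator
    sig_t[i] <- norm_scalar(s$properties$contractility, corpus$ranges$sigma_a)
  }

  set.seed(config$seed)
  p <- unet_init(gspec, seed = config$seed + 11L)
  st <- adam_init(p)
  p_ema <- p
  ema_t <- 0L
  tr <- split$train
  history <- vector("list", config$epochs)
  set.seed(config$seed + 13L)

  for (epoch in seq_len(config$epochs)) {
    lr_now <- epoch_lr(config$lr, epoch, config$epochs, config$lr_decay)
    idx <- sample(tr)
    nb <- ceiling(length(idx) / config$batch_size)
    ep <- c(map_mse = 0, sig_mse = 0)
    for (b in seq_len(nb)) {
      bi <- idx[seq((b - 1L) * config$batch_size + 1L,
                    min(b * config$batch_size, length(idx)))]
      xb <- x[, , , bi, drop = FALSE]
      eb <- es_t[, , , bi, drop = FALSE]
      mb <- mask[, , , bi, drop = FALSE]
      sb <- sig_t[bi]
      if (config$augment) {
        ops <- sample(d4_ops, length(bi), replace = TRUE)
        for (k in seq_along(ops)) {
          if (ops[k] == "identity") next
          r <- d4_apply_field(xb[, , 1, k], eb[, , 1, k],
                              xb[, , 2, k], xb[, , 3, k], ops[k])
          xb[, , 1, k] <- r$ind
          xb[, , 2, k] <- r$tx
          xb[, , 3, k] <- r$ty
          eb[, , 1, k] <- r$es
          mb[, , 1, k] <- r$ind
        }
      }
      fwd <- unet_forward(p, xb, gspec)
      diff <- (fwd$y - eb) * mb
      nmask <- max(sum(mb), 1)
      gy <- 2 * diff / nmask
      sdiff <- fwd$scalar - sb
      gs <- scalar_weight * 2 * sdiff / length(sb)
      grads <- unet_backward(p, fwd$cache, gy, gspec, gscalar = gs)
      upd <- adam_step(p, grads, st, lr_now, config$beta1, config$beta2)
      p <- upd$params; st <- upd$state
      if (config$ema > 0) {
        ema_t <- ema_t + 1L
        a <- min(config$ema, (1 + ema_t) / (10 + ema_t))
        for (nm in names(p)) {
          for (slot in names(p[[nm]])) {
            p_ema[[nm]][[slot]] <- a * p_ema[[nm]][[slot]] +
              (1 - a) * p[[nm]][[slot]]
          }
        }
      }
      map_mse <- sum(diff^2) / nmask
      sig_mse <- mean(sdiff^2)
      if (!is.finite(map_mse)) {
        stop("train_inverse: loss diverged (NaN) at epoch ", epoch)
      }
      ep <- ep + c(map_mse, sig_mse)
    }
    ep <- ep / nb
    history[[epoch]] <- tibble::tibble(epoch = epoch, map_mse = ep[1],
                                       sigma_mse = ep[2])
    if (verbose) {
      message(sprintf("epoch %3d | E_s mse %.5f | sigma mse %.5f",
                      epoch, ep[1], ep[2]))
    }
  }

  structure(
    list(params = p,
         params_ema = if (config$ema > 0) p_ema else NULL,
         gspec = gspec, config = config,
         traction_scale = corpus$traction_scale, ranges = corpus$ranges,
         n = n, split = split, history = dplyr::bind_rows(history),
         corpus_fingerprint = list(n_samples = ns, seed = corpus$seed)),
    class = "dtfm_inverse"
  )
}

#' @exportS3Method base::print
print.dtfm_inverse <- function(x, ...) {
  cat(sprintf(
    "<dtfm_inverse> U-Net depth %d (base %d) -> E_s map + sigma_A head; n=%d\n",
    x$gspec$depth, x$gspec$base, x$n
  ))
  invisible(x)
}

#' Recover the substrate stiffness field and contractility from a traction map
#'
#' Runs the trained inverse network on (geometry, traction). The stiffness
#' map is reported inside the footprint only (`NA` outside, where traction
#' carries no information); the contractility is returned in Pa. A
#' vanishing input traction is flagged as out-of-distribution with a
#' warning rather than an error.
#'
#' @param g A [cell_geometry()].
#' @param tf A [traction_field()] on the same grid.
#' @param model A `dtfm_inverse`.
#' @param symmetrize Average the recovery over the dihedral-4 orbit of the
#'   inputs (default TRUE).
#' @return List: `stiffness` (a `stiffness_field` whose values are `NA`
#'   outside the footprint), `ebar` (footprint mean, Pa), `sigma_a` (Pa).
#' @export
predict_stiffness <- function(g, tf, model, symmetrize = TRUE) {
  stopifnot(inherits(g, "cell_geometry"), inherits(tf, "traction_field"),
            inherits(model, "dtfm_inverse"))
  if (g$n != model$n || tf$n != model$n) {
    stop("predict_stiffness: resolution mismatch with the trained model")
  }
  if (max(abs(tf$components)) < 1e-12) {
    warning("predict_stiffness: input traction is identically zero; ",
            "the model is out of its training distribution")
  }
  x <- array(0, c(model$n, model$n, 3, 1))
  x[, , 1, 1] <- g$indicator
  x[, , 2:3, 1] <- normalize_traction(tf, model$traction_scale)$values
  prm <- model$params_ema %||% model$params
  fwd <- unet_forward(prm, x, model$gspec)
  es_acc <- fwd$y[, , 1, 1]
  sig_acc <- fwd$scalar
  if (isTRUE(symmetrize)) {
    inv_op <- c(rot90 = "rot270", rot180 = "rot180", rot270 = "rot90",
                flip_h = "flip_h", flip_v = "flip_v")
    for (op in names(inv_op)) {
      r <- d4_apply_field(x[, , 1, 1], x[, , 1, 1], x[, , 2, 1],
                          x[, , 3, 1], op)
      xt <- x
      xt[, , 1, 1] <- r$ind
      xt[, , 2, 1] <- r$tx
      xt[, , 3, 1] <- r$ty
      ft <- unet_forward(prm, xt, model$gspec)
      back <- d4_apply_field(ft$y[, , 1, 1], ft$y[, , 1, 1],
                             ft$y[, , 1, 1], ft$y[, , 1, 1], inv_op[[op]])
      es_acc <- es_acc + back$es
      sig_acc <- sig_acc + ft$scalar
    }
    es_acc <- es_acc / 6
    sig_acc <- sig_acc / 6
  }
  es_norm <- es_acc
  fwd <- list(scalar = sig_acc)
  es <- denorm_scalar(es_norm, model$ranges$e_s)
  es <- pmax(es, 1)                       # positivity after denormalization
  ebar <- mean(es[g$indicator == 1])
  es[g$indicator == 0] <- NA_real_
  sf <- structure(
    list(values = es, mode = "predicted", gradient = 0,
         pixel_size = g$pixel_size, n = g$n),
    class = "stiffness_field"
  )
  sigma_a <- denorm_scalar(fwd$scalar, model$ranges$sigma_a)
  list(stiffness = sf, ebar = ebar, sigma_a = as.numeric(sigma_a))
}

#' Recover the contractility-stiffness relation
#'
#' For each stiffness level in `e_grid`, simulates `n_colonies` fresh random
#' colonies on a uniform substrate of that stiffness, runs
#' [predict_stiffness()] on the simulated traction maps, and aggregates the
#' recovered mean stiffness and contractility. The output pairs the
#' ML-recovered relation with the ground-truth [contractility_law()] so the
#' two curves can be compared directly. Levels outside the model's trained
#' stiffness range are flagged as extrapolated with a warning.
#'
#' @param model A `dtfm_inverse`.
#' @param e_grid Stiffness levels in Pa.
#' @param n_colonies Colonies per level (default 5).
#' @param params [mechanics_params()] used for the fresh simulations.
#' @param n Grid size (must match the model).
#' @param seed Integer seed.
#' @param d_ranges Geometry descriptor ranges.
#' @return A tibble of class `contractility_curve`: one row per level with
#'   `e_s`, `ebar_true`, `ebar_pred`, `sigma_pred`, `sigma_true`,
#'   `sigma_pred_sd`, `extrapolated`.
#' @export
recover_contractility_curve <- function(model, e_grid = seq(5000, 40000,
                                                            length.out = 8),
                                        n_colonies = 5L,
                                        params = mechanics_params(),
                                        n = NULL, seed = 1L,
                                        d_ranges = default_d_ranges()) {
  stopifnot(inherits(model, "dtfm_inverse"))
  n <- n %||% model$n
  rng <- model$ranges$e_s
  if (any(e_grid < rng[1] - 1e-9) || any(e_grid > rng[2] + 1e-9)) {
    warning("recover_contractility_curve: grid extends outside the trained ",
            "stiffness range [", rng[1], ", ", rng[2], "] Pa; those levels ",
            "are flagged as extrapolated")
  }
  rows <- purrr::imap(e_grid, function(e0, k) {
    preds <- purrr::map(seq_len(n_colonies), function(j) {
      sub <- (as.integer(seed) + 7717L * (k * 1000L + j)) %% .Machine$integer.max
      geo <- random_cell_geometry(sub, n = n, d_ranges = d_ranges)
      s <- make_stiffness_field("uniform", n, geo$geometry$pixel_size, e0 = e0)
      tf <- solve_traction(geo$geometry, s, params)
      pr <- predict_stiffness(geo$geometry, tf, model)
      c(ebar = pr$ebar, sigma = pr$sigma_a)
    })
    pm <- do.call(rbind, preds)
    tibble::tibble(
      e_s = e0,
      ebar_true = e0,
      ebar_pred = mean(pm[, "ebar"]),
      sigma_pred = mean(pm[, "sigma"]),
      sigma_pred_sd = sd(pm[, "sigma"]),
      sigma_true = contractility_law(e0, params),
      extrapolated = e0 < rng[1] - 1e-9 | e0 > rng[2] + 1e-9
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("contractility_curve", class(out))
  out
}
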