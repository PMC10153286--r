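#' Adversarial training configuration
#'
#' Optimization settings for the adversarial translator: ADAM with learning
#' rate 0.0002 and moment parameters `beta1 = 0.6`, `beta2 = 0.95`; 200
#' epochs for the full profile; the scaled-down smoke profile used by the
#' package's own evaluations runs ~40 epochs at batch size 8 with
#' dihedral augmentation and a ramped exponential moving average of the
#' generator weights. An optional masked pixelwise L1 reconstruction term
#' with weight `lambda_rec` (default 100) anchors the otherwise purely
#' adversarial objective.
#'
#' @param epochs Training epochs (default 200).
#' @param lr ADAM learning rate (default 2e-4).
#' @param beta1,beta2 ADAM moment parameters (defaults 0.6, 0.95).
#' @param batch_size Minibatch size (default 8).
#' @param seed Master seed; fans out to weight initialization, batch
#'   shuffling and augmentation.
#' @param lambda_rec Reconstruction weight for the masked pixelwise L1
#'   anchor; 0 disables (the literal cross-entropy-only game).
#' @param d_lr Discriminator learning rate; defaults to `lr`. Setting 0
#'   freezes the discriminator at its (near-chance) initialization.
#' @param nonsaturating Use the non-saturating generator loss `-log D(fake)`
#'   instead of the literal second cross-entropy term.
#' @param augment Apply random dihedral-4 augmentation to each training
#'   batch.
#' @param val_every Compute validation error every this many epochs (0 =
#'   never).
#' @param lr_decay Linearly decay the learning rate to zero over the second
#'   half of training (default FALSE; useful for long schedules).
#' @param ema Decay constant for an exponential moving average of the
#'   generator weights, used for prediction (0 disables; default 0.995).
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, lr = 2e-4, beta1 = 0.6, beta2 = 0.95,
                         batch_size = 8L, seed = 1L, lambda_rec = 100,
                         nonsaturating = FALSE, augment = FALSE,
                         val_every = 0L, d_lr = NULL, lr_decay = FALSE,
                         ema = 0.995) {
  stopifnot(epochs >= 1, lr > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            batch_size >= 1, lambda_rec >= 0, ema >= 0, ema < 1)
  d_lr <- d_lr %||% lr
  stopifnot(d_lr >= 0)
  structure(
    list(epochs = as.integer(epochs), lr = lr, beta1 = beta1, beta2 = beta2,
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         lambda_rec = lambda_rec, nonsaturating = isTRUE(nonsaturating),
         augment = isTRUE(augment), val_every = as.integer(val_every),
         d_lr = d_lr, lr_decay = isTRUE(lr_decay), ema = ema),
    class = "train_config"
  )
}

#' Adversarial cross-entropy value
#'
#' The two-player objective `L(D, G) = E[log D(T)] + E[log(1 - D(G(.)))]`
#' evaluated from patch score grids: the discriminator ascends it, the
#' generator descends the second term. Scores are clamped away from 0/1 by
#' `1e-7` inside the logarithms. At the theoretical equilibrium (all scores
#' 1/2) the value is exactly `-2 log 2`.
#'
#' @param d_real Patch scores on real maps, values in `[0, 1]`.
#' @param d_fake Patch scores on generated maps, values in `[0, 1]`.
#' @return Scalar loss value.
#' @examples
#' gan_loss(0.5, 0.5)  # -2 log 2
#' @export
gan_loss <- function(d_real, d_fake) {
  d_real <- as.numeric(d_real)
  d_fake <- as.numeric(d_fake)
  if (any(d_real < 0 | d_real > 1) || any(d_fake < 0 | d_fake > 1)) {
    stop("gan_loss: scores must lie in [0, 1]")
  }
  eps <- 1e-7
  mean(log(pmax(d_real, eps))) + mean(log(pmax(1 - d_fake, eps)))
}

# assemble corpus tensors once: conditioning stack, normalized traction, mask
encode_corpus <- function(corpus) {
  n <- corpus$n
  ns <- length(corpus$samples)
  x <- array(0, c(n, n, 3, ns))
  tn <- array(0, c(n, n, 2, ns))
  mask <- array(0, c(n, n, 1, ns))
  for (i in seq_len(ns)) {
    s <- corpus$samples[[i]]
    x[, , , i] <- encode_inputs(s, corpus$ranges)
    tn[, , , i] <- normalize_traction(s$traction, corpus$traction_scale)$values
    mask[, , 1, i] <- s$geometry$indicator
  }
  list(x = x, tn = tn, mask = mask)
}

augment_batch <- function(xb, tb, mb, ops) {
  for (i in seq_along(ops)) {
    op <- ops[i]
    if (op == "identity") next
    res <- d4_apply_field(mb[, , 1, i], xb[, , 2, i],
                          tb[, , 1, i], tb[, , 2, i], op)
    mb[, , 1, i] <- res$ind
    xb[, , 1, i] <- res$ind
    xb[, , 2, i] <- res$es
    # channel 3 is a constant map: unchanged
    tb[, , 1, i] <- res$tx
    tb[, , 2, i] <- res$ty
  }
  list(x = xb, t = tb, m = mb)
}

mask2 <- function(m) m[, , c(1, 1), , drop = FALSE]

# constant learning rate for the first half of training, then linear decay
# to zero (a standard schedule for adversarial image translators)
epoch_lr <- function(lr, epoch, epochs, decay) {
  if (!decay || epochs < 4) return(lr)
  half <- epochs / 2
  if (epoch <= half) lr else lr * (epochs - epoch + 1) / (epochs - half)
}

# reconstruction weights: the footprint mask, shared by both vector
# channels (pixels outside the colony carry no signal and are excluded)
rec_weights <- function(tb, mb) {
  mb[, , c(1, 1), , drop = FALSE]
}

#' Train the conditional adversarial traction translator
#'
#' Alternating per-batch updates: the patch discriminator ascends the
#' adversarial cross-entropy on (conditioning, traction) stacks, the U-Net
#' generator descends its own term plus the masked L1 reconstruction anchor.
#' Generator outputs are masked to the colony footprint before both the
#' discriminator and the loss, enforcing the zero-outside-footprint
#' contract during training. History records per-epoch adversarial losses,
#' the reconstruction term and (optionally) validation error; training is
#' deterministic given the seed up to floating-point reduction order.
#'
#' @param corpus A [build_corpus()] result.
#' @param split Optional index split from [split_corpus()]; defaults to an
#'   80/10/10 split derived from the training seed.
#' @param gspec,dspec Network specifications ([generator_spec()],
#'   [discriminator_spec()]).
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return Object of class `dtfm_gan`: generator/discriminator parameters,
#'   specs, config, normalization metadata, split, and a history tibble.
#' @export
train_gan <- function(corpus, split = NULL,
                      gspec = generator_spec(),
                      dspec = discriminator_spec(),
                      config = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(corpus, "tfm_corpus"))
  if (length(corpus$samples) < 2) stop("train_gan: need at least 2 samples")
  if (is.null(split)) {
    split <- split_corpus(corpus, seed = config$seed)
  }
  enc <- encode_corpus(corpus)
  n <- corpus$n
  if (n %% 2L^(gspec$depth - 1L) != 0L) {
    stop("train_gan: grid size ", n, " not divisible by 2^(depth-1)")
  }

  set.seed(config$seed)
  gp <- unet_init(gspec, seed = config$seed + 1L)
  dp <- disc_init(dspec, seed = config$seed + 2L)
  gs <- adam_init(gp)
  ds <- adam_init(dp)
  gp_ema <- gp
  ema_t <- 0L

  tr <- split$train
  history <- vector("list", config$epochs)
  set.seed(config$seed + 3L)

  for (epoch in seq_len(config$epochs)) {
    lr_now <- epoch_lr(config$lr, epoch, config$epochs, config$lr_decay)
    d_lr_now <- if (config$d_lr > 0)
      epoch_lr(config$d_lr, epoch, config$epochs, config$lr_decay) else 0
    idx <- sample(tr)
    nb <- ceiling(length(idx) / config$batch_size)
    ep <- c(d_loss = 0, g_adv = 0, g_rec = 0)
    for (b in seq_len(nb)) {
      bi <- idx[seq((b - 1L) * config$batch_size + 1L,
                    min(b * config$batch_size, length(idx)))]
      xb <- enc$x[, , , bi, drop = FALSE]
      tb <- enc$tn[, , , bi, drop = FALSE]
      mb <- enc$mask[, , , bi, drop = FALSE]
      if (config$augment) {
        ops <- sample(d4_ops, length(bi), replace = TRUE)
        ab <- augment_batch(xb, tb, mb, ops)
        xb <- ab$x; tb <- ab$t; mb <- ab$m
      }
      m2 <- mask2(mb)

      gfwd <- unet_forward(gp, xb, gspec)
      fake <- gfwd$y * m2

      # --- simultaneous updates (max_D min_G): both players' gradients are
      # evaluated at the same parameter point before either steps. Real and
      # fake stacks run as one combined batch: instance-norm statistics are
      # per-sample, so the combination is exact ---
      nbatch <- dim(xb)[4]
      both <- concat_n(concat_ch(xb, tb), concat_ch(xb, fake))
      db <- disc_forward(dp, both, dspec)
      pb <- sigmoid(db$logits)
      ridx <- seq_len(length(pb) / 2)
      pr <- pb[ridx]
      pf <- pb[-ridx]
      np <- length(pr)
      glog <- array(0, dim(db$logits))
      glog[, , , seq_len(nbatch)] <- (pr - 1) / np      # d(-log p)/dlogit
      glog[, , , nbatch + seq_len(nbatch)] <- pf / np   # d(-log(1-p))/dlogit
      bb <- disc_backward(dp, db$cache, glog, dspec)
      dgrads <- bb$grads
      d_loss <- -(mean(log(pmax(pr, 1e-7))) + mean(log(pmax(1 - pf, 1e-7))))

      # --- generator gradients ---
      if (config$nonsaturating) {
        glog2 <- array(0, dim(db$logits))
        glog2[, , , nbatch + seq_len(nbatch)] <- (pf - 1) / np
        badv <- disc_backward(dp, db$cache, glog2, dspec)
        g_adv <- -mean(log(pmax(pf, 1e-7)))
        g_from_adv <- badv$gx[, , 4:5, nbatch + seq_len(nbatch),
                              drop = FALSE]
      } else {
        # descend +log(1 - D(fake)): gradient on the fake logits is the
        # negation of the discriminator's, so reuse its input gradient
        g_adv <- mean(log(pmax(1 - pf, 1e-7)))
        g_from_adv <- -bb$gx[, , 4:5, nbatch + seq_len(nbatch),
                             drop = FALSE]
      }
      if (d_lr_now > 0) {
        upd <- adam_step(dp, dgrads, ds, d_lr_now, config$beta1,
                         config$beta2)
        dp <- upd$params; ds <- upd$state
      }
      nmask <- max(sum(m2), 1)
      diff <- fake - tb
      w_rec <- rec_weights(tb, mb)
      g_rec_grad <- config$lambda_rec * sign(diff) * w_rec / nmask
      gfake <- (g_from_adv + g_rec_grad) * m2
      ggrads <- unet_backward(gp, gfwd$cache, gfake, gspec)
      upd <- adam_step(gp, ggrads, gs, lr_now, config$beta1, config$beta2)
      gp <- upd$params; gs <- upd$state
      if (config$ema > 0) {
        # ramped decay so the average tracks from the first steps instead of
        # lingering at the random initialization
        ema_t <- ema_t + 1L
        a <- min(config$ema, (1 + ema_t) / (10 + ema_t))
        for (nm in names(gp)) {
          for (slot in names(gp[[nm]])) {
            gp_ema[[nm]][[slot]] <- a * gp_ema[[nm]][[slot]] +
              (1 - a) * gp[[nm]][[slot]]
          }
        }
      }
      rec <- sum(abs(diff) * m2) / nmask

      if (!is.finite(d_loss) || !is.finite(rec)) {
        stop("train_gan: loss diverged (NaN) at epoch ", epoch)
      }
      ep <- ep + c(d_loss, g_adv, rec)
    }
    ep <- ep / nb
    eps_val <- NA_real_
    if (config$val_every > 0 && epoch %% config$val_every == 0 &&
        length(split$validation) > 0) {
      model_now <- new_gan_model(gp, dp, gspec, dspec, config, corpus, split,
                                 history = NULL)
      eps_val <- epsilon_t(
        predict_corpus(model_now, corpus, split$validation),
        lapply(split$validation, function(i) corpus$samples[[i]]$traction)
      )$epsilon_t
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, d_loss = ep[1], g_adv = ep[2], g_rec = ep[3],
      val_eps = eps_val
    )
    if (verbose) {
      message(sprintf("epoch %3d | D %.3f | G_adv %.3f | rec %.4f%s",
                      epoch, ep[1], ep[2], ep[3],
                      if (is.na(eps_val)) "" else sprintf(" | val eps %.3f", eps_val)))
    }
  }
  m <- new_gan_model(gp, dp, gspec, dspec, config, corpus, split,
                     dplyr::bind_rows(history))
  if (config$ema > 0) m$generator_ema <- gp_ema
  m
}

new_gan_model <- function(gp, dp, gspec, dspec, config, corpus, split,
                          history) {
  structure(
    list(generator = gp, discriminator = dp, gspec = gspec, dspec = dspec,
         config = config, traction_scale = corpus$traction_scale,
         ranges = corpus$ranges, n = corpus$n, split = split,
         history = history,
         corpus_fingerprint = list(n_samples = length(corpus$samples),
                                   seed = corpus$seed)),
    class = "dtfm_gan"
  )
}

#' @exportS3Method base::print
print.dtfm_gan <- function(x, ...) {
  cat(sprintf(
    "<dtfm_gan> U-Net depth %d (base %d) -> 2ch, patch D depth %d; n=%d, %d epochs\n",
    x$gspec$depth, x$gspec$base, x$dspec$depth, x$n,
    if (is.null(x$history)) 0L else max(x$history$epoch)
  ))
  invisible(x)
}

#' Predict a traction map from geometry and properties
#'
#' Runs the trained generator on the encoded conditioning stack,
#' denormalizes to Pa, and masks the output to exactly zero outside the
#' colony footprint. Inference is deterministic.
#'
#' @param model A trained `dtfm_gan`.
#' @param geometry A [cell_geometry()] at the trained resolution.
#' @param properties A [property_tensor()] (or a `stiffness_field`, from
#'   which the properties are derived with the default contractility law).
#' @param symmetrize Average the prediction over the dihedral-4 orbit of
#'   the inputs (default TRUE); exact on the square grid and removes
#'   orientation noise.
#' @return A [traction_field()] in Pa.
#' @export
predict_traction <- function(model, geometry, properties,
                             symmetrize = TRUE) {
  stopifnot(inherits(model, "dtfm_gan"), inherits(geometry, "cell_geometry"))
  if (inherits(properties, "stiffness_field")) {
    eb <- mean_stiffness(properties, geometry)
    properties <- property_tensor(properties, average_radius(geometry),
                                  contractility_law(eb))
  }
  if (geometry$n != model$n) {
    stop("predict_traction: geometry resolution ", geometry$n,
         " does not match the trained resolution ", model$n,
         " (no silent resampling)")
  }
  s <- list(geometry = geometry, properties = properties)
  class(s) <- "tfm_sample"
  x <- array(encode_inputs(s, model$ranges), c(model$n, model$n, 3, 1))
  out <- gen_apply(model, x, symmetrize = symmetrize)
  comp <- out[, , , 1] * model$traction_scale
  comp[, , 1] <- comp[, , 1] * geometry$indicator
  comp[, , 2] <- comp[, , 2] * geometry$indicator
  traction_field(comp, geometry$pixel_size)
}

gen_params <- function(model) model$generator_ema %||% model$generator

# run the generator, optionally averaging over the dihedral-4 orbit
# (transform inputs, predict, transform back); exact for the square grid
gen_apply <- function(model, x, symmetrize = TRUE) {
  gp <- gen_params(model)
  base <- unet_forward(gp, x, model$gspec)$y
  if (!symmetrize) return(base)
  acc <- base
  n_ops <- 1L
  d <- dim(x)
  inv_op <- c(rot90 = "rot270", rot180 = "rot180", rot270 = "rot90",
              flip_h = "flip_h", flip_v = "flip_v")
  for (op in c("rot90", "rot180", "rot270", "flip_h", "flip_v")) {
    xt <- x
    for (i in seq_len(d[4])) {
      r <- d4_apply_field(x[, , 1, i], x[, , 2, i],
                          x[, , 1, i], x[, , 1, i], op)
      xt[, , 1, i] <- r$ind
      xt[, , 2, i] <- r$es
      # channel 3 is constant
    }
    yt <- unet_forward(gp, xt, model$gspec)$y
    for (i in seq_len(d[4])) {
      r <- d4_apply_field(yt[, , 1, i], yt[, , 1, i],
                          yt[, , 1, i], yt[, , 2, i], inv_op[[op]])
      acc[, , 1, i] <- acc[, , 1, i] + r$tx
      acc[, , 2, i] <- acc[, , 2, i] + r$ty
    }
    n_ops <- n_ops + 1L
  }
  acc / n_ops
}

#' Batched prediction over corpus samples
#'
#' Runs the trained generator on the encoded conditioning stacks of the
#' selected corpus samples and returns denormalized, footprint-masked
#' traction fields.
#'
#' @param model A trained `dtfm_gan`.
#' @param corpus The `tfm_corpus` holding the samples.
#' @param idx Integer sample indices (e.g. a [split_corpus()] test set).
#' @param symmetrize Average over the dihedral-4 orbit (default TRUE).
#' @return List of [traction_field()]s, in `idx` order.
#' @export
predict_corpus <- function(model, corpus, idx, symmetrize = TRUE) {
  enc <- encode_corpus(corpus)
  x <- enc$x[, , , idx, drop = FALSE]
  out <- gen_apply(model, x, symmetrize = symmetrize)
  lapply(seq_along(idx), function(k) {
    i <- idx[k]
    g <- corpus$samples[[i]]$geometry
    comp <- out[, , , k] * model$traction_scale
    comp[, , 1] <- comp[, , 1] * g$indicator
    comp[, , 2] <- comp[, , 2] * g$indicator
    traction_field(comp, g$pixel_size)
  })
}

#' Rescale a predicted map to another contractile cell type
#'
#' Traction patterns of different contractile cell types share spatial
#' structure but differ in contractility; a single multiplicative factor
#' `alpha` adapts a map trained on one cell type to another. Force balance
#' is preserved exactly under the scaling.
#'
#' @param tf A [traction_field()].
#' @param alpha Positive scale factor.
#' @param cell_type Optional label recorded on the result.
#' @return The scaled [traction_field()] with `alpha` and `cell_type`
#'   attributes.
#' @export
scale_to_cell_type <- function(tf, alpha, cell_type = NULL) {
  stopifnot(inherits(tf, "traction_field"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    stop("scale_to_cell_type: alpha must be a positive scalar")
  }
  out <- traction_field(tf$components * alpha, tf$pixel_size)
  attr(out, "alpha") <- alpha
  attr(out, "cell_type") <- cell_type
  out
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the full parameter sets, specs, training config and
#' corpus fingerprint; reloading restores bitwise-equal weights.
#'
#' @param model A `dtfm_gan` or `dtfm_inverse` model.
#' @param path File path.
#' @return `path` (save); the model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    stop("load_checkpoint: cannot read checkpoint '", path, "': ",
         conditionMessage(e))
  })
  if (!inherits(model, c("dtfm_gan", "dtfm_inverse"))) {
    stop("load_checkpoint: '", path, "' is not a dtfm checkpoint")
  }
  model
}
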