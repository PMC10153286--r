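# Minimal dense-tensor neural-network primitives used by the generator,
# discriminator and inverse networks. Tensors are (H, W, C, N) arrays;
# convolutions run through the compiled im2col kernels, so the heavy work is
# BLAS gemm. Backward passes are explicit (no autodiff).

conv_init <- function(k, cin, cout, gain = sqrt(2)) {
  w <- array(rnorm(k * k * cin * cout, sd = gain / sqrt(k * k * cin)),
             c(k, k, cin, cout))
  list(w = w, b = numeric(cout))
}

conv_fw <- function(x, p, stride = 1L, pad = 1L) {
  cpp_conv_fw(x, p$w, p$b, as.integer(stride), as.integer(pad))
}

# caching variant: keeps the im2col matrix for the matching backward call
conv_fw_c <- function(x, p, stride = 1L, pad = 1L) {
  cpp_conv_fw_cache(x, p$w, p$b, as.integer(stride), as.integer(pad))
}

conv_bw <- function(x, p, gy, stride = 1L, pad = 1L, need_gx = TRUE,
                    col = NULL) {
  cpp_conv_bw(x, p$w, gy, as.integer(stride), as.integer(pad), need_gx, col)
}

relu <- function(z) cpp_relu(z)

sigmoid <- function(z) 1 / (1 + exp(-z))

pool_fw <- function(x) cpp_pool_fw(x)

pool_bw <- function(gy, cache_pool, in_dim) {
  cpp_pool_bw(gy, cache_pool$idx, as.integer(in_dim))
}

upconv_init <- function(cin, cout) {
  w <- array(rnorm(2 * 2 * cin * cout, sd = sqrt(2) / sqrt(cin)),
             c(2, 2, cin, cout))
  list(w = w, b = numeric(cout))
}

upconv_fw <- function(x, p) cpp_upconv_fw(x, p$w, p$b)

upconv_bw <- function(x, p, gy) cpp_upconv_bw(x, p$w, gy)

# Instance normalization: per-sample, per-channel standardization over the
# spatial plane with learned scale/shift; eps guards constant maps.
inorm_init <- function(c_) list(g = rep(1, c_), b = rep(0, c_))

inorm_fw <- function(x, p, eps = 1e-5) {
  out <- cpp_inorm_fw(x, p$g, p$b, eps)
  list(y = out$y, x = x, mu = out$mu, inv = out$inv)
}

inorm_bw <- function(cache, p, gy) {
  cpp_inorm_bw(cache$x, p$g, cache$mu, cache$inv, gy)
}

# concatenate two equal-shape batches along the sample dimension
concat_n <- function(a, b) {
  da <- dim(a)
  out <- array(0, c(da[1], da[2], da[3], da[4] + dim(b)[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(dim(b)[4])] <- b
  out
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  zero <- function(p) lapply(p, function(v) array(0, dim(v) %||% length(v)))
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (slot in names(params[[nm]])) {
      g <- grads[[nm]][[slot]]
      m <- beta1 * state$m[[nm]][[slot]] + (1 - beta1) * g
      v <- beta2 * state$v[[nm]][[slot]] + (1 - beta2) * g * g
      state$m[[nm]][[slot]] <- m
      state$v[[nm]][[slot]] <- v
      params[[nm]][[slot]] <- params[[nm]][[slot]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

# ---- U-Net --------------------------------------------------------------

#' Generator / regressor network specification
#'
#' A U-Net: the encoder halves the spatial size per level through 3x3
#' convolution + ReLU blocks and 2x2 max pooling, the decoder doubles it
#' with 2x2 up-convolutions, resolution-matched encoder features are
#' concatenated into the decoder through skip connections, and a final 1x1
#' convolution maps to `out_channels`. With `scalar_head = TRUE` a
#' global-average-pooled linear head on the bottleneck emits one scalar per
#' sample (used by the inverse network for the contractility).
#'
#' @param depth Number of resolution levels (input size must be divisible by
#'   `2^(depth - 1)`).
#' @param base_channels Channels at the first level; doubled per level.
#' @param in_channels Conditioning stack depth.
#' @param out_channels Output channels (2 for traction, 1 for stiffness).
#' @param scalar_head Add the scalar regression head.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(depth = 4L, base_channels = 8L, in_channels = 3L,
                           out_channels = 2L, scalar_head = FALSE) {
  stopifnot(depth >= 2, base_channels >= 1)
  structure(
    list(depth = as.integer(depth), base = as.integer(base_channels),
         in_ch = as.integer(in_channels), out_ch = as.integer(out_channels),
         scalar_head = isTRUE(scalar_head)),
    class = "generator_spec"
  )
}

unet_channels <- function(spec, level) spec$base * 2L^(level - 1L)

unet_init <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- list()
  for (l in seq_len(spec$depth - 1L)) {
    cin <- if (l == 1L) spec$in_ch else unet_channels(spec, l - 1L)
    cl <- unet_channels(spec, l)
    p[[paste0("enc", l, "_c1")]] <- conv_init(3, cin, cl)
    p[[paste0("enc", l, "_n1")]] <- inorm_init(cl)
    p[[paste0("enc", l, "_c2")]] <- conv_init(3, cl, cl)
    p[[paste0("enc", l, "_n2")]] <- inorm_init(cl)
  }
  cb <- unet_channels(spec, spec$depth)
  p$bot_c1 <- conv_init(3, unet_channels(spec, spec$depth - 1L), cb)
  p$bot_n1 <- inorm_init(cb)
  p$bot_c2 <- conv_init(3, cb, cb)
  p$bot_n2 <- inorm_init(cb)
  for (l in seq(spec$depth - 1L, 1L)) {
    cl <- unet_channels(spec, l)
    p[[paste0("dec", l, "_up")]] <- upconv_init(unet_channels(spec, l + 1L), cl)
    p[[paste0("dec", l, "_c1")]] <- conv_init(3, 2L * cl, cl)
    p[[paste0("dec", l, "_n1")]] <- inorm_init(cl)
    p[[paste0("dec", l, "_c2")]] <- conv_init(3, cl, cl)
    p[[paste0("dec", l, "_n2")]] <- inorm_init(cl)
  }
  p$out <- conv_init(1, unet_channels(spec, 1L), spec$out_ch, gain = 0.1)
  if (spec$scalar_head) {
    p$head <- list(w = matrix(rnorm(cb, sd = 1 / sqrt(cb)), cb, 1),
                   b = 0)
  }
  p
}

# conv -> instance norm -> ReLU, twice; norm+ReLU run as one fused kernel
conv_block_fw <- function(x, p1, p2, n1, n2) {
  f1 <- conv_fw_c(x, p1)
  i1 <- cpp_inrelu_fw(f1$y, n1$g, n1$b, 1e-5)
  f2 <- conv_fw_c(i1$y, p2)
  i2 <- cpp_inrelu_fw(f2$y, n2$g, n2$b, 1e-5)
  list(x = x, col1 = f1$col, col2 = f2$col,
       z1 = f1$y, z2 = f2$y, i1 = i1, i2 = i2, a2 = i2$y)
}

conv_block_bw <- function(cache, p1, p2, n1, n2, ga2, need_gx = TRUE) {
  b2n <- cpp_inrelu_bw(cache$z2, n2$g, cache$i2$mu, cache$i2$inv, ga2,
                       cache$i2$y)
  b2 <- conv_bw(cache$i1$y, p2, b2n$gx, col = cache$col2)
  b1n <- cpp_inrelu_bw(cache$z1, n1$g, cache$i1$mu, cache$i1$inv, b2$gx,
                       cache$i1$y)
  b1 <- conv_bw(cache$x, p1, b1n$gx, need_gx = need_gx, col = cache$col1)
  list(gx = b1$gx,
       g1 = list(w = b1$gw, b = b1$gb),
       g2 = list(w = b2$gw, b = b2$gb),
       gn1 = list(g = b1n$gg, b = b1n$gb),
       gn2 = list(g = b2n$gg, b = b2n$gb))
}

unet_forward <- function(params, x, spec) {
  cache <- list()
  cur <- x
  for (l in seq_len(spec$depth - 1L)) {
    blk <- conv_block_fw(cur, params[[paste0("enc", l, "_c1")]],
                         params[[paste0("enc", l, "_c2")]],
                         params[[paste0("enc", l, "_n1")]],
                         params[[paste0("enc", l, "_n2")]])
    cache[[paste0("enc", l)]] <- blk
    pl <- pool_fw(blk$a2)
    cache[[paste0("pool", l)]] <- pl
    cur <- pl$y
  }
  blk <- conv_block_fw(cur, params$bot_c1, params$bot_c2,
                       params$bot_n1, params$bot_n2)
  cache$bot <- blk
  cur <- blk$a2
  if (spec$scalar_head) {
    d <- dim(cur)
    pooled <- apply(cur, c(3, 4), mean)              # (C, N)
    scalar <- as.numeric(crossprod(pooled, params$head$w)) +
      as.numeric(params$head$b)
    cache$head_pooled <- pooled
    cache$head_dim <- d
  } else {
    scalar <- NULL
  }
  for (l in seq(spec$depth - 1L, 1L)) {
    up <- upconv_fw(cur, params[[paste0("dec", l, "_up")]])
    cache[[paste0("up_in", l)]] <- cur
    skip <- cache[[paste0("enc", l)]]$a2
    cat_ <- concat_ch(up, skip)
    cache[[paste0("cat", l)]] <- cat_
    blk <- conv_block_fw(cat_, params[[paste0("dec", l, "_c1")]],
                         params[[paste0("dec", l, "_c2")]],
                         params[[paste0("dec", l, "_n1")]],
                         params[[paste0("dec", l, "_n2")]])
    cache[[paste0("dec", l)]] <- blk
    cur <- blk$a2
  }
  y <- conv_fw(cur, params$out, stride = 1L, pad = 0L)
  cache$final_in <- cur
  list(y = y, scalar = scalar, cache = cache)
}

unet_backward <- function(params, cache, gy, spec, gscalar = NULL) {
  grads <- list()
  bo <- conv_bw(cache$final_in, params$out, gy, stride = 1L, pad = 0L)
  grads$out <- list(w = bo$gw, b = bo$gb)
  gcur <- bo$gx
  gskip <- list()
  for (l in seq_len(spec$depth - 1L)) {
    blk <- cache[[paste0("dec", l)]]
    bb <- conv_block_bw(blk, params[[paste0("dec", l, "_c1")]],
                        params[[paste0("dec", l, "_c2")]],
                        params[[paste0("dec", l, "_n1")]],
                        params[[paste0("dec", l, "_n2")]], gcur)
    grads[[paste0("dec", l, "_c1")]] <- bb$g1
    grads[[paste0("dec", l, "_c2")]] <- bb$g2
    grads[[paste0("dec", l, "_n1")]] <- bb$gn1
    grads[[paste0("dec", l, "_n2")]] <- bb$gn2
    cl <- unet_channels(spec, l)
    gup <- bb$gx[, , seq_len(cl), , drop = FALSE]
    gskip[[l]] <- bb$gx[, , cl + seq_len(cl), , drop = FALSE]
    bu <- upconv_bw(cache[[paste0("up_in", l)]],
                    params[[paste0("dec", l, "_up")]], gup)
    grads[[paste0("dec", l, "_up")]] <- list(w = bu$gw, b = bu$gb)
    gcur <- bu$gx
  }
  if (spec$scalar_head && !is.null(gscalar)) {
    d <- cache$head_dim
    pooled <- cache$head_pooled                      # (C, N)
    gpooled <- params$head$w %*% matrix(gscalar, nrow = 1)   # (C, N)
    grads$head <- list(w = pooled %*% matrix(gscalar, ncol = 1),
                       b = sum(gscalar))
    per_px <- 1 / (d[1] * d[2])
    gmap <- array(rep(as.numeric(gpooled), each = d[1] * d[2]) * per_px, d)
    gcur <- gcur + gmap
  } else if (spec$scalar_head) {
    grads$head <- list(w = array(0, dim(params$head$w)), b = 0)
  }
  bb <- conv_block_bw(cache$bot, params$bot_c1, params$bot_c2,
                      params$bot_n1, params$bot_n2, gcur)
  grads$bot_c1 <- bb$g1
  grads$bot_c2 <- bb$g2
  grads$bot_n1 <- bb$gn1
  grads$bot_n2 <- bb$gn2
  gcur <- bb$gx
  for (l in seq(spec$depth - 1L, 1L)) {
    ga2 <- pool_bw(gcur, cache[[paste0("pool", l)]],
                   dim(cache[[paste0("enc", l)]]$a2)) + gskip[[l]]
    bb <- conv_block_bw(cache[[paste0("enc", l)]],
                        params[[paste0("enc", l, "_c1")]],
                        params[[paste0("enc", l, "_c2")]],
                        params[[paste0("enc", l, "_n1")]],
                        params[[paste0("enc", l, "_n2")]], ga2,
                        need_gx = l > 1L)
    grads[[paste0("enc", l, "_c1")]] <- bb$g1
    grads[[paste0("enc", l, "_c2")]] <- bb$g2
    grads[[paste0("enc", l, "_n1")]] <- bb$gn1
    grads[[paste0("enc", l, "_n2")]] <- bb$gn2
    gcur <- bb$gx
  }
  grads
}

# ---- patch discriminator ------------------------------------------------

#' Patch discriminator specification
#'
#' A convolutional classifier that scores local patches of a (conditioning,
#' traction) stack: `depth` stride-2 3x3 convolution + ReLU levels shrink
#' the input `n x n` to an `m x m` grid (`m = n / 2^depth`), and a per-patch
#' fully connected stage (a 1x1 convolution) followed by a sigmoid emits an
#' `m x m` reliability matrix of patch validity scores in (0, 1).
#'
#' @param depth Number of stride-2 convolution levels (default 4: patch grid
#'   `n/16`).
#' @param base_channels First-level channel count; doubled per level.
#' @param in_channels Input stack depth (conditioning + traction channels).
#' @return Object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(depth = 4L, base_channels = 4L,
                               in_channels = 5L) {
  stopifnot(depth >= 1, base_channels >= 1)
  structure(
    list(depth = as.integer(depth), base = as.integer(base_channels),
         in_ch = as.integer(in_channels)),
    class = "discriminator_spec"
  )
}

disc_init <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- list()
  for (l in seq_len(spec$depth)) {
    cin <- if (l == 1L) spec$in_ch else spec$base * 2L^(l - 2L)
    p[[paste0("c", l)]] <- conv_init(3, cin, spec$base * 2L^(l - 1L))
    if (l > 1L) p[[paste0("n", l)]] <- inorm_init(spec$base * 2L^(l - 1L))
  }
  p$fc <- conv_init(1, spec$base * 2L^(spec$depth - 1L), 1L, gain = 0.5)
  p
}

# forward to patch logits (sigmoid applied by callers where needed)
disc_forward <- function(params, x, spec) {
  cache <- list(x0 = x)
  cur <- x
  for (l in seq_len(spec$depth)) {
    f <- conv_fw_c(cur, params[[paste0("c", l)]], stride = 2L, pad = 1L)
    cache[[paste0("col", l)]] <- f$col
    z <- f$y
    if (l > 1L) {
      ino <- inorm_fw(z, params[[paste0("n", l)]])
      cache[[paste0("in", l)]] <- ino
      z <- ino$y
    }
    cache[[paste0("z", l)]] <- z
    cur <- relu(z)
    cache[[paste0("a", l)]] <- cur
  }
  logits <- conv_fw(cur, params$fc, stride = 1L, pad = 0L)
  cache$fc_in <- cur
  list(logits = logits, cache = cache)
}

# backward from gradient on logits; returns grads and (optionally) the
# input gradient, which the generator step needs for the fake stack only
disc_backward <- function(params, cache, glogits, spec, need_gx = TRUE) {
  grads <- list()
  bfc <- conv_bw(cache$fc_in, params$fc, glogits, stride = 1L, pad = 0L)
  grads$fc <- list(w = bfc$gw, b = bfc$gb)
  gcur <- bfc$gx
  for (l in seq(spec$depth, 1L)) {
    gz <- cpp_relu_bw(gcur, cache[[paste0("z", l)]])
    if (l > 1L) {
      bn <- inorm_bw(cache[[paste0("in", l)]], params[[paste0("n", l)]], gz)
      grads[[paste0("n", l)]] <- list(g = bn$gg, b = bn$gb)
      gz <- bn$gx
    }
    xin <- if (l == 1L) cache$x0 else cache[[paste0("a", l - 1L)]]
    bl <- conv_bw(xin, params[[paste0("c", l)]], gz, stride = 2L, pad = 1L,
                  need_gx = l > 1L || need_gx,
                  col = cache[[paste0("col", l)]])
    grads[[paste0("c", l)]] <- list(w = bl$gw, b = bl$gb)
    gcur <- bl$gx
  }
  list(grads = grads, gx = gcur)
}
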