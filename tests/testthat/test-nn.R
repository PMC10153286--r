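# The conv/pool/upconv kernels carry the whole training stack, so their
# analytic gradients are checked against central differences here.

ns <- asNamespace("dtfm")

test_that("convolution forward matches a direct double-precision reference", {
  set.seed(1)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  p <- ns$conv_init(3, 3, 4)
  y <- ns$conv_fw(x, p)
  ref <- array(0, dim(y))
  for (n in 1:2) for (co in 1:4) {
    acc <- matrix(p$b[co], 8, 8)
    for (ci in 1:3) for (ki in 1:3) for (kj in 1:3) {
      xs <- matrix(0, 8, 8)
      si <- (1:8) + ki - 2
      sj <- (1:8) + kj - 2
      vi <- si >= 1 & si <= 8
      vj <- sj >= 1 & sj <= 8
      xs[vi, vj] <- x[si[vi], sj[vj], ci, n]
      acc <- acc + xs * p$w[ki, kj, ci, co]
    }
    ref[, , co, n] <- acc
  }
  expect_lt(max(abs(y - ref)), 1e-5)
})

grad_check <- function(f, analytic, param, n_checks = 25, eps = 1e-3,
                       tol = 0.02) {
  set.seed(42)
  for (i in sample(length(param), min(n_checks, length(param)))) {
    p1 <- param; p1[i] <- p1[i] + eps
    p2 <- param; p2[i] <- p2[i] - eps
    num <- (f(p1) - f(p2)) / (2 * eps)
    expect_lt(abs(num - analytic[i]), tol * max(1, abs(num)))
  }
}

test_that("conv backward agrees with central differences", {
  set.seed(2)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  p <- ns$conv_init(3, 3, 4)
  gy <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  bw <- ns$conv_bw(x, p, gy)
  grad_check(function(xx) sum(ns$conv_fw(xx, p) * gy), bw$gx, x)
  grad_check(function(ww) sum(ns$conv_fw(x, list(w = ww, b = p$b)) * gy),
             bw$gw, p$w)
  # stride-2 path (discriminator)
  gy2 <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  bw2 <- ns$conv_bw(x, p, gy2, stride = 2L)
  grad_check(function(xx) sum(ns$conv_fw(xx, p, stride = 2L) * gy2), bw2$gx, x)
})

test_that("max-pool and up-convolution backward pass the same check", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  pf <- ns$pool_fw(x)
  gy <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  gx <- ns$pool_bw(gy, pf, dim(x))
  grad_check(function(xx) sum(ns$pool_fw(xx)$y * gy), gx, x, eps = 1e-4,
             tol = 1e-3)
  pu <- ns$upconv_init(3, 2)
  gyu <- array(rnorm(16 * 16 * 2 * 2), c(16, 16, 2, 2))
  bu <- ns$upconv_bw(x, pu, gyu)
  grad_check(function(xx) sum(ns$upconv_fw(xx, pu) * gyu), bu$gx, x,
             eps = 1e-4, tol = 1e-3)
  grad_check(function(ww) sum(ns$upconv_fw(x, list(w = ww, b = pu$b)) * gyu),
             bu$gw, pu$w, eps = 1e-4, tol = 1e-3)
})

test_that("the full U-Net backward matches central differences", {
  spec <- generator_spec(depth = 3, base_channels = 4, in_channels = 3,
                         out_channels = 2, scalar_head = TRUE)
  set.seed(4)
  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  prm <- ns$unet_init(spec, seed = 5)
  gy <- array(rnorm(16 * 16 * 2 * 2), c(16, 16, 2, 2))
  gs <- rnorm(2)
  fwd <- ns$unet_forward(prm, x, spec)
  grads <- ns$unet_backward(prm, fwd$cache, gy, spec, gscalar = gs)
  loss <- function(pp) {
    f <- ns$unet_forward(pp, x, spec)
    sum(f$y * gy) + sum(f$scalar * gs)
  }
  set.seed(43)
  for (nm in c("enc1_c1", "bot_c2", "dec1_up", "dec2_c1", "out", "head")) {
    v <- prm[[nm]]$w
    for (i in sample(length(v), min(4, length(v)))) {
      p1 <- prm; p1[[nm]]$w[i] <- p1[[nm]]$w[i] + 1e-3
      p2 <- prm; p2[[nm]]$w[i] <- p2[[nm]]$w[i] - 1e-3
      num <- (loss(p1) - loss(p2)) / 2e-3
      expect_lt(abs(num - grads[[nm]]$w[i]), 0.1 * max(1, abs(num)))
    }
  }
})

test_that("network shape contracts hold for valid grid sizes", {
  spec <- generator_spec(depth = 3, base_channels = 4)
  prm <- ns$unet_init(spec, seed = 1)
  for (n in c(16, 32)) {
    x <- array(0, c(n, n, 3, 1))
    y <- ns$unet_forward(prm, x, spec)$y
    expect_equal(dim(y), c(n, n, 2, 1))
  }
  dspec <- discriminator_spec(depth = 4, base_channels = 4, in_channels = 5)
  dprm <- ns$disc_init(dspec, seed = 2)
  x <- array(rnorm(64 * 64 * 5 * 2), c(64, 64, 5, 2))
  out <- ns$disc_forward(dprm, x, dspec)
  expect_equal(dim(out$logits), c(4, 4, 1, 2))  # patch grid n/16
  scores <- ns$sigmoid(out$logits)
  expect_true(all(scores > 0 & scores < 1))
})

test_that("weight initialization is deterministic in the seed", {
  spec <- generator_spec(depth = 3, base_channels = 4)
  expect_identical(ns$unet_init(spec, seed = 9), ns$unet_init(spec, seed = 9))
  expect_false(identical(ns$unet_init(spec, seed = 9),
                         ns$unet_init(spec, seed = 10)))
})
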