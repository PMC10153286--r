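p_default <- mechanics_params()

test_that("contractility law has Hill midpoint, zero limit, monotonicity", {
  p <- mechanics_params()
  expect_equal(contractility_law(p$e_half, p), p$sigma_max / 2)
  expect_lt(contractility_law(1e-6, p), 1e-6)
  expect_gt(contractility_law(40000, p), contractility_law(5000, p))
  expect_lt(contractility_law(1e9, p), p$sigma_max)
  expect_error(contractility_law(-5, p))
})

test_that("stiffness fields honour their patterning modes", {
  s <- make_stiffness_field("uniform", 64, 2, e0 = 20700)
  expect_true(all(s$values == 20700))
  s0 <- make_stiffness_field("linear", 64, 2, e0 = 20700, gradient = 0)
  expect_equal(s0$values, s$values)
  sg <- make_stiffness_field("linear", 64, 2, e0 = 20000, gradient = 50)
  g <- make_disk_geometry(40, 64, 2)
  expect_equal(mean_stiffness(sg, g), 20000, tolerance = 1e-6)
  expect_error(make_stiffness_field("linear", 64, 2, e0 = 1000, gradient = 500),
               "non-positive")
  sc <- make_stiffness_field("circular", 64, 2, e_inner = 30000,
                             e_outer = 10000, radius = 30, edge_width = 5)
  ctr <- sc$values[32, 32]
  edge <- sc$values[1, 1]
  expect_gt(ctr, 28000); expect_lt(edge, 12000)
})

test_that("strip closed form is odd with the documented saturation limit", {
  expect_equal(strip_closed_form(0, 20, 10, 1000, 5), 0)
  expect_equal(strip_closed_form(-7, 20, 10, 1000, 5),
               -strip_closed_form(7, 20, 10, 1000, 5))
  lim <- strip_closed_form(200, 200, 10, 1000, 5)
  expect_equal(lim, 1000 * 5 / 10, tolerance = 1e-6)
})

test_that("zero contractility gives an identically zero field", {
  g <- make_disk_geometry(40, 64, 2)
  s <- make_stiffness_field("uniform", 64, 2, e0 = 20000)
  tf <- solve_traction(g, s, mechanics_params(sigma_max = 0))
  expect_true(all(tf$components == 0))
})

test_that("simulator matches the elastic-foundation strip closed form", {
  p <- mechanics_params()
  e_s <- 5000
  ell <- localization_length(e_s, p)
  px <- ell / 10
  n <- 128
  w_px <- 8                      # half-width 2 ell
  g <- make_strip_geometry(n, px, w_px)
  s <- make_stiffness_field("uniform", n, px, e0 = e_s)
  tf <- solve_traction(g, s, p)
  sigma_a <- contractility_law(e_s, p)
  mid <- n / 2
  xs <- (seq_len(n) - (n + 1) / 2) * px
  cols <- which(g$indicator[, mid] == 1)
  tx <- tf$components[cols, mid, 1]
  # stored fields are inward-positive; the closed form is outward-positive
  ana <- -strip_closed_form(xs[cols], w = w_px * px, ell = ell,
                            sigma_a = sigma_a, h = p$h)
  expect_lt(sqrt(mean((tx - ana)^2)) / sqrt(mean(ana^2)), 0.02)
})

test_that("traction doubles exactly when contractility doubles", {
  geo <- random_cell_geometry(seed = 5, n = 64)
  s <- make_stiffness_field("uniform", 64, geo$geometry$pixel_size, e0 = 20000)
  t1 <- solve_traction(geo$geometry, s, mechanics_params(sigma_max = 2000))
  t2 <- solve_traction(geo$geometry, s, mechanics_params(sigma_max = 4000))
  expect_lt(max(abs(t2$components - 2 * t1$components)),
            1e-10 * max(abs(t1$components)))
})

test_that("force and torque balance hold for random colonies", {
  for (seed in c(2, 9)) {
    geo <- random_cell_geometry(seed = seed, n = 64)
    px <- geo$geometry$pixel_size
    s <- make_stiffness_field("uniform", 64, px, e0 = 15000)
    tf <- solve_traction(geo$geometry, s)
    expect_lt(force_balance_residual(tf), 1e-6)
    xs <- matrix(dtfm:::pixel_centers(64, px), 64, 64)
    ys <- t(xs)
    fg <- geo$geometry$indicator == 1
    torque <- sum((xs[fg] - mean(xs[fg])) * tf$components[, , 2][fg] -
                  (ys[fg] - mean(ys[fg])) * tf$components[, , 1][fg])
    mag_scale <- sum(traction_magnitude(tf)[fg]) * px
    expect_lt(abs(torque) / mag_scale, 1e-3)
  }
})

test_that("fields are zero outside the footprint", {
  geo <- random_cell_geometry(seed = 13, n = 64)
  s <- make_stiffness_field("uniform", 64, geo$geometry$pixel_size, e0 = 20000)
  tf <- solve_traction(geo$geometry, s)
  out <- geo$geometry$indicator == 0
  expect_true(all(tf$components[, , 1][out] == 0))
  expect_true(all(tf$components[, , 2][out] == 0))
})

test_that("90-degree rotation of the inputs rotates the solution exactly", {
  geo <- random_cell_geometry(seed = 5, n = 64)
  g <- geo$geometry
  s <- make_stiffness_field("linear", 64, g$pixel_size, e0 = 20000,
                            gradient = 40)
  tf <- solve_traction(g, s)
  r90 <- function(m) {
    n <- nrow(m)
    matrix(m[cbind(rep(seq_len(n), times = n), rep(seq(n, 1), each = n))],
           n, n, byrow = TRUE)
  }
  g_r <- cell_geometry(r90(g$indicator), g$pixel_size)
  s_r <- s; s_r$values <- r90(s$values)
  tf_r <- solve_traction(g_r, s_r)
  err <- max(abs(tf_r$components[, , 1] - (-r90(tf$components[, , 2]))),
             abs(tf_r$components[, , 2] - r90(tf$components[, , 1])))
  expect_lt(err, 1e-8)
})

test_that("disk traction is radial, edge-localized, exponentially decaying", {
  p <- mechanics_params()
  radius <- 80; px <- 1.6; n <- 128
  g <- make_disk_geometry(radius, n, px)
  s <- make_stiffness_field("uniform", n, px, e0 = 20000)
  tf <- solve_traction(g, s, p)
  xs <- matrix(dtfm:::pixel_centers(n, px), n, n); ys <- t(xs)
  rho <- sqrt(xs^2 + ys^2)
  fg <- g$indicator == 1
  tx <- tf$components[, , 1]; ty <- tf$components[, , 2]
  rad <- (tx * xs + ty * ys) / pmax(rho, 1e-9)
  tang <- (-tx * ys + ty * xs) / pmax(rho, 1e-9)
  # rasterization breaks exact axisymmetry; tangential leakage stays small
  expect_lt(median(abs(tang[fg]) / pmax(abs(rad[fg]), 1e-12)), 0.01)
  expect_lt(max(abs(tang[fg])) / max(abs(rad[fg])), 0.10)
  # |T| monotone increasing with radius (binned)
  bins <- cut(rho[fg], breaks = seq(0, radius, length.out = 9))
  prof <- tapply(abs(rad[fg]), bins, mean)
  expect_true(all(diff(prof) > 0))
  # interior decay: slope of log|T| vs boundary distance ~ -1/ell (10%)
  ell <- localization_length(20000, p)
  dist_b <- radius - rho[fg]
  sel <- dist_b > ell & dist_b < 3 * ell
  fit <- stats::lm(log(abs(rad[fg][sel])) ~ dist_b[sel])
  expect_equal(unname(stats::coef(fit)[2]), -1 / ell, tolerance = 0.1)
})

test_that("mean traction rises with uniform substrate stiffness", {
  geo <- random_cell_geometry(seed = 5, n = 64)
  px <- geo$geometry$pixel_size
  means <- sapply(c(5000, 20000, 40000), function(e) {
    s <- make_stiffness_field("uniform", 64, px, e0 = e)
    mean(traction_magnitude(solve_traction(geo$geometry, s))[
      geo$geometry$indicator == 1])
  })
  expect_true(all(diff(means) > 0))
})

test_that("traction associates with convex boundary curvature on average", {
  # the boundary-|T| vs curvature association in the foundation model is
  # positive but weak at the single-sample scale (tips of lobes carry both
  # the curvature maxima and the largest displacements); assert the pooled
  # association over 20 random colonies
  rhos <- sapply(1:20, function(i) {
    geo <- random_cell_geometry(seed = 300 + i, n = 64)
    g <- geo$geometry
    s <- make_stiffness_field("uniform", 64, g$pixel_size, e0 = 20000)
    tf <- solve_traction(g, s)
    mag <- traction_magnitude(tf)
    prof <- geo$profile
    ctr <- (g$n + 1) / 2
    # peak |T| along each angular ray (the boundary-layer maximum)
    tvals <- sapply(seq_along(prof$theta), function(k) {
      rr <- seq(0.5, prof$r[k] - 0.01, length.out = 40)
      ix <- pmin(pmax(round(rr * cos(prof$theta[k]) / g$pixel_size + ctr),
                      1), g$n)
      iy <- pmin(pmax(round(rr * sin(prof$theta[k]) / g$pixel_size + ctr),
                      1), g$n)
      max(mag[cbind(ix, iy)])
    })
    ks <- dtfm:::smooth_circular(boundary_curvature(prof), 8)
    ts <- dtfm:::smooth_circular(tvals, 8)
    sel <- ks > 0
    suppressWarnings(stats::cor(ts[sel], ks[sel], method = "spearman"))
  })
  expect_gt(mean(rhos, na.rm = TRUE), 0)
  expect_gte(sum(rhos > 0, na.rm = TRUE), 10L)
})

test_that("stiffness gradients shift traction toward the stiff side", {
  geo <- random_cell_geometry(seed = 8, n = 64)
  g <- geo$geometry
  s_g <- make_stiffness_field("linear", 64, g$pixel_size, e0 = 20000,
                              gradient = 60)
  tf_g <- solve_traction(g, s_g)
  expect_gt(dtfm:::traction_asymmetry(tf_g, g), 0)
})

test_that("grid or pixel-size mismatches are refused", {
  g <- make_disk_geometry(40, 64, 2)
  s <- make_stiffness_field("uniform", 64, 2.5, e0 = 20000)
  expect_error(solve_traction(g, s), "pixel size")
  s2 <- make_stiffness_field("uniform", 32, 2, e0 = 20000)
  expect_error(solve_traction(g, s2))
})
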