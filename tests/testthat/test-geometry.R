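test_that("zero fluctuation or zero waves give an exact circle", {
  for (d in list(shape_descriptor(4, 50, 0, 2), shape_descriptor(0, 50, 0.3, 2))) {
    prof <- generate_profile(d, seed = 11)
    expect_equal(prof$r, rep(50, length(prof$r)))
    kappa <- boundary_curvature(prof)
    expect_equal(kappa, rep(1 / 50, length(kappa)), tolerance = 1e-8)
  }
})

test_that("very large smoothing converges to the circular mean", {
  d <- shape_descriptor(3, 50, 0.3, 5000)
  prof <- generate_profile(d, seed = 3)
  expect_lt(max(prof$r) - min(prof$r), 0.01 * 50)
})

test_that("profile generation is deterministic in (d, seed)", {
  d <- shape_descriptor(6, 80, 0.25, 3)
  p1 <- generate_profile(d, seed = 7)
  p2 <- generate_profile(d, seed = 7)
  expect_identical(p1$r, p2$r)
  p3 <- generate_profile(d, seed = 8)
  expect_false(identical(p1$r, p3$r))
})

test_that("excessive fluctuation is rejected with a descriptive error", {
  d <- shape_descriptor(5, 50, 60, 0)
  expect_error(generate_profile(d, seed = 1, max_retries = 5),
               "fluctuation")
})

test_that("rasterized circle area matches the point-in-polygon oracle", {
  prof <- generate_profile(shape_descriptor(0, 50, 0, 0), seed = 1)
  g <- rasterize_profile(prof, n = 128, pixel_size = 2)
  expect_equal(sum(g$indicator), pi * 25^2, tolerance = 0.01)
  # independent even-odd oracle over all pixel centers
  px <- prof$r * cos(prof$theta)
  py <- prof$r * sin(prof$theta)
  xs <- (seq_len(128) - 64.5) * 2
  qx <- rep(xs, times = 128)
  qy <- rep(xs, each = 128)
  oracle <- matrix(polygon_contains(px, py, qx, qy), 128, 128)
  agree <- mean(oracle == (g$indicator == 1))
  expect_gt(agree, 0.999)
})

test_that("rasterization output is strictly binary and in-frame", {
  geo <- random_cell_geometry(seed = 21, n = 64)
  ind <- geo$geometry$indicator
  expect_true(all(ind %in% c(0, 1)))
  expect_true(all(ind[1, ] == 0) && all(ind[64, ] == 0))
  expect_true(all(ind[, 1] == 0) && all(ind[, 64] == 0))
})

test_that("curves exceeding the field of view are refused", {
  prof <- generate_profile(shape_descriptor(0, 200, 0, 0), seed = 1)
  expect_error(rasterize_profile(prof, n = 64, pixel_size = 2),
               "field of view")
})

test_that("average radius follows the equal-area definition", {
  prof <- generate_profile(shape_descriptor(0, 50, 0, 0), seed = 1)
  g <- rasterize_profile(prof, n = 128, pixel_size = 2)
  expect_equal(average_radius(g), 50, tolerance = 0.01)
  # single-pixel closed form
  ind <- matrix(0, 8, 8); ind[4, 4] <- 1
  g1 <- cell_geometry(ind, pixel_size = 3)
  expect_equal(average_radius(g1), 3 / sqrt(pi))
  expect_error(cell_geometry(matrix(0, 8, 8), 1))
})

test_that("ellipse curvature peaks at the analytic value a/b^2", {
  a <- 100; b <- 50
  theta <- seq(0, 2 * pi, length.out = 2049)[1:2048]
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  prof <- structure(list(theta = theta, r = r,
                         descriptor = shape_descriptor(0, 70, 0, 0), seed = 0),
                    class = "cell_profile")
  kappa <- boundary_curvature(prof)
  expect_equal(max(kappa), a / b^2, tolerance = 1e-3)
  expect_equal(min(kappa), b / a^2, tolerance = 1e-3)
  # peak sits at the pointed ends (theta = 0 / pi)
  expect_true(which.max(kappa) %in% c(1, 1024, 1025, 2048))
})

test_that("curvature sign flips appear only for strong fluctuations", {
  calm <- generate_profile(shape_descriptor(3, 80, 0.05, 4), seed = 2)
  expect_true(all(boundary_curvature(calm) > 0))
  wavy <- generate_profile(shape_descriptor(7, 80, 0.35, 2), seed = 2)
  expect_true(any(boundary_curvature(wavy) < 0))
})

test_that("area preservation holds across random descriptors", {
  set.seed(99)
  for (i in 1:100) {
    d <- shape_descriptor(sample(2:8, 1), runif(1, 40, 190),
                          runif(1, 0, 0.35), runif(1, 1, 8))
    prof <- generate_profile(d, seed = 1000 + i)
    area <- 0.5 * sum(prof$r^2) * (2 * pi / length(prof$r))
    expect_equal(area, pi * d$rbar^2, tolerance = 1e-6)
    pixel_size <- 2 * max(prof$r) / (0.8 * 128)
    g <- rasterize_profile(prof, 128, pixel_size)
    expect_equal(sum(g$indicator) * pixel_size^2, pi * d$rbar^2,
                 tolerance = 0.02)
  }
})

test_that("generated boundaries are simple closed curves", {
  set.seed(5)
  for (i in 1:20) {
    d <- shape_descriptor(sample(2:8, 1), 80, runif(1, 0, 0.35),
                          runif(1, 1, 8))
    expect_true(is_simple_curve(generate_profile(d, seed = i)))
  }
})

test_that("random geometries are deterministic and single-component", {
  g1 <- random_cell_geometry(seed = 42, n = 64)
  g2 <- random_cell_geometry(seed = 42, n = 64)
  expect_identical(g1$geometry$indicator, g2$geometry$indicator)
  expect_identical(g1$geometry$pixel_size, g2$geometry$pixel_size)
  expect_equal(dtfm:::cpp_n_components(g1$geometry$indicator), 1L)
})

test_that("geometry round-trips through the PGM + JSON sidecar", {
  geo <- random_cell_geometry(seed = 3, n = 32)
  path <- file.path(withr::local_tempdir(), "omega.pgm")
  write_geometry(geo$geometry, path, meta = list(seed = 3))
  expect_true(file.exists(path))
  lines <- readLines(path)
  expect_identical(lines[1], "P2")
  meta <- jsonlite::read_json(sub("pgm$", "json", path))
  expect_equal(meta$pixel_size, geo$geometry$pixel_size)
  img <- as.matrix(read.table(path, skip = 3))
  expect_setequal(unique(as.vector(img)), c(0, 255))
  expect_equal(sum(img == 255), sum(geo$geometry$indicator))
})
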