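test_that("traction normalization round-trips and clips as documented", {
  geo <- random_cell_geometry(seed = 4, n = 32)
  s <- make_stiffness_field("uniform", 32, geo$geometry$pixel_size, e0 = 20000)
  tf <- solve_traction(geo$geometry, s)
  scale <- max(traction_magnitude(tf))
  nrm <- normalize_traction(tf, scale)
  expect_true(all(nrm$values >= -1 & nrm$values <= 1))
  back <- denormalize_traction(nrm$values, nrm$scale, tf$pixel_size)
  expect_lt(max(abs(back$components - tf$components)), 1e-5 * scale)
  z <- traction_field(array(0, c(32, 32, 2)), 1)
  expect_true(all(normalize_traction(z, 10)$values == 0))
  expect_error(normalize_traction(tf, 0), "positive")
  # an aggressive scale reports its clipping fraction
  clipped <- normalize_traction(tf, scale / 10)
  expect_gt(clipped$clip_fraction, 0)
})

test_that("dihedral augmentation transforms vectors consistently", {
  geo <- random_cell_geometry(seed = 4, n = 32)
  s <- make_stiffness_field("linear", 32, geo$geometry$pixel_size,
                            e0 = 20000, gradient = 40)
  tf <- solve_traction(geo$geometry, s)
  props <- property_tensor(s, average_radius(geo$geometry),
                           contractility_law(mean_stiffness(s, geo$geometry)))
  smp <- tfm_sample(geo$geometry, props, tf, seed = 4)

  r <- augment_sample(smp, "rot90")
  n <- 32
  # spot-check the vector rotation rule (tx, ty) -> (-ty, tx) at a mapped px
  i <- 20; j <- 12
  expect_equal(r$traction$components[n + 1 - j, i, 1],
               -smp$traction$components[i, j, 2])
  expect_equal(r$traction$components[n + 1 - j, i, 2],
               smp$traction$components[i, j, 1])
  # horizontal flip negates tx only
  fh <- augment_sample(smp, "flip_h")
  expect_equal(fh$traction$components[n + 1 - i, j, 1],
               -smp$traction$components[i, j, 1])
  expect_equal(fh$traction$components[n + 1 - i, j, 2],
               smp$traction$components[i, j, 2])
  # four quarter turns compose to the identity, bitwise
  r4 <- augment_sample(augment_sample(augment_sample(r, "rot90"), "rot90"),
                       "rot90")
  expect_identical(r4$traction$components, smp$traction$components)
  expect_identical(r4$geometry$indicator, smp$geometry$indicator)
  # rot180 equals two quarter turns
  expect_identical(augment_sample(smp, "rot180")$traction$components,
                   augment_sample(r, "rot90")$traction$components)
  # augmentation preserves force balance and the outside-zero invariant
  for (op in c("rot90", "rot270", "flip_v")) {
    a <- augment_sample(smp, op)
    expect_equal(force_balance_residual(a$traction),
                 force_balance_residual(smp$traction), tolerance = 1e-12)
    out <- a$geometry$indicator == 0
    expect_true(all(a$traction$components[, , 1][out] == 0))
  }
  expect_error(augment_sample(smp, 45), "arbitrary-angle")
})

test_that("corpus splits are disjoint, exhaustive, seeded, group-aware", {
  manifest <- tibble::tibble(id = 1:100, base_id = rep(1:50, each = 2))
  sp <- split_corpus(manifest, c(train = 0.8, validation = 0.1, test = 0.1),
                     seed = 3)
  expect_equal(lengths(sp), c(train = 80, validation = 10, test = 10))
  expect_identical(sort(unname(unlist(sp))), 1:100)
  expect_identical(sp, split_corpus(manifest, seed = 3))
  # augmented variants (shared base_id) never straddle splits
  for (nm in names(sp)) {
    bases <- manifest$base_id[manifest$id %in% sp[[nm]]]
    other <- manifest$base_id[manifest$id %in% unlist(sp[setdiff(names(sp), nm)])]
    expect_length(intersect(bases, other), 0)
  }
  expect_error(split_corpus(manifest, c(0.5, 0.4)), "sum to 1")
  expect_error(split_corpus(manifest, c(1.2, -0.2)), "sum to 1|\\(0, 1\\)")
})

test_that("conditioning stack uses the documented channel order", {
  geo <- random_cell_geometry(seed = 4, n = 32)
  g <- geo$geometry
  su <- make_stiffness_field("uniform", 32, g$pixel_size, e0 = 22000)
  props <- property_tensor(su, average_radius(g), 1000)
  smp <- list(geometry = g, properties = props)
  class(smp) <- "tfm_sample"
  x <- encode_inputs(smp)
  expect_identical(x[, , 1], g$indicator)
  expect_equal(length(unique(as.vector(x[, , 2]))), 1L)
  expect_equal(x[1, 1, 2], (22000 - 5000) / 35000)
  sg <- make_stiffness_field("linear", 32, g$pixel_size, e0 = 20000,
                             gradient = 40)
  props$stiffness_field <- sg
  smp$properties <- props
  xg <- encode_inputs(smp)
  expect_true(all(diff(xg[, 1, 2]) > 0))
})

test_that("corpus build is deterministic and persists bitwise", {
  co1 <- build_corpus(4, seed = 31, n = 32)
  co2 <- build_corpus(4, seed = 31, n = 32)
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(co1$samples[[3]]$traction$components,
                   co2$samples[[3]]$traction$components)
  expect_equal(nrow(co1$manifest), length(co1$samples))
  expect_true(all(co1$manifest$ebar >= 5000 & co1$manifest$ebar <= 40000))

  dir <- withr::local_tempdir()
  write_corpus(co1, dir)
  back <- read_corpus(dir)
  expect_identical(back$samples[[2]]$traction$components,
                   co1$samples[[2]]$traction$components)
  expect_equal(back$traction_scale, co1$traction_scale)
  expect_equal(nrow(back$manifest), 4)
  # corpus statistics are reproducible from the manifest alone
  mags <- unlist(lapply(co1$samples, function(s) {
    max(traction_magnitude(s$traction))
  }))
  expect_equal(sort(mags), sort(back$manifest$t_max), tolerance = 1e-12)
})

test_that("property tensors validate their entries", {
  s <- make_stiffness_field("uniform", 16, 2, e0 = 20000)
  expect_error(property_tensor(s, -5, 100))
  expect_error(property_tensor(s, 50, 100, alpha = 0))
  pt <- property_tensor(s, 50, 100)
  expect_equal(pt$alpha, 1)
  # scalar encoding is invertible over the declared range
  r <- default_ranges()
  for (v in c(5000, 17500, 40000)) {
    expect_equal(dtfm:::denorm_scalar(dtfm:::norm_scalar(v, r$e_s), r$e_s), v)
  }
})
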