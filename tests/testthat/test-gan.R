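test_that("adversarial loss matches its closed forms", {
  expect_equal(gan_loss(0.5, 0.5), 2 * log(0.5))
  expect_equal(gan_loss(rep(0.5, 16), rep(0.5, 16)), -2 * log(2))
  # perfect discriminator ceiling
  expect_gt(gan_loss(1 - 1e-7, 1e-7), -1e-5)
  # monotone decrease as fakes fool the discriminator
  vals <- sapply(c(0.1, 0.5, 0.9, 1 - 1e-6), function(pf) gan_loss(0.7, pf))
  expect_true(all(diff(vals) < 0))
  expect_error(gan_loss(1.2, 0.5), "\\[0, 1\\]")
  expect_error(gan_loss(0.5, -0.1), "\\[0, 1\\]")
})

test_that("a short training run is deterministic and checkpointable", {
  co <- tiny_corpus(12, 32L, 7L)
  sp <- list(train = 1:8, validation = integer(0), test = 9:12)
  cfg <- train_config(epochs = 1, batch_size = 4, seed = 5)
  gs <- generator_spec(depth = 3, base_channels = 4)
  ds <- discriminator_spec(depth = 3, base_channels = 4)
  m1 <- train_gan(co, split = sp, gspec = gs, dspec = ds, config = cfg)
  m2 <- train_gan(co, split = sp, gspec = gs, dspec = ds, config = cfg)
  expect_identical(m1$generator, m2$generator)
  expect_identical(m1$discriminator, m2$discriminator)
  expect_equal(nrow(m1$history), 1)
  path <- file.path(withr::local_tempdir(), "ckpt.rds")
  save_checkpoint(m1, path)
  back <- load_checkpoint(path)
  expect_identical(back$generator, m1$generator)
})

test_that("predictions are masked, deterministic, and resolution-checked", {
  co <- tiny_corpus(12, 32L, 7L)
  sp <- list(train = 1:8, validation = integer(0), test = 9:12)
  m <- train_gan(co, split = sp,
                 gspec = generator_spec(depth = 3, base_channels = 4),
                 dspec = discriminator_spec(depth = 3, base_channels = 4),
                 config = train_config(epochs = 2, batch_size = 4, seed = 5))
  s <- co$samples[[9]]
  p1 <- predict_traction(m, s$geometry, s$properties)
  p2 <- predict_traction(m, s$geometry, s$properties)
  expect_identical(p1$components, p2$components)
  out <- s$geometry$indicator == 0
  expect_true(all(p1$components[, , 1][out] == 0))
  expect_true(all(p1$components[, , 2][out] == 0))
  # passing a stiffness field derives the property record internally
  p3 <- predict_traction(m, s$geometry, s$properties$stiffness_field)
  expect_identical(dim(p3$components), dim(p1$components))
  g64 <- make_disk_geometry(40, 64, 2)
  expect_error(predict_traction(m, g64, s$properties), "resolution")
})

test_that("frozen-discriminator training overfits a 4-sample corpus", {
  co <- tiny_corpus(12, 32L, 7L)
  co$samples <- co$samples[1:4]
  co$manifest <- co$manifest[1:4, ]
  sp <- list(train = 1:4, validation = integer(0), test = integer(0))
  m <- train_gan(co, split = sp,
                 gspec = generator_spec(depth = 3, base_channels = 8),
                 dspec = discriminator_spec(depth = 3, base_channels = 4),
                 config = train_config(epochs = 50, batch_size = 4, seed = 2,
                                       lambda_rec = 100, d_lr = 0, lr = 2e-3,
                                       ema = 0))
  h <- m$history
  expect_lt(h$g_rec[50], 0.5 * h$g_rec[1])
  # frozen discriminator stays near chance, so its loss sits near 2 log 2
  expect_equal(unname(h$d_loss[50]), 2 * log(2), tolerance = 0.2)
})

test_that("cell-type scaling is exact and preserves force balance", {
  co <- tiny_corpus(12, 32L, 7L)
  tf <- co$samples[[1]]$traction
  expect_identical(scale_to_cell_type(tf, 1)$components, tf$components)
  doubled <- scale_to_cell_type(tf, 2, cell_type = "fibroblast")
  expect_equal(mean(traction_magnitude(doubled)),
               2 * mean(traction_magnitude(tf)), tolerance = 1e-12)
  expect_equal(force_balance_residual(doubled), force_balance_residual(tf),
               tolerance = 1e-12)
  expect_identical(attr(doubled, "cell_type"), "fibroblast")
  expect_error(scale_to_cell_type(tf, 0), "positive")
  expect_error(scale_to_cell_type(tf, -1), "positive")
})

test_that("corrupted checkpoints fail with the file named", {
  path <- file.path(withr::local_tempdir(), "bad.rds")
  writeLines("not an rds", path)
  expect_error(load_checkpoint(path), "bad.rds")
  path2 <- file.path(withr::local_tempdir(), "notmodel.rds")
  saveRDS(list(1, 2), path2)
  expect_error(load_checkpoint(path2), "not a dtfm checkpoint")
})

test_that("dihedral augmentation during training improves equivariance", {
  co <- tiny_corpus(12, 32L, 7L)
  sp <- list(train = 1:10, validation = integer(0), test = 11:12)
  gs <- generator_spec(depth = 3, base_channels = 4)
  ds <- discriminator_spec(depth = 3, base_channels = 4)
  equiv_err <- function(m) {
    errs <- sapply(11:12, function(i) {
      s <- co$samples[[i]]
      p <- predict_traction(m, s$geometry, s$properties)
      props <- s$properties
      rot <- augment_sample(s, "rot90")
      p_rot <- predict_traction(m, rot$geometry, rot$properties)
      # rotate the unrotated prediction and compare
      pr <- dtfm:::d4_apply_field(s$geometry$indicator,
                                  props$stiffness_field$values,
                                  p$components[, , 1], p$components[, , 2],
                                  "rot90")
      mean(abs(p_rot$components[, , 1] - pr$tx) +
           abs(p_rot$components[, , 2] - pr$ty))
    })
    mean(errs)
  }
  m_plain <- train_gan(co, split = sp, gspec = gs, dspec = ds,
                       config = train_config(epochs = 10, batch_size = 5,
                                             seed = 3, augment = FALSE))
  m_aug <- train_gan(co, split = sp, gspec = gs, dspec = ds,
                     config = train_config(epochs = 10, batch_size = 5,
                                           seed = 3, augment = TRUE))
  expect_lt(equiv_err(m_aug), equiv_err(m_plain))
})
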