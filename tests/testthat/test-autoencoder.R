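test_that("build respects shape contracts and seeded initialization", {
  cfg <- small_ae_cfg()
  m <- build_autoencoder(cfg)
  x <- minmax_normalize(rnorm(512))
  xhat <- reconstruct(m, x)
  expect_length(xhat, 512)
  expect_true(all(is.finite(xhat)))
  expect_true(all(xhat >= 0 & xhat <= 1)) # sigmoid output

  # identical seeds give identical weights; different seeds differ
  expect_identical(build_autoencoder(cfg)$weights, m$weights)
  cfg2 <- small_ae_cfg(seed = 22)
  expect_false(identical(build_autoencoder(cfg2)$weights, m$weights))

  # stride/length mismatch rejected at config time
  expect_error(ae_config(input_length = 4097), "divisible")
  expect_error(ae_config(kernel = 8), "odd")
})

test_that("training reduces reconstruction loss and records full history", {
  w <- small_trained_world()
  h <- w$ae$loss_history
  expect_length(h, w$ae$config$epochs)
  expect_lt(mean(utils::tail(h, 5)), mean(utils::head(h, 5)))
  expect_lt(h[length(h)], h[1])
})

test_that("one-class protocol is enforced", {
  ds <- generate_eeg_dataset(small_synth_cfg(n_per_class = 2))
  m <- build_autoencoder(small_ae_cfg(epochs = 1))
  expect_error(train_autoencoder(m, ds), "one-class")
  expect_error(train_autoencoder(m, ds[0, ]), "at least 2")
  one_epoch <- train_autoencoder(m, ds[ds$label == "healthy", ])
  expect_length(one_epoch$loss_history, 1)
})

test_that("training and inference are deterministic given the seed", {
  ds <- generate_eeg_dataset(small_synth_cfg(n_per_class = 3))
  ref <- ds[ds$label == "interictal", ]
  cfg <- small_ae_cfg(epochs = 3)
  m1 <- train_autoencoder(build_autoencoder(cfg), ref)
  m2 <- train_autoencoder(build_autoencoder(cfg), ref)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$loss_history, m2$loss_history)
  x <- ds$samples[[1]]
  expect_identical(reconstruct(m1, x), reconstruct(m1, x))
})

test_that("record length must match the model working length", {
  m <- build_autoencoder(small_ae_cfg())
  expect_error(reconstruct(m, rnorm(100)), "working length")
})

test_that("held-out reference-class records reconstruct better than ictal ones", {
  # train on part of the interictal records, compare held-out MSE
  # distributions across classes
  cfg <- small_synth_cfg(seed = 31, n_per_class = 16)
  ds <- generate_eeg_dataset(cfg)
  inter <- ds[ds$label == "interictal", ]
  ae <- train_autoencoder(build_autoencoder(small_ae_cfg(epochs = 60,
                                                         seed = 32)),
                          inter[1:12, ])
  held_inter <- extract_features(ae, inter[13:16, ])
  ictal <- extract_features(ae, ds[ds$label == "ictal", ])
  expect_lt(median(held_inter$mse), quantile(ictal$mse, 0.10))
})

test_that("checkpoint save/load round trips reconstructions bit for bit", {
  w <- small_trained_world()
  f <- withr::local_tempfile(fileext = ".json")
  save_autoencoder(w$ae, f)
  back <- load_autoencoder(f)
  expect_identical(back$weights, w$ae$weights)
  expect_equal(back$loss_history, w$ae$loss_history)
  x <- w$ds$samples[[1]]
  expect_identical(reconstruct(back, x), reconstruct(w$ae, x))
  expect_error(load_autoencoder({
    g <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(format = "other"), g)
    g
  }), "not an autoencoder checkpoint")
})

test_that("tidy/glance expose the training history", {
  w <- small_trained_world()
  td <- tidy(w$ae)
  expect_named(td, c("epoch", "loss"))
  expect_equal(nrow(td), w$ae$config$epochs)
  gl <- glance(w$ae)
  expect_true(gl$trained)
  expect_equal(gl$final_loss, utils::tail(w$ae$loss_history, 1))
})
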