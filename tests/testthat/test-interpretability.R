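test_that("exact Shapley values satisfy efficiency for every sample and class", {
  tab <- planted_table(n_per_class = 10)
  m <- train_classifier(tab, kind = "random_forest", seed = 5)
  sh <- exact_shapley(m, tab, tab, seed = 6)
  pz <- predict(m, tab, type = "prob")
  base <- sh$baseline
  for (k in 1:3) {
    lhs <- rowSums(sh$phi[, , k])
    expect_equal(lhs, unname(pz[, k] - base[k]), tolerance = 1e-6)
  }
})

test_that("exact Shapley matches the permutation-average oracle", {
  tab <- planted_table(n_per_class = 8)
  set.seed(60)
  sub <- tab[sort(sample.int(nrow(tab), 20)), ]
  bg <- tab[seq(1, nrow(tab), by = 2), ]
  m <- train_classifier(tab, kind = "gradient_boosting", seed = 7)
  sh <- exact_shapley(m, sub, bg, max_background = nrow(bg))
  oracle <- oracle_shapley(m, sub, bg)
  expect_equal(unname(sh$phi), oracle, tolerance = 1e-10)
})

test_that("symmetric duplicate features receive equal attributions", {
  set.seed(70)
  tab <- tibble::tibble(
    label = factor(rep(eeg_classes(), each = 5), eeg_classes()),
    a = rnorm(15), b = 0, c = rnorm(15))
  tab$b <- tab$a # identical columns
  sym <- probe_classifier(function(X) {
    s <- plogis(X$a + X$b) # symmetric in a and b
    cbind(s, (1 - s) / 2, (1 - s) / 2)
  }, feature_names = c("a", "b", "c"))
  sh <- exact_shapley(sym, tab, tab)
  expect_equal(sh$phi[, "a", ], sh$phi[, "b", ], tolerance = 1e-10)
  expect_equal(max(abs(sh$phi[, "c", ])), 0)
})

test_that("two-feature closed form: f(x1,x2) = x1 attributes everything to x1", {
  set.seed(71)
  tab <- tibble::tibble(
    label = factor(rep(eeg_classes(), length.out = 12), eeg_classes()),
    x1 = runif(12), x2 = runif(12))
  f <- probe_classifier(function(X) cbind(X$x1, 1 - X$x1, 0),
                        feature_names = c("x1", "x2"))
  sh <- exact_shapley(f, tab, tab)
  expect_equal(unname(sh$phi[, "x1", 1]), tab$x1 - mean(tab$x1),
               tolerance = 1e-12)
  expect_equal(max(abs(sh$phi[, "x2", ])), 0)
})

test_that("permutation importance is exactly zero for a provably ignored feature", {
  tab <- planted_table(n_per_class = 15)
  m <- probe_classifier(function(X) {
    cls <- cut(X$f_signal, c(-Inf, 2.5, 7.5, Inf), labels = FALSE)
    p <- matrix(0, nrow(X), 3)
    p[cbind(seq_len(nrow(X)), cls)] <- 1
    p
  }, feature_names = c("f_signal", "f_noise1", "f_noise2"))
  imp <- permutation_importance(m, tab, n_repeats = 30, seed = 8)
  expect_identical(imp$importance[imp$feature == "f_noise1"], 0)
  expect_identical(imp$importance[imp$feature == "f_noise2"], 0)
  # the lone informative feature dominates on balanced 3-class data
  expect_gte(imp$importance[imp$feature == "f_signal"], 0.5)
  expect_equal(imp$feature[which.max(imp$importance)], "f_signal")
  # deterministic given the seed
  imp2 <- permutation_importance(m, tab, n_repeats = 30, seed = 8)
  expect_identical(imp, imp2)
  expect_error(permutation_importance(m, tab[1, ], n_repeats = 2),
               "at least 2")
})

test_that("feature ranking sorts by class-averaged mean |SHAP| with alphabetical ties", {
  imp <- tibble::tibble(feature = c("mse", "cs", "orsr"),
                        mean_abs_shap = c(0.2, 0.3, 0.05))
  expect_equal(rank_features(imp), c("cs", "mse", "orsr"))
  ties <- tibble::tibble(feature = c("orsr", "cs", "mse"),
                         mean_abs_shap = c(0.1, 0.1, 0.1))
  expect_equal(rank_features(ties), c("cs", "mse", "orsr"))
  single <- tibble::tibble(feature = "mse", mean_abs_shap = 1)
  expect_equal(rank_features(single), "mse")
})

test_that("interpretability report bundles both methods and serializes", {
  tab <- planted_table(n_per_class = 10)
  m <- train_classifier(tab, kind = "random_forest", seed = 5)
  rep <- interpret_classifier(m, tab, tab, n_repeats = 5, seed = 6)
  expect_s3_class(rep, "importance_report")
  expect_setequal(rep$ranking, c("f_signal", "f_noise1", "f_noise2"))
  expect_equal(rep$ranking[1], "f_signal")
  td <- tidy(rep)
  expect_named(td, c("feature", "importance", "sd", "mean_abs_shap"))
  f <- withr::local_tempfile(fileext = ".json")
  write_importance_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$ranking, rep$ranking)
})

test_that("dimensionality guard refuses enumeration beyond 10 features", {
  tab <- planted_table(n_per_class = 5)
  for (i in 1:9) tab[[paste0("extra", i)]] <- rnorm(15)
  m <- probe_classifier(function(X) matrix(1 / 3, nrow(X), 3),
                        feature_names = setdiff(names(tab),
                                                c("record_id", "label")))
  expect_error(exact_shapley(m, tab, tab), "10 features")
})
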