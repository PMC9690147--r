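test_that("stratified 75/25 split partitions 300 balanced rows into 225/75", {
  tab <- planted_table(n_per_class = 100)
  sp <- split_table(tab, 0.75, seed = 3)
  expect_equal(nrow(sp$train), 225)
  expect_equal(nrow(sp$test), 75)
  expect_equal(as.vector(table(sp$test$label)), c(25, 25, 25))
  # disjoint and exhaustive
  expect_length(intersect(sp$train$record_id, sp$test$record_id), 0)
  expect_setequal(c(sp$train$record_id, sp$test$record_id), tab$record_id)
  # deterministic
  sp2 <- split_table(tab, 0.75, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp$train$record_id,
                         split_table(tab, 0.75, seed = 4)$train$record_id))
})

test_that("split honours fractions and guards degenerate strata", {
  tab <- planted_table(n_per_class = 2)[1:4, ] # 2 classes x 2 rows
  sp <- split_table(tab, 0.5, seed = 1)
  expect_equal(nrow(sp$train), 2)
  expect_equal(nrow(sp$test), 2)
  expect_error(split_table(tab, 1.5), "between 0 and 1")
  tab1 <- planted_table(n_per_class = 1)
  expect_error(split_table(tab1, 0.75), "at least 2")
})

test_that("split preserves class proportions to within one record", {
  tab <- planted_table(n_per_class = 30)
  for (frac in c(0.6, 0.75, 0.8)) {
    sp <- split_table(tab, frac, seed = 9)
    got <- table(sp$train$label)
    expect_true(all(abs(got - frac * 30) <= 1))
  }
})

test_that("all three ensembles fit separable data and emit proper probabilities", {
  tab <- planted_table(n_per_class = 25)
  for (kind in c("random_forest", "adaboost", "gradient_boosting")) {
    m <- train_classifier(tab, kind = kind, seed = 6)
    ev <- evaluate_classifier(m, tab)
    expect_gte(ev$test_accuracy, 0.99)
    p <- predict(m, tab, type = "prob")
    expect_equal(dim(p), c(75, 3))
    expect_equal(unname(rowSums(p)), rep(1, 75), tolerance = 1e-6)
    expect_true(all(p >= 0))
    # determinism under the seed
    m2 <- train_classifier(tab, kind = kind, seed = 6)
    expect_identical(predict(m2, tab), predict(m, tab))
  }
  expect_error(train_classifier(tab, kind = "svm"), "arg")
  single <- tab[tab$label == "healthy", ]
  expect_error(train_classifier(single, kind = "random_forest"),
               "single class")
})

test_that("label-shuffled features give chance-level test accuracy", {
  tab <- planted_table(n_per_class = 100)
  set.seed(41)
  tab$label <- sample(tab$label)
  sp <- split_table(tab, 0.75, seed = 42)
  m <- train_classifier(sp$train, kind = "random_forest", seed = 43)
  acc <- evaluate_classifier(m, sp$test)$test_accuracy
  # binomial 99% band around 1/3 at n = 75
  expect_gte(acc, 0.20)
  expect_lte(acc, 0.47)
})

test_that("evaluation reports a consistent confusion matrix", {
  tab <- planted_table(n_per_class = 25)
  perfect <- probe_classifier(function(X) {
    # reads the informative feature directly
    cls <- cut(X$f_signal, c(-Inf, 2.5, 7.5, Inf), labels = FALSE)
    p <- matrix(0, nrow(X), 3)
    p[cbind(seq_len(nrow(X)), cls)] <- 1
    p
  }, feature_names = c("f_signal", "f_noise1", "f_noise2"))
  ev <- evaluate_classifier(perfect, tab)
  expect_equal(unname(ev$confusion), diag(c(25, 25, 25)))
  expect_equal(ev$test_accuracy, 1)

  constant <- probe_classifier(function(X) {
    matrix(rep(c(0, 0, 1), each = nrow(X)), nrow(X), 3)
  }, feature_names = c("f_signal", "f_noise1", "f_noise2"))
  ev2 <- evaluate_classifier(constant, tab)
  expect_equal(sum(ev2$confusion[, 1:2]), 0)
  expect_equal(ev2$test_accuracy, 1 / 3)

  # accuracy equals trace/total recomputed from the matrix itself
  m <- train_classifier(tab, kind = "adaboost", seed = 2)
  ev3 <- evaluate_classifier(m, tab)
  expect_equal(ev3$test_accuracy,
               sum(diag(ev3$confusion)) / sum(ev3$confusion))
  expect_equal(sum(ev3$confusion), nrow(tab))
})

test_that("feature-name mismatches are rejected at predict time", {
  tab <- planted_table()
  m <- train_classifier(tab, kind = "random_forest", seed = 1)
  bad <- dplyr::rename(tab, other = "f_signal")
  expect_error(predict(m, bad), "feature mismatch")
  expect_error(evaluate_classifier(m, tab[0, ]), "empty")
})

test_that("eval reports serialize to JSON with nested confusion rows", {
  tab <- planted_table()
  ev <- evaluate_classifier(train_classifier(tab, "random_forest", seed = 1),
                            tab, train = tab)
  f <- withr::local_tempfile(fileext = ".json")
  write_eval_report(ev, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$test_accuracy, ev$test_accuracy)
  expect_equal(back$confusion, unname(unclass(ev$confusion)))
  expect_equal(back$class_order, eeg_classes())
})
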