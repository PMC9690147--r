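#' Split a feature table into training and test sets
#'
#' Random, disjoint, exhaustive partition; stratified by class by default
#' so per-class test counts stay balanced (a 75/25 split of 300 balanced
#' records gives exactly 25 test records per class). Deterministic given
#' the seed.
#'
#' @param table Feature table tibble with a `label` column.
#' @param train_fraction Fraction assigned to training (default 0.75).
#' @param seed Split seed.
#' @param stratified Stratify by class (default TRUE).
#' @return A list with elements `train` and `test`.
#' @export
split_table <- function(table, train_fraction = 0.75, seed = 1,
                        stratified = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  n <- nrow(table)
  if (stratified) {
    counts <- table(table$label)
    if (any(counts[counts > 0] < 2)) {
      stop("stratified split needs at least 2 records per present class",
           call. = FALSE)
    }
    train_idx <- unlist(lapply(levels(table$label), function(cl) {
      idx <- which(table$label == cl)
      if (length(idx) == 0) return(integer(0))
      sample(idx, round(train_fraction * length(idx)))
    }))
  } else {
    train_idx <- sample.int(n, round(train_fraction * n))
  }
  train_idx <- sort(train_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[setdiff(seq_len(n), train_idx), , drop = FALSE])
}

classifier_kinds <- function() c("random_forest", "adaboost",
                                 "gradient_boosting")

#' Train an ensemble classifier on a feature table
#'
#' Three ensembles are available: a random forest (100 trees via
#' \pkg{randomForest}), multiclass AdaBoost (SAMME over shallow trees),
#' and gradient boosting (multinomial trees via \pkg{xgboost}).
#' Hyperparameters follow common defaults and can be overridden via
#' `...`: `n_trees` (all, default 100), `max_depth` (AdaBoost and
#' gradient boosting, default 3), `learning_rate` (AdaBoost 1.0,
#' gradient boosting 0.1).
#'
#' @param table Training feature table (columns `record_id`, `label`,
#'   features).
#' @param kind One of `"random_forest"`, `"adaboost"`,
#'   `"gradient_boosting"`.
#' @param seed Training seed; fits are deterministic given it.
#' @param ... Hyperparameter overrides, see Details.
#' @return An `eeg_classifier` object with a [predict()] method returning
#'   labels (`type = "class"`) or a 3-class probability matrix
#'   (`type = "prob"`, rows summing to 1).
#' @export
train_classifier <- function(table, kind = classifier_kinds(), seed = 1,
                             ...) {
  kind <- match.arg(kind)
  feats <- feature_names(table)
  y <- droplevels(table$label)
  if (nlevels(y) < 2) {
    stop("training data contains a single class; nothing to classify",
         call. = FALSE)
  }
  X <- as.data.frame(table[feats])
  opts <- list(...)
  n_trees <- opts$n_trees %||% 100
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  fit <- switch(
    kind,
    random_forest = randomForest::randomForest(
      x = X, y = y, ntree = n_trees),
    adaboost = fit_adaboost(X, y, n_trees = n_trees,
                            learning_rate = opts$learning_rate %||% 1.0,
                            max_depth = opts$max_depth %||% 3),
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X),
                                     label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = nlevels(y),
                      max_depth = opts$max_depth %||% 3,
                      eta = opts$learning_rate %||% 0.1,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = n_trees, verbose = 0)
    })
  structure(list(kind = kind, fit = fit, feature_names = feats,
                 class_levels = levels(y), seed = seed),
            class = "eeg_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap a probability function as a classifier
#'
#' Builds an `eeg_classifier` around an arbitrary function mapping a
#' feature data frame to a class-probability matrix. Useful for probing
#' the interpretability machinery with models whose behaviour is known in
#' closed form (e.g. a model that provably ignores a feature).
#'
#' @param predict_fn Function taking a data frame of the named features
#'   and returning an (n x classes) probability matrix.
#' @param feature_names Character vector of feature column names.
#' @param class_levels Class labels of the probability columns.
#' @return An `eeg_classifier` of kind `"custom"`.
#' @export
probe_classifier <- function(predict_fn, feature_names,
                             class_levels = eeg_classes()) {
  stopifnot(is.function(predict_fn))
  structure(list(kind = "custom", fit = predict_fn,
                 feature_names = feature_names,
                 class_levels = class_levels, seed = NA_integer_),
            class = "eeg_classifier")
}

# Multiclass AdaBoost (SAMME) over shallow rpart trees. Depth-3 base
# learners by default: with K = 3 classes SAMME needs base error < 2/3,
# and depth-1 stumps on a low-dimensional feature space cannot express
# the feature conjunctions that separate overlapping classes.
fit_adaboost <- function(X, y, n_trees = 100, learning_rate = 1.0,
                         max_depth = 3) {
  n <- nrow(X)
  K <- nlevels(y)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_trees)
  alphas <- numeric(n_trees)
  df <- cbind(.y = y, X)
  used <- 0L
  for (m in seq_len(n_trees)) {
    stump <- rpart::rpart(.y ~ ., data = df, weights = w,
                          method = "class",
                          control = rpart::rpart.control(
                            maxdepth = max_depth, cp = -1, minsplit = 2,
                            minbucket = 1, xval = 0))
    pred <- predict(stump, X, type = "class")
    miss <- as.numeric(pred != y)
    err <- sum(w * miss)
    if (err >= 1 - 1 / K) break # worse than chance: stop boosting
    err <- max(err, 1e-10)
    alpha <- learning_rate * (log((1 - err) / err) + log(K - 1))
    used <- used + 1L
    stumps[[used]] <- stump
    alphas[used] <- alpha
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
    if (err <= 1e-10) break # perfect stump: voting is already decided
  }
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)],
       classes = levels(y))
}

predict_adaboost <- function(fit, X) {
  K <- length(fit$classes)
  scores <- matrix(0, nrow(X), K, dimnames = list(NULL, fit$classes))
  for (m in seq_along(fit$stumps)) {
    pred <- predict(fit$stumps[[m]], X, type = "class")
    scores[cbind(seq_len(nrow(X)), as.integer(pred))] <-
      scores[cbind(seq_len(nrow(X)), as.integer(pred))] + fit$alphas[m]
  }
  scores
}

#' @export
predict.eeg_classifier <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing) > 0) {
    stop("feature mismatch: trained on ",
         paste(object$feature_names, collapse = ", "),
         " but new data lacks ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.data.frame(newdata[object$feature_names])
  prob <- switch(
    object$kind,
    custom = {
      p <- object$fit(X)
      colnames(p) <- object$class_levels
      p
    },
    random_forest = {
      p <- predict(object$fit, X, type = "prob")
      p[, object$class_levels, drop = FALSE]
    },
    adaboost = {
      s <- predict_adaboost(object$fit, X)
      s / pmax(rowSums(s), .Machine$double.eps)
    },
    gradient_boosting = {
      p <- predict(object$fit, xgboost::xgb.DMatrix(as.matrix(X)))
      if (!is.matrix(p)) {
        p <- matrix(p, ncol = length(object$class_levels), byrow = TRUE)
      }
      dimnames(p) <- list(NULL, object$class_levels)
      p
    })
  if (type == "prob") {
    return(prob)
  }
  # ties broken toward the lowest class index, for determinism
  idx <- apply(prob, 1, which.max)
  factor(object$class_levels[idx], levels = eeg_classes())
}

#' Evaluate a classifier on a feature table
#'
#' @param model An `eeg_classifier`.
#' @param test Feature table to evaluate on (typically the held-out
#'   split).
#' @param train Optional training table; when given, training accuracy is
#'   reported too.
#' @return An `eeg_eval` report: 3x3 confusion matrix (rows = true class,
#'   columns = predicted), test accuracy, per-class recall, and training
#'   accuracy if `train` was supplied.
#' @export
evaluate_classifier <- function(model, test, train = NULL) {
  if (nrow(test) == 0) stop("test table is empty", call. = FALSE)
  pred <- predict(model, test, type = "class")
  truth <- factor(as.character(test$label), levels = eeg_classes())
  cm <- table(truth = truth, predicted = pred)
  cm <- unclass(cm)
  acc <- sum(diag(cm)) / sum(cm)
  recall <- diag(cm) / pmax(rowSums(cm), 1)
  train_acc <- NA_real_
  if (!is.null(train)) {
    ptr <- predict(model, train, type = "class")
    train_acc <- mean(as.character(ptr) == as.character(train$label))
  }
  structure(list(classifier = model$kind, confusion = cm,
                 test_accuracy = acc, train_accuracy = train_acc,
                 per_class_recall = recall, n_test = sum(cm)),
            class = "eeg_eval")
}

#' @export
print.eeg_eval <- function(x, ...) {
  cat("Evaluation of", x$classifier, "on", x$n_test, "records\n")
  print(x$confusion)
  cat("test accuracy:", format(x$test_accuracy, digits = 4))
  if (!is.na(x$train_accuracy)) {
    cat(" | training accuracy:", format(x$train_accuracy, digits = 4))
  }
  cat("\n")
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `eeg_eval`.
#' @param ... Unused.
#' @return `tidy()`: the confusion matrix in long form (`truth`,
#'   `predicted`, `n`); `glance()`: a one-row accuracy summary.
#' @export
tidy.eeg_eval <- function(x, ...) {
  df <- as.data.frame(as.table(x$confusion))
  names(df) <- c("truth", "predicted", "n")
  tibble::as_tibble(df)
}

#' @rdname tidy.eeg_eval
#' @export
glance.eeg_eval <- function(x, ...) {
  tibble::tibble(classifier = x$classifier,
                 test_accuracy = x$test_accuracy,
                 train_accuracy = x$train_accuracy,
                 n_test = x$n_test)
}

eval_to_list <- function(report) {
  list(classifier = report$classifier,
       confusion = unname(apply(report$confusion, 1, function(r)
         as.integer(r), simplify = FALSE)),
       class_order = eeg_classes(),
       test_accuracy = report$test_accuracy,
       train_accuracy = if (is.na(report$train_accuracy)) NULL
                        else report$train_accuracy,
       per_class_recall = as.list(report$per_class_recall),
       n_test = report$n_test)
}

#' Write an evaluation report as JSON
#'
#' @param report An `eeg_eval`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(eval_to_list(report), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
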