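#' Permutation feature importance
#'
#' Importance of a feature = mean drop in accuracy when that feature's
#' column is independently shuffled, over `n_repeats` shuffles. A feature
#' the model never uses gets importance exactly 0 because predictions are
#' unchanged by permuting it.
#'
#' @param model An `eeg_classifier`.
#' @param table Feature table to measure on (typically the test split).
#' @param n_repeats Shuffles per feature (default 30).
#' @param seed Shuffle seed.
#' @return A tibble with `feature`, `importance` (mean accuracy drop) and
#'   `sd` over repeats, in the model's feature order.
#' @export
permutation_importance <- function(model, table, n_repeats = 30, seed = 1) {
  if (nrow(table) < 2) {
    stop("permutation importance needs at least 2 rows", call. = FALSE)
  }
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  truth <- as.character(table$label)
  baseline <- mean(as.character(predict(model, table)) == truth)
  feats <- model$feature_names
  stats <- purrr::map(feats, function(f) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      shuffled <- table
      shuffled[[f]] <- sample(shuffled[[f]])
      baseline - mean(as.character(predict(model, shuffled)) == truth)
    }, numeric(1))
    tibble::tibble(feature = f, importance = mean(drops), sd = sd(drops))
  })
  dplyr::bind_rows(stats)
}

#' Exact interventional Shapley values
#'
#' Per-sample, per-class feature attributions by full enumeration of all
#' `2^d` feature coalitions (`d` = number of features, at most 10; here
#' typically 3). The value of a coalition S for a sample z is the mean
#' model output over the background set with z's features spliced in on S;
#' attributions use the exact Shapley weights, so no sampling
#' approximation is involved. Satisfies the efficiency axiom: per sample
#' and class, attributions sum to `f(z) - mean_b f(b)`.
#'
#' @param model An `eeg_classifier`.
#' @param table Feature table of samples to explain.
#' @param background Feature table serving as the interventional baseline
#'   (typically the training split, subsampled to at most `max_background`
#'   rows).
#' @param max_background Cap on background rows (default 100, seeded
#'   subsample).
#' @param seed Seed for the background subsample.
#' @return An `eeg_shapley` object: array `phi` of dimension
#'   (samples x features x classes), the per-class baselines, and the
#'   feature names.
#' @export
exact_shapley <- function(model, table, background, max_background = 100,
                          seed = 1) {
  feats <- model$feature_names
  d <- length(feats)
  if (d > 10) {
    stop("exact enumeration is limited to 10 features (got ", d, "); ",
         "use a sampling approximation instead", call. = FALSE)
  }
  if (nrow(background) == 0) stop("background table is empty", call. = FALSE)
  if (nrow(background) > max_background) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    background <- background[sort(sample.int(nrow(background),
                                             max_background)), ,
                             drop = FALSE]
  }
  n <- nrow(table)
  nb <- nrow(background)
  classes <- model$class_levels
  K <- length(classes)

  # v[[S]] = n x K matrix of coalition values, S encoded as a bitmask
  coalition_value <- function(mask) {
    in_s <- feats[bitwAnd(mask, bitwShiftL(1L, seq_len(d) - 1L)) != 0L]
    # rows: for each sample z, nb hybrid rows (background with z's
    # features on S)
    hybrid <- background[rep(seq_len(nb), times = n), feats, drop = FALSE]
    for (f in in_s) {
      hybrid[[f]] <- rep(table[[f]], each = nb)
    }
    p <- predict(model, hybrid, type = "prob")
    g <- rep(seq_len(n), each = nb)
    out <- rowsum(p, g) / nb
    unname(out)
  }
  values <- lapply(0:(2^d - 1), coalition_value)

  fact <- factorial(0:d)
  phi <- array(0, dim = c(n, d, K),
               dimnames = list(NULL, feats, classes))
  for (j in seq_len(d)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(2^d - 1)) {
      if (bitwAnd(mask, bit) != 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(d) - 1L)) != 0L)
      w <- fact[s + 1] * fact[d - s] / fact[d + 1] # s!(d-s-1)!/d!
      delta <- values[[mask + bit + 1L]] - values[[mask + 1L]]
      phi[, j, ] <- phi[, j, ] + w * delta
    }
  }
  structure(list(phi = phi, baseline = values[[1]][1, ],
                 feature_names = feats, class_levels = classes,
                 record_id = if ("record_id" %in% names(table))
                   table$record_id else NULL),
            class = "eeg_shapley")
}

#' Mean absolute Shapley value per feature
#'
#' The bar-chart summary: the mean of |phi| over samples, per feature and
#' class, plus the class average used for ranking.
#'
#' @param shapley An `eeg_shapley` from [exact_shapley()].
#' @return A tibble with `feature`, one column per class, and
#'   `mean_abs_shap` (class-averaged).
#' @export
shapley_importance <- function(shapley) {
  m <- apply(abs(shapley$phi), c(2, 3), mean)
  out <- tibble::as_tibble(m, rownames = "feature")
  out$mean_abs_shap <- rowMeans(m)
  out
}

#' Rank features by Shapley importance
#'
#' Sorts by class-averaged mean |phi| descending; ties break
#' alphabetically.
#'
#' @param importance A tibble with columns `feature` and `mean_abs_shap`
#'   (from [shapley_importance()]), or an `eeg_shapley` object.
#' @return Character vector of feature names, most important first.
#' @export
rank_features <- function(importance) {
  if (inherits(importance, "eeg_shapley")) {
    importance <- shapley_importance(importance)
  }
  ord <- order(-importance$mean_abs_shap, importance$feature)
  importance$feature[ord]
}

#' Full interpretability report for one classifier
#'
#' Bundles permutation importance and exact Shapley values, the per-class
#' mean |phi| summary and the resulting feature ranking.
#'
#' @param model An `eeg_classifier`.
#' @param test Feature table to measure importance on.
#' @param background Background table for the Shapley baseline.
#' @param n_repeats Permutation repeats (default 30).
#' @param seed Seed for shuffles and background subsampling.
#' @return An `importance_report` list.
#' @export
interpret_classifier <- function(model, test, background, n_repeats = 30,
                                 seed = 1) {
  perm <- permutation_importance(model, test, n_repeats = n_repeats,
                                 seed = seed)
  shap <- exact_shapley(model, test, background, seed = seed)
  imp <- shapley_importance(shap)
  structure(list(classifier = model$kind,
                 permutation = perm,
                 shapley = shap,
                 shap_importance = imp,
                 ranking = rank_features(imp)),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Interpretability report for", x$classifier, "\n")
  cat("  feature ranking (mean |SHAP|):",
      paste(x$ranking, collapse = " > "), "\n")
  cat("  permutation importance:\n")
  print(as.data.frame(x$permutation), row.names = FALSE)
  invisible(x)
}

#' Tidy an interpretability report
#'
#' @param x An `importance_report`.
#' @param ... Unused.
#' @return A tibble joining permutation importance and mean |SHAP| per
#'   feature.
#' @export
tidy.importance_report <- function(x, ...) {
  dplyr::left_join(
    x$permutation,
    x$shap_importance[, c("feature", "mean_abs_shap")],
    by = "feature")
}

importance_to_list <- function(report) {
  shap_means <- report$shap_importance
  list(classifier = report$classifier,
       permutation = lapply(seq_len(nrow(report$permutation)), function(i) {
         as.list(report$permutation[i, ])
       }),
       mean_abs_shap = lapply(seq_len(nrow(shap_means)), function(i) {
         as.list(shap_means[i, ])
       }),
       ranking = as.list(report$ranking))
}

#' Write an interpretability report as JSON
#'
#' @param report An `importance_report`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_importance_report <- function(report, path) {
  jsonlite::write_json(importance_to_list(report), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
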