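#' Fit the PCA feature baseline
#'
#' The comparison feature extractor: centered principal component analysis
#' on the raw normalized signals of all classes pooled (the unsupervised
#' baseline sees every class, whereas the autoencoder sees only the
#' reference class — that asymmetry is the comparison design). Component
#' signs are fixed so each component's largest-magnitude loading is
#' positive, making fits reproducible.
#'
#' @param data EEG dataset tibble; needs more records than components.
#' @param k Number of components to keep (default 10).
#' @return An `eeg_pca` object with fields `mean` (length-L center),
#'   `components` (k x L orthonormal rows) and `explained_variance`
#'   (length k, non-increasing).
#' @export
fit_pca <- function(data, k = 10) {
  if (nrow(data) <= k) {
    stop("PCA needs more records (", nrow(data), ") than components (",
         k, ")", call. = FALSE)
  }
  X <- t(dataset_matrix(data, length(data$samples[[1]])))
  fit <- prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  comp <- t(fit$rotation) # k x L
  flip <- apply(comp, 1, function(r) sign(r[which.max(abs(r))]))
  comp <- comp * flip
  structure(list(mean = as.numeric(fit$center), components = comp,
                 explained_variance = fit$sdev[seq_len(k)]^2, k = k,
                 length = ncol(comp)),
            class = "eeg_pca")
}

#' Project a dataset onto fitted principal components
#'
#' @param model An `eeg_pca` from [fit_pca()].
#' @param data EEG dataset tibble; record length must match the fit.
#' @return Feature table tibble with columns `record_id`, `label`,
#'   `pc1..pck`.
#' @export
pca_transform <- function(model, data) {
  X <- t(dataset_matrix(data, model$length))
  scores <- sweep(X, 2, model$mean) %*% t(model$components)
  colnames(scores) <- paste0("pc", seq_len(model$k))
  dplyr::bind_cols(
    tibble::tibble(record_id = data$record_id, label = data$label),
    tibble::as_tibble(scores)
  )
}

#' Min-max normalize leading principal components
#'
#' Scales the first `m` PC columns each into \[0, 1\] — used only for
#' distribution plots, never as classifier input.
#'
#' @param table A PC feature table from [pca_transform()].
#' @param m How many leading components to scale (default 3).
#' @return The table with the first `m` PC columns rescaled.
#' @export
normalize_pcs <- function(table, m = 3) {
  feats <- feature_names(table)
  if (m > length(feats)) {
    stop("asked to normalize ", m, " components but table has only ",
         length(feats), call. = FALSE)
  }
  for (f in feats[seq_len(m)]) {
    table[[f]] <- minmax_normalize(table[[f]])
  }
  table
}

#' @export
print.eeg_pca <- function(x, ...) {
  cat("PCA feature baseline:", x$k, "components on length-", x$length,
      "signals\n", sep = " ")
  cat("  explained variance:",
      paste(format(x$explained_variance, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a fitted PCA baseline
#'
#' @param x An `eeg_pca`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with `component`, `variance` and
#'   `prop_variance`; `glance()`: a one-row summary.
#' @export
tidy.eeg_pca <- function(x, ...) {
  tibble::tibble(component = paste0("pc", seq_len(x$k)),
                 variance = x$explained_variance,
                 prop_variance = x$explained_variance /
                   sum(x$explained_variance))
}

#' @rdname tidy.eeg_pca
#' @export
glance.eeg_pca <- function(x, ...) {
  tibble::tibble(k = x$k, signal_length = x$length,
                 total_variance = sum(x$explained_variance))
}
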