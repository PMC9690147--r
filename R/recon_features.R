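#' Reconstruction-divergence features
#'
#' Three indicators quantify how well the autoencoder reproduced a signal.
#' For an original signal `x` and its reconstruction `xhat` of common
#' length `n`:
#'
#' * **MSE** — mean squared error, `(1/n) * sum((x - xhat)^2)`; 0 for a
#'   perfect reconstruction.
#' * **ORSR** — original-to-reconstructed signal ratio,
#'   `10 * log10(sum(x^2) / sum(xhat^2))` in dB, the energy ratio in the
#'   style of a signal-to-noise ratio; 0 dB for equal energy.
#' * **CS** — cosine similarity,
#'   `sum(x * xhat) / (sqrt(sum(x^2)) * sqrt(sum(xhat^2)))`; 1 for
#'   identical direction, clamped into \[-1, 1\] against floating-point
#'   overshoot.
#'
#' @param x Original sample vector.
#' @param xhat Reconstructed sample vector, same length.
#' @return A single numeric value.
#' @name recon_features
NULL

check_pair <- function(x, xhat) {
  if (length(x) != length(xhat)) {
    stop("signals differ in length (", length(x), " vs ", length(xhat), ")",
         call. = FALSE)
  }
  if (length(x) < 1) stop("signals must be nonempty", call. = FALSE)
}

#' @rdname recon_features
#' @export
compute_mse <- function(x, xhat) {
  check_pair(x, xhat)
  mean((x - xhat)^2)
}

#' @rdname recon_features
#' @export
compute_orsr <- function(x, xhat) {
  check_pair(x, xhat)
  ex <- sum(x^2)
  exh <- sum(xhat^2)
  if (ex == 0 || exh == 0) {
    stop("degenerate energy: a signal with zero energy has no dB ratio",
         call. = FALSE)
  }
  10 * log10(ex / exh)
}

#' @rdname recon_features
#' @export
compute_cs <- function(x, xhat) {
  check_pair(x, xhat)
  nx <- sqrt(sum(x^2))
  nxh <- sqrt(sum(xhat^2))
  if (nx == 0 || nxh == 0) {
    stop("cosine similarity undefined for a zero-norm signal", call. = FALSE)
  }
  if (identical(x, xhat)) return(1) # self-similarity, exact
  min(1, max(-1, sum(x * xhat) / (nx * nxh)))
}

#' Extract the reconstruction feature table for a dataset
#'
#' Runs every record through the trained autoencoder and computes the
#' (MSE, ORSR, CS) triple on normalized signals — the space the model was
#' trained in. Records of the reference class reconstruct well (low MSE,
#' ORSR near 0 dB, CS near 1); off-class records diverge, which is what
#' the downstream classifiers exploit.
#'
#' @param model A trained `eeg_autoencoder`.
#' @param data An EEG dataset tibble.
#' @return A feature table tibble with columns `record_id`, `label`,
#'   `mse`, `orsr`, `cs`; zero rows for an empty dataset.
#' @export
extract_features <- function(model, data) {
  if (nrow(data) == 0) {
    return(tibble::tibble(record_id = character(0),
                          label = factor(character(0), eeg_classes()),
                          mse = numeric(0), orsr = numeric(0),
                          cs = numeric(0)))
  }
  xhat <- reconstruct(model, data$samples)
  tibble::tibble(
    record_id = data$record_id,
    label = data$label,
    mse = purrr::map2_dbl(data$samples, xhat, compute_mse),
    orsr = purrr::map2_dbl(data$samples, xhat, compute_orsr),
    cs = purrr::map2_dbl(data$samples, xhat, compute_cs)
  )
}

feature_names <- function(table) {
  setdiff(names(table), c("record_id", "label"))
}

#' Write / read a feature table as CSV
#'
#' @param table Feature table tibble.
#' @param path CSV path.
#' @return `write_feature_table()`: `path` invisibly;
#'   `read_feature_table()`: the table.
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  df$label <- as.character(df$label)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$label <- factor(df$label, levels = eeg_classes())
  tibble::as_tibble(df)
}
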