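#' Read a Bonn-format EEG file
#'
#' The Bonn EEG corpus distributes each recording as a plain-text file with
#' one amplitude sample per line (ASCII decimal, optionally with a trailing
#' blank line). This reads one such file into a raw numeric vector, in file
#' order, without any normalization.
#'
#' @param path Path to a Bonn-style ASCII file.
#' @return Numeric vector of raw amplitudes.
#' @export
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("12", "-5", "0"), f)
#' read_bonn_file(f)
read_bonn_file <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read EEG file: '", path, "' does not exist", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("EEG file '", path, "' contains no samples", call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x)) {
    bad <- which(keep)[which(is.na(x))[1]]
    stop("non-numeric sample at line ", bad, " of '", path, "'",
         call. = FALSE)
  }
  x
}

#' Write samples in the Bonn ASCII dialect
#'
#' One sample per line; the exact inverse of [read_bonn_file()] (round trips
#' are value-exact for values printed at full precision).
#'
#' @param x Numeric sample vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bonn_file <- function(x, path) {
  writeLines(format(x, digits = 17, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Min-max normalize a signal to \[0, 1\]
#'
#' Affine, order-preserving map `(x - min) / (max - min)`. Each recording is
#' normalized independently, so downstream features live on a common
#' amplitude scale.
#'
#' @param x Numeric vector, length at least 2, non-constant.
#' @return Numeric vector with minimum 0 and maximum 1.
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2L) {
    stop("cannot normalize a signal with fewer than 2 samples", call. = FALSE)
  }
  r <- range(x)
  if (r[1] == r[2]) {
    stop("degenerate signal: constant amplitude (max equals min)",
         call. = FALSE)
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Trim a signal to a working length
#'
#' Keeps the first `L` samples. Bonn recordings hold 4097 samples; the
#' convolutional stack needs a length its strides divide, so the default
#' pipeline trims to 4096 (dropping ~5.8 ms of signal).
#'
#' @param x Numeric sample vector.
#' @param L Target length, at most `length(x)`.
#' @return The first `L` samples of `x`.
#' @export
trim_to_length <- function(x, L) {
  if (length(x) < L) {
    stop("signal has ", length(x), " samples; cannot trim to ", L,
         call. = FALSE)
  }
  x[seq_len(L)]
}

new_eeg_dataset <- function(record_id, label, fs, samples) {
  label <- factor(label, levels = eeg_classes())
  if (anyNA(label)) {
    stop("labels must be one of: ", paste(eeg_classes(), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(record_id)) {
    stop("record ids must be unique", call. = FALSE)
  }
  tibble::tibble(record_id = as.character(record_id), label = label,
                 fs = fs, samples = samples)
}

#' Load a directory tree of Bonn-format EEG files as a labeled dataset
#'
#' Walks one subdirectory per class, reads every file in lexicographic
#' filename order, trims each signal to the working length and min-max
#' normalizes it per record. The result is a tibble with one row per
#' recording and the signal held in a `samples` list-column.
#'
#' @param root Directory containing one subdirectory per class.
#' @param class_map Named character vector mapping subdirectory name to
#'   class label, e.g. `c(A = "healthy", D = "interictal", E = "ictal")`.
#' @param L Working length to trim to (default 4096).
#' @param fs Sampling rate in Hz, recorded as metadata (default 173.61).
#' @return A tibble with columns `record_id`, `label`, `fs`, `samples`.
#' @export
load_eeg_dataset <- function(root, class_map, L = 4096, fs = 173.61) {
  dirs <- file.path(root, names(class_map))
  missing <- dirs[!dir.exists(dirs)]
  if (length(missing) > 0) {
    stop("missing class directories: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- purrr::map2(names(class_map), unname(class_map), function(d, lab) {
    files <- sort(list.files(file.path(root, d), full.names = TRUE))
    if (length(files) == 0L) {
      stop("class directory '", file.path(root, d), "' contains no files",
           call. = FALSE)
    }
    sig <- purrr::map(files, function(f) {
      minmax_normalize(trim_to_length(read_bonn_file(f), L))
    })
    tibble::tibble(
      record_id = paste0(d, "/", basename(files)),
      label = lab,
      samples = sig
    )
  })
  out <- dplyr::bind_rows(rows)
  new_eeg_dataset(out$record_id, out$label, fs, out$samples)
}

#' Per-class record counts of a dataset
#'
#' @param data An EEG dataset tibble.
#' @return Named integer vector of counts per class label.
#' @export
class_counts <- function(data) {
  table(data$label)
}

#' Dataset manifest
#'
#' One row per record with its label, length and raw amplitude range —
#' written alongside pipeline outputs so a run is auditable.
#'
#' @param data An EEG dataset tibble.
#' @return A tibble with columns `record_id`, `label`, `n_samples`,
#'   `min_raw`, `max_raw` (the range of the stored, normalized samples).
#' @export
dataset_manifest <- function(data) {
  tibble::tibble(
    record_id = data$record_id,
    label = as.character(data$label),
    n_samples = purrr::map_int(data$samples, length),
    min_raw = purrr::map_dbl(data$samples, min),
    max_raw = purrr::map_dbl(data$samples, max)
  )
}

#' Write a dataset as a Bonn-style directory tree
#'
#' Inverse of [load_eeg_dataset()] up to normalization: each record's stored
#' samples go to `<root>/<dir>/<id>.txt`, one sample per line, one
#' subdirectory per class. Used by the `simulate` pipeline stage so that
#' synthetic and downloaded data flow through the identical loading path.
#'
#' @param data An EEG dataset tibble.
#' @param root Output directory (created if needed).
#' @param class_dirs Named character vector mapping class label to
#'   subdirectory name; defaults to the label names themselves.
#' @return `root`, invisibly.
#' @export
write_eeg_dataset <- function(data, root,
                              class_dirs = stats::setNames(eeg_classes(),
                                                           eeg_classes())) {
  for (i in seq_len(nrow(data))) {
    lab <- as.character(data$label[i])
    dir <- file.path(root, class_dirs[[lab]])
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    id <- gsub("[^A-Za-z0-9_.-]", "_", data$record_id[i])
    write_bonn_file(data$samples[[i]], file.path(dir, paste0(id, ".txt")))
  }
  invisible(root)
}
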