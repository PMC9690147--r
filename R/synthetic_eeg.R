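#' Synthetic EEG generator configuration
#'
#' Builds the configuration for the three-class synthetic EEG generator.
#' Each class combines a pink-ish (1/f-weighted) background, an optional
#' band-limited rhythm, optional Poisson-timed biphasic spikes, and white
#' Gaussian noise; the raw mixture is min-max normalized per record, like
#' real recordings. The defaults emulate the qualitative contrast between
#' healthy surface EEG (moderate 8-12 Hz alpha rhythm), interictal EEG
#' (low-amplitude background with sparse epileptiform spikes) and ictal EEG
#' (high-amplitude rhythmic 3-5 Hz discharge).
#'
#' The `"reduced"` contrast preset shrinks spike and discharge amplitudes
#' and raises the noise floor, giving a deliberately harder problem for
#' stress-testing feature extractors.
#'
#' @param n_per_class Records to generate per class (default 100, matching
#'   the size of one Bonn subset).
#' @param length Samples per record (default 4096).
#' @param fs Sampling rate in Hz (default 173.61).
#' @param seed Master seed; every record derives its own substream from it.
#' @param contrast `"default"` or `"reduced"` (hard mode).
#' @param classes Optional per-class parameter override; a named list with
#'   entries `healthy`, `interictal`, `ictal`, each holding
#'   `background_amp`, `band` (c(low, high) Hz for the rhythm),
#'   `rhythm_amp`, `rhythm_jitter`, `spike_rate` (events/s), `spike_amp`,
#'   `noise_sd`.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_class = 100, length = 4096, fs = 173.61,
                             seed = 42, contrast = c("default", "reduced"),
                             classes = NULL) {
  contrast <- match.arg(contrast)
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  if (length < 64) stop("length must be >= 64", call. = FALSE)
  if (is.null(classes)) {
    classes <- list(
      healthy = list(background_amp = 0.3, band = c(8, 12),
                     rhythm_amp = 0.5, rhythm_jitter = 0,
                     spike_rate = 0, spike_amp = 0, noise_sd = 0.1),
      interictal = list(background_amp = 0.3, band = c(0, 0),
                        rhythm_amp = 0, rhythm_jitter = 0,
                        spike_rate = 0.8, spike_amp = 2.0, noise_sd = 0.1),
      ictal = list(background_amp = 0.3, band = c(4, 4),
                   rhythm_amp = 3.0, rhythm_jitter = 0.2,
                   spike_rate = 0, spike_amp = 0, noise_sd = 0.1)
    )
    if (contrast == "reduced") {
      classes$healthy$rhythm_amp <- 0.35
      classes$healthy$noise_sd <- 0.2
      classes$interictal$spike_amp <- 0.8
      classes$interictal$noise_sd <- 0.2
      classes$ictal$rhythm_amp <- 1.0
      classes$ictal$noise_sd <- 0.2
    }
  }
  for (cl in eeg_classes()) {
    p <- classes[[cl]]
    if (is.null(p)) stop("missing class parameters for '", cl, "'",
                         call. = FALSE)
    if (any(c(p$background_amp, p$rhythm_amp, p$spike_amp) < 0)) {
      stop("amplitudes must be nonnegative", call. = FALSE)
    }
    if (any(p$band < 0) || any(p$band >= fs / 2)) {
      stop("rhythm band must lie in [0, fs/2)", call. = FALSE)
    }
  }
  structure(list(n_per_class = n_per_class, length = length, fs = fs,
                 seed = as.integer(seed), contrast = contrast,
                 classes = classes),
            class = "synthetic_config")
}

# pink-ish background: FFT-shaped noise with amplitude ~ 1/sqrt(f),
# rescaled to unit sd
pinkish_noise <- function(n) {
  white <- rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1)) # avoid dividing DC by zero
  f <- pmin(f, n - f + 1) # fold to two-sided frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# biphasic spike template: one positive then one negative lobe, Hann
# windowed, peak amplitude 1
spike_template <- function(n) {
  t <- seq_len(n)
  w <- 0.5 * (1 - cos(2 * pi * (t - 1) / (n - 1)))
  s <- sin(2 * pi * (t - 1) / (n - 1)) * w
  s / max(abs(s))
}

# slowly varying positive envelope with given fractional jitter
slow_envelope <- function(n, fs, jitter) {
  if (jitter <= 0) return(rep(1, n))
  k <- max(4, round(fs / 2)) # ~0.5 s smoothing window
  z <- stats::filter(rnorm(n + k), rep(1 / k, k), sides = 1)
  z <- as.numeric(z[(k + 1):(n + k)])
  z <- z / max(sd(z), 1e-12)
  pmax(1 + jitter * z, 0)
}

#' Generate one synthetic EEG record
#'
#' @param label Class label: `"healthy"`, `"interictal"` or `"ictal"`.
#' @param cfg A [synthetic_config()].
#' @param index Record counter within the class; together with `cfg$seed`
#'   it determines the record's private random substream, so any record is
#'   reproducible independently of generation order.
#' @param normalize Min-max normalize the mixture (default TRUE; FALSE
#'   returns the raw mixture, useful for inspecting component amplitudes).
#' @return Numeric sample vector of length `cfg$length`.
#' @export
generate_record <- function(label, cfg, index = 1, normalize = TRUE) {
  if (!label %in% eeg_classes()) {
    stop("unknown class label '", label, "'", call. = FALSE)
  }
  p <- cfg$classes[[label]]
  n <- cfg$length
  class_id <- match(label, eeg_classes())
  substream <- (as.double(cfg$seed) * 7919 + class_id * 999983 +
                  index * 104729) %% 2147483629
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(substream))

  t <- (seq_len(n) - 1) / cfg$fs
  x <- p$background_amp * pinkish_noise(n)
  if (p$rhythm_amp > 0) {
    freq <- runif(1, p$band[1], p$band[2])
    phase <- runif(1, 0, 2 * pi)
    env <- slow_envelope(n, cfg$fs, p$rhythm_jitter)
    x <- x + p$rhythm_amp * env * sin(2 * pi * freq * t + phase)
  }
  if (p$spike_rate > 0 && p$spike_amp > 0) {
    width <- max(5L, round(0.060 * cfg$fs)) # 60 ms biphasic transient
    tmpl <- spike_template(width)
    n_spikes <- rpois(1, p$spike_rate * n / cfg$fs)
    if (n_spikes > 0) {
      starts <- sort(sample.int(max(n - width, 1), n_spikes, replace = TRUE))
      signs <- sample(c(1, -1), n_spikes, replace = TRUE, prob = c(0.8, 0.2))
      for (j in seq_len(n_spikes)) {
        idx <- starts[j]:(starts[j] + width - 1)
        x[idx] <- x[idx] + signs[j] * p$spike_amp * tmpl
      }
    }
  }
  x <- x + rnorm(n, sd = p$noise_sd)
  if (normalize) minmax_normalize(x) else x
}

#' Generate a balanced three-class synthetic EEG dataset
#'
#' @param cfg A [synthetic_config()].
#' @return An EEG dataset tibble (`record_id`, `label`, `fs`, `samples`)
#'   with `cfg$n_per_class` records per class, deterministic given
#'   `cfg$seed`.
#' @export
generate_eeg_dataset <- function(cfg) {
  rows <- purrr::map(eeg_classes(), function(lab) {
    sig <- purrr::map(seq_len(cfg$n_per_class), function(i) {
      generate_record(lab, cfg, index = i)
    })
    tibble::tibble(
      record_id = sprintf("%s_%03d", lab, seq_len(cfg$n_per_class)),
      label = lab,
      samples = sig
    )
  })
  out <- dplyr::bind_rows(rows)
  new_eeg_dataset(out$record_id, out$label, cfg$fs, out$samples)
}

# save/restore the global RNG state so generation does not perturb the
# caller's stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_set <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  }
}
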