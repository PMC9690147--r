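#' Convolutional autoencoder configuration
#'
#' Describes the stacked 1-D convolutional autoencoder: three strided
#' convolution encoder layers (E1-E3) and three mirrored transposed
#' convolution decoder layers (D1-D3). Every hidden layer is a convolution
#' followed by ReLU; the output layer uses a logistic sigmoid so
#' reconstructions stay in \[0, 1\], the range of the normalized input.
#'
#' The default dimensions compress toward the bottleneck (16/8/8 channels)
#' and use long kernels (21 taps, ~120 ms at 173.61 Hz): a narrow code
#' forces the model to commit to the reference class instead of learning a
#' near-identity map, and long kernels make the learned filters
#' frequency-selective, which stabilizes the contrast between the two
#' off-class signal types.
#'
#' @param input_length Working signal length; must be divisible by the
#'   product of the encoder strides (default 4096).
#' @param channels Channel widths of E1, E2, E3 (decoder mirrors them).
#' @param kernel Convolution kernel size, odd (default 21).
#' @param stride Stride of every conv / transposed-conv layer (default 2).
#' @param lr Adam learning rate (default 0.001).
#' @param epochs Training epochs (default 400).
#' @param batch_size Minibatch size (default 4).
#' @param seed Seed for weight initialization and minibatch shuffling.
#' @return An `ae_config` list.
#' @export
ae_config <- function(input_length = 4096, channels = c(16, 8, 8),
                      kernel = 21, stride = 2, lr = 0.001, epochs = 400,
                      batch_size = 4, seed = 1) {
  if (lr <= 0) stop("learning rate must be positive", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (kernel %% 2 == 0) {
    stop("kernel size must be odd (symmetric padding)", call. = FALSE)
  }
  stride_product <- stride^length(channels)
  if (input_length %% stride_product != 0) {
    stop("input_length (", input_length, ") must be divisible by the ",
         "product of encoder strides (", stride_product, ")", call. = FALSE)
  }
  structure(list(input_length = as.integer(input_length),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 stride = as.integer(stride), lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "ae_config")
}

# layer specs consumed by the C++ kernels; pad chosen so a stride-s conv
# maps L -> L/s exactly and the mirrored tconv maps back (out_pad = s - 1
# for even kernels' asymmetry; with odd kernel k, pad = (k - 1) / 2 and
# out_pad = s - 1)
ae_layers <- function(cfg) {
  k <- cfg$kernel
  s <- cfg$stride
  pad <- (k - 1) %/% 2
  ch <- cfg$channels
  enc_in <- c(1L, ch[-length(ch)])
  layers <- list()
  for (i in seq_along(ch)) {
    layers[[length(layers) + 1]] <- list(
      type = "conv", in_ch = enc_in[i], out_ch = ch[i], kernel = k,
      stride = s, pad = pad, out_pad = 0L, activation = "relu")
  }
  dec_out <- c(rev(ch)[-1], 1L)
  dec_in <- rev(ch)
  for (i in seq_along(dec_in)) {
    layers[[length(layers) + 1]] <- list(
      type = "tconv", in_ch = dec_in[i], out_ch = dec_out[i], kernel = k,
      stride = s, pad = pad, out_pad = s - 1L,
      activation = if (i < length(dec_in)) "relu" else "sigmoid")
  }
  layers
}

# fan-in-scaled uniform initialization, seeded; conv W: out_ch x (in_ch*k),
# tconv W: in_ch x (out_ch*k) (adjoint-convolution layout)
ae_init_weights <- function(cfg) {
  layers <- ae_layers(cfg)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$seed)
  lapply(layers, function(l) {
    if (l$type == "conv") {
      nrow <- l$out_ch
      ncol <- l$in_ch * l$kernel
      fan_in <- l$in_ch * l$kernel
    } else {
      nrow <- l$in_ch
      ncol <- l$out_ch * l$kernel
      fan_in <- l$in_ch * l$kernel / l$stride
    }
    bound <- 1 / sqrt(fan_in)
    list(W = matrix(runif(nrow * ncol, -bound, bound), nrow, ncol),
         b = runif(l$out_ch, -bound, bound))
  })
}

#' Build an untrained autoencoder
#'
#' Instantiates the layer stack and seeds the initial weights
#' (fan-in-scaled uniform). The returned object reconstructs already —
#' badly — so shape contracts can be checked before training.
#'
#' @param cfg An [ae_config()].
#' @return An `eeg_autoencoder` object.
#' @export
build_autoencoder <- function(cfg) {
  stopifnot(inherits(cfg, "ae_config"))
  structure(list(config = cfg, layers = ae_layers(cfg),
                 weights = ae_init_weights(cfg),
                 loss_history = numeric(0), trained = FALSE),
            class = "eeg_autoencoder")
}

dataset_matrix <- function(data, L) {
  lens <- purrr::map_int(data$samples, length)
  if (any(lens != L)) {
    stop("all records must have length ", L, "; found lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  do.call(cbind, data$samples)
}

#' Train the autoencoder on one class of EEG records
#'
#' One-class training is the heart of the method: the model only ever sees
#' the reference class (interictal by convention), so signals from other
#' classes reconstruct poorly and the reconstruction-divergence features
#' separate the classes. Optimizes mean squared reconstruction error with
#' Adam at the configured learning rate; deterministic given the config
#' seed and record order.
#'
#' @param model An `eeg_autoencoder` from [build_autoencoder()].
#' @param data EEG dataset tibble whose records all carry one label.
#' @return The trained `eeg_autoencoder`, with `loss_history` holding the
#'   mean training loss of each epoch.
#' @export
train_autoencoder <- function(model, data) {
  stopifnot(inherits(model, "eeg_autoencoder"))
  if (nrow(data) < 2) {
    stop("training needs at least 2 records", call. = FALSE)
  }
  labs <- unique(as.character(data$label))
  if (length(labs) != 1) {
    stop("one-class protocol violated: training data mixes labels ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  cfg <- model$config
  X <- dataset_matrix(data, cfg$input_length)
  fit <- .cpp_ae_train(X, model$layers, model$weights, cfg$lr, cfg$epochs,
                       cfg$batch_size, cfg$seed)
  model$weights <- lapply(fit$weights, function(w) {
    list(W = w$W, b = as.numeric(w$b))
  })
  model$loss_history <- as.numeric(fit$loss_history)
  model$trained <- TRUE
  model$trained_on <- labs
  model
}

#' Reconstruct signals through the autoencoder
#'
#' @param model An `eeg_autoencoder`.
#' @param x A numeric sample vector of the model's working length, a list
#'   of such vectors, or an EEG dataset tibble.
#' @return For a vector input, the reconstructed vector; otherwise a list
#'   of reconstructed vectors in input order. Inference is deterministic.
#' @export
reconstruct <- function(model, x) {
  stopifnot(inherits(model, "eeg_autoencoder"))
  L <- model$config$input_length
  single <- is.numeric(x)
  if (single) x <- list(x)
  if (is.data.frame(x)) x <- x$samples
  lens <- purrr::map_int(x, length)
  if (any(lens != L)) {
    stop("record length ", paste(unique(lens[lens != L]), collapse = ", "),
         " does not match model working length ", L, call. = FALSE)
  }
  X <- do.call(cbind, x)
  Xhat <- .cpp_ae_forward(X, model$layers, model$weights)
  out <- lapply(seq_len(ncol(Xhat)), function(j) Xhat[, j])
  if (single) out[[1]] else out
}

#' @export
print.eeg_autoencoder <- function(x, ...) {
  cfg <- x$config
  cat("1-D convolutional autoencoder\n")
  cat("  input length:", cfg$input_length,
      "| channels:", paste(cfg$channels, collapse = "/"),
      "| kernel:", cfg$kernel, "| stride:", cfg$stride, "\n")
  if (x$trained) {
    cat("  trained on:", x$trained_on, "for", length(x$loss_history),
        "epochs; final loss", format(utils::tail(x$loss_history, 1),
                                     digits = 4), "\n")
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' @rdname tidy.eeg_autoencoder
#' @export
glance.eeg_autoencoder <- function(x, ...) {
  tibble::tibble(
    trained = x$trained,
    epochs = length(x$loss_history),
    final_loss = if (x$trained) utils::tail(x$loss_history, 1) else NA_real_,
    n_parameters = sum(purrr::map_int(x$weights,
                                      ~ length(.x$W) + length(.x$b)))
  )
}

#' Tidy the training history of an autoencoder
#'
#' @param x An `eeg_autoencoder`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with `epoch` and `loss`; `glance()`: a
#'   one-row training summary.
#' @export
tidy.eeg_autoencoder <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' Save an autoencoder checkpoint
#'
#' Writes a single structured-text (JSON) archive holding a format tag,
#' the configuration and the full-precision weight arrays, so reloading
#' reproduces reconstructions bit for bit.
#'
#' @param model An `eeg_autoencoder`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_autoencoder <- function(model, path) {
  payload <- list(
    format = "eegrecon-ae-checkpoint",
    version = 1L,
    config = unclass(model$config),
    trained = model$trained,
    trained_on = if (is.null(model$trained_on)) NA_character_
                 else model$trained_on,
    loss_history = model$loss_history,
    # weights as %.17g strings: JSON writers round doubles to 15
    # significant digits, which would break bit-exact reloading
    weights = lapply(model$weights, function(w) {
      list(W_dim = dim(w$W),
           W = sprintf("%.17g", as.numeric(w$W)),
           b = sprintf("%.17g", as.numeric(w$b)))
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load an autoencoder checkpoint
#'
#' @param path Path written by [save_autoencoder()].
#' @return An `eeg_autoencoder`.
#' @export
load_autoencoder <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "eegrecon-ae-checkpoint")) {
    stop("'", path, "' is not an autoencoder checkpoint", call. = FALSE)
  }
  cfg <- do.call(ae_config, payload$config[c("input_length", "channels",
                                             "kernel", "stride", "lr",
                                             "epochs", "batch_size", "seed")])
  weights <- lapply(seq_len(nrow_or_len(payload$weights)), function(i) {
    w <- payload_weight(payload$weights, i)
    dims <- as.integer(unlist(w$W_dim))
    list(W = matrix(as.numeric(unlist(w$W)), dims[1], dims[2]),
         b = as.numeric(unlist(w$b)))
  })
  structure(list(config = cfg, layers = ae_layers(cfg), weights = weights,
                 loss_history = as.numeric(payload$loss_history),
                 trained = isTRUE(payload$trained),
                 trained_on = payload$trained_on),
            class = "eeg_autoencoder")
}

# jsonlite simplifies a homogeneous list of lists to a data frame;
# tolerate both shapes
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
payload_weight <- function(x, i) {
  if (is.data.frame(x)) {
    list(W_dim = x$W_dim[[i]], W = x$W[[i]], b = x$b[[i]])
  } else {
    x[[i]]
  }
}
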