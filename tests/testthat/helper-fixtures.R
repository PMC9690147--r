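# Small fixtures shared across test files. Everything is generated in code;
# heavyweight trained models are cached per test run so several test files
# can share one training.

small_synth_cfg <- function(seed = 11, n_per_class = 8, length = 512) {
  synthetic_config(n_per_class = n_per_class, length = length, seed = seed)
}

small_ae_cfg <- function(length = 512, epochs = 30, seed = 21) {
  ae_config(input_length = length, channels = c(4, 4, 4), kernel = 9,
            epochs = epochs, batch_size = 4, seed = seed)
}

# writes a tiny Bonn-style tree: <root>/<dir>/<files>, returns root
write_bonn_tree <- function(dirs, n_files = 2, n_samples = 64, seed = 5) {
  root <- withr::local_tempdir(.local_envir = parent.frame())
  set.seed(seed)
  for (d in dirs) {
    dir.create(file.path(root, d))
    for (i in seq_len(n_files)) {
      write_bonn_file(round(rnorm(n_samples) * 100),
                      file.path(root, d, sprintf("%s%03d.txt", d, i)))
    }
  }
  root
}

# toy 3-class feature table with a single informative feature
planted_table <- function(n_per_class = 25, seed = 33) {
  set.seed(seed)
  lab <- rep(eeg_classes(), each = n_per_class)
  informative <- rep(c(0, 5, 10), each = n_per_class) + rnorm(3 * n_per_class, sd = 0.2)
  tibble::tibble(
    record_id = paste0("r", seq_along(lab)),
    label = factor(lab, eeg_classes()),
    f_signal = informative,
    f_noise1 = rnorm(3 * n_per_class),
    f_noise2 = rnorm(3 * n_per_class)
  )
}

# session-level cache so expensive fits are shared between test blocks
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small but real end-to-end fit: synthetic data + trained AE + features
small_trained_world <- function() {
  cached("small_world", {
    ds <- generate_eeg_dataset(small_synth_cfg())
    ae <- train_autoencoder(
      build_autoencoder(small_ae_cfg()),
      ds[ds$label == "interictal", ])
    list(ds = ds, ae = ae, features = extract_features(ae, ds))
  })
}
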