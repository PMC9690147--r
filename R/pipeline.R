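#' Build a run configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()]:
#' data source, autoencoder settings, reference class for one-class
#' training, PCA baseline settings, split protocol, classifier set,
#' interpretability settings and the master seed. The master seed fans
#' out to per-stage seeds by fixed offsets (data +0, autoencoder +1,
#' split +2, classifiers +3, interpretability +4), all recorded in the
#' run manifest.
#'
#' @param seed Master seed.
#' @param data Data source: list with `source = "synthetic"` plus
#'   [synthetic_config()] arguments, or `source = "directory"` plus
#'   `root`, `class_map`, and optionally `fs`.
#' @param working_length Signal working length (default 4096).
#' @param autoencoder Named list of [ae_config()] overrides.
#' @param reference_class Class the autoencoder trains on (default
#'   `"interictal"`).
#' @param pca List with `k` (components fed to classifiers, default 10)
#'   and `m` (leading components normalized for plots, default 3).
#' @param split List with `train_fraction` (default 0.75) and
#'   `stratified` (default TRUE).
#' @param classifiers Character vector of classifier kinds.
#' @param interpretability List with `n_repeats` (default 30) and
#'   `max_background` (default 100).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 42,
                       data = list(source = "synthetic"),
                       working_length = 4096,
                       autoencoder = list(),
                       reference_class = "interictal",
                       pca = list(k = 10, m = 3),
                       split = list(train_fraction = 0.75,
                                    stratified = TRUE),
                       classifiers = classifier_kinds(),
                       interpretability = list(n_repeats = 30,
                                               max_background = 100)) {
  if (!reference_class %in% eeg_classes()) {
    stop("reference_class must be one of ",
         paste(eeg_classes(), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(classifiers, classifier_kinds())
  if (length(bad) > 0) {
    stop("unknown classifier kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data$source <- data$source %||% "synthetic"
  if (!data$source %in% c("synthetic", "directory")) {
    stop("data$source must be 'synthetic' or 'directory'", call. = FALSE)
  }
  pca$k <- pca$k %||% 10
  pca$m <- pca$m %||% 3
  split$train_fraction <- split$train_fraction %||% 0.75
  split$stratified <- split$stratified %||% TRUE
  interpretability$n_repeats <- interpretability$n_repeats %||% 30
  interpretability$max_background <- interpretability$max_background %||% 100
  structure(list(seed = as.integer(seed), data = data,
                 working_length = as.integer(working_length),
                 autoencoder = autoencoder,
                 reference_class = reference_class, pca = pca,
                 split = split, classifiers = classifiers,
                 interpretability = interpretability),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; absent keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @param overrides Named list applied on top of the file (CLI flags).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, args)
}

stage_seed <- function(cfg, stage) {
  offsets <- c(data = 0L, autoencoder = 1L, split = 2L, classifiers = 3L,
               interpretability = 4L)
  cfg$seed + offsets[[stage]]
}

pipeline_data <- function(cfg) {
  if (cfg$data$source == "synthetic") {
    scfg <- synthetic_config(
      n_per_class = cfg$data$n_per_class %||% 100,
      length = cfg$working_length,
      fs = cfg$data$fs %||% 173.61,
      seed = stage_seed(cfg, "data"),
      contrast = cfg$data$contrast %||% "default")
    generate_eeg_dataset(scfg)
  } else {
    load_eeg_dataset(cfg$data$root,
                     unlist(cfg$data$class_map),
                     L = cfg$working_length,
                     fs = cfg$data$fs %||% 173.61)
  }
}

pipeline_ae <- function(cfg, data) {
  acfg <- do.call(ae_config, utils::modifyList(
    list(input_length = cfg$working_length,
         seed = stage_seed(cfg, "autoencoder")),
    cfg$autoencoder))
  ref <- data[data$label == cfg$reference_class, , drop = FALSE]
  if (nrow(ref) == 0) {
    stop("no records of reference class '", cfg$reference_class, "'",
         call. = FALSE)
  }
  train_autoencoder(build_autoencoder(acfg), ref)
}

#' Run the full detection pipeline
#'
#' Executes every stage in order: data loading or simulation, one-class
#' autoencoder training on the reference class, reconstruction feature
#' extraction for all records, the PCA baseline, a stratified train/test
#' split shared by both feature sets, training and evaluation of each
#' configured classifier on both feature sets, and interpretability
#' (permutation importance + exact Shapley) for each classifier on the
#' autoencoder features. Fully reproducible from (config, seed).
#'
#' @param cfg A `run_config` (or path to a YAML config file).
#' @param output_dir Optional directory; when given, all artifacts are
#'   written there (manifest and feature CSVs, autoencoder checkpoint,
#'   JSON evaluation and importance reports, summary table).
#' @return An `eeg_run` list with the dataset, trained models, feature
#'   tables, evaluation reports (`evaluations[[feature_set]][[kind]]`),
#'   importance reports and the accuracy `summary` tibble.
#' @export
run_pipeline <- function(cfg, output_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  stage <- "data"
  result <- tryCatch({
    data <- pipeline_data(cfg)

    stage <- "autoencoder"
    ae <- pipeline_ae(cfg, data)

    stage <- "features"
    feats_ae <- extract_features(ae, data)

    stage <- "pca"
    pca <- fit_pca(data, k = cfg$pca$k)
    feats_pca <- pca_transform(pca, data)

    stage <- "split"
    split_seed <- stage_seed(cfg, "split")
    sp <- split_table(feats_ae, cfg$split$train_fraction, seed = split_seed,
                      stratified = cfg$split$stratified)
    train_ids <- sp$train$record_id
    splits <- list(
      ae = sp,
      pca = list(train = feats_pca[feats_pca$record_id %in% train_ids, ],
                 test = feats_pca[!feats_pca$record_id %in% train_ids, ]))

    stage <- "classifiers"
    clf_seed <- stage_seed(cfg, "classifiers")
    models <- list()
    evals <- list()
    for (fs_name in names(splits)) {
      models[[fs_name]] <- list()
      evals[[fs_name]] <- list()
      for (kind in cfg$classifiers) {
        m <- train_classifier(splits[[fs_name]]$train, kind = kind,
                              seed = clf_seed)
        models[[fs_name]][[kind]] <- m
        evals[[fs_name]][[kind]] <- evaluate_classifier(
          m, splits[[fs_name]]$test, train = splits[[fs_name]]$train)
      }
    }

    stage <- "interpretability"
    int_seed <- stage_seed(cfg, "interpretability")
    importance <- list()
    for (kind in cfg$classifiers) {
      importance[[kind]] <- interpret_classifier(
        models$ae[[kind]], splits$ae$test, splits$ae$train,
        n_repeats = cfg$interpretability$n_repeats, seed = int_seed)
    }

    summary <- dplyr::bind_rows(lapply(names(evals), function(fs_name) {
      dplyr::bind_rows(lapply(evals[[fs_name]], glance)) |>
        dplyr::mutate(feature_set = fs_name, .before = 1)
    }))

    structure(list(config = cfg, data = data, autoencoder = ae,
                   features = list(ae = feats_ae, pca = feats_pca),
                   pca = pca, splits = splits, models = models,
                   evaluations = evals, importance = importance,
                   summary = summary),
              class = "eeg_run")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(output_dir)) write_run_artifacts(result, output_dir)
  result
}

#' Write all artifacts of a pipeline run
#'
#' @param run An `eeg_run` from [run_pipeline()].
#' @param output_dir Directory to write into (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_run_artifacts <- function(run, output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  p <- function(...) file.path(output_dir, ...)
  write.csv(as.data.frame(dataset_manifest(run$data)), p("manifest.csv"),
            row.names = FALSE)
  save_autoencoder(run$autoencoder, p("ae_checkpoint.json"))
  write_feature_table(run$features$ae, p("features_ae.csv"))
  write_feature_table(run$features$pca, p("features_pca.csv"))
  for (fs_name in names(run$evaluations)) {
    for (kind in names(run$evaluations[[fs_name]])) {
      write_eval_report(run$evaluations[[fs_name]][[kind]],
                        p(sprintf("eval_%s_%s.json", fs_name, kind)))
    }
  }
  for (kind in names(run$importance)) {
    write_importance_report(run$importance[[kind]],
                            p(sprintf("importance_%s.json", kind)))
  }
  df <- as.data.frame(run$summary)
  write.csv(df, p("summary.csv"), row.names = FALSE)
  seeds <- list(master = run$config$seed,
                stages = lapply(c("data", "autoencoder", "split",
                                  "classifiers", "interpretability"),
                                function(s) list(
                                  stage = s,
                                  seed = stage_seed(run$config, s))))
  jsonlite::write_json(seeds, p("seeds.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(output_dir)
}

#' @export
print.eeg_run <- function(x, ...) {
  cat("EEG detection pipeline run (seed", x$config$seed, ")\n")
  cat("  records:", nrow(x$data), "| reference class:",
      x$config$reference_class, "\n\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Accuracy summary of a pipeline run
#'
#' @param x An `eeg_run`.
#' @param ... Unused.
#' @return The run's summary tibble: one row per (feature set,
#'   classifier) with train/test accuracy.
#' @export
tidy.eeg_run <- function(x, ...) {
  x$summary
}
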