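#' Write a synthetic dataset to a directory
#'
#' One CSV per trial (samples x channels), a `manifest.csv` (trial id, the
#' three ratings, the three true classes, data file) and a `config.yaml`
#' echo of the generator configuration.
#'
#' @param dataset a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$trials)
  files <- sprintf("trial%03d.csv", seq_len(n))
  for (i in seq_len(n)) {
    m <- t(dataset$trials[[i]]$data)
    colnames(m) <- dataset$trials[[i]]$labels
    utils::write.csv(m, file.path(dir, files[i]), row.names = FALSE)
  }
  rt <- t(vapply(dataset$trials, function(tr) unlist(tr$ratings), numeric(3)))
  manifest <- data.frame(trial = seq_len(n),
                         valence = rt[, 1], arousal = rt[, 2],
                         dominance = rt[, 3],
                         class_valence = dataset$true_class[, "valence"],
                         class_arousal = dataset$true_class[, "arousal"],
                         class_dominance = dataset$true_class[, "dominance"],
                         file = files)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- unclass(dataset$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read back a dataset written by [write_synth_dataset()]
#'
#' @param dir the dataset directory.
#' @return A `synth_dataset`.
#' @export
read_synth_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  cfg_raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- do.call(synth_config, cfg_raw[setdiff(names(cfg_raw), "n_trials")] |>
                   c(list(n_trials = cfg_raw$n_trials)))
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- as.matrix(utils::read.csv(file.path(dir, manifest$file[i]),
                                   check.names = FALSE))
    eeg_trial(t(m), cfg$fs, colnames(m),
              c(valence = manifest$valence[i], arousal = manifest$arousal[i],
                dominance = manifest$dominance[i]))
  })
  true_class <- as.matrix(manifest[, c("class_valence", "class_arousal",
                                       "class_dominance")])
  colnames(true_class) <- c("valence", "arousal", "dominance")
  ds <- list(trials = trials, true_class = true_class, config = cfg)
  class(ds) <- "synth_dataset"
  ds
}

#' Read a generator configuration from YAML
#'
#' Keys mirror the arguments of [synth_config()].
#'
#' @param file YAML path.
#' @return A `synth_config`.
#' @export
read_synth_config <- function(file) {
  do.call(synth_config, yaml::read_yaml(file))
}

#' Write a metrics report (and optional baselines) as JSON
#'
#' @param report a `metrics_report`.
#' @param file output path.
#' @param baselines optional `baseline_report` to embed.
#' @export
write_metrics_json <- function(report, file, baselines = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write JSON reports")
  x <- list(method = report$method, dimension = report$dimension,
            mean_accuracy = report$mean_accuracy,
            mean_macro_f1 = report$mean_macro_f1,
            per_fold = report$per_fold)
  if (!is.null(baselines)) x$baselines <- baselines
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}
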