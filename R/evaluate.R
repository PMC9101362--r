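#' Binarize affect ratings at the dataset threshold
#'
#' A rating maps to `"high"` iff it exceeds the threshold strictly
#' (ratings exactly at 4.5 / 2.5 are `"low"`). The 1-9 scales binarize at
#' 4.5, the 1-5 scale at 2.5.
#'
#' @param ratings numeric ratings within the scale.
#' @param scale `c(min, max, threshold)`, threshold strictly inside.
#' @return Factor with levels `low`, `high`.
#' @export
binarize_ratings <- function(ratings, scale = c(1, 9, 4.5)) {
  if (!(scale[3] > scale[1] && scale[3] < scale[2]))
    stop("threshold must lie strictly inside the scale")
  if (any(ratings < scale[1] | ratings > scale[2]))
    stop("rating outside the scale [", scale[1], ", ", scale[2], "]")
  factor(ifelse(ratings > scale[3], "high", "low"), levels = c("low", "high"))
}

#' Stratified k-fold assignment
#'
#' Assigns every trial to exactly one test fold. Within each class the
#' (seed-shuffled) instances are dealt round-robin, continuing the deal
#' across classes so overall fold sizes differ by at most one.
#'
#' @param y labels (used for stratification).
#' @param k number of folds (default 10).
#' @param stratified deal per class (default) or over all trials.
#' @param seed RNG seed; same seed, same folds.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(y, k = 10, stratified = TRUE, seed = 1L) {
  n <- length(y)
  if (n < k) stop("fewer trials than folds")
  with_seed(seed, {
    fold <- integer(n)
    groups <- if (stratified) split(seq_len(n), y) else list(seq_len(n))
    offset <- 0L
    for (g in groups) {
      g <- g[sample.int(length(g))]
      fold[g] <- (offset + seq_along(g) - 1L) %% k + 1L
      offset <- offset + length(g)
    }
    fold
  })
}

#' Accuracy and macro-averaged F1 (percent)
#'
#' Macro-F1 is the unweighted mean of the per-class F1 scores over the
#' label levels; a class that is never predicted (or absent) contributes an
#' F1 of 0.
#'
#' @param truth,pred label vectors of equal length.
#' @return Named numeric: `accuracy` and `macro_f1`, both on the 0-100
#'   scale.
#' @export
classification_metrics <- function(truth, pred) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  c(accuracy = 100 * mean(truth == pred), macro_f1 = 100 * mean(f1))
}

#' Chance baselines for a label vector
#'
#' The three reference classifiers: `random` guesses each class uniformly
#' (Monte-Carlo), `majority` always predicts the most frequent class (its
#' accuracy is exactly the majority fraction), and `class_ratio` guesses
#' with the empirical class probabilities (expected accuracy
#' `p^2 + (1-p)^2` for a binary split).
#'
#' @param labels binarized labels.
#' @param seed RNG seed for the Monte-Carlo baselines.
#' @param n_draws total simulated predictions per stochastic baseline.
#' @return A `baseline_report`: data.frame with one row per baseline and
#'   `accuracy` / `macro_f1` columns (percent).
#' @export
baselines <- function(labels, seed = 1L, n_draws = 1e5) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n == 0) stop("empty labels")
  classes <- sort(unique(labels))
  probs <- as.numeric(table(labels)[classes]) / n
  reps <- max(1L, ceiling(n_draws / n))
  mc <- function(p) {
    m <- vapply(seq_len(reps), function(r) {
      classification_metrics(labels, sample(classes, n, replace = TRUE,
                                            prob = p))
    }, numeric(2))
    rowMeans(m)
  }
  with_seed(seed, {
    rnd <- mc(rep(1 / length(classes), length(classes)))
    rat <- mc(probs)
    maj_class <- classes[which.max(probs)]
    maj <- classification_metrics(labels, rep(maj_class, n))
    out <- data.frame(baseline = c("random", "majority", "class_ratio"),
                      accuracy = c(rnd[1], maj[1], rat[1]),
                      macro_f1 = c(rnd[2], maj[2], rat[2]),
                      row.names = NULL)
    class(out) <- c("baseline_report", "data.frame")
    out
  })
}

#' Evaluate the full pipeline with stratified 10-fold cross-validation
#'
#' Runs the complete recognition chain on one participant's trials:
#' binarize ratings on the chosen affect dimension, and per fold (i) rank
#' channels on the training trials only (ReliefF = R-HOLO-FM, NCA =
#' N-HOLO-FM) and keep the top `top_n`, (ii) render the 45 holographic
#' feature maps per trial on the selected channels, (iii) train one CNN per
#' characteristic on the training-fold maps (each (trial, band) map is one
#' training sample), (iv) extract and fuse the per-band FC features, (v)
#' fit the polynomial SVM on the fused training rows and predict the test
#' fold. Channel selection, CNN training and the SVM never see test-fold
#' trials; set `select_per_fold = FALSE` to reproduce the leakier
#' select-once-per-participant variant.
#'
#' @param dataset a `synth_dataset` (one participant).
#' @param method `"relieff"` or `"nca"`.
#' @param dimension affect dimension to classify.
#' @param top_n channels retained per fold.
#' @param k_folds cross-validation folds (default 10).
#' @param cgh a `cgh_config` (maps can be rendered below 200x200 for
#'   speed; the spatial layout is unchanged).
#' @param spec a `cnn_spec` matching `cgh$resolution`.
#' @param train_cfg a `train_config`.
#' @param svm_degree,svm_C polynomial SVM hyper-parameters.
#' @param select_per_fold rank channels inside each training fold (default)
#'   or once on all trials.
#' @param seed seed for fold assignment and model initialization.
#' @return A `metrics_report`: list with per-fold `accuracy` and
#'   `macro_f1` (percent), their means, the per-fold channel selections and
#'   the configuration echo.
#' @export
evaluate_pipeline <- function(dataset, method = c("relieff", "nca"),
                              dimension = "valence", top_n = 10,
                              k_folds = 10,
                              cgh = cgh_config(resolution = c(64, 64)),
                              spec = cnn_spec(input_shape = c(cgh$resolution, 3),
                                              n1 = 4, n2 = 8, d_fc = 16),
                              train_cfg = train_config(epochs = 6),
                              svm_degree = 3, svm_C = 1,
                              select_per_fold = TRUE, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "synth_dataset"))
  scale <- dataset$config$rating_scale
  ratings <- vapply(dataset$trials, function(tr) tr$ratings[[dimension]],
                    numeric(1))
  y <- binarize_ratings(ratings, scale)
  if (length(unique(y)) < 2)
    stop("single-class participant on dimension ", dimension)
  n <- length(y)
  layout <- standard_layout(dataset$config$montage_name)
  ft <- feature_tensor(dataset)
  folds <- make_folds(y, k = k_folds, seed = seed)
  chars <- characteristic_names()
  bands <- names(eeg_bands())

  ranking_all <- if (!select_per_fold)
    select_channels(dataset, method, dimension, top_n, scale, ft = ft)
  else NULL

  fold_metrics <- matrix(NA_real_, k_folds, 2,
                         dimnames = list(NULL, c("accuracy", "macro_f1")))
  selections <- vector("list", k_folds)
  nb <- length(bands)
  for (f in seq_len(k_folds)) {
    train_idx <- which(folds != f)
    test_idx <- which(folds == f)
    ranking <- if (select_per_fold) {
      select_channels(dataset, method, dimension, top_n, scale, ft = ft,
                      trial_subset = train_idx)
    } else ranking_all
    selections[[f]] <- ranking$channel
    # per characteristic: render all (trial, band) maps on the selected
    # channels, train the CNN on the training-fold samples, extract for all
    blocks <- stats::setNames(vector("list", length(chars)), chars)
    for (char in chars) {
      imgs <- render_feature_images(ft, ranking$channel, layout, cgh, char)
      tr_slots <- as.integer(outer(seq_len(nb), (train_idx - 1) * nb, "+"))
      tr_lab <- rep(y[train_idx], each = nb)
      ext <- train_cnn(imgs[, , , tr_slots, drop = FALSE], tr_lab, spec,
                       train_config(learning_rate = train_cfg$learning_rate,
                                    l2 = train_cfg$l2,
                                    batch_size = train_cfg$batch_size,
                                    momentum = train_cfg$momentum,
                                    epochs = train_cfg$epochs,
                                    seed = train_cfg$seed + f))
      feats <- extract_features(ext, imgs)         # (n * 5) x d_fc
      # concatenate the 5 band blocks per trial
      blocks[[char]] <- do.call(cbind, lapply(seq_len(nb), function(b) {
        feats[seq(b, n * nb, by = nb), , drop = FALSE]
      }))
    }
    fused <- fuse_feature_blocks(blocks)
    clf <- train_svm(fused[train_idx, , drop = FALSE], y[train_idx],
                     degree = svm_degree, C = svm_C)
    pred <- predict_svm(clf, fused[test_idx, , drop = FALSE])
    fold_metrics[f, ] <- classification_metrics(y[test_idx], pred)
  }
  report <- list(method = method, dimension = dimension,
                 per_fold = as.data.frame(fold_metrics),
                 mean_accuracy = mean(fold_metrics[, 1]),
                 mean_macro_f1 = mean(fold_metrics[, 2]),
                 selections = selections, k_folds = k_folds,
                 top_n = top_n, seed = seed)
  class(report) <- "metrics_report"
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s on %s: mean accuracy %.2f%%, macro-F1 %.2f%% (%d folds)\n",
              toupper(x$method), x$dimension, x$mean_accuracy,
              x$mean_macro_f1, x$k_folds))
  invisible(x)
}

#' Subset a cohort of participants
#'
#' A cohort is a named list of per-participant `synth_dataset`s; this keeps
#' only the listed participants (e.g. a male or female subset for
#' gender-specific runs).
#'
#' @param cohort named list of `synth_dataset`s.
#' @param ids names (or indices) of the participants to keep.
#' @return The subset cohort; an empty selection warns.
#' @export
subset_participants <- function(cohort, ids) {
  stopifnot(is.list(cohort))
  if (is.character(ids)) {
    unknown <- setdiff(ids, names(cohort))
    if (length(unknown)) stop("unknown participant id(s): ",
                              paste(unknown, collapse = ", "))
  } else if (any(ids < 1 | ids > length(cohort))) {
    stop("participant index out of range")
  }
  out <- cohort[ids]
  if (length(out) == 0) warning("empty participant subset")
  out
}
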