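#' ReliefF feature weighting
#'
#' Instance-based feature weights after Kononenko's ReliefF. For every
#' visited instance `x_i`, the `k` nearest same-class hits `h_j` and, for
#' each other class `c`, the `k` nearest misses `m_j(c)` are located (by
#' the summed range-normalized per-feature distance); the weight of feature
#' `a` is then updated by
#' `w(a) <- w(a) - sum_j dist(a, x_i, h_j) / (m k)
#'        + sum_{c != class(x_i)} P(c) / (1 - P(class(x_i)))
#'          sum_j dist(a, x_i, m_j(c)) / (m k)`
#' with `dist(a, x, y) = |x_a - y_a| / (max_a - min_a)` and `P(c)` the class
#' prior (class fraction). In `full_pass` mode every instance is visited
#' once in index order (`m = n`, deterministic); in `sampled` mode `m`
#' instances are drawn with the given seed.
#'
#' Constant features contribute zero distance. If a class has fewer than
#' `k + 1` members, `k` is reduced for that class with a warning.
#'
#' @param X trials x d numeric feature matrix.
#' @param y class labels (factor or character), one per row.
#' @param k nearest-neighbor count (default 10).
#' @param m iteration count for `sampled` mode (defaults to `nrow(X)`).
#' @param mode `"full_pass"` (default) or `"sampled"`.
#' @param seed RNG seed for `sampled` mode.
#' @return Numeric weight vector of length `d` (named after `colnames(X)`).
#' @export
relieff_weights <- function(X, y, k = 10, m = NULL,
                            mode = c("full_pass", "sampled"), seed = 1L) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  d <- ncol(X)
  stopifnot(n == length(y), k >= 1)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes")
  counts <- table(y)
  if (any(counts < 2)) stop("need at least 2 instances per class")
  priors <- as.numeric(counts[classes]) / n
  names(priors) <- classes

  rng <- apply(X, 2, function(col) diff(range(col)))
  scale <- ifelse(rng > 0, rng, Inf)       # constant columns: zero diff
  Xs <- sweep(X, 2, scale, "/")            # normalized once; diffs are |.|

  if (mode == "full_pass") {
    visits <- seq_len(n)
  } else {
    if (is.null(m)) m <- n
    visits <- with_seed(seed, sample.int(n, m, replace = m > n))
  }
  m_iter <- length(visits)

  if (any(counts < k + 1))
    warning("class with fewer than k+1 members; k reduced for that class")

  idx_by_class <- split(seq_len(n), y)
  w <- numeric(d)
  for (i in visits) {
    di <- rowSums(abs(sweep(Xs, 2, Xs[i, ], "-")))   # L1 in normalized space
    cls_i <- y[i]
    for (cl in classes) {
      pool <- idx_by_class[[cl]]
      if (cl == cls_i) pool <- setdiff(pool, i)
      k_use <- min(k, length(pool))
      nn <- pool[order(di[pool], pool)][seq_len(k_use)]
      contrib <- colSums(abs(Xs[nn, , drop = FALSE] -
                               matrix(Xs[i, ], k_use, d, byrow = TRUE)))
      if (cl == cls_i) {
        w <- w - contrib / (m_iter * k_use)
      } else {
        w <- w + (priors[cl] / (1 - priors[cls_i])) * contrib / (m_iter * k_use)
      }
    }
  }
  names(w) <- colnames(X)
  w
}

#' Neighborhood component analysis feature weights (diagonal transform)
#'
#' Learns a diagonal feature weighting `A = diag(a)` by maximizing the
#' expected leave-one-out neighbor-class agreement
#' `f(A) = sum_i sum_{j in C_i} p_ij`, where
#' `p_ij = exp(-||A x_i - A x_j||^2) / sum_{k != i} exp(-||A x_i - A x_k||^2)`
#' and `p_ii = 0`, optionally ridge-penalized by `lambda * sum(a^2)`.
#' Optimization is gradient ascent from the all-ones start with step
#' halving on non-improving steps, stopping when the objective gain falls
#' below `tol` or after `max_iter` iterations. Softmax terms are
#' log-sum-exp shifted, so large distances do not underflow.
#'
#' @param X trials x d feature matrix.
#' @param y class labels, one per row (>= 2 classes).
#' @param lambda ridge penalty on the diagonal entries (>= 0); defaults to
#'   `1/n`. A nonzero penalty is what makes NCA act as a feature
#'   *selector*: when classes are well separated the neighbor probabilities
#'   saturate and the unpenalized gradient vanishes, leaving uninformative
#'   weights at their start value; the ridge term then shrinks exactly the
#'   features the objective does not defend.
#' @param learning_rate initial ascent step.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the objective.
#' @param standardize center/scale columns first (recommended; constant
#'   columns are left unscaled).
#' @return Nonnegative weight vector of length `d`: the squared diagonal
#'   entries `a^2`, named after `colnames(X)`. The achieved objective and
#'   its trajectory are attached as attributes `objective` and `trace`.
#' @export
nca_weights <- function(X, y, lambda = NULL, learning_rate = 0.1,
                        max_iter = 100, tol = 1e-6, standardize = TRUE) {
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  d <- ncol(X)
  if (is.null(lambda)) lambda <- 1 / n
  stopifnot(n == length(y), learning_rate > 0, tol > 0, lambda >= 0)
  if (length(unique(y)) < 2) stop("need at least 2 classes")
  if (standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  }
  same <- outer(y, y, "==")
  diag(same) <- FALSE

  objective_and_grad <- function(a) {
    Xw <- sweep(X, 2, a, "*")
    sq <- rowSums(Xw^2)
    D <- outer(sq, sq, "+") - 2 * tcrossprod(Xw)   # ||A x_i - A x_j||^2
    D[D < 0] <- 0
    diag(D) <- Inf
    shift <- apply(D, 1, min)
    shift[!is.finite(shift)] <- 0
    E <- exp(-(D - shift))
    diag(E) <- 0
    denom <- rowSums(E)
    denom[denom == 0] <- 1
    P <- E / denom                                  # p_ij
    p_i <- rowSums(P * same)
    f <- sum(p_i) - lambda * sum(a^2)
    # d f / d a_r = 2 a_r [ sum_ik p_i p_ik d_ik,r - sum_{j in C_i} p_ij d_ij,r ]
    M <- P * p_i - P * same                        # coefficient of d_ij,r
    rM <- rowSums(M)
    cM <- colSums(M)
    s <- (rM + cM) %*% X^2 - 2 * colSums(X * (M %*% X))
    grad <- 2 * a * as.numeric(s) - 2 * lambda * a
    list(f = f, grad = grad)
  }

  a <- rep(1, d)
  og <- objective_and_grad(a)
  lr <- learning_rate
  trace <- og$f
  for (it in seq_len(max_iter)) {
    if (!all(is.finite(og$grad))) stop("non-finite NCA gradient")
    accepted <- FALSE
    for (tries in 1:20) {
      a_new <- a + lr * og$grad
      og_new <- objective_and_grad(a_new)
      if (is.finite(og_new$f) && og_new$f >= og$f) { accepted <- TRUE; break }
      lr <- lr / 2
    }
    if (!accepted) break
    gain <- og_new$f - og$f
    a <- a_new
    og <- og_new
    trace <- c(trace, og$f)
    lr <- lr * 1.1
    if (gain < tol) break
  }
  w <- a^2
  names(w) <- colnames(X)
  attr(w, "objective") <- og$f + lambda * sum(a^2)  # raw f(A)
  attr(w, "trace") <- trace
  w
}

#' Aggregate feature weights into a channel ranking
#'
#' A channel's score is the sum of the positive parts of the weights of its
#' 45 features (negative weights are clipped, so harmful features cannot
#' cancel informative ones). Channels are ordered by descending score; ties
#' break lexicographically by label.
#'
#' @param w feature weight vector.
#' @param index flat-column index (`feature_tensor()$index`), mapping each
#'   weight to its (channel, band, characteristic).
#' @param top_n number of channels to retain (default 10).
#' @param method tag recorded in the ranking (`"relieff"` or `"nca"`).
#' @return A `channel_ranking`: data.frame with `rank`, `channel`, `score`.
#' @export
channels_from_feature_weights <- function(w, index, top_n = 10,
                                          method = "relieff") {
  stopifnot(length(w) == nrow(index))
  score <- tapply(pmax(w, 0), index$channel, sum)
  channels <- names(score)
  if (top_n > length(channels)) stop("top_n exceeds channel count")
  ord <- order(-score, channels)
  out <- data.frame(rank = seq_len(top_n),
                    channel = channels[ord][seq_len(top_n)],
                    score = as.numeric(score[ord][seq_len(top_n)]),
                    row.names = NULL)
  attr(out, "method") <- method
  class(out) <- c("channel_ranking", "data.frame")
  out
}

#' Select the most informative channels of a dataset
#'
#' Builds the labeled feature table (flattened [feature_tensor()] plus
#' ratings binarized on the chosen affect dimension), weights every feature
#' by ReliefF or NCA, aggregates the weights per channel and returns the
#' top-ranked channels.
#'
#' @param dataset a `synth_dataset` (or list of `eeg_trial`s with ratings).
#' @param method `"relieff"` or `"nca"`.
#' @param dimension affect dimension to binarize (`"valence"`, `"arousal"`,
#'   `"dominance"`).
#' @param top_n channels to retain (default 10, the R-/N-HOLO-FM rule).
#' @param scale rating scale `c(min, max, threshold)`.
#' @param ft optional precomputed `feature_tensor` for the dataset.
#' @param trial_subset optional integer subset of trials to use (e.g. a
#'   training fold).
#' @param ... passed on to [relieff_weights()] or [nca_weights()].
#' @return A `channel_ranking`.
#' @export
select_channels <- function(dataset, method = c("relieff", "nca"),
                            dimension = "valence", top_n = 10,
                            scale = NULL, ft = NULL, trial_subset = NULL,
                            ...) {
  method <- match.arg(method)
  if (is.null(scale)) {
    scale <- if (inherits(dataset, "synth_dataset"))
      dataset$config$rating_scale else c(1, 9, 4.5)
  }
  if (is.null(ft)) ft <- feature_tensor(dataset)
  trials <- if (inherits(dataset, "synth_dataset")) dataset$trials else dataset
  ratings <- vapply(trials, function(tr) tr$ratings[[dimension]], numeric(1))
  y <- binarize_ratings(ratings, scale)
  X <- flatten_features(ft)
  if (!is.null(trial_subset)) {
    X <- X[trial_subset, , drop = FALSE]
    y <- y[trial_subset]
  }
  if (length(unique(y)) < 2)
    stop("single-class label vector on dimension ", dimension)
  w <- if (method == "relieff") relieff_weights(X, y, ...)
       else nca_weights(X, y, ...)
  channels_from_feature_weights(w, ft$index, top_n = top_n, method = method)
}

#' @export
print.channel_ranking <- function(x, ...) {
  cat(sprintf("<channel_ranking> top %d channels (%s)\n", nrow(x),
              attr(x, "method") %||% "?"))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a channel ranking as CSV (rank,label,score,method)
#'
#' @param ranking a `channel_ranking`.
#' @param file output path.
#' @export
write_ranking_csv <- function(ranking, file) {
  df <- data.frame(rank = ranking$rank, label = ranking$channel,
                   score = ranking$score,
                   method = attr(ranking, "method") %||% NA)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
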