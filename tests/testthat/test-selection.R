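# Literal-pseudocode ReliefF: explicit loops over iterations, classes and
# features, transcribed directly from the algorithm's definition (full-pass
# deterministic order, range-normalized feature distances, nearest ties
# broken by instance index).
oracle_relieff <- function(X, y, k) {
  n <- nrow(X); d <- ncol(X)
  classes <- sort(unique(y))
  priors <- sapply(classes, function(cl) mean(y == cl))
  rng <- apply(X, 2, function(col) diff(range(col)))
  dist1 <- function(a, i, j) {
    if (rng[a] == 0) return(0)
    abs(X[i, a] - X[j, a]) / rng[a]
  }
  total_dist <- function(i, j) sum(sapply(1:d, function(a) dist1(a, i, j)))
  w <- numeric(d)
  for (i in 1:n) {
    for (cl in classes) {
      pool <- setdiff(which(y == cl), i)
      dd <- sapply(pool, function(j) total_dist(i, j))
      ord <- pool[order(dd, pool)]
      k_use <- min(k, length(ord))
      nn <- ord[seq_len(k_use)]
      for (a in 1:d) {
        s <- sum(sapply(nn, function(j) dist1(a, i, j)))
        if (cl == y[i]) {
          w[a] <- w[a] - s / (n * k_use)
        } else {
          w[a] <- w[a] + (priors[cl] / (1 - priors[y[i]])) * s / (n * k_use)
        }
      }
    }
  }
  w
}

# Literal double-loop NCA objective f(A) = sum_i sum_{j in C_i} p_ij for a
# diagonal transform with entries `a`.
oracle_nca_objective <- function(X, y, a) {
  n <- nrow(X)
  f <- 0
  for (i in 1:n) {
    num <- numeric(n)
    for (j in 1:n) {
      if (j == i) next                       # p_ii = 0
      num[j] <- exp(-sum((a * (X[i, ] - X[j, ]))^2))
    }
    if (sum(num) == 0) next
    p <- num / sum(num)
    f <- f + sum(p[y == y[i]])
  }
  f
}

test_that("ReliefF separates a hand-built 4-instance problem", {
  # feature A separates the classes perfectly, feature B is constant
  X <- cbind(A = c(0, 0.1, 1, 1.1), B = rep(5, 4))
  y <- c("low", "low", "high", "high")
  w <- relieff_weights(X, y, k = 1)
  expect_gt(w["A"], 0)
  expect_equal(unname(w["B"]), 0)
  expect_equal(unname(w), oracle_relieff(X, y, 1), tolerance = 1e-12)
})

test_that("ReliefF full pass is deterministic and duplication-invariant", {
  set.seed(31)
  y <- rep(c("low", "high"), 10)
  # strong separator, weak separator, pure noise: after ReliefF's range
  # normalization the three weights are unambiguously ordered
  X <- cbind(strong = ifelse(y == "high", 1, -1) + rnorm(20, sd = 0.05),
             weak = ifelse(y == "high", 1, -1) + rnorm(20, sd = 1.2),
             noise = rnorm(20))
  w1 <- relieff_weights(X, y, k = 3)
  w2 <- relieff_weights(X, y, k = 3)
  expect_identical(w1, w2)
  expect_equal(order(-w1), 1:3)
  # duplicating every instance preserves the feature ranking
  wd <- relieff_weights(rbind(X, X), c(y, y), k = 3)
  expect_equal(order(-wd), order(-w1))
})

test_that("ReliefF matches the literal-pseudocode oracle on random tables", {
  set.seed(32)
  for (rep in 1:5) {
    n <- sample(12:30, 1); d <- sample(5:10, 1)
    X <- matrix(rnorm(n * d), n, d)
    X[, d] <- 7                                 # one constant feature
    y <- sample(c("low", "high"), n, replace = TRUE)
    if (min(table(y)) < 2) next
    k <- sample(1:3, 1)
    expect_equal(unname(relieff_weights(X, y, k = k)),
                 oracle_relieff(X, y, k), tolerance = 1e-12)
  }
})

test_that("ReliefF warns and degrades k for small classes", {
  X <- matrix(rnorm(12), 6, 2)
  y <- c("low", "low", "low", "low", "high", "high")
  expect_warning(relieff_weights(X, y, k = 3), "k reduced")
})

test_that("NCA objective is a bounded probability mass with p_ii = 0", {
  set.seed(33)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rep(c("low", "high"), 15)
  w <- nca_weights(X, y, standardize = FALSE, max_iter = 25)
  f <- attr(w, "objective")
  expect_gte(f, 0)
  expect_lte(f, 30)
  # objective agrees with the literal double-loop oracle at the optimum
  expect_equal(f, oracle_nca_objective(X, y, sqrt(w)), tolerance = 1e-8)
  # non-decreasing across accepted steps
  expect_true(all(diff(attr(w, "trace")) >= 0))
})

test_that("NCA upweights an informative feature over pure noise", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 60
    y <- rep(c("low", "high"), n / 2)
    X <- cbind(ifelse(y == "high", 3, -3) + rnorm(n, sd = 0.5), rnorm(n))
    w <- nca_weights(X, y, standardize = TRUE)
    if (w[1] / max(w[2], 1e-12) > 5) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("channel aggregation follows the clipped-sum rule", {
  idx <- fix_ft$index
  w <- numeric(nrow(idx))
  w[idx$channel == "F3"] <- 1
  rk <- channels_from_feature_weights(w, idx, top_n = 5)
  expect_equal(rk$channel[1], "F3")
  expect_equal(rk$score[1], 45)
  # all-zero weights: lexicographic order, zero scores
  rk0 <- channels_from_feature_weights(numeric(nrow(idx)), idx, top_n = 14)
  expect_equal(rk0$channel, sort(fix_layout$labels))
  expect_true(all(rk0$score == 0))
  # permuting columns together with the index leaves the ranking unchanged
  perm <- sample(nrow(idx))
  rkp <- channels_from_feature_weights(w[perm], idx[perm, ], top_n = 5)
  expect_equal(rkp$channel, rk$channel)
  expect_error(channels_from_feature_weights(w, idx, top_n = 15), "top_n")
})

test_that("negative weights are clipped, not cancelling", {
  idx <- fix_ft$index
  w <- numeric(nrow(idx))
  w[idx$channel == "F3"] <- c(1, rep(-10, 44))   # one good, many harmful
  rk <- channels_from_feature_weights(w, idx, top_n = 14)
  expect_equal(rk$score[rk$channel == "F3"], 1)
})

test_that("select_channels recovers the informative channels", {
  ds <- generate_synth_eeg(synth_config(n_trials = 60, duration_s = 2,
                                        effect_size = 4, seed = 34))
  ft <- feature_tensor(ds)
  for (method in c("relieff", "nca")) {
    rk <- select_channels(ds, method, "valence", top_n = 10, ft = ft)
    expect_true(all(c("F3", "F4", "T7") %in% rk$channel))
    expect_equal(attr(rk, "method"), method)
  }
})

test_that("select_channels honors top_n and rejects degenerate labels", {
  rk_all <- select_channels(fix_ds, "relieff", top_n = 14, ft = fix_ft)
  expect_setequal(rk_all$channel, fix_layout$labels)
  # single-class labels: force via an impossible threshold
  ds1 <- fix_ds
  ds1$config$rating_scale <- c(0, 10, 9.9)
  expect_error(select_channels(ds1, "relieff", ft = fix_ft), "single-class")
})

test_that("ranking CSV export carries rank,label,score,method", {
  rk <- select_channels(fix_ds, "relieff", top_n = 5, ft = fix_ft)
  f <- tempfile(fileext = ".csv")
  write_ranking_csv(rk, f)
  df <- read.csv(f)
  expect_equal(names(df), c("rank", "label", "score", "method"))
  expect_equal(df$method[1], "relieff")
  expect_equal(nrow(df), 5)
})
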