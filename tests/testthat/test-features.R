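# Literal-loop reference implementations used as oracles. They are written
# as direct transcriptions of the defining formulas, independent of the
# package's vectorized code paths.

oracle_band_power <- function(x) { s <- 0; for (v in x) s <- s + v^2; s / length(x) }
oracle_rms <- function(x) sqrt(oracle_band_power(x))
oracle_p2p <- function(x) max(x) - min(x)
oracle_de <- function(x) 0.5 * log(2 * pi * exp(1) * var(x))

oracle_higuchi <- function(x, k_max) {
  n <- length(x)
  Lk <- numeric(k_max)
  for (k in 1:k_max) {
    Lm <- numeric(k)
    for (m in 1:k) {
      i_max <- floor((n - m) / k)
      s <- 0
      for (i in 1:i_max) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      Lm[m] <- (s * (n - 1) / (i_max * k)) / k
    }
    Lk[k] <- mean(Lm)
  }
  fit <- lm(log(Lk) ~ log(1:k_max))
  list(Lk = Lk, D = -unname(coef(fit)[2]))
}

oracle_hjorth <- function(x) {
  n <- length(x)
  act <- sum((x - mean(x))^2) / n
  v <- function(u) sum((u - mean(u))^2) / length(u)
  mob <- sqrt(v(diff(x)) / v(x))
  cx <- sqrt(v(diff(diff(x))) / v(diff(x))) / mob
  c(activity = act, mobility = mob, complexity = cx)
}

test_that("band power, rms and peak-to-peak match their definitions", {
  expect_equal(band_power(c(1, 2, 3)), 14 / 3)
  expect_equal(band_power(rep(0, 10)), 0)
  set.seed(1); x <- rnorm(50)
  expect_equal(band_power(2 * x), 4 * band_power(x))
  expect_equal(rms(rep(-3, 5)), 3)
  expect_equal(peak_to_peak(rep(4, 5)), 0)
  expect_equal(peak_to_peak(c(-1, 3)), 4)
  expect_equal(rms(x)^2, band_power(x))
  expect_error(band_power(numeric(0)), "empty")
})

test_that("differential entropy matches the Gaussian closed form", {
  # an exact unit-sample-variance series
  x <- c(-1, 1) / sqrt(var(c(-1, 1)))
  expect_equal(diff_entropy(x), 0.5 * log(2 * pi * exp(1)))
  expect_equal(round(diff_entropy(x), 4), 1.4189)
  x0 <- c(-1, 1) * sqrt(1 / (2 * pi * exp(1)) / var(c(-1, 1)))
  expect_equal(diff_entropy(x0), 0)
  set.seed(2); y <- rnorm(100)
  expect_equal(diff_entropy(3 * y), diff_entropy(y) + log(3))
  expect_error(diff_entropy(rep(1, 10)), "degenerate")
})

test_that("differential entropy increases strictly with variance", {
  set.seed(3); y <- rnorm(200)
  des <- vapply(c(0.5, 1, 2, 4, 8), function(s) diff_entropy(s * y), numeric(1))
  expect_true(all(diff(des) > 0))
})

test_that("Higuchi dimension is ~1 for a line and ~2 for white noise", {
  line <- higuchi_fd(as.numeric(1:1000), k_max = 8)
  expect_gt(line$D, 0.95); expect_lt(line$D, 1.05)
  for (seed in 1:20) {
    set.seed(seed)
    d <- higuchi_fd(rnorm(2000), k_max = 8)$D
    expect_gt(d, 1.85); expect_lt(d, 2.05)
  }
  expect_error(higuchi_fd(rnorm(5), k_max = 8), "shorter")
})

test_that("Hjorth parameters behave on a discretized sine", {
  A <- 3
  x <- A * sin(2 * pi * 4 * (0:1279) / 128)
  hj <- hjorth(x)
  expect_equal(hj$activity, A^2 / 2, tolerance = 0.02)
  expect_gt(hj$complexity, 0.98); expect_lt(hj$complexity, 1.05)
  set.seed(4); y <- rnorm(100)
  expect_equal(hjorth(5 * y)$mobility, hjorth(y)$mobility)
  expect_equal(hjorth(5 * y)$complexity, hjorth(y)$complexity)
  expect_error(hjorth(rep(2, 50)), "degenerate|constant")
})

test_that("Welch PSD conserves power and scales quadratically", {
  set.seed(6)
  x <- rnorm(5000, sd = 2)
  m <- psd_welch_mean(x, fs = 128)
  expect_equal(m, 2 * 4 / 128, tolerance = 0.1)
  expect_equal(psd_welch_mean(2 * x, 128), 4 * m)
  expect_identical(psd_welch_mean(x, 128), psd_welch_mean(x, 128))
  expect_error(psd_welch(rnorm(50), 128), "shorter")
})

test_that("every scalar feature matches its literal-loop oracle", {
  set.seed(7)
  for (rep in 1:100) {
    x <- rnorm(sample(60:200, 1), sd = runif(1, 0.1, 5))
    expect_equal(band_power(x), oracle_band_power(x), tolerance = 1e-12)
    expect_equal(rms(x), oracle_rms(x), tolerance = 1e-12)
    expect_equal(peak_to_peak(x), oracle_p2p(x), tolerance = 1e-12)
    expect_equal(diff_entropy(x), oracle_de(x), tolerance = 1e-12)
    oh <- oracle_hjorth(x)
    hj <- hjorth(x)
    expect_equal(hj$activity, unname(oh["activity"]), tolerance = 1e-12)
    expect_equal(hj$mobility, unname(oh["mobility"]), tolerance = 1e-12)
    expect_equal(hj$complexity, unname(oh["complexity"]), tolerance = 1e-12)
  }
  for (rep in 1:10) {
    x <- rnorm(300)
    expect_equal(higuchi_fd(x, 8)$D, oracle_higuchi(x, 8)$D, tolerance = 1e-12)
    expect_equal(higuchi_fd(x, 8)$Lk, oracle_higuchi(x, 8)$Lk, tolerance = 1e-12)
  }
})

test_that("time reversal leaves the amplitude features unchanged", {
  set.seed(8); x <- rnorm(256)
  xr <- rev(x)
  expect_equal(band_power(xr), band_power(x))
  expect_equal(rms(xr), rms(x))
  expect_equal(peak_to_peak(xr), peak_to_peak(x))
  expect_equal(diff_entropy(xr), diff_entropy(x))
  expect_equal(hjorth(xr)$activity, hjorth(x)$activity)
})

test_that("the feature tensor has the 45-per-channel layout", {
  expect_equal(dim(fix_ft$values), c(12, 14, 5, 9))
  X <- flatten_features(fix_ft)
  expect_equal(dim(X), c(12, 14 * 45))
  # index is a bijection onto channels x bands x characteristics
  key <- with(fix_ft$index, paste(channel, band, characteristic))
  expect_false(any(duplicated(key)))
  expect_equal(nrow(fix_ft$index), 630)
})

test_that("tensor entries reproduce direct scalar calls", {
  tr <- fix_ds$trials[[5]]
  sb <- decompose_subbands(tr)
  ch <- match("T7", tr$labels)
  x <- sb$bands$alpha[ch, ]
  expect_equal(fix_ft$values[5, "T7", "alpha", "band_power"], band_power(x))
  expect_equal(fix_ft$values[5, "T7", "alpha", "diff_entropy"], diff_entropy(x))
  expect_equal(fix_ft$values[5, "T7", "alpha", "fractal_dim"],
               higuchi_fd(x, 8)$D)
  expect_equal(fix_ft$values[5, "T7", "alpha", "hjorth_mobility"],
               hjorth(x)$mobility)
  expect_equal(fix_ft$values[5, "T7", "alpha", "psd_welch_mean"],
               psd_welch_mean(x, 128))
})

test_that("permuting trials permutes tensor rows identically", {
  perm <- c(4, 1, 3, 2)
  ft_perm <- feature_tensor(fix_ds$trials[perm])
  expect_equal(ft_perm$values[1, , , ], fix_ft$values[4, , , ])
  expect_equal(ft_perm$values[4, , , ], fix_ft$values[2, , , ])
})

test_that("feature CSV export is long-format and complete", {
  f <- tempfile(fileext = ".csv")
  small <- feature_tensor(fix_ds$trials[1:2])
  write_feature_csv(small, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 2 * 630)
  expect_equal(names(df), c("trial", "channel", "band", "characteristic",
                            "value"))
  sub <- df[df$trial == 1 & df$channel == "F3" & df$band == "gamma" &
              df$characteristic == "rms", "value"]
  expect_equal(sub, small$values[1, "F3", "gamma", "rms"])
})
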