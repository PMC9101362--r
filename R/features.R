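#' Per-window signal characteristics
#'
#' The nine scalar characteristics computed on every (channel, band) series:
#' band power, differential entropy, Higuchi fractal dimension, the three
#' Hjorth parameters, RMS, peak-to-peak and the mean of the Welch PSD.
#'
#' @param x numeric series.
#' @return `band_power`: mean of the squared samples, `sum(x^2)/N`.
#' @seealso [feature_tensor()] for assembling all nine over a dataset.
#' @export
band_power <- function(x) {
  if (!length(x)) stop("empty input")
  sum(x^2) / length(x)
}

#' Differential entropy of a series (Gaussian closed form)
#'
#' `0.5 * log(2 * pi * e * var(x))` in nats, with the unbiased sample
#' variance. For a Gaussian signal this is the exact differential entropy;
#' it grows by `log|c|` when the signal is scaled by `c`.
#'
#' @param x numeric series (length >= 2, non-constant).
#' @return Differential entropy in nats.
#' @export
diff_entropy <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  s2 <- stats::var(x)
  if (s2 <= 0) stop("degenerate input: zero variance")
  0.5 * log(2 * pi * exp(1) * s2)
}

#' Higuchi fractal dimension
#'
#' For each interval time `k = 1..k_max` and initial time `m = 1..k`, the
#' normalized curve length of the coarse-grained series
#' `X(m), X(m+k), X(m+2k), ...` is
#' `L_m(k) = [ sum |X(m+ik) - X(m+(i-1)k)| ] * (N-1) / (floor((N-m)/k) * k) / k`,
#' and `<L(k)>` is the mean over `m`. The fractal dimension `D` is the
#' negative least-squares slope of `log <L(k)>` against `log k`
#' (`<L(k)> ~ k^-D`): `D = 1` for a straight line, `D -> 2` for white noise.
#'
#' @param x numeric series, length > `k_max`.
#' @param k_max largest coarse-graining interval (default 8, a common choice
#'   for 128 Hz windows).
#' @return A `higuchi_curve`: list with `k`, `Lk` (mean curve lengths) and
#'   `D` (fitted fractal dimension).
#' @export
higuchi_fd <- function(x, k_max = 8) {
  n <- length(x)
  if (k_max < 2) stop("k_max must be >= 2")
  if (n <= k_max) stop("series shorter than k_max + 1")
  Lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      nm <- length(idx) - 1          # floor((N - m) / k)
      if (nm < 1) { Lm[m] <- NA; next }
      Lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (nm * k) / k
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  ok <- Lk > 0
  if (sum(ok) < 2) stop("degenerate input: curve length vanishes")
  fit <- stats::lsfit(log(seq_len(k_max)[ok]), log(Lk[ok]))
  out <- list(k = seq_len(k_max), Lk = Lk, D = -unname(fit$coefficients[2]))
  class(out) <- "higuchi_curve"
  out
}

#' Hjorth parameters
#'
#' Activity is the mean squared deviation from the mean (variance with the
#' `1/N` convention); mobility is `sqrt(var(x') / var(x))` with `x'` the
#' first difference; complexity is `mobility(x') / mobility(x)`. Mobility
#' and complexity are scale-invariant; complexity is ~1 for a pure sinusoid.
#'
#' @param x numeric series (length >= 3, non-constant).
#' @return A `hjorth_triple`: list with `activity`, `mobility`, `complexity`.
#' @export
hjorth <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples")
  mom2 <- function(v) sum((v - mean(v))^2) / length(v)
  a <- mom2(x)
  if (a <= 0) stop("degenerate input: constant signal")
  d1 <- diff(x)
  d2 <- diff(d1)
  mob <- sqrt(mom2(d1) / a)
  mob_d <- sqrt(mom2(d2) / mom2(d1))
  out <- list(activity = a, mobility = mob, complexity = mob_d / mob)
  class(out) <- "hjorth_triple"
  out
}

#' @rdname band_power
#' @return `rms`: root mean square, `sqrt(sum(x^2)/N)`.
#' @export
rms <- function(x) {
  if (!length(x)) stop("empty input")
  sqrt(sum(x^2) / length(x))
}

#' @rdname band_power
#' @return `peak_to_peak`: `max(x) - min(x)`.
#' @export
peak_to_peak <- function(x) {
  if (!length(x)) stop("empty input")
  max(x) - min(x)
}

#' Welch power spectral density
#'
#' One-sided Welch PSD with Hamming-windowed segments (default 128 samples,
#' i.e. 1 s at 128 Hz) and 50% overlap, density-scaled so the PSD integrates
#' to the signal power (`sum(psd) * fs / nperseg ~ var(x)` for white noise).
#'
#' @param x numeric series, at least one segment long.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples.
#' @param overlap fractional segment overlap in `[0, 1)`.
#' @return List with `freq` and `psd` vectors.
#' @export
psd_welch <- function(x, fs, nperseg = 128, overlap = 0.5) {
  n <- length(x)
  if (n < nperseg) stop("series shorter than one segment")
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nperseg) - 1) / (nperseg - 1))
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  nf <- nperseg %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    sp <- Mod(stats::fft(seg)[seq_len(nf)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * sum(w^2))
  # one-sided: double everything except DC and (for even nperseg) Nyquist
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / nperseg, psd = psd * dbl)
}

#' @rdname psd_welch
#' @return `psd_welch_mean`: the mean over frequency bins of the Welch PSD.
#' @export
psd_welch_mean <- function(x, fs, nperseg = 128, overlap = 0.5) {
  mean(psd_welch(x, fs, nperseg = nperseg, overlap = overlap)$psd)
}

#' Fixed characteristic order of the feature tensor
#'
#' @return Character vector of the nine characteristic names in their
#'   canonical order.
#' @export
characteristic_names <- function() {
  c("band_power", "diff_entropy", "fractal_dim", "hjorth_activity",
    "hjorth_mobility", "hjorth_complexity", "rms", "peak_to_peak",
    "psd_welch_mean")
}

#' Assemble the trials x channels x bands x characteristics feature tensor
#'
#' Decomposes every trial into its five wavelet subbands and computes the
#' nine signal characteristics on each (channel, band) series. Degenerate
#' series (constant within a band) yield 0 for the affected entropy/Hjorth
#' features; the number of such substitutions is reported in the
#' `degenerate` attribute and as a warning.
#'
#' @param dataset a `synth_dataset`, or a plain list of `eeg_trial`s.
#' @param k_max Higuchi interval bound, see [higuchi_fd()].
#' @return A `feature_tensor`: list with `values` (4-d array, trials x
#'   channels x 5 bands x 9 characteristics), `channels`, `bands`,
#'   `characteristics` and `index` (flat-column to (channel, band,
#'   characteristic) mapping used by [flatten_features()]).
#' @export
feature_tensor <- function(dataset, k_max = 8) {
  trials <- if (inherits(dataset, "synth_dataset")) dataset$trials else dataset
  stopifnot(length(trials) >= 1)
  labels <- trials[[1]]$labels
  for (tr in trials) {
    if (!identical(tr$labels, labels))
      stop("inconsistent channel sets across trials")
  }
  bands <- names(eeg_bands())
  chars <- characteristic_names()
  n <- length(trials)
  n_ch <- length(labels)
  vals <- array(0, dim = c(n, n_ch, length(bands), length(chars)),
                dimnames = list(NULL, labels, bands, chars))
  degenerate <- 0L
  for (i in seq_len(n)) {
    sb <- decompose_subbands(trials[[i]])
    fs <- trials[[i]]$fs
    for (b in seq_along(bands)) {
      bm <- sb$bands[[bands[b]]]
      for (ch in seq_len(n_ch)) {
        x <- bm[ch, ]
        vals[i, ch, b, "band_power"] <- band_power(x)
        vals[i, ch, b, "rms"] <- rms(x)
        vals[i, ch, b, "peak_to_peak"] <- peak_to_peak(x)
        vals[i, ch, b, "psd_welch_mean"] <- psd_welch_mean(x, fs)
        if (stats::var(x) > 0) {
          vals[i, ch, b, "diff_entropy"] <- diff_entropy(x)
          hj <- hjorth(x)
          vals[i, ch, b, "hjorth_activity"] <- hj$activity
          vals[i, ch, b, "hjorth_mobility"] <- hj$mobility
          vals[i, ch, b, "hjorth_complexity"] <- hj$complexity
          vals[i, ch, b, "fractal_dim"] <- higuchi_fd(x, k_max)$D
        } else {
          degenerate <- degenerate + 1L
        }
      }
    }
  }
  if (degenerate > 0)
    warning(degenerate, " degenerate (constant) band series recorded as 0")
  index <- expand.grid(characteristic = chars, band = bands, channel = labels,
                       stringsAsFactors = FALSE)[, 3:1]
  index$col <- seq_len(nrow(index))
  out <- list(values = vals, channels = labels, bands = bands,
              characteristics = chars, index = index)
  attr(out, "degenerate") <- degenerate
  class(out) <- "feature_tensor"
  out
}

#' Flatten a feature tensor to a trials x d matrix
#'
#' Columns are ordered channel-major, then band, then characteristic, in the
#' order given by the tensor's `index` (d = channels * 5 * 9 = channels * 45).
#'
#' @param ft a `feature_tensor`.
#' @return Numeric matrix with `d` columns named `channel.band.characteristic`.
#' @export
flatten_features <- function(ft) {
  stopifnot(inherits(ft, "feature_tensor"))
  n <- dim(ft$values)[1]
  idx <- ft$index
  out <- matrix(0, n, nrow(idx))
  for (j in seq_len(nrow(idx))) {
    out[, j] <- ft$values[, idx$channel[j], idx$band[j], idx$characteristic[j]]
  }
  colnames(out) <- paste(idx$channel, idx$band, idx$characteristic, sep = ".")
  out
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_tensor> %d trials x %d channels x %d bands x %d characteristics\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Export / import a feature tensor as a flat CSV
#'
#' Long format with columns trial, channel, band, characteristic, value.
#'
#' @param ft a `feature_tensor`.
#' @param file CSV path.
#' @export
write_feature_csv <- function(ft, file) {
  stopifnot(inherits(ft, "feature_tensor"))
  n <- dim(ft$values)[1]
  flat <- flatten_features(ft)
  idx <- ft$index
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(trial = i, idx[, c("channel", "band", "characteristic")],
               value = flat[i, ])
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
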