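# Daubechies-5 orthonormal filter taps (standard published coefficients).
.db5_dec_lo <- c(0.0033357252854737712, -0.012580751999081999,
                 -0.006241490212798274, 0.07757149384004572,
                 -0.032244869584638375, -0.24229488706638203,
                 0.13842814590132074, 0.7243085284377729,
                 0.6038292697971896, 0.16010239797419293)
.db5_dec_hi <- c(-0.16010239797419293, 0.6038292697971896,
                 -0.7243085284377729, 0.13842814590132074,
                 0.24229488706638203, -0.032244869584638375,
                 -0.07757149384004572, -0.006241490212798274,
                 0.012580751999081999, 0.0033357252854737712)
.db5_rec_lo <- rev(.db5_dec_lo)
.db5_rec_hi <- rev(.db5_dec_hi)

# One periodized analysis step: inner products of x with the even shifts of
# the orthonormal filter (correlation + dyadic downsampling).
dwt_step <- function(x, filt) {
  n <- length(x)
  k2 <- seq(0, n - 2, by = 2)
  out <- numeric(n / 2)
  for (j in seq_along(filt)) out <- out + filt[j] * x[(k2 + j - 1) %% n + 1]
  out
}

# One periodized synthesis step: expand approximation/detail coefficients on
# the same orthonormal basis. Exact inverse of dwt_step for db5.
idwt_step <- function(a, d, lo = .db5_rec_lo, hi = .db5_rec_hi) {
  half <- length(a)
  n <- 2 * half
  y <- numeric(n)
  k2 <- seq(0, n - 2, by = 2)
  for (j in seq_along(lo)) {
    idx <- (k2 + j - 1) %% n + 1
    y[idx] <- y[idx] + a * lo[j] + d * hi[j]
  }
  y
}

# 4-level periodized db5 decomposition of one series.
dwt_db5 <- function(x, levels = 4) {
  coefs <- vector("list", levels + 1)
  names(coefs) <- c(paste0("d", seq_len(levels)), paste0("a", levels))
  cur <- x
  for (lev in seq_len(levels)) {
    coefs[[paste0("d", lev)]] <- dwt_step(cur, .db5_rec_hi)
    cur <- dwt_step(cur, .db5_rec_lo)
  }
  coefs[[paste0("a", levels)]] <- cur
  coefs
}

# Reconstruct a single coefficient branch to full signal length, zeroing all
# other branches.
reconstruct_branch <- function(coefs, branch, levels = 4) {
  if (startsWith(branch, "a")) {
    cur <- coefs[[branch]]
    from <- levels
  } else {
    lev <- as.integer(substring(branch, 2))
    cur <- idwt_step(numeric(length(coefs[[branch]])), coefs[[branch]])
    from <- lev - 1
  }
  if (from >= 1) for (lev in seq(from, 1)) {
    cur <- idwt_step(cur, numeric(length(cur)))
  }
  cur
}

#' Wavelet subband decomposition of an EEG trial
#'
#' Splits every channel into the five dyadic subbands (delta 0-4, theta 4-8,
#' alpha 8-16, beta 16-32, gamma 32-64 Hz at 128 Hz sampling) by a 4-level
#' discrete wavelet transform with the db5 mother wavelet. Each band series
#' is the inverse transform of a single coefficient branch (D1 = gamma,
#' D2 = beta, D3 = alpha, D4 = theta, A4 = delta) with all other branches
#' zeroed, so the five band series have the trial's original length and sum
#' exactly back to the input (the periodized transform on the orthonormal
#' db5 basis reconstructs perfectly).
#'
#' Signals whose length is not a multiple of 16 are padded circularly to the
#' next multiple before the transform and the band series cropped back, which
#' preserves the exact sum-to-input property.
#'
#' @param trial an `eeg_trial` sampled at 128 Hz with at least 2 s of data.
#' @return A `subband_set`: list with `bands` (named list of channels x
#'   samples matrices, one per band), `fs`, `labels`.
#' @examples
#' ds <- generate_synth_eeg(synth_config(n_trials = 1, duration_s = 2))
#' sb <- decompose_subbands(ds$trials[[1]])
#' max(abs(Reduce(`+`, sb$bands) - ds$trials[[1]]$data))  # ~1e-15
#' @export
decompose_subbands <- function(trial) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (trial$fs != 128)
    stop("subband decomposition is defined at fs = 128 Hz, got ", trial$fs)
  n <- ncol(trial$data)
  if (n < 2 * trial$fs) stop("trial too short: need at least 2 s of samples")
  pad <- (16 - n %% 16) %% 16
  branch_of <- c(delta = "a4", theta = "d4", alpha = "d3",
                 beta = "d2", gamma = "d1")
  n_ch <- nrow(trial$data)
  bands <- lapply(branch_of, function(b) matrix(0, n_ch, n))
  for (ch in seq_len(n_ch)) {
    x <- trial$data[ch, ]
    if (pad > 0) x <- c(x, x[seq_len(pad)])
    coefs <- dwt_db5(x)
    for (bn in names(branch_of)) {
      bands[[bn]][ch, ] <- reconstruct_branch(coefs, branch_of[[bn]])[seq_len(n)]
    }
  }
  out <- list(bands = bands, fs = trial$fs, labels = trial$labels)
  class(out) <- "subband_set"
  out
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set> %d channels x %d samples, bands: %s\n",
              nrow(x$bands[[1]]), ncol(x$bands[[1]]),
              paste(names(x$bands), collapse = " ")))
  invisible(x)
}
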