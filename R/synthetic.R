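#' Configuration for the synthetic EEG generator
#'
#' Builds the configuration object for [generate_synth_eeg()]. The generator
#' emulates the statistical structure the downstream pipeline assumes: every
#' channel carries a 1/f Gaussian noise floor plus one band-limited
#' oscillation; on the `informative_channels` the oscillation amplitude is
#' multiplied by `effect_size` whenever the trial's latent class on
#' `informative_dimension` is "high". Self-assessment ratings are drawn
#' uniformly from the corresponding side of the rating threshold, so
#' binarizing them recovers the latent classes exactly.
#'
#' @param n_trials number of trials.
#' @param montage_name montage passed to [standard_layout()].
#' @param fs sampling rate in Hz; the pipeline is defined at 128.
#' @param duration_s trial duration in seconds (integer, >= 2).
#' @param informative_channels montage labels whose oscillation is
#'   class-modulated.
#' @param informative_band one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"gamma"`; the oscillation's centre frequency is drawn uniformly inside
#'   this band (capped below the Nyquist frequency).
#' @param effect_size amplitude ratio high/low class on informative
#'   channels (> 0; 1 = null).
#' @param noise_exponent spectral slope of the 1/f noise floor
#'   (power ~ f^-noise_exponent).
#' @param rating_scale numeric `c(min, max, threshold)`; defaults to the
#'   1-9 scale binarized at 4.5.
#' @param class_balance fraction of "high" trials on each affect dimension.
#' @param informative_dimension affect dimension driven by the signal;
#'   the other two get independent latent classes.
#' @param seed integer seed; regeneration is byte-identical per seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_trials = 40,
                         montage_name = "emotiv14",
                         fs = 128,
                         duration_s = 4,
                         informative_channels = c("F3", "F4", "T7"),
                         informative_band = "gamma",
                         effect_size = 4,
                         noise_exponent = 1,
                         rating_scale = c(1, 9, 4.5),
                         class_balance = 0.5,
                         informative_dimension = "valence",
                         seed = 1L) {
  layout <- standard_layout(montage_name)
  unknown <- setdiff(informative_channels, layout$labels)
  if (length(unknown))
    stop("informative channel(s) not in montage: ", paste(unknown, collapse = ", "))
  if (effect_size <= 0) stop("effect_size must be > 0")
  if (duration_s <= 0) stop("duration must be positive")
  n_samp <- duration_s * fs
  if (abs(n_samp - round(n_samp)) > 1e-9 || n_samp < 2 * fs)
    stop("duration_s * fs must be an integer >= 2 * fs")
  if (!(rating_scale[3] > rating_scale[1] && rating_scale[3] < rating_scale[2]))
    stop("rating threshold must lie strictly inside the scale")
  if (!informative_band %in% names(eeg_bands()))
    stop("unknown band: ", informative_band)
  if (!informative_dimension %in% c("valence", "arousal", "dominance"))
    stop("unknown affect dimension: ", informative_dimension)
  cfg <- list(n_trials = as.integer(n_trials), montage_name = montage_name,
              fs = fs, duration_s = duration_s,
              informative_channels = informative_channels,
              informative_band = informative_band,
              effect_size = effect_size, noise_exponent = noise_exponent,
              rating_scale = rating_scale, class_balance = class_balance,
              informative_dimension = informative_dimension,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' The five dyadic EEG frequency bands at 128 Hz
#'
#' @return Named list of `c(low, high)` band edges in Hz: delta 0-4,
#'   theta 4-8, alpha 8-16, beta 16-32, gamma 32-64.
#' @export
eeg_bands <- function() {
  list(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 16),
       beta = c(16, 32), gamma = c(32, 64))
}

#' Generate a labeled synthetic EEG dataset
#'
#' See [synth_config()] for the generative model. Each trial is a
#' channels-by-samples matrix; per-trial ratings on the three affect
#' dimensions (valence, arousal, dominance) sit strictly on the side of the
#' rating threshold given by the trial's latent classes.
#'
#' @param cfg a `synth_config`.
#' @return A `synth_dataset`: list with `trials` (list of `eeg_trial`),
#'   `true_class` (n x 3 character matrix, `"low"`/`"high"`), `config`.
#' @examples
#' ds <- generate_synth_eeg(synth_config(n_trials = 4, duration_s = 2))
#' dim(ds$trials[[1]]$data)  # 14 x 256
#' @export
generate_synth_eeg <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  layout <- standard_layout(cfg$montage_name)
  n_ch <- length(layout$labels)
  n <- cfg$n_trials
  n_samp <- as.integer(round(cfg$duration_s * cfg$fs))
  band <- eeg_bands()[[cfg$informative_band]]
  f_hi <- min(band[2], 0.95 * cfg$fs / 2)
  informative <- layout$labels %in% cfg$informative_channels
  dims <- c("valence", "arousal", "dominance")
  scale <- cfg$rating_scale

  with_seed(cfg$seed, {
    # balanced latent classes per affect dimension
    true_class <- sapply(dims, function(d) {
      n_high <- round(n * cfg$class_balance)
      cls <- c(rep("high", n_high), rep("low", n - n_high))
      sample(cls)
    })
    dimnames(true_class) <- list(NULL, dims)

    drive <- true_class[, cfg$informative_dimension]
    tvec <- (seq_len(n_samp) - 1) / cfg$fs
    trials <- vector("list", n)
    for (i in seq_len(n)) {
      noise <- colored_noise(n_samp, n_ch, cfg$noise_exponent)
      f0 <- stats::runif(1, band[1], f_hi)
      phases <- stats::runif(n_ch, 0, 2 * pi)
      amp <- ifelse(informative & drive[i] == "high", cfg$effect_size, 1)
      osc <- t(sin(outer(tvec, rep(2 * pi * f0, n_ch)) +
                     matrix(phases, n_samp, n_ch, byrow = TRUE))) * amp
      ratings <- sapply(dims, function(d) {
        if (true_class[i, d] == "high") stats::runif(1, scale[3], scale[2])
        else stats::runif(1, scale[1], scale[3])
      })
      trials[[i]] <- eeg_trial(noise + osc, cfg$fs, layout$labels, ratings)
    }
    ds <- list(trials = trials, true_class = true_class, config = cfg)
    class(ds) <- "synth_dataset"
    ds
  })
}

#' Construct a single EEG trial
#'
#' @param data channels x samples numeric matrix (microvolt scale).
#' @param fs sampling rate in Hz.
#' @param labels montage labels, one per row of `data`.
#' @param ratings named numeric vector (valence, arousal, dominance).
#' @return An `eeg_trial` object.
#' @export
eeg_trial <- function(data, fs, labels, ratings) {
  data <- as.matrix(data)
  if (nrow(data) != length(labels))
    stop("label count must equal channel count")
  if (!all(is.finite(data))) stop("trial data must be finite")
  tr <- list(data = data, fs = fs, labels = labels,
             ratings = ratings)
  class(tr) <- "eeg_trial"
  tr
}

#' @export
print.synth_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synth_dataset> %d trials, %s montage, %g s @ %g Hz\n",
    length(x$trials), cfg$montage_name, cfg$duration_s, cfg$fs))
  cat(sprintf("  informative: %s (%s band, effect size %g)\n",
              paste(cfg$informative_channels, collapse = ", "),
              cfg$informative_band, cfg$effect_size))
  invisible(x)
}

# 1/f^alpha Gaussian noise by spectral shaping of white noise, returned as a
# channels x samples matrix with (approximately) unit variance per channel.
colored_noise <- function(n_samp, n_ch, alpha) {
  nf <- n_samp %/% 2
  freqs <- seq_len(nf)                      # bin index is proportional to f
  shape <- freqs^(-alpha / 2)
  out <- matrix(0, n_ch, n_samp)
  for (ch in seq_len(n_ch)) {
    re <- stats::rnorm(nf) * shape
    im <- stats::rnorm(nf) * shape
    spec <- complex(real = re, imaginary = im)
    full <- complex(length.out = n_samp)
    full[2:(nf + 1)] <- spec
    if (n_samp %% 2 == 0) {
      full[nf + 1] <- complex(real = re[nf], imaginary = 0)
      if (nf > 1) full[n_samp:(n_samp - nf + 2)] <- Conj(spec[1:(nf - 1)])
    } else {
      full[n_samp:(n_samp - nf + 1)] <- Conj(spec)
    }
    x <- Re(stats::fft(full, inverse = TRUE)) / n_samp
    out[ch, ] <- x / stats::sd(x)
  }
  out
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}
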