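# Shared fixtures, built once per test run. Small on purpose: 12 trials of
# 2 s keep the unit tests fast; the acceptance tests build their own
# datasets at the benchmark sizes.

fix_cfg <- synth_config(n_trials = 12, duration_s = 2, effect_size = 4,
                        seed = 101)
fix_ds <- generate_synth_eeg(fix_cfg)
fix_ft <- feature_tensor(fix_ds)
fix_layout <- standard_layout("emotiv14")

# one single-channel trial wrapping an arbitrary series, for feature tests
wrap_trial <- function(x, fs = 128) {
  eeg_trial(matrix(x, nrow = 1), fs, "Cz",
            c(valence = 5, arousal = 5, dominance = 5))
}

# labels of a synth dataset on one affect dimension
ds_labels <- function(ds, dimension = "valence") {
  binarize_ratings(
    vapply(ds$trials, function(tr) tr$ratings[[dimension]], numeric(1)),
    ds$config$rating_scale)
}
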