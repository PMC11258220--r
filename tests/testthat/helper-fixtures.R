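# Shared fixtures, all built in code.

# Small, fast generator settings for unit tests: short epochs, few
# channels. Spectral contracts (bin spacing = 1/epoch_duration) hold at
# any epoch length.
small_params <- function(...) {
  args <- modifyList(list(n_channels = 2, n_trials = 8, fs = 100,
                          epoch_duration = 4, n_subjects = 4,
                          noise_scale = 1),
                     list(...))
  do.call(eeg_sim_params, args)
}

# Canonical-geometry params (22-s epochs at 500 Hz) with one channel,
# used where the 1/22-Hz grid matters.
canonical_params <- function(...) {
  eeg_sim_params(n_channels = 1, ...)
}

# A fourier_set built directly from given per-trial phases at one bin.
fset_from_phases <- function(phases, freq = 1) {
  co <- array(complex(modulus = 1, argument = phases),
              dim = c(length(phases), 1, 1))
  structure(list(coeffs = co, freqs = freq, k = length(phases),
                 epoch_duration = 22, channel_labels = "ch01"),
            class = "fourier_set")
}

# Hand-built epochs from a trials x samples matrix (single channel).
epochs_from_matrix <- function(m, fs) {
  eeg_epochs(array(m, dim = c(nrow(m), 1, ncol(m))), fs)
}

# 48 ramped, normalized tokens for stream tests.
make_tokens <- function(seed = 1, n = 48) {
  lapply(seq_len(n), function(i)
    apply_ramp(normalize_token_duration(
      simulate_token(0.3 + 0.4 * ((i * 7919 + seed) %% 100) / 100,
                     seed = seed * 1000 + i), 0.5)))
}

# Frequency grid of the canonical 22-s analysis band.
canonical_freqs <- function() {
  (ceiling(0.3 * 22):floor(5 * 22)) / 22
}
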