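#' Parameters of the synthetic EEG cohort generator
#'
#' Bundles and validates the parameters of the generative model for
#' synthetic frequency-tagged EEG. Each trial is
#' \deqn{x(t) = a_w \sin(2\pi f_w t + \phi_w) + a_p \sin(2\pi f_p (t-\tau) + \phi_p) + \epsilon(t)}
#' where the word-rate (\eqn{f_w}, default 2 Hz) and phrase-rate
#' (\eqn{f_p}, default 1 Hz) components are phase-locked across trials up
#' to von Mises trial phases (mean 0, concentration `phase_concentration`),
#' \eqn{\tau} is a Gaussian trial-wise latency shift applied to the
#' phrase-rate component only in conditions with alternating head position,
#' and \eqn{\epsilon} is \eqn{1/f^\alpha} Gaussian background noise with
#' RMS `noise_scale`. All channels carry the same expected signal scaled by
#' a fixed random topography vector; realistic scalp topographies are not
#' modeled.
#'
#' Condition-dependent amplitudes (`amp_word`, `amp_phrase`) are named
#' vectors over the six design cells; a scalar is recycled. The phrase-rate
#' amplitude is forced to zero in conditions with neither structural nor
#' sequential regularity (`R-R`, `V-V`), which carry no 1-Hz regularity of
#' any kind.
#'
#' @param word_rate,phrase_rate stimulation rates in Hz.
#' @param amp_word,amp_phrase response amplitudes in microvolts, scalar or
#'   named per condition.
#' @param phase_concentration von Mises concentration `kappa` (>= 0) of the
#'   trial phases; `Inf` means perfect phase locking.
#' @param latency_jitter_sd SD (s) of the trial-wise latency shift of the
#'   phrase component in alternating-head conditions.
#' @param noise_exponent exponent `alpha` of the 1/f^alpha background.
#' @param noise_scale RMS amplitude (microvolts) of the background noise.
#' @param n_trials,n_channels,fs,epoch_duration epoch geometry.
#' @param n_subjects,between_subject_sd cohort size and the SD (log scale)
#'   of the lognormal per-subject amplitude multiplier.
#' @param seed integer seed fixing the topography and cohort randomness.
#' @return A validated list of class `eeg_sim_params`.
#' @seealso [simulate_epochs()], [simulate_cohort()]
#' @export
eeg_sim_params <- function(word_rate = 2,
                           phrase_rate = 1,
                           amp_word = 1,
                           amp_phrase = c("V-N" = 1, "V-Adv" = 0.75,
                                          "V-Adv-alt" = 0.55, "N-R" = 0.5,
                                          "R-R" = 0, "V-V" = 0),
                           phase_concentration = 6,
                           latency_jitter_sd = 0.06,
                           noise_exponent = 1,
                           noise_scale = 12,
                           n_trials = 24L,
                           n_channels = 59L,
                           fs = 500,
                           epoch_duration = 22,
                           n_subjects = 20L,
                           between_subject_sd = 0.25,
                           seed = 1L) {
  p <- list(word_rate = word_rate, phrase_rate = phrase_rate,
            amp_word = amp_word, amp_phrase = amp_phrase,
            phase_concentration = phase_concentration,
            latency_jitter_sd = latency_jitter_sd,
            noise_exponent = noise_exponent, noise_scale = noise_scale,
            n_trials = as.integer(n_trials),
            n_channels = as.integer(n_channels),
            fs = fs, epoch_duration = epoch_duration,
            n_subjects = as.integer(n_subjects),
            between_subject_sd = between_subject_sd,
            seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "eeg_sim_params"
  p
}

validate_sim_params <- function(p) {
  bad <- character(0)
  if (any(p$amp_word < 0) || any(p$amp_phrase < 0))
    bad <- c(bad, "amplitudes must be >= 0")
  if (is.na(p$phase_concentration) || p$phase_concentration < 0)
    bad <- c(bad, "phase_concentration (kappa) must be >= 0")
  if (p$latency_jitter_sd < 0) bad <- c(bad, "latency_jitter_sd must be >= 0")
  if (p$noise_scale < 0) bad <- c(bad, "noise_scale must be >= 0")
  if (p$n_trials < 1) bad <- c(bad, "n_trials must be >= 1")
  if (p$n_channels < 1) bad <- c(bad, "n_channels must be >= 1")
  if (p$fs <= 0 || p$epoch_duration <= 0)
    bad <- c(bad, "fs and epoch_duration must be > 0")
  if (abs(p$fs * p$epoch_duration - round(p$fs * p$epoch_duration)) > 1e-9)
    bad <- c(bad, "fs * epoch_duration must be an integer number of samples")
  if (length(bad))
    stop("invalid simulation parameters: ", paste(bad, collapse = "; "),
         call. = FALSE)
  invisible(p)
}

# amplitude for one condition from a scalar or named vector
amp_for <- function(amp, condition) {
  if (length(amp) == 1L && is.null(names(amp))) return(unname(amp))
  if (!condition %in% names(amp))
    stop("no amplitude given for condition '", condition, "'", call. = FALSE)
  unname(amp[[condition]])
}

# von Mises sampler (Best & Fisher 1979 rejection algorithm), mean 0.
rvonmises <- function(n, kappa) {
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(runif(1) - 0.5) * acos(max(-1, min(1, f)))
      i <- i + 1L
    }
  }
  out
}

# 1/f^alpha Gaussian noise, frequency-domain synthesis with random phases.
# Returns an n x m matrix of real series with expected RMS `scale`.
onef_noise <- function(n, m, alpha, scale) {
  if (scale == 0 || m == 0L) return(matrix(0, n, m))
  nh <- (n - 1L) %/% 2L            # strictly positive, non-Nyquist bins
  j <- seq_len(nh)
  w <- j^(-alpha / 2)
  has_nyq <- n %% 2L == 0L
  w_nyq <- if (has_nyq) (n / 2)^(-alpha / 2) else numeric(0)
  # Var(x) = (2*sum(w^2) + w_nyq^2) / n^2 per unit complex variance
  v <- (2 * sum(w^2) + sum(w_nyq^2)) / n^2
  w <- w * scale / sqrt(v)
  w_nyq <- w_nyq * scale / sqrt(v)
  X <- matrix(0 + 0i, n, m)
  Z <- matrix(complex(real = rnorm(nh * m, sd = sqrt(0.5)),
                      imaginary = rnorm(nh * m, sd = sqrt(0.5))), nh, m)
  X[j + 1L, ] <- Z * w
  X[n + 1L - j, ] <- Conj(X[j + 1L, ])
  if (has_nyq) X[n / 2 + 1L, ] <- rnorm(m) * w_nyq
  Re(mvfft(X, inverse = TRUE)) / n
}

# Fixed channel topography derived from the generator master seed: a
# positive gain per channel, shared by every subject and condition.
sim_topography <- function(params) {
  with_seed(params$seed, exp(rnorm(params$n_channels, 0, 0.25)))
}

#' Simulate one subject-condition set of EEG epochs
#'
#' Generates a `trials x channels x samples` array of synthetic EEG for a
#' single subject and condition under the generative model documented in
#' [eeg_sim_params()]. Determinism contract: the same `subject_seed` (with
#' the same parameters) yields a bit-identical result.
#'
#' @param params an [eeg_sim_params()] object.
#' @param condition one row of [condition_designs()] (or a condition name).
#' @param subject_seed integer seed for this subject-condition draw.
#' @param amp_scale extra amplitude multiplier (used for between-subject
#'   variability by [simulate_cohort()]).
#' @return An object of class `eeg_epochs`: list with `data`
#'   (trials x channels x samples, microvolts), `fs`, `epoch_duration`,
#'   `condition`, `subject_id`, `channel_labels`.
#' @export
simulate_epochs <- function(params, condition, subject_seed = 1L,
                            amp_scale = 1) {
  validate_sim_params(params)
  if (is.character(condition)) {
    d <- condition_designs()
    if (!condition %in% d$name)
      stop("unknown condition '", condition, "'", call. = FALSE)
    condition <- d[d$name == condition, ]
  }
  n <- as.integer(round(params$fs * params$epoch_duration))
  tt <- (seq_len(n) - 1L) / params$fs
  aw <- amp_for(params$amp_word, condition$name) * amp_scale
  ap <- amp_for(params$amp_phrase, condition$name) * amp_scale
  if (!condition$structural && !condition$sequential) ap <- 0
  gain <- sim_topography(params)
  ntr <- params$n_trials; nch <- params$n_channels
  with_seed(subject_seed, {
    phi_w <- rvonmises(ntr, params$phase_concentration)
    phi_p <- rvonmises(ntr, params$phase_concentration)
    tau <- if (identical(condition$head_pattern, "alternating"))
      rnorm(ntr, 0, params$latency_jitter_sd) else numeric(ntr)
    # trials x samples signal matrix, fully vectorized
    wt <- outer(phi_w, 2 * pi * params$word_rate * tt, "+")
    pt_ <- 2 * pi * params$phrase_rate * outer(-tau, tt, "+") + phi_p
    sig <- aw * sin(wt) + ap * sin(pt_)
    noise <- onef_noise(n, ntr * nch, params$noise_exponent,
                        params$noise_scale)
    # noise columns are grouped per trial (channel fastest)
    x <- aperm(array(noise, dim = c(n, nch, ntr)), c(3, 2, 1)) +
      aperm(outer(sig, gain), c(1, 3, 2))
    eeg_epochs(x, fs = params$fs, condition = condition$name,
               subject_id = NA_character_,
               channel_labels = sprintf("ch%02d", seq_len(nch)))
  })
}

#' Simulate a multi-subject cohort across all six conditions
#'
#' Draws one lognormal amplitude multiplier per subject (SD
#' `between_subject_sd` on the log scale) and applies it to all of that
#' subject's conditions, then simulates every subject x condition epoch
#' set with [simulate_epochs()]. With default geometry (59 channels, 22-s
#' epochs) a full in-memory cohort is large; for simulation studies use a
#' reduced `n_channels`, or stream subjects via [run_pipeline()].
#'
#' @param params an [eeg_sim_params()] object (`n_subjects >= 2`).
#' @param conditions subset of [condition_designs()] rows to generate.
#' @return An object of class `eeg_cohort`: list with `epochs` (nested
#'   list, `epochs[[subject]][[condition]]` of `eeg_epochs`),
#'   `subject_ids`, `multipliers`, `params`.
#' @export
simulate_cohort <- function(params, conditions = condition_designs()) {
  validate_sim_params(params)
  if (params$n_subjects < 2L)
    stop("n_subjects must be >= 2 (within-subject inference needs pairing)",
         call. = FALSE)
  ns <- params$n_subjects
  ncond <- nrow(conditions)
  with_seed(params$seed, {
    mult <- exp(rnorm(ns, 0, params$between_subject_sd))
    seeds <- matrix(sample.int(.Machine$integer.max - 1L, ns * ncond),
                    ns, ncond)
  })
  ids <- sprintf("S%02d", seq_len(ns))
  epochs <- vector("list", ns)
  names(epochs) <- ids
  for (s in seq_len(ns)) {
    epochs[[s]] <- vector("list", ncond)
    names(epochs[[s]]) <- conditions$name
    for (ci in seq_len(ncond)) {
      e <- simulate_epochs(params, conditions[ci, ], seeds[s, ci],
                           amp_scale = mult[s])
      e$subject_id <- ids[s]
      epochs[[s]][[ci]] <- e
    }
  }
  structure(list(epochs = epochs, subject_ids = ids, multipliers = mult,
                 params = params),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat("<eeg_cohort> ", length(x$subject_ids), " subjects x ",
      length(x$epochs[[1]]), " conditions\n", sep = "")
  e <- x$epochs[[1]][[1]]
  cat("  epochs: ", dim(e$data)[1], " trials x ", dim(e$data)[2],
      " channels x ", dim(e$data)[3], " samples @ ", e$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Simulate a synthetic audio token
#'
#' A band-limited harmonic burst with a syllable-like attack-decay
#' amplitude contour plus a low-level noise floor, standing in for a
#' synthesized monosyllabic word. Audio rate 24,000 samples/s by default.
#'
#' @param duration token duration in seconds, in \[0.1, 1\].
#' @param seed integer seed; identical seeds give identical waveforms.
#' @param fs_audio audio sampling rate (samples/s).
#' @return A `token_wave` object (see [token_wave()]).
#' @export
simulate_token <- function(duration, seed = 1L, fs_audio = 24000) {
  if (!is.numeric(duration) || duration < 0.1 || duration > 1.0)
    stop("duration must be in [0.1, 1] seconds", call. = FALSE)
  n <- round(duration * fs_audio)
  with_seed(seed, {
    t <- (seq_len(n) - 1L) / fs_audio
    f0 <- runif(1, 110, 220)
    nh <- 8L
    x <- numeric(n)
    for (h in seq_len(nh)) {
      if (h * f0 > fs_audio / 2 * 0.8) break
      x <- x + (1 / h) * sin(2 * pi * h * f0 * t + runif(1, 0, 2 * pi))
    }
    # attack-decay contour peaking in the first third of the token
    tp <- duration * runif(1, 0.2, 0.4)
    env <- (t / tp) * exp(1 - t / tp)
    x <- x * env + rnorm(n, sd = 0.01)
    token_wave(x / max(abs(x)), fs_audio)
  })
}

#' Simulate a bigram corpus and its pair-count table
#'
#' Generates a word chain from a Zipfian unigram distribution coupled with
#' a Markov bigram process, and tabulates adjacent word-pair counts. With
#' `zipf_s = 0` and `markov_conc = Inf` the process is i.i.d. uniform, so
#' every transitional probability converges to `1/vocab_size`.
#'
#' @param vocab_size number of word types (>= 2).
#' @param n_tokens chain length (>= vocab_size); yields `n_tokens - 1`
#'   bigram tokens.
#' @param seed integer seed.
#' @param zipf_s Zipf exponent of the unigram distribution (0 = uniform).
#' @param markov_conc Dirichlet concentration of the per-word transition
#'   rows around the unigram distribution; `Inf` makes transitions exactly
#'   the unigram distribution (no sequential dependence).
#' @return A `bigram_table` object: `pair_counts` (vocab x vocab matrix of
#'   counts, rows = first word), `words`, `n_tokens`.
#' @seealso [bigram_tp()]
#' @export
simulate_bigram_corpus <- function(vocab_size, n_tokens, seed = 1L,
                                   zipf_s = 1, markov_conc = 50) {
  vocab_size <- as.integer(vocab_size)
  n_tokens <- as.integer(n_tokens)
  if (vocab_size < 2L) stop("vocab_size must be >= 2", call. = FALSE)
  if (n_tokens < vocab_size)
    stop("n_tokens must be >= vocab_size", call. = FALSE)
  with_seed(seed, {
    pu <- seq_len(vocab_size)^(-zipf_s)
    pu <- pu / sum(pu)
    if (is.finite(markov_conc)) {
      # row i = transition distribution out of word i, Dirichlet around pu
      g <- matrix(rgamma(vocab_size^2,
                         shape = markov_conc * rep(pu, times = vocab_size)),
                  vocab_size, vocab_size, byrow = TRUE)
      Tm <- g / rowSums(g)
    } else {
      Tm <- matrix(pu, vocab_size, vocab_size, byrow = TRUE)
    }
    chain <- integer(n_tokens)
    chain[1L] <- sample.int(vocab_size, 1L, prob = pu)
    if (is.finite(markov_conc)) {
      for (i in 2:n_tokens)
        chain[i] <- sample.int(vocab_size, 1L, prob = Tm[chain[i - 1L], ])
    } else {
      chain[2:n_tokens] <- sample.int(vocab_size, n_tokens - 1L,
                                      replace = TRUE, prob = pu)
    }
    words <- sprintf("w%03d", seq_len(vocab_size))
    counts <- matrix(0L, vocab_size, vocab_size,
                     dimnames = list(words, words))
    idx <- cbind(chain[-n_tokens], chain[-1L])
    tab <- table(factor(idx[, 1], levels = seq_len(vocab_size)),
                 factor(idx[, 2], levels = seq_len(vocab_size)))
    counts[] <- as.integer(tab)
    structure(list(pair_counts = counts, words = words, n_tokens = n_tokens),
              class = "bigram_table")
  })
}

#' @export
print.bigram_table <- function(x, ...) {
  cat("<bigram_table> ", length(x$words), " word types, ",
      sum(x$pair_counts), " bigram tokens\n", sep = "")
  invisible(x)
}
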