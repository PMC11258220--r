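#' Audio token waveform
#'
#' Lightweight container for a mono audio token.
#'
#' @param samples numeric amplitude vector.
#' @param fs_audio sampling rate in samples/s.
#' @return An object of class `token_wave` with fields `samples`,
#'   `fs_audio` and `duration = length(samples)/fs_audio`.
#' @export
token_wave <- function(samples, fs_audio) {
  stopifnot(is.numeric(samples), fs_audio > 0)
  structure(list(samples = as.numeric(samples), fs_audio = fs_audio,
                 duration = length(samples) / fs_audio),
            class = "token_wave")
}

#' @export
print.token_wave <- function(x, ...) {
  cat("<token_wave> ", length(x$samples), " samples @ ", x$fs_audio,
      " Hz (", signif(x$duration, 4), " s)\n", sep = "")
  invisible(x)
}

#' Normalize a token to an exact duration
#'
#' Shorter tokens are zero-padded symmetrically at both edges (an odd
#' remainder puts the extra sample at the end); longer tokens are
#' truncated symmetrically by the same convention.
#'
#' @param tok a [token_wave()].
#' @param target target duration in seconds (> 0).
#' @return A `token_wave` of exactly `round(target * fs_audio)` samples.
#' @export
normalize_token_duration <- function(tok, target = 0.5) {
  stopifnot(inherits(tok, "token_wave"))
  if (target <= 0) stop("target duration must be > 0", call. = FALSE)
  if (length(tok$samples) == 0L)
    stop("cannot normalize an empty token", call. = FALSE)
  n <- length(tok$samples)
  nt <- round(target * tok$fs_audio)
  if (n == nt) return(tok)
  if (n < nt) {
    pad <- nt - n
    left <- pad %/% 2L
    out <- c(numeric(left), tok$samples, numeric(pad - left))
  } else {
    cut <- n - nt
    left <- cut %/% 2L
    out <- tok$samples[(left + 1L):(left + nt)]
  }
  token_wave(out, tok$fs_audio)
}

#' Apply an onset/offset ramp to a token
#'
#' Multiplies the first and last `fraction` of the samples by a ramp
#' rising from 0 to 1 (mirrored at offset); the middle is untouched.
#' `window = "sine"` uses a quarter-sine ramp \eqn{\sin(\pi t / 2 T_r)};
#' `"hann"` uses a raised-cosine alternative.
#'
#' @param tok a [token_wave()].
#' @param fraction ramped fraction of the token at each edge, in (0, 0.5).
#' @param window `"sine"` (default) or `"hann"`.
#' @return The ramped `token_wave`.
#' @export
apply_ramp <- function(tok, fraction = 0.1, window = c("sine", "hann")) {
  stopifnot(inherits(tok, "token_wave"))
  window <- match.arg(window)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 0.5)
    stop("fraction must be in (0, 0.5)", call. = FALSE)
  n <- length(tok$samples)
  nr <- round(n * fraction)
  if (nr < 2L) return(tok)
  u <- (seq_len(nr) - 1) / (nr - 1)        # 0 .. 1
  w <- switch(window,
              sine = sin(pi * u / 2),
              hann = 0.5 * (1 - cos(pi * u)))
  x <- tok$samples
  x[seq_len(nr)] <- x[seq_len(nr)] * w
  x[n - seq_len(nr) + 1L] <- x[n - seq_len(nr) + 1L] * w
  token_wave(x, tok$fs_audio)
}

#' Concatenate normalized tokens into an isochronous stream
#'
#' Builds a stimulus stream from exactly `n_tokens` tokens of exactly
#' `token_duration` seconds each, all at the same audio rate. With the
#' defaults this yields the canonical 24-s stream of 48 words with onsets
#' at 0.0, 0.5, ..., 23.5 s.
#'
#' @param tokens list of [token_wave()] objects.
#' @param condition condition label attached to the stream.
#' @param n_tokens required token count.
#' @param token_duration required duration of every token (s).
#' @return An object of class `stimulus_stream` with fields `samples`,
#'   `fs_audio`, `token_onsets` (s), `condition`, `duration`.
#' @export
concatenate_stream <- function(tokens, condition = NA_character_,
                               n_tokens = 48L, token_duration = 0.5) {
  if (!is.list(tokens) || length(tokens) != n_tokens)
    stop("expected exactly ", n_tokens, " tokens, got ", length(tokens),
         call. = FALSE)
  fs <- unique(vapply(tokens, function(t) t$fs_audio, numeric(1)))
  if (length(fs) != 1L)
    stop("all tokens must share the same audio rate", call. = FALSE)
  nper <- round(token_duration * fs)
  lens <- vapply(tokens, function(t) length(t$samples), integer(1))
  if (any(lens != nper))
    stop("all tokens must be exactly ", token_duration,
         " s; normalize first", call. = FALSE)
  samples <- unlist(lapply(tokens, `[[`, "samples"), use.names = FALSE)
  structure(list(samples = samples, fs_audio = fs,
                 token_onsets = token_duration * (seq_len(n_tokens) - 1),
                 condition = condition,
                 duration = n_tokens * token_duration),
            class = "stimulus_stream")
}

#' @export
print.stimulus_stream <- function(x, ...) {
  cat("<stimulus_stream> ", x$duration, " s, ", length(x$token_onsets),
      " tokens @ ", x$fs_audio, " Hz", sep = "")
  if (!is.na(x$condition)) cat(" [", x$condition, "]", sep = "")
  cat("\n")
  invisible(x)
}

# Analytic signal via the FFT (zero negative frequencies, double positive).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Envelope power spectrum of a stimulus stream
#'
#' The acoustic control of the paradigm: verifies where the acoustic
#' energy of a stream is modulated. Pipeline (order fixed): half-wave
#' rectify the waveform, take the analytic-signal magnitude (Hilbert
#' envelope), anti-alias low-pass and resample to `env_fs` samples/s, then
#' take the DFT amplitude spectrum. The DC bin is reported but should be
#' excluded from peak searches (see [env_peak_freq()]). For an isochronous
#' stream of 500-ms tokens the unique non-DC peak sits at the 2-Hz word
#' rate; no peak arises at the 1-Hz phrase rate.
#'
#' @param stream a [concatenate_stream()] result (duration >= 2 s).
#' @param env_fs envelope sampling rate after downsampling (samples/s).
#' @return An object of class `envelope_spectrum` with fields `freqs`
#'   (Hz, spacing `1/duration`), `power` (amplitude per bin), `env_fs`.
#' @export
envelope_spectrum <- function(stream, env_fs = 200) {
  stopifnot(inherits(stream, "stimulus_stream"))
  if (stream$duration < 2)
    stop("stream must be at least 2 s long", call. = FALSE)
  if (all(stream$samples == 0))
    stop("cannot compute the envelope spectrum of a silent stream",
         call. = FALSE)
  rect <- pmax(stream$samples, 0)
  env <- Mod(analytic_signal(rect))
  env_ds <- resample_env(env, stream$fs_audio, env_fs)
  n <- round(stream$duration * env_fs)
  if (length(env_ds) > n) env_ds <- env_ds[seq_len(n)]
  if (length(env_ds) < n) env_ds <- c(env_ds, rep(env_ds[length(env_ds)],
                                                  n - length(env_ds)))
  amp <- Mod(fft(env_ds)) / n
  nb <- n %/% 2L + 1L
  structure(list(freqs = (seq_len(nb) - 1) / stream$duration,
                 power = amp[seq_len(nb)],
                 env_fs = env_fs),
            class = "envelope_spectrum")
}

# Polyphase anti-aliased resampling, staged for large integer factors.
resample_env <- function(x, fs_from, fs_to) {
  if (fs_from == fs_to) return(x)
  ratio <- fs_from / fs_to
  if (abs(ratio - round(ratio)) < 1e-9) {
    q <- as.integer(round(ratio))
    # decimate in stages of at most 10 (FIR anti-alias each stage)
    while (q > 1L) {
      step <- if (q > 10L) {
        divs <- (2:10)[q %% 2:10 == 0L]
        if (length(divs)) max(divs) else q
      } else q
      x <- signal::decimate(x, step, ftype = "fir")
      q <- q %/% step
    }
    x
  } else {
    g <- gcd_int(round(fs_to), round(fs_from))
    signal::resample(x, round(fs_to) / g, round(fs_from) / g)
  }
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Frequency of the maximal non-DC envelope bin
#'
#' @param es an [envelope_spectrum()].
#' @return The frequency (Hz) of the largest non-DC amplitude bin.
#' @export
env_peak_freq <- function(es) {
  stopifnot(inherits(es, "envelope_spectrum"))
  es$freqs[-1L][which.max(es$power[-1L])]
}

#' @export
print.envelope_spectrum <- function(x, ...) {
  cat("<envelope_spectrum> ", length(x$freqs), " bins, spacing ",
      signif(x$freqs[2], 4), " Hz; peak (non-DC) at ",
      signif(env_peak_freq(x), 4), " Hz\n", sep = "")
  invisible(x)
}

#' @export
plot.envelope_spectrum <- function(x, fmax = 5, ...) {
  sel <- x$freqs > 0 & x$freqs <= fmax
  graphics::plot(x$freqs[sel], x$power[sel], type = "h",
                 xlab = "Frequency (Hz)", ylab = "Envelope amplitude", ...)
  invisible(x)
}
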