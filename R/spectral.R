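#' Whole-epoch discrete Fourier transform
#'
#' Transforms each trial and channel with a plain DFT — no zero-padding
#' and no taper — so the frequency resolution is exactly
#' `1/epoch_duration` (1/22 Hz for canonical 22-s epochs, placing 1 Hz
#' and 2 Hz exactly on bins 22 and 44). Coefficients are the raw DFT sums
#' \eqn{X_j = \sum_n x_n e^{-2\pi i j n / N}}.
#'
#' @param epochs an [eeg_epochs()].
#' @param fmin,fmax analysis band in Hz (defaults 0.3-5); bins at
#'   `j/epoch_duration` with `fmin <= j/T <= fmax` are retained.
#' @return An object of class `fourier_set`: `coeffs` (complex,
#'   trials x channels x bins), `freqs`, `k` (trial count),
#'   `epoch_duration`, `channel_labels`.
#' @export
fourier_transform <- function(epochs, fmin = 0.3, fmax = 5) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (fmin >= fmax) stop("fmin must be < fmax", call. = FALSE)
  d <- dim(epochs$data)
  n <- d[3]
  dur <- epochs$epoch_duration
  jmin <- max(1L, as.integer(ceiling(fmin * dur - 1e-9)))
  jmax <- as.integer(floor(fmax * dur + 1e-9))
  if (jmax > n %/% 2L)
    stop("fmax exceeds the Nyquist frequency", call. = FALSE)
  if (jmin > jmax)
    stop("epoch too short: no DFT bin falls inside [fmin, fmax]",
         call. = FALSE)
  # one FFT pass over all trial-channel series
  m <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = n)
  X <- mvfft(m)[jmin:jmax + 1L, , drop = FALSE]
  coeffs <- aperm(array(t(X), dim = c(d[2], d[1], jmax - jmin + 1L)),
                  c(2, 1, 3))
  structure(list(coeffs = coeffs, freqs = (jmin:jmax) / dur, k = d[1],
                 epoch_duration = dur,
                 channel_labels = epochs$channel_labels),
            class = "fourier_set")
}

#' @export
print.fourier_set <- function(x, ...) {
  cat("<fourier_set> ", x$k, " trials x ", dim(x$coeffs)[2],
      " channels x ", length(x$freqs), " bins (",
      signif(min(x$freqs), 4), "-", signif(max(x$freqs), 4),
      " Hz, spacing ", signif(1 / x$epoch_duration, 6), " Hz)\n", sep = "")
  invisible(x)
}

#' Evoked power spectrum
#'
#' Averages the trials in the time domain first (suppressing activity
#' that is not phase-locked to the stimulus) and then Fourier-transforms
#' the average; power is the squared magnitude of the averaged signal's
#' coefficients, scaled by `1/N^2` so a unit sinusoid on a bin yields
#' power 0.25.
#'
#' @param epochs an [eeg_epochs()] with at least one trial.
#' @param fmin,fmax analysis band in Hz.
#' @return An object of class `power_spectrum`: `values`
#'   (channels x bins, microvolts squared), `freqs`, `n_trials_averaged`,
#'   `channel_labels`.
#' @export
evoked_power <- function(epochs, fmin = 0.3, fmax = 5) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (d[1] < 1L) stop("empty epoch set", call. = FALSE)
  avg <- apply(epochs$data, c(2, 3), mean)           # channels x samples
  if (is.null(dim(avg))) avg <- matrix(avg, nrow = 1L)
  avg_ep <- eeg_epochs(array(avg, dim = c(1L, d[2], d[3])), epochs$fs,
                       channel_labels = epochs$channel_labels)
  fs <- fourier_transform(avg_ep, fmin, fmax)
  vals <- (Mod(fs$coeffs[1, , , drop = FALSE][1, , , drop = TRUE]) /
             d[3])^2
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = d[2])
  structure(list(values = vals, freqs = fs$freqs,
                 n_trials_averaged = d[1],
                 channel_labels = epochs$channel_labels),
            class = "power_spectrum")
}

#' Inter-trial phase coherence
#'
#' Phase consistency across trials at each channel and frequency bin,
#' from the phase angles \eqn{\theta_k} of the per-trial Fourier
#' coefficients (magnitudes discarded). Two conventions are kept:
#' \describe{
#'   \item{`printed_formula`}{\eqn{R(f) = \frac{1}{k}[(\sum_k \cos\theta_k)^2
#'     + (\sum_k \sin\theta_k)^2]}, ranging over \[0, k\];}
#'   \item{`normalized`}{the mean resultant length
#'     \eqn{\frac{1}{k}|\sum_k e^{i\theta_k}|}, ranging over \[0, 1\].}
#' }
#' The two satisfy `printed = k * normalized^2` at every bin. The
#' `normalized` convention is the pipeline default; its chance level for
#' uniform phases is approximately \eqn{\sqrt{\pi/(4k)}}.
#'
#' Bins with a zero-magnitude coefficient have an undefined phase; the
#' phase is taken as 0 and the occurrences are counted in the
#' `n_zero_phase` field with a warning.
#'
#' @param fset a [fourier_transform()] result.
#' @param convention `"normalized"` (default) or `"printed_formula"`.
#' @return An object of class `itpc_spectrum`: `values`
#'   (channels x bins), `freqs`, `k`, `convention`, `n_zero_phase`,
#'   `channel_labels`.
#' @export
itpc <- function(fset, convention = c("normalized", "printed_formula")) {
  stopifnot(inherits(fset, "fourier_set"))
  convention <- match.arg(convention)
  nz <- sum(Mod(fset$coeffs) == 0)
  if (nz > 0)
    warning(nz, " zero-magnitude coefficient(s): phase undefined, ",
            "treated as 0", call. = FALSE)
  th <- Arg(fset$coeffs)                       # Arg(0+0i) is 0
  C <- apply(cos(th), c(2, 3), sum)
  S <- apply(sin(th), c(2, 3), sum)
  if (is.null(dim(C))) { C <- matrix(C, nrow = 1L); S <- matrix(S, nrow = 1L) }
  R2 <- C^2 + S^2
  vals <- switch(convention,
                 printed_formula = R2 / fset$k,
                 normalized = sqrt(R2) / fset$k)
  structure(list(values = vals, freqs = fset$freqs, k = fset$k,
                 convention = convention, n_zero_phase = nz,
                 channel_labels = fset$channel_labels),
            class = "itpc_spectrum")
}

#' @export
print.itpc_spectrum <- function(x, ...) {
  cat("<itpc_spectrum> ", nrow(x$values), " channels x ",
      length(x$freqs), " bins, k = ", x$k, " trials, convention = ",
      x$convention, "\n", sep = "")
  invisible(x)
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat("<power_spectrum> ", nrow(x$values), " channels x ",
      length(x$freqs), " bins (evoked, ", x$n_trials_averaged,
      " trials averaged)\n", sep = "")
  invisible(x)
}

#' Reduce a spectrum over a channel region of interest
#'
#' Unweighted mean of the selected channels at every bin. Applies to both
#' [evoked_power()] and [itpc()] spectra.
#'
#' @param spec a `power_spectrum` or `itpc_spectrum`.
#' @param roi `"all"` or a character vector of channel labels.
#' @return The same class of spectrum with a single pseudo-channel
#'   `"ROI"`.
#' @export
channel_reduce <- function(spec, roi = "all") {
  stopifnot(inherits(spec, c("power_spectrum", "itpc_spectrum")))
  if (identical(roi, "all")) {
    idx <- seq_len(nrow(spec$values))
  } else {
    if (length(roi) == 0L) stop("roi must be non-empty", call. = FALSE)
    miss <- setdiff(roi, spec$channel_labels)
    if (length(miss))
      stop("unknown channel label(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    idx <- match(roi, spec$channel_labels)
  }
  spec$values <- matrix(colMeans(spec$values[idx, , drop = FALSE]),
                        nrow = 1L)
  spec$channel_labels <- "ROI"
  spec
}

#' @export
plot.itpc_spectrum <- function(x, channel = 1, ...) {
  graphics::plot(x$freqs, x$values[channel, ], type = "l",
                 xlab = "Frequency (Hz)",
                 ylab = paste0("ITPC (", x$convention, ")"), ...)
  graphics::abline(v = c(1, 2), lty = 3, col = "grey60")
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, channel = 1, ...) {
  graphics::plot(x$freqs, x$values[channel, ], type = "l",
                 xlab = "Frequency (Hz)",
                 ylab = expression(paste("Evoked power (", mu, V^2, ")")),
                 ...)
  graphics::abline(v = c(1, 2), lty = 3, col = "grey60")
  invisible(x)
}
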