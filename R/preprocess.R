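#' EEG epoch set
#'
#' The unit fed to spectral estimation: all trials of one condition for
#' one subject, as a `trials x channels x samples` array in microvolts.
#'
#' @param data 3-d numeric array, trials x channels x samples.
#' @param fs sampling rate (samples/s).
#' @param condition,subject_id labels.
#' @param channel_labels character vector, one per channel.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, condition = NA_character_,
                       subject_id = NA_character_, channel_labels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, fs > 0)
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%02d", seq_len(dim(data)[2]))
  if (length(channel_labels) != dim(data)[2])
    stop("channel_labels length must match the channel dimension",
         call. = FALSE)
  if (anyNA(data)) stop("epoch data must not contain NAs", call. = FALSE)
  structure(list(data = data, fs = fs,
                 epoch_duration = dim(data)[3] / fs,
                 condition = condition, subject_id = subject_id,
                 channel_labels = channel_labels),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$fs, " Hz (", signif(x$epoch_duration, 4), " s)",
      sep = "")
  if (!is.na(x$condition)) cat("  [", x$condition, "]", sep = "")
  if (!is.na(x$subject_id)) cat("  subject ", x$subject_id, sep = "")
  cat("\n")
  invisible(x)
}

#' Continuous EEG recording
#'
#' @param data channels x samples matrix (microvolts).
#' @param fs sampling rate (samples/s).
#' @param channel_labels one label per channel.
#' @param trial_onsets trial onset times in seconds.
#' @param reference_labels labels of the two mastoid reference channels.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs, channel_labels,
                          trial_onsets = numeric(0),
                          reference_labels = c("LM", "RM")) {
  stopifnot(is.matrix(data), fs > 0,
            length(channel_labels) == nrow(data))
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 trial_onsets = trial_onsets,
                 reference_labels = reference_labels),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("<raw_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz; ", length(x$trial_onsets),
      " trial onsets\n", sep = "")
  invisible(x)
}

#' Cut a continuous recording into trial epochs
#'
#' Each epoch spans `[onset + start_offset, onset + end_offset)`. The
#' canonical window (2, 24) s skips the first two phrases of each stream
#' (transient auditory onset responses) and keeps 22 s. Trials whose
#' window exceeds the recording are dropped with a warning.
#'
#' @param rec a [raw_recording()] with `trial_onsets`.
#' @param start_offset,end_offset epoch window relative to onset (s).
#' @param condition,subject_id labels forwarded to the result.
#' @return An [eeg_epochs()] object.
#' @export
epoch_trials <- function(rec, start_offset = 2, end_offset = 24,
                         condition = NA_character_,
                         subject_id = NA_character_) {
  stopifnot(inherits(rec, "raw_recording"))
  if (start_offset >= end_offset)
    stop("start_offset must be < end_offset", call. = FALSE)
  if (length(rec$trial_onsets) == 0L)
    stop("recording has no trial onsets", call. = FALSE)
  n <- round((end_offset - start_offset) * rec$fs)
  i0 <- round((rec$trial_onsets + start_offset) * rec$fs) + 1L
  ok <- i0 >= 1L & (i0 + n - 1L) <= ncol(rec$data)
  if (any(!ok))
    warning(sum(!ok), " trial(s) dropped: epoch window outside recording",
            call. = FALSE)
  if (!any(ok)) stop("no trial fits inside the recording", call. = FALSE)
  i0 <- i0[ok]
  x <- array(0, dim = c(length(i0), nrow(rec$data), n))
  for (k in seq_along(i0))
    x[k, , ] <- rec$data[, i0[k]:(i0[k] + n - 1L)]
  eeg_epochs(x, rec$fs, condition = condition, subject_id = subject_id,
             channel_labels = rec$channel_labels)
}

#' Re-reference to the average of two mastoid channels
#'
#' Subtracts the sample-wise mean of the two reference channels from every
#' channel. Generic over epochs and continuous recordings (the operation
#' is linear, so it commutes with epoching).
#'
#' @param x an [eeg_epochs()] or [raw_recording()].
#' @param ref_labels labels of the two reference channels.
#' @return The re-referenced object, same class as `x`.
#' @export
rereference <- function(x, ref_labels = c("LM", "RM")) {
  UseMethod("rereference")
}

check_refs <- function(labels, ref_labels) {
  miss <- setdiff(ref_labels, labels)
  if (length(miss))
    stop("reference channel(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  match(ref_labels, labels)
}

#' @export
rereference.eeg_epochs <- function(x, ref_labels = c("LM", "RM")) {
  ri <- check_refs(x$channel_labels, ref_labels)
  for (k in seq_len(dim(x$data)[1])) {
    ref <- colMeans(x$data[k, ri, , drop = FALSE][1, , ])
    x$data[k, , ] <- sweep(x$data[k, , , drop = FALSE][1, , , drop = TRUE],
                           2, ref, "-")
  }
  x
}

#' @export
rereference.raw_recording <- function(x, ref_labels = c("LM", "RM")) {
  ri <- check_refs(x$channel_labels, ref_labels)
  ref <- colMeans(x$data[ri, , drop = FALSE])
  x$data <- sweep(x$data, 2, ref, "-")
  x
}

#' Zero-phase bandpass filter
#'
#' Applies a zero-phase (forward-backward) Butterworth cascade: a 3rd-order
#' high-pass at `low` and a 4th-order low-pass at `high`. The realization
#' meets the pipeline contract: a sinusoid within `[2*low, high/2]` retains
#' at least 95% of its amplitude with no group delay; a sinusoid at
#' `2*high` is attenuated by at least 90%; DC is removed.
#'
#' @param epochs an [eeg_epochs()].
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @return The filtered `eeg_epochs`.
#' @export
bandpass <- function(epochs, low = 0.3, high = 25) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!(low > 0 && low < high && high < epochs$fs / 2))
    stop("need 0 < low < high < fs/2", call. = FALSE)
  nyq <- epochs$fs / 2
  hp <- signal::butter(3, low / nyq, type = "high")
  lp <- signal::butter(4, high / nyq, type = "low")
  d <- dim(epochs$data)
  for (k in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      y <- signal::filtfilt(hp, epochs$data[k, c, ])
      epochs$data[k, c, ] <- signal::filtfilt(lp, y)
    }
  }
  epochs
}

#' Interpolate bad channels from weighted neighbors
#'
#' Replaces each bad channel by the weight-normalized average of its good
#' neighbors, per trial and sample. Good channels are untouched. The
#' neighbor map is montage-specific and supplied by the caller.
#'
#' @param epochs an [eeg_epochs()].
#' @param bad character vector of bad channel labels.
#' @param neighbor_map named list: for each channel label, a named numeric
#'   vector of neighbor weights (names = neighbor labels).
#' @return The repaired `eeg_epochs`.
#' @export
interpolate_channels <- function(epochs, bad, neighbor_map) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (length(bad) == 0L) return(epochs)
  miss <- setdiff(bad, epochs$channel_labels)
  if (length(miss))
    stop("unknown bad channel(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  good <- setdiff(epochs$channel_labels, bad)
  for (b in bad) {
    nb <- neighbor_map[[b]]
    if (is.null(nb))
      stop("no neighbor entry for channel ", b, call. = FALSE)
    nb <- nb[names(nb) %in% good]
    if (length(nb) == 0L)
      stop("bad channel ", b, " has no good neighbors", call. = FALSE)
    w <- nb / sum(nb)
    bi <- match(b, epochs$channel_labels)
    ni <- match(names(nb), epochs$channel_labels)
    for (k in seq_len(dim(epochs$data)[1])) {
      seg <- epochs$data[k, ni, , drop = FALSE][1, , , drop = TRUE]
      if (is.null(dim(seg))) seg <- matrix(seg, nrow = 1L)
      epochs$data[k, bi, ] <- colSums(seg * w)
    }
  }
  epochs
}

#' Ocular artifact removal hook
#'
#' Placeholder for ICA-based removal of eye blinks and movements, which is
#' outside the scope of this package. Returns its input unchanged; the
#' synthetic generator produces no ocular artifacts.
#'
#' @param epochs an [eeg_epochs()].
#' @param method only `"none"` is implemented.
#' @return `epochs`, unchanged.
#' @export
remove_ocular_artifacts <- function(epochs, method = "none") {
  if (!identical(method, "none"))
    stop("only method = 'none' is implemented; ICA is out of scope",
         call. = FALSE)
  epochs
}

#' Subject-level quality control
#'
#' Excludes subjects on two grounds: (i) more than
#' `max_rejected_fraction` of their trials were rejected during artifact
#' screening, and (ii) optionally, absence of reliable word-rate (2-Hz)
#' tracking, assessed by a permutation peak test on the subject's
#' channel-averaged ITPC pooled over conditions (one observation per
#' condition). Word-rate tracking is treated as a prerequisite for
#' phrase-rate tracking.
#'
#' @param cohort an `eeg_cohort` from [simulate_cohort()] (or any nested
#'   `epochs[[subject]][[condition]]` list of [eeg_epochs()]).
#' @param rejected_fraction named numeric vector (per subject id) of the
#'   fraction of trials rejected upstream; defaults to 0 for all.
#' @param max_rejected_fraction exclusion threshold (default 0.6).
#' @param require_word_peak drop subjects with 2-Hz ITPC peak p >= alpha.
#' @param alpha,n_perm,seed settings of the per-subject permutation test.
#' @return A list with `cohort` (retained subjects), `log` (data frame of
#'   exclusions with reasons). Errors if every subject is excluded.
#' @export
qc_exclude_subjects <- function(cohort, rejected_fraction = NULL,
                                max_rejected_fraction = 0.6,
                                require_word_peak = TRUE,
                                alpha = 0.05, n_perm = 1000L, seed = 1L) {
  ids <- names(cohort$epochs)
  if (length(ids) == 0L) stop("empty cohort", call. = FALSE)
  if (is.null(rejected_fraction))
    rejected_fraction <- setNames(rep(0, length(ids)), ids)
  reasons <- character(0); dropped <- character(0)
  for (s in ids) {
    rf <- if (s %in% names(rejected_fraction)) rejected_fraction[[s]] else 0
    if (rf > max_rejected_fraction) {
      dropped <- c(dropped, s)
      reasons <- c(reasons, sprintf("rejected fraction %.2f > %.2f", rf,
                                    max_rejected_fraction))
      next
    }
    if (require_word_peak) {
      specs <- lapply(cohort$epochs[[s]], function(e) {
        channel_reduce(itpc(fourier_transform(e)), "all")
      })
      vals <- do.call(rbind, lapply(specs, function(sp) sp$values[1, ]))
      pt <- permutation_peak_test(vals, freqs = specs[[1]]$freqs,
                                  target_freq = 2,
                                  neighbor_rule = "bilateral3",
                                  n_perm = n_perm, seed = seed)
      if (pt$p >= alpha) {
        dropped <- c(dropped, s)
        reasons <- c(reasons, sprintf(
          "no reliable word-rate tracking (2-Hz ITPC peak p = %.3f)", pt$p))
      }
    }
  }
  keep <- setdiff(ids, dropped)
  if (length(keep) == 0L)
    stop("all subjects excluded; no analyzable cohort", call. = FALSE)
  cohort$epochs <- cohort$epochs[keep]
  cohort$subject_ids <- keep
  list(cohort = cohort,
       log = data.frame(subject = dropped, reason = reasons,
                        stringsAsFactors = FALSE))
}
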