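# Epoch array container: one raw little-endian float64 file per
# subject-condition plus a JSON sidecar holding dimensions and metadata.
# Array order on disk is trials x channels x samples, column-major.

#' Write an epoch set to the package array container
#'
#' @param epochs an [eeg_epochs()].
#' @param path output path for the data file; the JSON sidecar is written
#'   next to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  con <- file(path, "wb")
  writeBin(as.numeric(epochs$data), con, size = 8, endian = "little")
  close(con)
  meta <- list(dim = dim(epochs$data), fs = epochs$fs,
               epoch_duration = epochs$epoch_duration,
               condition = epochs$condition, subject_id = epochs$subject_id,
               channel_labels = epochs$channel_labels,
               dtype = "float64_le", order = "trials,channels,samples")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an epoch set from the package array container
#'
#' @param path path to the data file written by [write_epochs()].
#' @return The reconstructed [eeg_epochs()].
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(path, "rb")
  x <- readBin(con, "numeric", n, size = 8, endian = "little")
  close(con)
  eeg_epochs(array(x, dim = meta$dim), fs = meta$fs,
             condition = meta$condition, subject_id = meta$subject_id,
             channel_labels = meta$channel_labels)
}

#' Write a cohort to a directory, one container file per subject-condition
#'
#' @param cohort an `eeg_cohort` from [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(cohort$epochs)) {
    for (cond in names(cohort$epochs[[s]])) {
      fn <- file.path(dir, paste0(s, "_", gsub("[^A-Za-z0-9-]", "", cond),
                                  ".f64"))
      write_epochs(cohort$epochs[[s]][[cond]], fn)
    }
  }
  invisible(dir)
}

#' Read a cohort back from a container directory
#'
#' Inverse of [write_cohort()]: collects every `*.f64` container file in
#' `dir` into the nested `epochs[[subject]][[condition]]` structure,
#' using each sidecar's `subject_id` and `condition` metadata.
#'
#' @param dir directory written by [write_cohort()].
#' @return An object of class `eeg_cohort` (without generator params).
#' @export
read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "\\.f64$", full.names = TRUE)
  if (length(files) == 0L)
    stop("no container files found in ", dir, call. = FALSE)
  epochs <- list()
  for (f in files) {
    e <- read_epochs(f)
    sid <- e$subject_id
    if (is.na(sid)) sid <- sub("_.*$", "", basename(f))
    epochs[[sid]][[e$condition]] <- e
  }
  structure(list(epochs = epochs, subject_ids = names(epochs),
                 multipliers = NULL, params = NULL),
            class = "eeg_cohort")
}

#' Export a spectrum to long-format CSV
#'
#' One row per channel x frequency bin, with subject/condition metadata.
#'
#' @param spec a `power_spectrum` or `itpc_spectrum`.
#' @param path output CSV path.
#' @param subject,condition labels written into the table.
#' @return The exported data frame, invisibly.
#' @export
export_spectrum_csv <- function(spec, path, subject = NA, condition = NA) {
  stat <- if (inherits(spec, "itpc_spectrum")) "itpc" else "evoked_power"
  df <- data.frame(
    subject = subject, condition = condition,
    channel = rep(spec$channel_labels, times = length(spec$freqs)),
    freq = rep(spec$freqs, each = nrow(spec$values)),
    statistic = stat,
    value = as.numeric(spec$values))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
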