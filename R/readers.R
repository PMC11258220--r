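# Readers (and matching writers, used for round-trip tests and data
# exchange) for two standard continuous-EEG formats: EDF and BrainVision.
# Hand-written minimal implementations: no installed package reads these
# formats. Coverage is intentionally narrow — uniform sampling rate,
# int16/float32 BrainVision data, int16 EDF data, stimulus markers as
# trial onsets.

trim <- function(x) sub("\\s+$", "", sub("^\\s+", "", x))

#' Read a BrainVision recording (.vhdr/.vmrk/.eeg)
#'
#' Supports binary `IEEE_FLOAT_32` and `INT_16` data as well as the ASCII
#' data format, in multiplexed orientation. Marker positions of type
#' `Stimulus` become trial onsets (seconds).
#'
#' @param vhdr_path path to the `.vhdr` header file.
#' @return A [raw_recording()].
#' @export
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  kv <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    trim(sub(paste0("^", key, "="), "", ln[1]))
  }
  data_file <- kv("DataFile")
  marker_file <- kv("MarkerFile")
  fmt <- toupper(kv("DataFormat") %||% "BINARY")
  orient <- toupper(kv("DataOrientation") %||% "MULTIPLEXED")
  if (orient != "MULTIPLEXED")
    stop("only MULTIPLEXED orientation supported", call. = FALSE)
  nch <- as.integer(kv("NumberOfChannels"))
  fs <- 1e6 / as.numeric(kv("SamplingInterval"))   # microseconds per sample
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_info <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(ch_info, function(x) trim(x[1]), character(1))
  resol <- vapply(ch_info, function(x) {
    r <- suppressWarnings(as.numeric(x[3])); if (is.na(r)) 1 else r
  }, numeric(1))
  dir <- dirname(vhdr_path)
  dpath <- file.path(dir, data_file)
  if (fmt == "BINARY") {
    bfmt <- toupper(kv("BinaryFormat") %||% "IEEE_FLOAT_32")
    sz <- file.info(dpath)$size
    con <- file(dpath, "rb")
    on.exit(close(con))
    if (bfmt == "IEEE_FLOAT_32") {
      raw_vals <- readBin(con, "numeric", sz %/% 4, size = 4,
                          endian = "little")
      scale <- rep(1, nch)
    } else if (bfmt == "INT_16") {
      raw_vals <- readBin(con, "integer", sz %/% 2, size = 2,
                          endian = "little", signed = TRUE)
      scale <- resol
    } else stop("unsupported BinaryFormat: ", bfmt, call. = FALSE)
    ns <- length(raw_vals) %/% nch
    data <- matrix(raw_vals[seq_len(ns * nch)], nrow = nch) * scale
  } else if (fmt == "ASCII") {
    tab <- as.matrix(utils::read.table(dpath))
    data <- t(tab)                       # multiplexed: rows = samples
    dimnames(data) <- NULL
    storage.mode(data) <- "double"
  } else stop("unsupported DataFormat: ", fmt, call. = FALSE)
  onsets <- numeric(0)
  if (!is.null(marker_file) && file.exists(file.path(dir, marker_file))) {
    mk <- readLines(file.path(dir, marker_file), warn = FALSE)
    mk <- grep("^Mk[0-9]+=", mk, value = TRUE)
    parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
    for (p in parts) {
      if (length(p) >= 3 && trim(p[1]) == "Stimulus")
        onsets <- c(onsets, (as.numeric(p[3]) - 1) / fs)
    }
  }
  raw_recording(data, fs, labels, trial_onsets = onsets)
}

#' Write a BrainVision recording
#'
#' Companion writer to [read_brainvision()], mainly for data exchange and
#' round-trip testing. Writes `.vhdr`, `.vmrk` and the data file.
#'
#' @param rec a [raw_recording()].
#' @param basepath output path without extension.
#' @param format `"float32"`, `"int16"` or `"ascii"`.
#' @param resolution microvolts per bit for `int16`.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, basepath,
                              format = c("float32", "int16", "ascii"),
                              resolution = 0.1) {
  format <- match.arg(format)
  base <- basename(basepath)
  ext <- if (format == "ascii") ".dat" else ".eeg"
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ext),
    paste0("MarkerFile=", base, ".vmrk"),
    paste0("DataFormat=", if (format == "ascii") "ASCII" else "BINARY"),
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    if (format != "ascii") "[Binary Infos]",
    if (format == "float32") "BinaryFormat=IEEE_FLOAT_32",
    if (format == "int16") "BinaryFormat=INT_16",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(nrow(rec$data)),
            rec$channel_labels,
            if (format == "int16") format(resolution) else "1"))
  writeLines(hdr, paste0(basepath, ".vhdr"))
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Marker Infos]",
          if (length(rec$trial_onsets))
            sprintf("Mk%d=Stimulus,S  1,%d,1,0",
                    seq_along(rec$trial_onsets),
                    round(rec$trial_onsets * rec$fs) + 1L))
  writeLines(mk, paste0(basepath, ".vmrk"))
  dpath <- paste0(basepath, ext)
  if (format == "ascii") {
    utils::write.table(t(rec$data), dpath, row.names = FALSE,
                       col.names = FALSE)
  } else {
    con <- file(dpath, "wb")
    if (format == "float32") {
      writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(round(rec$data / resolution)), con, size = 2,
               endian = "little")
    }
    close(con)
  }
  invisible(paste0(basepath, ".vhdr"))
}

edf_field <- function(x, width) {
  formatC(substr(as.character(x), 1, width), width = width, flag = "-")
}

#' Read an EDF recording
#'
#' Minimal European Data Format reader: 16-bit samples with per-signal
#' physical scaling, uniform sampling rate across signals. EDF files
#' carry no standard trial markers; supply onsets via `trial_onsets`.
#'
#' @param path path to the `.edf` file.
#' @param trial_onsets optional trial onset times (s).
#' @return A [raw_recording()].
#' @export
read_edf <- function(path, trial_onsets = numeric(0)) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256))
  n_records <- as.integer(trim(substr(hdr, 237, 244)))
  rec_dur <- as.numeric(trim(substr(hdr, 245, 252)))
  ns <- as.integer(trim(substr(hdr, 253, 256)))
  sig <- rawToChar(readBin(con, "raw", 256 * ns))
  # layout offsets in bytes within the signal header block
  at <- function(start, width)
    vapply(seq_len(ns), function(i)
      trim(substr(sig, start + (i - 1) * width + 1, start + i * width)),
      character(1))
  pos <- c(label = 0, transducer = 16 * ns, dim = 96 * ns,
           phys_min = 104 * ns, phys_max = 112 * ns, dig_min = 120 * ns,
           dig_max = 128 * ns, prefilter = 136 * ns, nsamp = 216 * ns)
  labels <- at(pos["label"], 16)
  phys_min <- as.numeric(at(pos["phys_min"], 8))
  phys_max <- as.numeric(at(pos["phys_max"], 8))
  dig_min <- as.numeric(at(pos["dig_min"], 8))
  dig_max <- as.numeric(at(pos["dig_max"], 8))
  nsamp <- as.integer(at(pos["nsamp"], 8))
  if (length(unique(nsamp)) != 1L)
    stop("signals with differing sampling rates not supported",
         call. = FALSE)
  fs <- nsamp[1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  data <- matrix(0, ns, n_records * nsamp[1])
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", ns * nsamp[1], size = 2,
                     endian = "little", signed = TRUE)
    bm <- matrix(block, nrow = nsamp[1])        # one column per signal
    idx <- (r - 1) * nsamp[1] + seq_len(nsamp[1])
    data[, idx] <- t(bm) * gain + offset
  }
  raw_recording(data, fs, labels, trial_onsets = trial_onsets)
}

#' Write an EDF recording
#'
#' Companion writer to [read_edf()]; 16-bit EDF with one data-record
#' duration of `record_duration` seconds.
#'
#' @param rec a [raw_recording()]; `fs * record_duration` must be an
#'   integer and the sample count a multiple of it.
#' @param path output path.
#' @param record_duration data record length in seconds.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_duration = 1) {
  ns <- nrow(rec$data)
  nsamp <- round(rec$fs * record_duration)
  if (ncol(rec$data) %% nsamp != 0)
    stop("sample count must be a multiple of fs * record_duration",
         call. = FALSE)
  n_records <- ncol(rec$data) %/% nsamp
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max == phys_min
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- rep(-32768, ns); dig_max <- rep(32767, ns)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, width) writeChar(edf_field(x, width), con, eos = NULL)
  w("0", 8); w("synthetic", 80); w("synthetic", 80)
  w("01.01.26", 8); w("00.00.00", 8)
  w(as.character(256 * (1 + ns)), 8); w("", 44)
  w(as.character(n_records), 8)
  w(format(record_duration, scientific = FALSE), 8)
  w(as.character(ns), 4)
  for (lab in rec$channel_labels) w(lab, 16)
  for (i in seq_len(ns)) w("synthetic", 80)
  for (i in seq_len(ns)) w("uV", 8)
  for (v in phys_min) w(format(v, digits = 6, scientific = FALSE), 8)
  for (v in phys_max) w(format(v, digits = 6, scientific = FALSE), 8)
  for (v in dig_min) w(as.character(v), 8)
  for (v in dig_max) w(as.character(v), 8)
  for (i in seq_len(ns)) w("", 80)
  for (i in seq_len(ns)) w(as.character(nsamp), 8)
  for (i in seq_len(ns)) w("", 32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  for (r in seq_len(n_records)) {
    idx <- (r - 1) * nsamp + seq_len(nsamp)
    dig <- round((rec$data[, idx, drop = FALSE] - offset) / gain)
    dig <- pmin(pmax(dig, -32768), 32767)   # dig first: keeps dim
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}
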