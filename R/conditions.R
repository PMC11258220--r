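#' The six-condition experimental design
#'
#' Returns the 2 (structural regularity) x 2 (sequential regularity) design
#' with its grammatical refinements. Three conditions contain grammatical
#' two-word phrases (`V-N`, `V-Adv`, `V-Adv-alt`); three contain
#' non-grammatical word combinations (`N-R`, `R-R`, `V-V`). Structural
#' regularity holds exactly in the grammatical conditions; sequential
#' regularity (repetition of a part of speech every phrase) holds in `V-N`,
#' `V-Adv` and `N-R`. The grammatical conditions further differ in the
#' position of the phrasal head (`initial` vs. randomly `alternating`) and
#' in attachment type (`complement` vs. `adjunct`).
#'
#' @return A data frame of class `condition_design` with one row per
#'   condition and columns `name`, `structural`, `sequential`,
#'   `head_pattern` and `attachment`.
#' @examples
#' condition_designs()
#' @export
condition_designs <- function() {
  d <- data.frame(
    name         = c("V-N", "V-Adv", "V-Adv-alt", "N-R", "R-R", "V-V"),
    structural   = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    sequential   = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    head_pattern = c("initial", "initial", "alternating", "none", "none", "none"),
    attachment   = c("complement", "adjunct", "adjunct", "none", "none", "none"),
    stringsAsFactors = FALSE
  )
  class(d) <- c("condition_design", "data.frame")
  d
}

#' Fixed design constants of the frequency-tagging paradigm
#'
#' Structural constants of the paradigm: words are presented isochronously
#' at 2 Hz (500-ms tokens), so two-word phrases occur at 1 Hz; 48 words are
#' concatenated into 24-s streams; epochs are analyzed from 2 s to 24 s
#' (22 s), giving a spectral resolution of 1/22 Hz; each condition has 288
#' unique two-word combinations, each presented twice (576 phrases), spread
#' over 24 streams of 24 phrases.
#'
#' @return A named list of constants.
#' @export
design_constants <- function() {
  word_rate <- 2
  token_duration <- 1 / word_rate
  words_per_stream <- 48L
  epoch_start <- 2
  epoch_end <- 24
  list(
    word_rate          = word_rate,
    phrase_rate        = word_rate / 2,
    token_duration     = token_duration,
    words_per_stream   = words_per_stream,
    stream_duration    = words_per_stream * token_duration,
    epoch_start        = epoch_start,
    epoch_end          = epoch_end,
    epoch_duration     = epoch_end - epoch_start,
    freq_resolution    = 1 / (epoch_end - epoch_start),
    n_unique_pairs     = 288L,
    n_repetitions      = 2L,
    n_phrases          = 288L * 2L,
    n_streams          = 24L,
    phrases_per_stream = words_per_stream %/% 2L,
    fs_eeg             = 500,
    fs_audio           = 24000,
    env_fs             = 200
  )
}

#' @export
print.condition_design <- function(x, ...) {
  cat("Six-condition frequency-tagging design",
      "(structural x sequential regularity)\n\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
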