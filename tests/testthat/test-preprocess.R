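# A small continuous recording with known content for epoching tests.
make_recording <- function(n_ch = 3, dur = 60, fs = 100,
                           onsets = c(1, 26), labels = NULL) {
  if (is.null(labels)) labels <- c("Cz", "LM", "RM")[seq_len(n_ch)]
  set.seed(2024)
  raw_recording(matrix(rnorm(n_ch * dur * fs), n_ch), fs, labels,
                trial_onsets = onsets)
}

test_that("epoching yields fs x window samples and honors the offsets", {
  rec <- make_recording(fs = 500, dur = 60, onsets = c(0, 30))
  e <- epoch_trials(rec, 2, 24)
  expect_equal(dim(e$data), c(2L, 3L, 11000L))
  expect_equal(e$epoch_duration, 22)
  e0 <- epoch_trials(rec, 0, 24)
  expect_equal(dim(e0$data)[3], 12000L)
  # content check: epoch 1 equals the raw slice
  expect_equal(e$data[1, 1, ], rec$data[1, 1001:12000])
  expect_error(epoch_trials(rec, 24, 2), "start_offset")
})

test_that("trials that exceed the recording are dropped with a warning", {
  rec <- make_recording(dur = 40, fs = 100, onsets = c(1, 30))
  expect_warning(e <- epoch_trials(rec, 2, 24), "dropped")
  expect_equal(dim(e$data)[1], 1L)
})

test_that("mastoid re-referencing subtracts the reference mean exactly", {
  # hand-built 3-channel epochs: direct arithmetic oracle
  x <- array(0, dim = c(1, 3, 4))
  x[1, 1, ] <- c(1, 2, 3, 4)
  x[1, 2, ] <- c(1, 1, 1, 1)    # LM
  x[1, 3, ] <- c(3, 3, 3, 3)    # RM
  e <- eeg_epochs(x, 100, channel_labels = c("Cz", "LM", "RM"))
  r <- rereference(e)
  expect_equal(r$data[1, 1, ], c(1, 2, 3, 4) - 2)
  expect_equal(r$data[1, 2, ], c(1, 1, 1, 1) - 2)
  # zero references leave data unchanged
  x0 <- x; x0[1, 2, ] <- 0; x0[1, 3, ] <- 0
  e0 <- eeg_epochs(x0, 100, channel_labels = c("Cz", "LM", "RM"))
  expect_equal(rereference(e0)$data, e0$data)
  # constant offset c on both references shifts all channels by -c
  xc <- x; xc[1, 2, ] <- 5; xc[1, 3, ] <- 5
  ec <- eeg_epochs(xc, 100, channel_labels = c("Cz", "LM", "RM"))
  expect_equal(rereference(ec)$data[1, 1, ], c(1, 2, 3, 4) - 5)
  expect_error(rereference(e, c("LM", "M2")), "M2")
})

test_that("epoching and re-referencing commute", {
  rec <- make_recording(fs = 100, dur = 60, onsets = c(1, 26))
  a <- rereference(epoch_trials(rec, 2, 24))
  b <- epoch_trials(rereference(rec), 2, 24)
  expect_equal(a$data, b$data, tolerance = 1e-12)
})

test_that("the zero-phase bandpass meets its amplitude contract", {
  fs <- 500; dur <- 22
  t <- (0:(fs * dur - 1)) / fs
  mid <- seq(2000, 9000)           # interior, away from filter edges
  ratio <- function(f) {
    e <- epochs_from_matrix(matrix(sin(2 * pi * f * t), 1), fs)
    y <- bandpass(e, 0.3, 25)$data[1, 1, ]
    sd(y[mid]) / sd(sin(2 * pi * f * t)[mid])
  }
  expect_gte(ratio(0.6), 0.95)     # 2 x low edge
  expect_gte(ratio(2), 0.95)       # passband
  expect_gte(ratio(12.5), 0.95)    # high/2
  expect_lte(ratio(50), 0.10)      # 2 x high edge
  # DC removal
  e_dc <- epochs_from_matrix(matrix(rep(1, fs * dur), 1), fs)
  expect_lte(max(abs(bandpass(e_dc, 0.3, 25)$data[1, 1, mid])), 0.10)
  # zero phase: group delay below one sample on a passband tone
  e2 <- epochs_from_matrix(matrix(sin(2 * pi * 2 * t), 1), fs)
  y2 <- bandpass(e2, 0.3, 25)$data[1, 1, mid]
  x2 <- sin(2 * pi * 2 * t)[mid]
  lagfit <- which.max(vapply(-3:3, function(l)
    sum(y2 * sin(2 * pi * 2 * (t[mid] - l / fs))), numeric(1)))
  expect_equal((-3:3)[lagfit], 0)
  expect_gt(sum(y2 * x2) / sqrt(sum(y2^2) * sum(x2^2)), 0.999)
  expect_error(bandpass(e2, 30, 25), "low < high")
})

test_that("bad-channel interpolation is the weight-normalized neighbor mean", {
  x <- array(0, dim = c(2, 3, 5))
  x[, 1, ] <- 1; x[, 2, ] <- 3; x[, 3, ] <- 99
  e <- eeg_epochs(x, 100, channel_labels = c("A", "B", "C"))
  nm <- list(C = c(A = 1, B = 1))
  r <- interpolate_channels(e, "C", nm)
  expect_true(all(r$data[, 3, ] == 2))
  expect_equal(r$data[, 1:2, ], e$data[, 1:2, ])   # good channels untouched
  # weights (0.75, 0.25) on values (4, 0) -> 3
  x2 <- array(0, dim = c(1, 3, 2))
  x2[1, 1, ] <- 4; x2[1, 2, ] <- 0
  e2 <- eeg_epochs(x2, 100, channel_labels = c("A", "B", "C"))
  r2 <- interpolate_channels(e2, "C", list(C = c(A = 0.75, B = 0.25)))
  expect_true(all(r2$data[1, 3, ] == 3))
  # identity on an empty bad list
  expect_identical(interpolate_channels(e, character(0), nm), e)
  # no good neighbors -> error
  expect_error(interpolate_channels(e, c("A", "B", "C"),
                                    list(A = c(B = 1), B = c(A = 1),
                                         C = c(A = 1, B = 1))),
               "no good neighbors")
})

test_that("subject QC drops high-rejection subjects and non-trackers", {
  p <- small_params(n_subjects = 3, fs = 100, epoch_duration = 4,
                    noise_scale = 0.5, phase_concentration = 20)
  co <- simulate_cohort(p)
  # rejection-fraction rule alone
  rf <- c(S01 = 0.61, S02 = 0.1, S03 = 0)
  res <- qc_exclude_subjects(co, rejected_fraction = rf,
                             require_word_peak = FALSE)
  expect_equal(res$log$subject, "S01")
  expect_match(res$log$reason, "rejected fraction")
  expect_setequal(res$cohort$subject_ids, c("S02", "S03"))
  # a clean cohort passes the word-peak prerequisite
  res2 <- qc_exclude_subjects(co, require_word_peak = TRUE, n_perm = 1000,
                              seed = 4)
  expect_equal(nrow(res2$log), 0L)
  # a subject generated without word-rate response is excluded
  p0 <- small_params(n_subjects = 2, fs = 100, epoch_duration = 4,
                     amp_word = 0, amp_phrase = 0, noise_scale = 1)
  co_mixed <- simulate_cohort(p)
  co_null <- simulate_cohort(p0)
  co_mixed$epochs[["S02"]] <- co_null$epochs[["S01"]]
  res3 <- qc_exclude_subjects(co_mixed, require_word_peak = TRUE,
                              n_perm = 1000, seed = 4)
  expect_true("S02" %in% res3$log$subject)
  expect_match(res3$log$reason[res3$log$subject == "S02"], "word-rate")
  # all excluded -> error
  expect_error(
    qc_exclude_subjects(co, rejected_fraction = c(S01 = 1, S02 = 1, S03 = 1),
                        require_word_peak = FALSE),
    "all subjects excluded")
})

test_that("the ocular-artifact hook is an identity", {
  e <- epochs_from_matrix(matrix(rnorm(200), 2), 100)
  expect_identical(remove_ocular_artifacts(e), e)
  expect_error(remove_ocular_artifacts(e, method = "ica"), "out of scope")
})

test_that("epoch containers and EEG file formats round-trip", {
  p <- small_params(n_trials = 2)
  e <- simulate_epochs(p, "V-N", 5)
  e$subject_id <- "S01"
  # package array container
  f <- tempfile(fileext = ".f64")
  write_epochs(e, f)
  back <- read_epochs(f)
  expect_equal(back$data, e$data)
  expect_equal(back$condition, "V-N")
  expect_equal(back$fs, e$fs)
  # cohort directory round-trip
  co <- simulate_cohort(small_params(n_subjects = 2, n_trials = 2))
  cd <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, cd)
  co2 <- read_cohort(cd)
  expect_setequal(co2$subject_ids, co$subject_ids)
  expect_equal(co2$epochs[["S01"]][["V-N"]]$data,
               co$epochs[["S01"]][["V-N"]]$data)
  # BrainVision float32 + markers
  rec <- raw_recording(matrix(rnorm(3 * 1000), 3), 100,
                       c("Cz", "LM", "RM"), trial_onsets = c(0.5, 4))
  bp <- file.path(tempdir(), "bv_test")
  read_back <- read_brainvision(write_brainvision(rec, bp,
                                                  format = "float32"))
  expect_equal(read_back$data, rec$data, tolerance = 1e-6)
  expect_equal(read_back$fs, 100)
  expect_equal(read_back$channel_labels, rec$channel_labels)
  expect_equal(read_back$trial_onsets, rec$trial_onsets)
  # BrainVision ASCII
  bpa <- file.path(tempdir(), "bv_ascii")
  back_a <- read_brainvision(write_brainvision(rec, bpa, format = "ascii"))
  expect_equal(back_a$data, rec$data, tolerance = 1e-12)
  # EDF (16-bit quantization: generous tolerance)
  fe <- tempfile(fileext = ".edf")
  write_edf(rec, fe, record_duration = 1)
  back_e <- read_edf(fe, trial_onsets = c(0.5, 4))
  expect_equal(back_e$fs, 100)
  expect_equal(back_e$channel_labels, rec$channel_labels)
  expect_equal(back_e$data, rec$data, tolerance = 1e-3)
  expect_equal(back_e$trial_onsets, c(0.5, 4))
})
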