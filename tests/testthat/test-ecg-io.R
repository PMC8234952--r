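test_that("CSV records round-trip and reject malformed cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,lead_1,lead_2", "0,0.1,1", "0.002,0.2,2", "0.004,0.3,3"), path)
  rec <- read_ecg_record(path, format = "csv")
  expect_s3_class(rec, "ecg_record")
  expect_equal(dim(rec$samples), c(3L, 2L))
  expect_equal(rec$samples[, "lead_2"], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(rec$sample_rate, 500)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,lead_1", "0,0.1", "0.002,oops"), bad)
  err <- expect_error(read_ecg_record(bad, format = "csv"),
    class = "tensorecg_format_error")
  expect_match(conditionMessage(err), "lead_1")
  expect_match(conditionMessage(err), "line 2")
})

test_that("the stream CSV writer round-trips through the reader", {
  s <- synthesize_stream(beat_template(), rep("NORMAL", 3),
    lead_gains = c(1, 0.7), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream_csv(s, path)
  rec <- read_ecg_record(path, format = "csv")
  expect_equal(unname(rec$samples), unname(s$samples), tolerance = 1e-6)
  expect_equal(rec$sample_rate, s$sample_rate, tolerance = 1e-6)
})

test_that("WFDB records round-trip within the quantization step", {
  s <- synthesize_stream(beat_template(), rep("NORMAL", 4),
    lead_gains = c(1, 0.6), seed = 9)
  dir <- withr::local_tempdir()
  write_stream_wfdb(s, dir, record = "t1", gain = 200)
  rec <- read_ecg_record(file.path(dir, "t1.hea"), format = "wfdb")
  expect_equal(dim(rec$samples), dim(s$samples))
  expect_equal(rec$sample_rate, 500)
  expect_lt(max(abs(rec$samples - s$samples)), 1 / 200 + 1e-12)
  # annotations carry the ground truth back
  expect_equal(rec$annotations$sample, s$r_centers)
  expect_equal(rec$annotations$label, s$beat_labels)
})

test_that("WFDB reader flags missing and inconsistent files", {
  dir <- withr::local_tempdir()
  expect_error(read_ecg_record(file.path(dir, "nope.hea"), format = "wfdb"),
    class = "tensorecg_format_error")
  s <- synthesize_stream(beat_template(), rep("NORMAL", 2), lead_gains = 1, seed = 1)
  write_stream_wfdb(s, dir, record = "t2")
  # truncate the signal file: header/signal length mismatch
  dat <- file.path(dir, "t2.dat")
  bytes <- readBin(dat, "raw", file.size(dat))
  writeBin(bytes[1:100], dat)
  expect_error(read_ecg_record(file.path(dir, "t2.hea"), format = "wfdb"),
    class = "tensorecg_format_error")
})

test_that("R peaks of a clean synthetic stream land within 20 ms of truth", {
  s <- synthesize_stream(quiet_spec(), rep("NORMAL", 10), lead_gains = 1, seed = 2)
  pk <- detect_r_peaks(as_ecg_record(s))
  expect_length(pk, 10)
  expect_true(all(abs(pk - s$r_centers) <= 0.02 * s$sample_rate))
})

test_that("peak detection handles flat signals and is gain-invariant", {
  flat <- tensorecg:::new_ecg_record("flat", 500, matrix(0, 1000, 1))
  expect_identical(detect_r_peaks(flat), integer(0))

  s <- synthesize_stream(beat_template(), rep("NORMAL", 8), lead_gains = 1, seed = 4)
  rec <- as_ecg_record(s)
  rec$annotations <- NULL
  scaled <- rec
  scaled$samples <- rec$samples * 3.7
  expect_identical(detect_r_peaks(rec), detect_r_peaks(scaled))
})

test_that("annotated records prefer their annotations over detection", {
  s <- synthesize_stream(beat_template(), rep("NORMAL", 6), lead_gains = 1, seed = 3)
  rec <- as_ecg_record(s)
  expect_identical(beat_r_centers(rec), sort(s$r_centers))
})

test_that("segmentation drops edge windows and is identity at native length", {
  s <- synthesize_stream(quiet_spec(), rep("NORMAL", 6), lead_gains = 1, seed = 1)
  rec <- as_ecg_record(s)
  fs <- rec$sample_rate
  win_n <- round((0.25 + 0.45) * fs)

  # a peak too close to the record start is silently dropped
  early <- segment_cycles(rec, r_peaks = c(5L, s$r_centers[3]))
  expect_length(early, 1L)

  cycles <- segment_cycles(rec)
  # every full window fits inside this record
  expect_length(cycles, 6L)
  # native out_len: resampling is the identity on the raw window
  r <- s$r_centers[3]
  expect_equal(
    unname(cycles[[3]]$samples[, 1]),
    s$samples[(r - round(0.25 * fs)):(r - round(0.25 * fs) + win_n - 1), 1],
    tolerance = 1e-12
  )
  expect_equal(cycles[[2]]$label, "NORMAL")
})

test_that("noiseless periodic cycles are pairwise equal after resampling", {
  s <- synthesize_stream(quiet_spec(), rep("NORMAL", 8), lead_gains = c(1, 0.8), seed = 1)
  cycles <- segment_cycles(as_ecg_record(s), out_len = 64)
  expect_true(length(cycles) >= 6)
  ref <- cycles[[1]]$samples
  for (cy in cycles[-1]) {
    expect_equal(cy$samples, ref, tolerance = 1e-6)
  }
})

test_that("the ensemble cycle is the pointwise mean", {
  s <- synthesize_stream(quiet_spec(), rep("NORMAL", 5), lead_gains = 1, seed = 1)
  cycles <- segment_cycles(as_ecg_record(s), out_len = 32)

  expect_equal(ensemble_cycle(cycles[1])$samples, cycles[[1]]$samples)

  neg <- cycles[[1]]
  neg$samples <- -neg$samples
  expect_equal(ensemble_cycle(list(cycles[[1]], neg))$samples,
    matrix(0, 32, 1), ignore_attr = TRUE)

  expect_error(ensemble_cycle(list()), class = "tensorecg_invalid_input")
})

test_that("averaging noisy copies recovers the template within 0.05 mV", {
  spec <- beat_template(noise_sd = 0.1, period_jitter_sd = 0)
  s <- synthesize_stream(spec, rep("NORMAL", 102), lead_gains = 1, seed = 11)
  cycles <- segment_cycles(as_ecg_record(s))
  expect_true(length(cycles) >= 100)
  ens <- ensemble_cycle(cycles)
  # noiseless reference from the same template
  clean <- synthesize_stream(quiet_spec(), rep("NORMAL", 5), lead_gains = 1, seed = 11)
  ref <- segment_cycles(as_ecg_record(clean))[[2]]
  expect_lt(max(abs(ens$samples - ref$samples)), 0.05)
})

test_that("segment plus ensemble reproduces the generator beat within 1e-3", {
  s <- synthesize_stream(quiet_spec(), rep("NORMAL", 8), lead_gains = 1, seed = 6)
  cycles <- segment_cycles(as_ecg_record(s))
  ens <- ensemble_cycle(cycles)
  fs <- s$sample_rate
  n_beat <- round(0.8 * fs)
  beat <- make_beat(quiet_spec(), n_beat)
  # expected window: concatenated identical beats cut around the R centre
  stream1 <- rep(beat, 3)
  r <- 1 + n_beat + round(0.42 * n_beat) # 1-based onset of beat 2 plus R offset
  expected <- stream1[(r - round(0.25 * fs)):(r + round(0.45 * fs) - 1)]
  expect_lt(max(abs(ens$samples[, 1] - expected)), 1e-3)
})
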