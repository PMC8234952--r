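test_that("make_beat renders the Gaussian wave model exactly", {
  # zero template -> zero signal
  z <- beat_template(
    amplitudes = c(P = 0, Q = 0, R = 0, S = 0, T = 0),
    baseline = 0, st_shift = 0
  )
  expect_equal(make_beat(z, 64), rep(0, 64))

  # a lone R wave peaks at its centre with unit height
  r_only <- beat_template(
    amplitudes = c(P = 0, Q = 0, R = 1, S = 0, T = 0),
    centers = c(P = 0.18, Q = 0.38, R = 0.5, S = 0.56, T = 0.75),
    st_shift = 0
  )
  b <- make_beat(r_only, 400)
  expect_equal(which.max(b), 0.5 * 400 + 1) # t = (i-1)/n hits 0.5 at i = 201
  expect_lt(abs(max(b) - 1), 1e-9)
})

test_that("invalid templates are rejected", {
  expect_error(
    beat_template(widths = c(P = 0.02, Q = 0, R = 0.01, S = 0.01, T = 0.05)),
    class = "tensorecg_invalid_spec"
  )
  expect_error(
    beat_template(centers = c(P = 0.4, Q = 0.38, R = 0.42, S = 0.46, T = 0.7)),
    class = "tensorecg_invalid_spec"
  )
  expect_error(make_beat(beat_template(), 4))
})

test_that("T-inversion morph reflects exactly the T wave about baseline", {
  base <- quiet_spec()
  morph <- morph_template(base, "TINV_LIKE")
  n <- 512
  b0 <- make_beat(base, n)
  b1 <- make_beat(morph, n)
  # oracle: the difference must be exactly twice the T-wave Gaussian
  t <- (seq_len(n) - 1) / n
  t_wave <- base$amplitudes[["T"]] *
    exp(-(t - base$centers[["T"]])^2 / (2 * base$widths[["T"]]^2))
  expect_lt(max(abs((b0 - b1) - 2 * t_wave)), 1e-12)
  # far from the T wave the two beats agree
  far <- abs(t - base$centers[["T"]]) > 6 * base$widths[["T"]]
  expect_lt(max(abs(b0[far] - b1[far])), 1e-7)
})

test_that("streams are seed-deterministic", {
  s1 <- synthesize_stream(beat_template(), rep("NORMAL", 5), seed = 42)
  s2 <- synthesize_stream(beat_template(), rep("NORMAL", 5), seed = 42)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$beat_onsets, s2$beat_onsets)
  s3 <- synthesize_stream(beat_template(), rep("NORMAL", 5), seed = 43)
  expect_false(identical(s1$samples, s3$samples))
})

test_that("a noiseless jitter-free stream is exact beat repetitions", {
  spec <- quiet_spec()
  s <- synthesize_stream(spec, rep("NORMAL", 3), sample_rate = 500,
    lead_gains = 1, seed = 7)
  n_beat <- round(spec$beat_period * 500)
  expect_equal(nrow(s$samples), 3 * n_beat)
  one <- make_beat(spec, n_beat)
  expect_equal(as.numeric(s$samples[, 1]), rep(one, 3), tolerance = 1e-12)
  expect_equal(s$beat_onsets, 1L + n_beat * 0:2)
})

test_that("ST elevation shifts the ST-interval mean by exactly st_shift", {
  spec <- quiet_spec()
  labels <- c(rep("NORMAL", 50), rep("STE_LIKE", 50))
  s <- synthesize_stream(spec, labels, sample_rate = 500, lead_gains = 1,
    seed = 3, st_shift_mV = 0.15)
  n_beat <- round(spec$beat_period * 500)
  lim <- st_interval(spec)
  t <- (seq_len(n_beat) - 1) / n_beat
  in_plateau <- which(t >= lim[1] & t <= lim[2])
  beat_mean <- vapply(seq_along(labels), function(i) {
    mean(s$samples[s$beat_onsets[i] + in_plateau - 1L, 1])
  }, numeric(1))
  expect_equal(mean(beat_mean[51:100]) - mean(beat_mean[1:50]), 0.15,
    tolerance = 1e-9)
})

test_that("morph labels deterministically alter their defining feature", {
  spec <- quiet_spec()
  n <- 512
  t <- (seq_len(n) - 1) / n

  # AF: no P-wave energy
  af <- morph_template(spec, "AF_LIKE")
  expect_equal(af$amplitudes[["P"]], 0)
  expect_gt(af$period_jitter_sd, spec$period_jitter_sd)
  p_region <- abs(t - spec$centers[["P"]]) < 3 * spec$widths[["P"]]
  expect_lt(sum(make_beat(af, n)[p_region]^2),
    sum(make_beat(spec, n)[p_region]^2) / 100)

  # BBB: wider QRS, smaller R
  bbb <- morph_template(spec, "BBB_LIKE")
  expect_equal(unname(bbb$widths[c("Q", "R", "S")] / spec$widths[c("Q", "R", "S")]),
    rep(1.8, 3))
  expect_lt(bbb$amplitudes[["R"]], spec$amplitudes[["R"]])

  # STD: negative shift; STE: positive
  expect_lt(morph_template(spec, "STD_LIKE")$st_shift, 0)
  expect_gt(morph_template(spec, "STE_LIKE")$st_shift, 0)
})

test_that("leads are exact gain multiples of each other when noiseless", {
  s <- synthesize_stream(quiet_spec(), rep("NORMAL", 4),
    lead_gains = c(1, 0.5, 2), seed = 1)
  expect_equal(s$samples[, 2], 0.5 * s$samples[, 1], tolerance = 1e-12,
    ignore_attr = TRUE)
  expect_equal(s$samples[, 3], 2 * s$samples[, 1], tolerance = 1e-12,
    ignore_attr = TRUE)
})

test_that("premature beats shorten the preceding interval", {
  labels <- c("NORMAL", "NORMAL", "PREMATURE", "NORMAL")
  s <- synthesize_stream(quiet_spec(), labels, lead_gains = 1, seed = 1)
  gaps <- diff(s$beat_onsets)
  expect_lt(gaps[2], 0.7 * gaps[1]) # interval before the premature beat
  expect_equal(gaps[1], gaps[3])
})

test_that("stream construction validates its inputs", {
  expect_error(synthesize_stream(beat_template(), character(0)),
    class = "tensorecg_invalid_spec")
  expect_error(synthesize_stream(beat_template(), "NORMAL", lead_gains = numeric(0)),
    class = "tensorecg_invalid_spec")
  expect_error(synthesize_stream(beat_template(), "NOT_A_MORPH"),
    class = "tensorecg_invalid_spec")
})
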