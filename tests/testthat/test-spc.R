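test_that("one-dimensional T-squared is the squared z-score", {
  x <- c(1.2, 0.8, 1.5, 0.9, 1.1, 1.4, 0.7, 1.0)
  chart <- t2_calibrate(matrix(x, ncol = 1), alpha = 0.1)
  mon <- t2_monitor(chart, matrix(x, ncol = 1))
  expect_equal(mon$t2, ((x - mean(x)) / sd(x))^2, tolerance = 1e-12)
  expect_equal(t2_monitor(chart, mean(x))$t2, 0, tolerance = 1e-12)
})

test_that("Phase-I coverage matches the nominal alpha", {
  X <- feature_cluster(10000, 5, seed = 31)
  for (alpha in c(0.01, 0.05)) {
    chart <- t2_calibrate(X, alpha = alpha)
    frac <- mean(chart$t2 > chart$ucl)
    expect_lt(abs(frac - alpha), 2 / sqrt(nrow(X)))
  }
})

test_that("in-control monitoring alarms near the nominal rate", {
  chart <- t2_calibrate(feature_cluster(5000, 4, seed = 32), alpha = 0.05)
  fresh <- feature_cluster(5000, 4, seed = 33)
  mon <- t2_monitor(chart, fresh)
  se <- sqrt(0.05 * 0.95 / nrow(fresh))
  expect_lt(abs(mean(mon$out_of_control) - 0.05), 3 * se)
})

test_that("T-squared is invariant under invertible affine maps", {
  Z <- feature_cluster(200, 4, seed = 34)
  stream <- feature_cluster(50, 4, center = c(1, 0, -1, 2), seed = 35)
  withr::with_seed(36, {
    A <- matrix(rnorm(16), 4, 4) + diag(4)
    b <- rnorm(4)
  })
  transform <- function(X) X %*% A + matrix(b, nrow(X), 4, byrow = TRUE)
  c1 <- t2_calibrate(Z, alpha = 0.05)
  c2 <- t2_calibrate(transform(Z), alpha = 0.05)
  expect_equal(c1$ridge, 0)
  expect_equal(c2$ridge, 0)
  m1 <- t2_monitor(c1, stream)
  m2 <- t2_monitor(c2, transform(stream))
  expect_equal(m1$t2, m2$t2, tolerance = 1e-8)
  expect_equal(attr(m1, "ucl"), attr(m2, "ucl"), tolerance = 1e-8)
})

test_that("T-squared is non-negative and monotone along a ray", {
  chart <- t2_calibrate(feature_cluster(100, 3, seed = 37), alpha = 0.05)
  dir <- c(1, -0.5, 2)
  ray <- t(vapply(seq(0, 3, by = 0.25), function(s) chart$mean + s * dir,
    numeric(3)))
  t2 <- t2_monitor(chart, ray)$t2
  expect_true(all(t2 >= 0))
  expect_true(all(diff(t2) >= -1e-10))
})

test_that("batch and one-at-a-time monitoring agree; runs are recorded", {
  chart <- t2_calibrate(feature_cluster(80, 3, seed = 38), alpha = 0.05)
  stream <- feature_cluster(40, 3, seed = 39)
  mon <- t2_monitor(chart, stream)
  single <- vapply(seq_len(40), function(i) t2_monitor(chart, stream[i, ])$t2,
    numeric(1))
  expect_equal(mon$t2, single, tolerance = 1e-12)
  expect_identical(mon$out_of_control, mon$t2 > attr(mon, "ucl"))
  runs <- attr(mon, "alarm_runs")
  expect_equal(sum(runs$length), sum(mon$out_of_control))
})

test_that("degenerate calibrations are caught or regularised", {
  expect_error(t2_calibrate(feature_cluster(4, 5, seed = 40)),
    class = "tensorecg_ill_posed")
  expect_error(t2_calibrate(feature_cluster(50, 2, seed = 41), alpha = 0),
    class = "tensorecg_invalid_parameter")
  X <- feature_cluster(50, 3, seed = 42)
  X[, 2] <- 7 # zero-variance feature
  expect_warning(chart <- t2_calibrate(X, alpha = 0.05), "zero")
  expect_gt(chart$ridge, 0)
  expect_true(all(is.finite(t2_monitor(chart, X)$t2)))
  chart2 <- t2_calibrate(feature_cluster(50, 3, seed = 43))
  expect_error(t2_monitor(chart2, matrix(0, 2, 4)),
    class = "tensorecg_invalid_input")
})

test_that("charts are patient-specific: cross-applied limits misbehave", {
  patient_a <- beat_template(noise_sd = 0.04)
  patient_b <- beat_template(
    amplitudes = c(P = 0.1, Q = -0.05, R = 0.8, S = -0.3, T = 0.45),
    noise_sd = 0.04
  )
  fit_patient <- function(spec, seed) {
    cycles <- generate_condition_cycles("NORMAL", 150, base_spec = spec,
      lead_gains = 1, seed = seed)
    m <- fit_mpca(build_gadf_tensors(cycles, 16), dims = "gap", p = 5)
    feats <- mpca_features(m, build_gadf_tensors(cycles, 16))
    fresh <- generate_condition_cycles("NORMAL", 100, base_spec = spec,
      lead_gains = 1, seed = seed + 1)
    list(
      chart = t2_calibrate(feats, alpha = 0.05),
      fresh = mpca_features(m, build_gadf_tensors(fresh, 16))
    )
  }
  a <- fit_patient(patient_a, seed = 44)
  b <- fit_patient(patient_b, seed = 46)
  expect_false(isTRUE(all.equal(a$chart$ucl, b$chart$ucl)))
  # cross-applying the patient with the tighter limit to the other
  # patient's stream inflates that patient's false-alarm rate
  if (b$chart$ucl < a$chart$ucl) {
    own <- t2_monitor(a$chart, a$fresh)
    cross <- t2_monitor(a$chart, a$fresh, ucl = b$chart$ucl)
  } else {
    own <- t2_monitor(b$chart, b$fresh)
    cross <- t2_monitor(b$chart, b$fresh, ucl = a$chart$ucl)
  }
  expect_gt(mean(cross$out_of_control), mean(own$out_of_control))
})
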