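#' Calibrate a Hotelling T-squared control chart (Phase I)
#'
#' Estimates the in-control mean vector and covariance matrix from Phase-I
#' (normal) feature vectors, computes the T-squared statistic
#' `(x - xbar)' S^{-1} (x - xbar)` for each Phase-I sample, and sets the
#' upper control limit (UCL) to the empirical `(1 - alpha)` quantile of
#' those statistics (linear-interpolation quantile). The covariance uses
#' the `N0 - 1` denominator; when it is ill-conditioned (condition number
#' above 1e10, e.g. collinear or zero-variance features) a ridge
#' `epsilon I` with `epsilon = 1e-8 trace(S)/p` is added and the chart is
#' flagged as regularised.
#'
#' @param features Numeric matrix of Phase-I feature vectors (rows are
#'   samples); needs more samples than feature dimensions.
#' @param alpha Significance level in (0, 1); default 0.05.
#'
#' @return An object of class `t2_chart`: `mean` (length p), `cov`,
#'   `cov_inv`, `alpha`, `ucl`, `n0`, `ridge` (0 when not applied), and the
#'   Phase-I `t2` statistics.
#' @seealso [t2_monitor()]
#' @export
t2_calibrate <- function(features, alpha = 0.05) {
  X <- as.matrix(features)
  if (anyNA(X) || any(!is.finite(X))) stop_invalid("Features must be finite.")
  n0 <- nrow(X)
  p <- ncol(X)
  if (!(alpha > 0 && alpha < 1)) {
    stop_invalid("`alpha` must lie strictly between 0 and 1.",
      class = "tensorecg_invalid_parameter")
  }
  if (n0 <= p) {
    stop_invalid(sprintf(
      "Phase-I calibration is ill-posed: %d samples for %d feature dimensions (need N0 > p).",
      n0, p
    ), class = "tensorecg_ill_posed")
  }
  xbar <- colMeans(X)
  S <- cov(X)
  zero_var <- diag(S) == 0
  if (any(zero_var)) {
    warn(sprintf(
      "%d feature(s) have zero Phase-I variance; ridge regularisation applied.",
      sum(zero_var)
    ))
  }
  ridge <- 0
  if (any(zero_var) || kappa(S, exact = FALSE) > 1e10) {
    ridge <- 1e-8 * sum(diag(S)) / p
    if (ridge == 0) ridge <- 1e-8
    S <- S + diag(ridge, p)
  }
  S_inv <- solve(S)
  centered <- t(t(X) - xbar)
  t2 <- rowSums((centered %*% S_inv) * centered)
  structure(
    list(
      mean = xbar,
      cov = S,
      cov_inv = S_inv,
      alpha = alpha,
      ucl = unname(quantile(t2, 1 - alpha, type = 7)),
      n0 = n0,
      ridge = ridge,
      t2 = unname(t2)
    ),
    class = "t2_chart"
  )
}

#' @export
print.t2_chart <- function(x, ...) {
  cat(sprintf(
    "<t2_chart> p = %d features, N0 = %d Phase-I samples, alpha = %g, UCL = %.4g%s\n",
    length(x$mean), x$n0, x$alpha, x$ucl,
    if (x$ridge > 0) sprintf(" (ridge %.3g)", x$ridge) else ""
  ))
  invisible(x)
}

#' Phase-II cycle-to-cycle monitoring with a T-squared chart
#'
#' Computes the Hotelling T-squared statistic of each monitored feature
#' vector against the frozen Phase-I mean and covariance and flags cycles
#' whose statistic exceeds the chart's UCL. The statistic is a pure
#' function of the chart and the single cycle, so batch and one-at-a-time
#' monitoring agree exactly.
#'
#' @param chart A calibrated [t2_calibrate()] chart.
#' @param features Numeric matrix of monitored feature vectors in arrival
#'   order (rows are cycles), or a single vector.
#' @param ucl Optional UCL override.
#'
#' @return A tibble of class `t2_monitoring` with columns `cycle_index`,
#'   `t2`, `out_of_control`; attributes `ucl`, `alpha`, and `alarm_runs`
#'   (a tibble of start index and length of each consecutive alarm run).
#' @export
t2_monitor <- function(chart, features, ucl = NULL) {
  stopifnot(inherits(chart, "t2_chart"))
  X <- if (is.null(dim(features))) matrix(features, nrow = 1) else as.matrix(features)
  p <- length(chart$mean)
  if (ncol(X) != p) {
    stop_invalid(sprintf(
      "Feature length %d does not match the chart dimension %d.", ncol(X), p
    ))
  }
  ucl <- ucl %||% chart$ucl
  centered <- t(t(X) - chart$mean)
  t2 <- rowSums((centered %*% chart$cov_inv) * centered)
  flag <- t2 > ucl
  runs <- rle(flag)
  ends <- cumsum(runs$lengths)
  alarm_runs <- tibble::tibble(
    start = (ends - runs$lengths + 1L)[runs$values],
    length = runs$lengths[runs$values]
  )
  out <- tibble::tibble(
    cycle_index = seq_len(nrow(X)),
    t2 = unname(t2),
    out_of_control = unname(flag)
  )
  attr(out, "ucl") <- ucl
  attr(out, "alpha") <- chart$alpha
  attr(out, "alarm_runs") <- alarm_runs
  class(out) <- c("t2_monitoring", class(out))
  out
}

#' @describeIn t2_calibrate Tidy summary: one row per feature with its
#'   Phase-I mean and variance.
#' @param x A `t2_chart`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.t2_chart <- function(x, ...) {
  tibble::tibble(
    feature = names(x$mean) %||% paste0("feat_", seq_along(x$mean)),
    mean = unname(x$mean),
    variance = unname(diag(x$cov))
  )
}

#' @describeIn t2_calibrate One-row chart summary (N0, alpha, UCL, ridge).
#' @exportS3Method generics::glance
glance.t2_chart <- function(x, ...) {
  tibble::tibble(
    n0 = x$n0,
    p = length(x$mean),
    alpha = x$alpha,
    ucl = x$ucl,
    ridge = x$ridge,
    phase1_alarm_fraction = mean(x$t2 > x$ucl)
  )
}
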