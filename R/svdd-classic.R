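#' Fit a classic kernel SVDD on normal feature vectors
#'
#' Finds the minimum-volume hypersphere enclosing (most of) the training
#' features in Gaussian-kernel space by solving the dual quadratic program
#'
#' \deqn{\min_\alpha \alpha^\top K \alpha - \sum_i \alpha_i K_{ii}
#'   \quad \text{s.t.}\quad \sum_i \alpha_i = 1,\; 0 \le \alpha_i \le \gamma,}
#'
#' using the interior-point solver [kernlab::ipop()]. The squared radius
#' is the kernel-space squared distance to the centre of any support vector
#' whose coefficient lies strictly inside `(0, gamma)`; a point is declared
#' anomalous when its kernel distance squared exceeds `R^2`. The trade-off
#' `gamma` bounds the fraction of training points outside the sphere by
#' `1 / (gamma N0)`; `gamma <= 1/N0` makes the constraint set infeasible
#' and errors.
#'
#' @param features Numeric matrix, one row per training sample.
#' @param gamma Trade-off between sphere volume and boundary violations
#'   (default 1: a hard boundary).
#' @param sigma Gaussian kernel bandwidth; defaults to the median pairwise
#'   training distance (median heuristic).
#'
#' @return An object of class `classic_svdd`: support coefficients `alpha`
#'   (summing to 1 in `[0, gamma]`), `sigma`, `gamma`, `R2`, the stored
#'   training features, and the constant kernel self-term.
#' @seealso [score_anomaly()]
#' @export
fit_classic_svdd <- function(features, gamma = 1, sigma = NULL) {
  X <- as.matrix(features)
  if (anyNA(X) || any(!is.finite(X))) stop_invalid("Features must be finite.")
  N <- nrow(X)
  if (N < 1) stop_invalid("At least one training sample is required.")
  check_number(gamma, "gamma", 0, strict = TRUE)
  if (gamma <= 1 / N) {
    stop_invalid(sprintf(
      "gamma = %g is infeasible: it must exceed 1/N0 = %g.", gamma, 1 / N
    ), class = "tensorecg_invalid_parameter")
  }

  D2 <- as.matrix(stats::dist(X))^2
  if (is.null(sigma)) {
    pd <- sqrt(D2[upper.tri(D2)])
    sigma <- if (length(pd) == 0 || median(pd) == 0) 1 else median(pd)
  }
  check_number(sigma, "sigma", 0, strict = TRUE)
  K <- exp(-D2 / (2 * sigma^2))

  if (N == 1 || max(D2) == 0) {
    # All training points coincide: the sphere degenerates to that point.
    alpha <- rep(1 / N, N)
    R2 <- 0
  } else {
    qp <- kernlab::ipop(
      c = -diag(K), H = 2 * K,
      A = matrix(1, 1, N), b = 1, r = 0,
      l = rep(0, N), u = rep(gamma, N),
      sigf = 9, maxiter = 200
    )
    alpha <- pmin(pmax(kernlab::primal(qp), 0), gamma)
    alpha <- alpha / sum(alpha)
    aKa <- drop(t(alpha) %*% K %*% alpha)
    dist2 <- 1 - 2 * drop(K %*% alpha) + aKa # K(x,x) = 1 for the Gaussian kernel
    tol <- 1e-6 * gamma
    interior <- which(alpha > tol & alpha < gamma - tol)
    R2 <- if (length(interior)) {
      mean(dist2[interior])
    } else {
      # No strictly interior support vector (e.g. hard-margin corner case):
      # take the largest distance among support vectors on the boundary.
      max(dist2[alpha > tol])
    }
  }

  structure(
    list(
      alpha = alpha,
      sigma = sigma,
      gamma = gamma,
      R2 = max(R2, 0),
      X = X,
      aKa = if (exists("aKa", inherits = FALSE)) aKa else 1
    ),
    class = "classic_svdd"
  )
}

#' @export
print.classic_svdd <- function(x, ...) {
  cat(sprintf(
    "<classic_svdd> %d training samples, %d support vectors, sigma = %.4g, gamma = %g, R^2 = %.4g\n",
    nrow(x$X), sum(x$alpha > 1e-6 * x$gamma), x$sigma, x$gamma, x$R2
  ))
  invisible(x)
}

# Kernel-space squared distance of rows of `Xnew` to the SVDD centre.
svdd_dist2 <- function(model, Xnew) {
  Xnew <- matrix(Xnew, ncol = ncol(model$X))
  D2 <- outer(rowSums(Xnew^2), rowSums(model$X^2), `+`) - 2 * tcrossprod(Xnew, model$X)
  Kx <- exp(-pmax(D2, 0) / (2 * model$sigma^2))
  d2 <- 1 - 2 * drop(Kx %*% model$alpha) + model$aKa
  # cancellation guard: kernel distances are non-negative, and values at
  # rounding level are genuinely zero (e.g. a point coinciding with a
  # degenerate one-point sphere must not be flagged anomalous)
  d2[abs(d2) < 1e-12] <- 0
  pmax(d2, 0)
}

#' @describeIn fit_classic_svdd Tidy summary: one row per training sample
#'   with its dual coefficient and support-vector status.
#' @param x An object returned by `fit_classic_svdd()`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.classic_svdd <- function(x, ...) {
  tol <- 1e-6 * x$gamma
  tibble::tibble(
    sample = seq_along(x$alpha),
    alpha = x$alpha,
    support = x$alpha > tol,
    at_bound = x$alpha >= x$gamma - tol
  )
}

#' @describeIn fit_classic_svdd One-row fit summary.
#' @exportS3Method generics::glance
glance.classic_svdd <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$X),
    n_support = sum(x$alpha > 1e-6 * x$gamma),
    sigma = x$sigma,
    gamma = x$gamma,
    r_squared = x$R2
  )
}
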