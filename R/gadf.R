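#' Rescale a signal into the unit interval
#'
#' Min-max rescaling `(x - min x) / (max x - min x)`, the first step of
#' Gramian angular imaging. A constant signal has no angular content and
#' raises a degenerate-signal error.
#'
#' @param x Numeric vector of length at least 2.
#' @return Numeric vector in `[0, 1]` with attributes `orig_min` and
#'   `orig_max` recording the original range.
#' @export
rescale_unit <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    stop_invalid("`x` must be a numeric vector of length >= 2.")
  }
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) {
    stop_invalid("Constant signal cannot be rescaled to [0, 1] (max == min).",
      class = "tensorecg_degenerate_signal")
  }
  structure((x - lo) / (hi - lo), orig_min = lo, orig_max = hi)
}

#' Piecewise aggregate approximation
#'
#' Reduces a series of length `M` to `target_len` values by averaging over
#' near-equal blocks: block `k` (1-based) covers indices
#' `(floor((k-1) M / M') + 1) : floor(k M / M')`. When `target_len == M`
#' the input is returned unchanged; when `target_len` divides `M` the
#' global mean is preserved exactly.
#'
#' @param x Numeric vector of length `M`.
#' @param target_len Output length `M'`, with `1 <= M' <= M`.
#' @return Numeric vector of length `target_len`.
#' @export
paa <- function(x, target_len) {
  M <- length(x)
  if (!is_wholenumber(target_len) || target_len < 1 || target_len > M) {
    stop_invalid(sprintf(
      "`target_len` must be a whole number in [1, %d], got %s.", M, format(target_len)
    ), class = "tensorecg_invalid_parameter")
  }
  target_len <- as.integer(target_len)
  if (target_len == M) {
    return(x)
  }
  bounds <- floor(seq_len(target_len) * M / target_len)
  starts <- c(0L, bounds[-target_len]) + 1L
  vapply(seq_len(target_len), function(k) mean(x[starts[k]:bounds[k]]), numeric(1))
}

#' Gramian Angular Difference Field of a rescaled signal
#'
#' Maps a `[0, 1]`-valued series to polar angles `phi = arccos(x)` (the
#' radius `m / M` orders the samples in time) and forms the difference-field
#' Gramian `G[i, j] = sin(phi_i - phi_j)`, computed in closed matrix form
#' `G = sqrt(1 - x^2) x' - x sqrt(1 - x^2)'`. Values are clipped into
#' `[0, 1]` before the square root and arccos to absorb floating-point
#' overshoot. The result is antisymmetric with a zero diagonal and all
#' entries in `[-1, 1]`.
#'
#' @param x Numeric vector with values in `[0, 1]` (e.g. [rescale_unit()]
#'   output, possibly reduced by [paa()]).
#' @param lead Optional source lead name stored on the image.
#' @return A `gadf_image`: an M' x M' numeric matrix with attribute `lead`.
#' @export
#' @examples
#' gadf(c(0, 0.5, 1))
gadf <- function(x, lead = NULL) {
  if (!is.numeric(x) || length(x) < 2) {
    stop_invalid("`x` must be a numeric vector of length >= 2.")
  }
  x <- pmin(pmax(as.numeric(x), 0), 1)
  s <- sqrt(1 - x^2)
  G <- tcrossprod(s, x) - tcrossprod(x, s)
  structure(G, lead = lead, class = c("gadf_image", class(G)))
}

#' @export
print.gadf_image <- function(x, ...) {
  lead <- attr(x, "lead")
  cat(sprintf(
    "<gadf_image> %d x %d%s, range [%.3f, %.3f]\n",
    nrow(x), ncol(x), if (is.null(lead)) "" else paste0(" (", lead, ")"),
    min(x), max(x)
  ))
  invisible(x)
}

#' Build the GADF tensor of a multi-lead cycle
#'
#' Per lead: min-max rescale, reduce to `image_size` samples with [paa()],
#' and compute the GADF; the per-lead images are stacked along the third
#' axis in lead order, giving the `image_size x image_size x C` sample
#' tensor fed to MPCA.
#'
#' @param cycle An `ecg_cycle` (or a plain samples-by-leads numeric matrix).
#' @param image_size Side length M' of each GADF image; must not exceed the
#'   cycle length.
#' @return An `ecg_tensor`: 3-D array with `dimnames` on the lead axis and
#'   attribute `label` copied from the cycle.
#' @export
build_gadf_tensor <- function(cycle, image_size = 32) {
  samples <- if (inherits(cycle, "ecg_cycle")) cycle$samples else as.matrix(cycle)
  M <- nrow(samples)
  if (!is_wholenumber(image_size) || image_size < 2 || image_size > M) {
    stop_invalid(sprintf(
      "`image_size` must be a whole number in [2, %d] (cycle length), got %s.",
      M, format(image_size)
    ), class = "tensorecg_invalid_parameter")
  }
  image_size <- as.integer(image_size)
  leads <- colnames(samples) %||% paste0("lead_", seq_len(ncol(samples)))
  A <- array(0, dim = c(image_size, image_size, ncol(samples)),
    dimnames = list(NULL, NULL, leads))
  for (c_idx in seq_len(ncol(samples))) {
    x <- samples[, c_idx]
    if (max(x) == min(x)) {
      stop_invalid(sprintf("Lead '%s' is constant; its GADF is undefined.", leads[c_idx]),
        class = "tensorecg_degenerate_signal")
    }
    A[, , c_idx] <- gadf(paa(rescale_unit(x), image_size))
  }
  structure(A,
    label = if (inherits(cycle, "ecg_cycle")) cycle$label else NULL,
    class = c("ecg_tensor", class(A))
  )
}

#' GADF tensors for a list of cycles
#'
#' Convenience wrapper applying [build_gadf_tensor()] to each cycle.
#'
#' @param cycles List of `ecg_cycle` objects.
#' @param image_size Side length of each GADF image.
#' @return List of `ecg_tensor` arrays.
#' @export
build_gadf_tensors <- function(cycles, image_size = 32) {
  lapply(cycles, build_gadf_tensor, image_size = image_size)
}
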