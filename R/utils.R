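# Internal validators and small tensor helpers shared across modules.

stop_invalid <- function(msg, class = "tensorecg_invalid_input") {
  abort(msg, class = c(class, "tensorecg_error"))
}

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop_invalid(sprintf(
      "`%s` must be %s %s, got %s.", name,
      if (strict) "greater than" else "at least", format(lower), format(x)
    ))
  }
  invisible(x)
}

# Mode-k unfolding of an array (any order); rows index mode `k`,
# remaining modes vary column-major in their original order.
unfold_mode <- function(A, k) {
  d <- dim(A)
  perm <- c(k, setdiff(seq_along(d), k))
  B <- aperm(A, perm)
  dim(B) <- c(d[k], prod(d[-k]))
  B
}

# Inverse of unfold_mode: fold a matrix back into an array of dims `d`
# along mode `k`.
fold_mode <- function(M, k, d) {
  perm <- c(k, setdiff(seq_along(d), k))
  A <- array(M, dim = d[perm])
  aperm(A, order(perm))
}

# Mode-k product A x_k U (U: J x I_k); works on arrays of any order,
# so a 4th sample mode passes through untouched.
mode_mult <- function(A, U, k) {
  d <- dim(A)
  stopifnot(ncol(U) == d[k])
  out_d <- d
  out_d[k] <- nrow(U)
  fold_mode(U %*% unfold_mode(A, k), k, out_d)
}

# Stable deterministic sign fix: make the largest-magnitude entry of each
# column positive so eigenvector bases are reproducible across platforms.
fix_signs <- function(U) {
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < tol
}
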