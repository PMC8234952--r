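#' Fit multilinear PCA on a set of third-order tensors
#'
#' Learns one column-orthonormal projection matrix per tensor mode so that
#' the projected core tensors capture the maximum total scatter (the sum
#' over samples of the squared Frobenius norm of the centred, projected
#' tensors). Samples are centred by their mean tensor; each mode's
#' projection is initialised from the leading eigenvectors of that mode's
#' unfolding scatter (full-projection initialisation), and the solver then
#' alternates over modes, re-solving the mode-k eigenproblem with the other
#' modes projected, until the relative change in total scatter falls below
#' `tol` or `max_iter` sweeps. Per-mode output dimensions are either given
#' explicitly via `dims`, or chosen as the smallest counts whose eigenvalue
#' mass reaches `variance_keep` per mode. Finally the coordinates of the
#' vectorised core are ranked by their scatter across the training samples
#' (descending, ties broken by coordinate index); [mpca_features()] keeps
#' the first `p` of them.
#'
#' @param tensors List of equal-shape 3-D arrays (e.g. from
#'   [build_gadf_tensors()]), or a 4-D array with samples on the 4th axis.
#' @param variance_keep Fraction of per-mode eigenvalue mass to retain when
#'   `dims` is not given (default 0.97).
#' @param dims Optional explicit per-mode output dimensions `(P1, P2, P3)`,
#'   or `"gap"` to pick each mode's rank at the last spectral gap (eigenvalue
#'   ratio of at least 2) of the mode's initial scatter spectrum — the
#'   robust choice when beat-to-beat variation rides on a flat noise bulk.
#' @param p Number of ranked vectorised-core coordinates kept as the
#'   feature vector (default 10). When dims come from `variance_keep` they
#'   are enlarged if needed so at least `p` coordinates exist; explicit
#'   `dims` with fewer than `p` coordinates raise an error.
#' @param max_iter Maximum alternating sweeps (default 20).
#' @param tol Relative total-scatter change declaring convergence
#'   (default 1e-6).
#' @param center Centre samples by the mean tensor (default `TRUE`).
#'
#' @return An object of class `mpca_model`: projection matrices `U` (list of
#'   3), `mean_tensor`, `dims`, input `shape`, feature `ranking` (permutation
#'   of the vectorised core), `p`, per-coordinate `coord_scatter`,
#'   `scatter_history` (total scatter per recorded iteration, starting at
#'   initialisation), `total_scatter` of the centred data, and `n`.
#' @seealso [mpca_project()], [mpca_features()]
#' @export
fit_mpca <- function(tensors, variance_keep = 0.97, dims = NULL, p = 10,
                     max_iter = 20, tol = 1e-6, center = TRUE) {
  X <- as_tensor_batch(tensors)
  d <- dim(X)[1:3]
  N <- dim(X)[4]
  if (N < 2) stop_invalid("At least 2 tensors are required to fit MPCA.")
  if (!is_wholenumber(p) || p < 1) stop_invalid("`p` must be a positive whole number.")
  p <- as.integer(p)

  mean_tensor <- array(rowMeans(matrix(X, ncol = N)), dim = d)
  Xc <- if (center) X - array(mean_tensor, dim = dim(X)) else X
  total_scatter <- sum(Xc^2)

  # Full-projection initialisation: per-mode eigendecomposition of the
  # unfolding scatter of the centred samples.
  eigs <- lapply(1:3, function(k) {
    Xk <- unfold_mode(Xc, k)
    eigen(tcrossprod(Xk), symmetric = TRUE)
  })

  gap_dims <- is.character(dims) && identical(dims[1], "gap")
  if (gap_dims) {
    # Spectral-gap rank selection: keep eigenvalues up to the last ratio
    # gap of at least `gap_ratio`; with no clear gap the mode keeps full
    # rank. A retained-variance fraction degenerates on noise-dominated
    # (flat) spectra — it keeps nearly every dimension because the noise
    # bulk holds most of the mass — whereas the structured directions
    # stand above the bulk and are separated from it by a visible gap.
    gap_ratio <- 2
    dims <- vapply(seq_len(3), function(k) {
      ev <- pmax(eigs[[k]]$values, 0)
      if (length(ev) < 2 || sum(ev) == 0) return(1L)
      ratios <- ev[-length(ev)] / pmax(ev[-1], .Machine$double.eps)
      # Only gaps while the spectrum is still above the bulk level count;
      # ratio gaps between near-zero tail eigenvalues are meaningless.
      hit <- which(ratios >= gap_ratio & ev[-length(ev)] > mean(ev))
      if (length(hit)) max(hit) else length(ev)
    }, integer(1))
    while (prod(dims) < p) {
      nxt <- vapply(1:3, function(k) {
        if (dims[k] < d[k]) eigs[[k]]$values[dims[k] + 1] else -Inf
      }, numeric(1))
      if (all(!is.finite(nxt))) break
      k <- which.max(nxt)
      dims[k] <- dims[k] + 1L
    }
    if (p > prod(dims)) {
      stop_invalid(sprintf("p = %d exceeds the full core size (%d).", p, prod(dims)))
    }
  }
  if (gap_dims) {
    # dims already selected above
  } else if (!is.null(dims)) {
    dims <- as.integer(dims)
    if (length(dims) != 3 || any(dims < 1) || any(dims > d)) {
      stop_invalid(sprintf(
        "`dims` must give three values within the tensor shape (%s).",
        paste(d, collapse = " x ")
      ))
    }
    if (p > prod(dims)) {
      stop_invalid(sprintf(
        "p = %d exceeds the number of core coordinates (%d).", p, prod(dims)
      ))
    }
  } else {
    check_number(variance_keep, "variance_keep", 0, strict = TRUE)
    if (variance_keep > 1) stop_invalid("`variance_keep` must be in (0, 1].")
    dims <- vapply(eigs, function(e) {
      ev <- pmax(e$values, 0)
      if (sum(ev) == 0) return(1L)
      as.integer(which(cumsum(ev) / sum(ev) >= variance_keep - 1e-12)[1])
    }, integer(1))
    # Enlarge greedily (mode with the largest next eigenvalue) until the
    # core has at least p coordinates.
    while (prod(dims) < p) {
      nxt <- vapply(1:3, function(k) {
        if (dims[k] < d[k]) eigs[[k]]$values[dims[k] + 1] else -Inf
      }, numeric(1))
      if (all(!is.finite(nxt))) break
      k <- which.max(nxt)
      dims[k] <- dims[k] + 1L
    }
    if (p > prod(dims)) {
      stop_invalid(sprintf(
        "p = %d exceeds the full core size (%d).", p, prod(dims)
      ))
    }
  }

  core_all <- function(U) {
    S <- Xc
    for (k in 1:3) S <- mode_mult(S, t(U[[k]]), k)
    S
  }

  solve_dims <- function(dims, eigs) {
    U <- lapply(1:3, function(k) {
      fix_signs(eigs[[k]]$vectors[, seq_len(dims[k]), drop = FALSE])
    })
    history <- sum(core_all(U)^2)
    for (it in seq_len(max_iter)) {
      for (k in 1:3) {
        Y <- Xc
        for (j in setdiff(1:3, k)) Y <- mode_mult(Y, t(U[[j]]), j)
        Yk <- unfold_mode(Y, k)
        ek <- eigen(tcrossprod(Yk), symmetric = TRUE)
        U[[k]] <- fix_signs(ek$vectors[, seq_len(dims[k]), drop = FALSE])
        eigs[[k]] <- ek
      }
      history <- c(history, sum(core_all(U)^2))
      h <- length(history)
      if (abs(history[h] - history[h - 1]) <= tol * max(history[h - 1], .Machine$double.eps)) {
        break
      }
    }
    list(U = U, history = history, eigs = eigs)
  }

  repeat {
    fit <- solve_dims(dims, eigs)
    cores <- core_all(fit$U)
    vec_mat <- matrix(cores, nrow = prod(dims), ncol = N)
    coord_scatter <- rowSums(vec_mat^2)
    rk <- rank_coordinates(vec_mat, coord_scatter, p)
    # With gap-selected dims, grow the core until p *distinct* coordinates
    # exist: exact twin/zero coordinates (e.g. from the antisymmetry of
    # Gramian difference images) would otherwise pad the feature vector
    # with redundant entries.
    if (!gap_dims || rk$n_distinct >= p || all(dims >= d)) break
    nxt <- vapply(1:3, function(k) {
      if (dims[k] < d[k]) fit$eigs[[k]]$values[dims[k] + 1] else -Inf
    }, numeric(1))
    if (all(!is.finite(nxt))) break
    k <- which.max(nxt)
    dims[k] <- dims[k] + 1L
  }
  ranking <- rk$ranking
  history <- fit$history
  U <- fit$U

  structure(
    list(
      U = U,
      mean_tensor = mean_tensor,
      dims = dims,
      shape = d,
      ranking = ranking,
      p = p,
      coord_scatter = coord_scatter,
      scatter_history = history,
      total_scatter = total_scatter,
      center = center,
      n = N
    ),
    class = "mpca_model"
  )
}

# Rank vectorised-core coordinates by training scatter, descending, ties
# broken by coordinate index — but demote coordinates that (nearly)
# duplicate an already-ranked one. Antisymmetry of GADF images makes the
# mode-1 and mode-2 scatter matrices identical, so core coordinates come
# in +/- twin pairs (exact twins when the two mode bases coincide, near
# twins otherwise) plus zero diagonals; without this filter the twins
# would consume much of the p-feature budget while adding nothing (and
# make the feature covariance singular or ill-conditioned).
rank_coordinates <- function(vec_mat, coord_scatter, p, tol = 1e-10, dup_cor = 0.999) {
  base <- order(-coord_scatter, seq_along(coord_scatter))
  norms <- sqrt(coord_scatter)
  top <- max(norms, 1)
  kept <- integer(0)
  dropped <- integer(0)
  remaining <- base
  for (pos in seq_along(base)) {
    if (length(kept) >= p) {
      remaining <- base[pos:length(base)]
      break
    }
    remaining <- integer(0)
    i <- base[pos]
    if (norms[i] <= tol * top) {
      dropped <- c(dropped, i)
      next
    }
    dup <- FALSE
    for (j in kept) {
      co <- sum(vec_mat[i, ] * vec_mat[j, ]) / (norms[i] * norms[j])
      if (abs(co) >= dup_cor) {
        dup <- TRUE
        break
      }
    }
    if (dup) dropped <- c(dropped, i) else kept <- c(kept, i)
  }
  list(ranking = c(kept, remaining, dropped), n_distinct = length(kept))
}

as_tensor_batch <- function(tensors) {
  if (is.array(tensors) && length(dim(tensors)) == 4) {
    return(tensors)
  }
  if (!is.list(tensors) || length(tensors) == 0) {
    stop_invalid("`tensors` must be a non-empty list of 3-D arrays or a 4-D array.")
  }
  d <- dim(tensors[[1]])
  if (length(d) != 3) stop_invalid("Each tensor must be a 3-D array.")
  ok <- vapply(tensors, function(a) {
    length(dim(a)) == 3 && all(dim(a) == d)
  }, logical(1))
  if (!all(ok)) stop_invalid("All tensors must share one 3-D shape.")
  X <- array(0, dim = c(d, length(tensors)))
  for (i in seq_along(tensors)) X[, , , i] <- tensors[[i]]
  X
}

#' @export
print.mpca_model <- function(x, ...) {
  cat(sprintf(
    "<mpca_model> %s -> %s core (p = %d features), fit on %d tensors\n",
    paste(x$shape, collapse = " x "), paste(x$dims, collapse = " x "), x$p, x$n
  ))
  cat(sprintf(
    "retained scatter %.4f of total after %d sweep(s)\n",
    tail(x$scatter_history, 1) / x$total_scatter, length(x$scatter_history) - 1L
  ))
  invisible(x)
}

#' Project a tensor onto an MPCA model
#'
#' Subtracts the model's mean tensor, then multiplies each mode by the
#' transposed projection matrix, giving the `P1 x P2 x P3` core. Mode
#' multiplications commute, so the order is immaterial.
#'
#' @param model An `mpca_model`.
#' @param tensor 3-D array matching the model's input shape.
#' @return The core tensor (3-D array).
#' @export
mpca_project <- function(model, tensor) {
  stopifnot(inherits(model, "mpca_model"))
  if (length(dim(tensor)) != 3 || any(dim(tensor) != model$shape)) {
    stop_invalid(sprintf(
      "Tensor shape (%s) does not match the model's input shape (%s).",
      paste(dim(tensor), collapse = " x "), paste(model$shape, collapse = " x ")
    ))
  }
  S <- if (model$center) tensor - model$mean_tensor else tensor
  for (k in 1:3) S <- mode_mult(S, t(model$U[[k]]), k)
  S
}

#' Feature vectors from MPCA cores
#'
#' Vectorises each core (column-major), reorders the coordinates by the
#' model's scatter ranking, and keeps the first `p` — the 1-D feature
#' vector consumed by the one-class detectors and the control chart.
#'
#' @param model An `mpca_model`.
#' @param tensors A single 3-D tensor, a list of them, or a 4-D batch;
#'   cores are computed with [mpca_project()]. Alternatively a single core
#'   already matching `model$dims` is accepted.
#' @return Numeric matrix with one row per sample and `p` columns
#'   (`feat_1 .. feat_p`).
#' @export
mpca_features <- function(model, tensors) {
  stopifnot(inherits(model, "mpca_model"))
  if (is.array(tensors) && length(dim(tensors)) == 3) {
    tensors <- list(tensors)
  } else if (is.array(tensors) && length(dim(tensors)) == 4) {
    tensors <- lapply(seq_len(dim(tensors)[4]), function(i) tensors[, , , i])
  }
  keep <- model$ranking[seq_len(model$p)]
  out <- t(vapply(tensors, function(a) {
    core <- if (all(dim(a) == model$dims) && !all(model$dims == model$shape)) {
      a # already a core
    } else {
      mpca_project(model, a)
    }
    as.numeric(core)[keep]
  }, numeric(model$p)))
  colnames(out) <- paste0("feat_", seq_len(model$p))
  out
}

#' Vectorise and rank a single core
#'
#' Low-level variant of [mpca_features()] for one already-projected core:
#' vectorise, reorder by the model's ranking, truncate to `p` entries.
#'
#' @param model An `mpca_model`.
#' @param core Core tensor with shape `model$dims`.
#' @return Numeric vector of length `model$p`.
#' @export
mpca_featurize_core <- function(model, core) {
  stopifnot(inherits(model, "mpca_model"))
  if (length(dim(core)) != 3 || any(dim(core) != model$dims)) {
    stop_invalid(sprintf(
      "Core shape (%s) does not match the model's core shape (%s).",
      paste(dim(core), collapse = " x "), paste(model$dims, collapse = " x ")
    ))
  }
  as.numeric(core)[model$ranking[seq_len(model$p)]]
}

#' @describeIn fit_mpca Tidy summary: one row per ranked core coordinate
#'   with its mode indices, scatter and scatter share.
#' @param x,object An `mpca_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mpca_model <- function(x, ...) {
  idx <- arrayInd(x$ranking, x$dims)
  tibble::tibble(
    rank = seq_along(x$ranking),
    coord = x$ranking,
    mode1 = idx[, 1], mode2 = idx[, 2], mode3 = idx[, 3],
    scatter = x$coord_scatter[x$ranking],
    scatter_share = x$coord_scatter[x$ranking] / sum(x$coord_scatter),
    kept = seq_along(x$ranking) <= x$p
  )
}

#' @describeIn fit_mpca One-row model summary (dims, retained scatter,
#'   sweeps, convergence).
#' @exportS3Method generics::glance
glance.mpca_model <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    p = x$p,
    dim1 = x$dims[1], dim2 = x$dims[2], dim3 = x$dims[3],
    total_scatter = x$total_scatter,
    retained_scatter = tail(x$scatter_history, 1),
    retained_fraction = tail(x$scatter_history, 1) / x$total_scatter,
    sweeps = length(x$scatter_history) - 1L
  )
}
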