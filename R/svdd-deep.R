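#' Fit a deep SVDD on normal feature vectors
#'
#' Trains a small bias-free multilayer perceptron `phi(.; W)` so that the
#' mapped training (normal) features cluster around a fixed centre `c` in
#' latent space, by minimising
#'
#' \deqn{\frac{1}{N_0}\sum_i \|\phi(\vartheta^{(i)}; W) - c\|^2 +
#'   \frac{\lambda}{2}\sum_l \|W_l\|_F^2}
#'
#' with mini-batch stochastic gradient descent. The centre is set once,
#' before training, to the mean of the untrained network's outputs over the
#' training set (entries with magnitude below `center_floor` pushed out to
#' `±center_floor` to avoid a trivially reachable centre), and is never
#' updated by gradient steps. The network has no bias parameters and no
#' bounded output activation — both would admit the collapsed solution
#' `phi == c`. Hidden layers use a leaky rectifier. All randomness
#' (weight initialisation, batch shuffling) flows from `seed`, so refits
#' are bit-identical.
#'
#' Features are standardised per dimension using training statistics
#' stored in the model (disable with `standardize = FALSE`). The anomaly
#' score of a vector is its squared latent distance to the centre; the
#' stored decision threshold is the `(1 - alpha)` quantile of the training
#' scores.
#'
#' @param features Numeric matrix, one row per training sample.
#' @param hidden Integer vector of hidden-layer widths; `integer(0)` gives
#'   a single linear map.
#' @param weights Optional list of initial weight matrices (each
#'   `out x in`), e.g. `list(diag(p))` for a fixed identity network.
#' @param epochs Training epochs (0 skips training, keeping the initial
#'   weights).
#' @param batch_size Mini-batch size.
#' @param lr Learning rate; multiplied by 0.1 once, at epoch
#'   `lr_decay_epoch`.
#' @param lr_decay_epoch Epoch at which the single learning-rate decay
#'   happens.
#' @param lambda Weight-decay coefficient.
#' @param leak Negative-slope of the leaky rectifier.
#' @param alpha Significance level for the stored score threshold.
#' @param standardize Standardise features with training mean/sd.
#' @param center_floor Minimum magnitude of each centre entry (applied only
#'   when training steps occur).
#' @param seed Integer seed.
#'
#' @return An object of class `deep_svdd`: `weights`, `center`, `leak`,
#'   standardisation stats, `threshold`, `alpha`, training `objective`
#'   history (initial value first), `training_scores`, and the config.
#' @seealso [score_anomaly()]
#' @export
fit_deep_svdd <- function(features,
                          hidden = c(32, 16),
                          weights = NULL,
                          epochs = 300,
                          batch_size = 64,
                          lr = 2e-3,
                          lr_decay_epoch = 200,
                          lambda = 1e-6,
                          leak = 0.1,
                          alpha = 0.05,
                          standardize = TRUE,
                          center_floor = 0.1,
                          seed = 1L) {
  X <- as.matrix(features)
  if (anyNA(X) || any(!is.finite(X))) stop_invalid("Features must be finite.")
  N <- nrow(X)
  if (N < 2) stop_invalid("At least 2 training samples are required.")
  p <- ncol(X)

  mu <- if (standardize) colMeans(X) else rep(0, p)
  sdv <- if (standardize) apply(X, 2, sd) else rep(1, p)
  sdv[sdv == 0] <- 1
  Xs <- t((t(X) - mu) / sdv) # N x p

  # Layer widths: input p, then the hidden widths; the last hidden layer is
  # the latent space. With no hidden layers the network is one linear map p -> p.
  sizes <- c(p, if (length(hidden)) hidden else p)

  model <- withr::with_seed(as.integer(seed), {
    if (is.null(weights)) {
      W <- lapply(seq_len(length(sizes) - 1), function(l) {
        fan_in <- sizes[l]
        matrix(rnorm(sizes[l + 1] * fan_in, 0, sqrt(2 / fan_in)),
          nrow = sizes[l + 1], ncol = fan_in)
      })
    } else {
      W <- lapply(weights, as.matrix)
      if (ncol(W[[1]]) != p) stop_invalid("First weight matrix must have `p` columns.")
    }
    L <- length(W)

    forward <- function(W, Xmat) { # Xmat: p x B; returns latent out x B
      a <- Xmat
      for (l in seq_len(L)) {
        z <- W[[l]] %*% a
        a <- if (l < L) ifelse(z > 0, z, leak * z) else z
      }
      a
    }

    Xt <- t(Xs) # p x N
    out0 <- forward(W, Xt)
    cvec <- rowMeans(out0)
    if (epochs > 0 && center_floor > 0) {
      small <- abs(cvec) < center_floor
      cvec[small] <- ifelse(cvec[small] >= 0, center_floor, -center_floor)
    }

    objective <- function(W) {
      out <- forward(W, Xt)
      mean(colSums((out - cvec)^2)) + lambda / 2 * sum(vapply(W, function(w) sum(w^2), numeric(1)))
    }

    obj_history <- objective(W)
    if (epochs > 0) {
      rate <- lr
      for (ep in seq_len(epochs)) {
        if (ep == lr_decay_epoch) rate <- rate * 0.1
        perm <- sample.int(N)
        for (start in seq(1, N, by = batch_size)) {
          idx <- perm[start:min(start + batch_size - 1, N)]
          B <- length(idx)
          a <- vector("list", L + 1)
          z <- vector("list", L)
          a[[1]] <- Xt[, idx, drop = FALSE]
          for (l in seq_len(L)) {
            z[[l]] <- W[[l]] %*% a[[l]]
            a[[l + 1]] <- if (l < L) ifelse(z[[l]] > 0, z[[l]], leak * z[[l]]) else z[[l]]
          }
          delta <- 2 * (a[[L + 1]] - cvec) / B
          for (l in rev(seq_len(L))) {
            grad <- tcrossprod(delta, a[[l]]) + lambda * W[[l]]
            if (l > 1) {
              delta <- (t(W[[l]]) %*% delta) * ifelse(z[[l - 1]] > 0, 1, leak)
            }
            W[[l]] <- W[[l]] - rate * grad
          }
        }
        obj_history <- c(obj_history, objective(W))
      }
    }

    train_scores <- colSums((forward(W, Xt) - cvec)^2)
    list(W = W, cvec = cvec, obj_history = obj_history, train_scores = train_scores)
  })

  structure(
    list(
      weights = model$W,
      center = model$cvec,
      leak = leak,
      mu = mu,
      sdv = sdv,
      standardize = standardize,
      lambda = lambda,
      alpha = alpha,
      threshold = unname(quantile(model$train_scores, 1 - alpha, type = 7)),
      objective = model$obj_history,
      training_scores = model$train_scores,
      config = list(
        hidden = hidden, epochs = epochs, batch_size = batch_size, lr = lr,
        lr_decay_epoch = lr_decay_epoch, center_floor = center_floor, seed = seed
      ),
      n = N
    ),
    class = "deep_svdd"
  )
}

#' @export
print.deep_svdd <- function(x, ...) {
  widths <- c(ncol(x$weights[[1]]), vapply(x$weights, nrow, integer(1)))
  cat(sprintf(
    "<deep_svdd> network %s (no biases), trained on %d samples\n",
    paste(widths, collapse = " -> "), x$n
  ))
  cat(sprintf(
    "objective %.6g -> %.6g over %d epochs; threshold %.4g (alpha = %g)\n",
    x$objective[1], tail(x$objective, 1), length(x$objective) - 1L, x$threshold, x$alpha
  ))
  invisible(x)
}

deep_svdd_forward <- function(model, X) {
  Xs <- t((t(as.matrix(X)) - model$mu) / model$sdv)
  a <- t(Xs)
  L <- length(model$weights)
  for (l in seq_len(L)) {
    z <- model$weights[[l]] %*% a
    a <- if (l < L) ifelse(z > 0, z, model$leak * z) else z
  }
  a
}

#' @describeIn fit_deep_svdd One-row fit summary (objective decrease,
#'   threshold, config).
#' @param x An object returned by `fit_deep_svdd()`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.deep_svdd <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    latent_dim = length(x$center),
    epochs = length(x$objective) - 1L,
    objective_initial = x$objective[1],
    objective_final = tail(x$objective, 1),
    threshold = x$threshold,
    alpha = x$alpha
  )
}

#' Score feature vectors for abnormality
#'
#' Generic scorer for the fitted one-class models. For a deep SVDD the
#' score is the squared latent distance of the network output to the fixed
#' centre; for a classic SVDD it is the Gaussian-kernel squared distance to
#' the hypersphere centre. A sample is flagged anomalous when its score
#' exceeds the model's stored threshold (the `(1 - alpha)` training-score
#' quantile for deep SVDD; the squared radius `R^2` for classic SVDD),
#' unless an explicit `threshold` is supplied. Scoring is stateless: each
#' row is scored independently of the others in the batch.
#'
#' @param model A fitted `deep_svdd` or `classic_svdd`.
#' @param features Numeric matrix (rows are samples) or a single vector.
#' @param threshold Optional threshold override.
#' @param ... Method-specific arguments (unused).
#' @return A tibble with columns `score`, `threshold`, `is_anomaly`.
#' @export
score_anomaly <- function(model, features, threshold = NULL, ...) {
  UseMethod("score_anomaly")
}

#' @export
score_anomaly.deep_svdd <- function(model, features, threshold = NULL, ...) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1) else as.matrix(features)
  if (ncol(X) != ncol(model$weights[[1]])) {
    stop_invalid(sprintf(
      "Feature length %d does not match the model input width %d.",
      ncol(X), ncol(model$weights[[1]])
    ))
  }
  out <- deep_svdd_forward(model, X)
  sc <- colSums((out - model$center)^2)
  thr <- threshold %||% model$threshold
  tibble::tibble(score = unname(sc), threshold = thr, is_anomaly = sc > thr)
}

#' @export
score_anomaly.classic_svdd <- function(model, features, threshold = NULL, ...) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1) else as.matrix(features)
  if (ncol(X) != ncol(model$X)) {
    stop_invalid(sprintf(
      "Feature length %d does not match the model input width %d.",
      ncol(X), ncol(model$X)
    ))
  }
  sc <- svdd_dist2(model, X)
  thr <- threshold %||% model$R2
  tibble::tibble(score = unname(sc), threshold = thr, is_anomaly = sc > thr)
}
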