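# Shared fixtures for the test suite; everything is generated in code.

quiet_spec <- function(...) {
  beat_template(noise_sd = 0, period_jitter_sd = 0, ...)
}

# Gaussian feature cluster with a fixed seed.
feature_cluster <- function(n, p, center = rep(0, p), sd = 1, seed = 1) {
  withr::with_seed(seed, {
    matrix(rnorm(n * p, 0, sd), n, p) + matrix(center, n, p, byrow = TRUE)
  })
}

# Random list of small 3-D tensors.
random_tensors <- function(n, d, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) array(rnorm(prod(d)), dim = d))
  })
}

# Elementwise GADF oracle: the definition as a double loop over angles.
gadf_oracle <- function(x) {
  phi <- acos(pmin(pmax(x, 0), 1))
  M <- length(x)
  G <- matrix(0, M, M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      G[i, j] <- sin(phi[i] - phi[j])
    }
  }
  G
}

# Brute-force SVDD dual objective over a simplex grid (3 points), refined
# around the coarse optimum.
svdd_grid_oracle <- function(K, gamma, step = 2e-3, refine = 1e-4) {
  objective <- function(a) drop(t(a) %*% K %*% a) - sum(a * diag(K))
  best <- NULL
  best_val <- Inf
  scan <- function(a1s, a2s) {
    for (a1 in a1s) {
      for (a2 in a2s) {
        a3 <- 1 - a1 - a2
        if (a3 < 0 || a3 > gamma || a1 > gamma || a2 > gamma) next
        v <- objective(c(a1, a2, a3))
        if (v < best_val) {
          best_val <<- v
          best <<- c(a1, a2, a3)
        }
      }
    }
  }
  scan(seq(0, min(1, gamma), by = step), seq(0, min(1, gamma), by = step))
  scan(
    seq(max(0, best[1] - step), min(gamma, best[1] + step), by = refine),
    seq(max(0, best[2] - step), min(gamma, best[2] + step), by = refine)
  )
  best
}

# Brute-force AUROC: concordant pairs count with ties worth one half.
auroc_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (sp in pos) {
    for (sn in neg) {
      total <- total + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  total / (length(pos) * length(neg))
}
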