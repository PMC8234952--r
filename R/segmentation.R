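#' Detect R peaks with a squared-derivative envelope
#'
#' A deliberately simple detector for beat segmentation: the squared first
#' difference of the chosen lead is smoothed with a short moving average,
#' an adaptive threshold `median + k * MAD` of the envelope marks candidate
#' regions, local envelope maxima above the threshold are snapped to the
#' nearby signal maximum, and peaks closer than the refractory period are
#' pruned keeping the larger amplitude. The threshold is scale-covariant, so
#' rescaling a lead by a positive gain leaves the detected indices unchanged.
#' When the record carries beat annotations those should be preferred
#' (see [beat_r_centers()]); this detector is plumbing for unannotated data.
#'
#' @param record An `ecg_record`.
#' @param lead Lead name or index used for detection.
#' @param refractory_s Minimum separation between peaks (seconds, > 0).
#' @param k_mad Threshold multiplier on the MAD of the envelope.
#' @param smooth_s Moving-average window for the envelope (seconds).
#' @param search_s Half-width of the window in which a candidate is snapped
#'   to the signal maximum (seconds).
#'
#' @return Sorted integer vector of 1-based peak sample indices (possibly
#'   empty, e.g. for a flat signal).
#' @export
detect_r_peaks <- function(record, lead = 1, refractory_s = 0.25,
                           k_mad = 6, smooth_s = 0.04, search_s = 0.05) {
  stopifnot(inherits(record, "ecg_record"))
  check_number(refractory_s, "refractory_s", 0, strict = TRUE)
  x <- record$samples[, lead]
  n <- length(x)
  if (n < 3 || var(x) == 0) {
    return(integer(0))
  }
  moving_avg <- function(v, w) {
    if (w <= 1) return(v)
    sm <- stats::filter(v, rep(1 / w, w), sides = 2)
    as.numeric(ifelse(is.na(sm), 0, sm))
  }
  # Pre-smooth before differencing: differentiation amplifies white noise
  # far more than the QRS slope, so a short moving average first is what
  # makes the squared-derivative envelope usable at realistic noise levels.
  xs <- moving_avg(x, max(1L, as.integer(round(0.01 * record$sample_rate))))
  env <- moving_avg(
    c(0, diff(xs)^2),
    max(1L, as.integer(round(smooth_s * record$sample_rate)))
  )
  # Adaptive threshold; both terms scale with the square of a lead gain, so
  # detection is invariant to positive rescaling.
  thr <- median(env) + k_mad * mad(env)
  above <- env > thr & env > 0
  if (!any(above)) {
    return(integer(0))
  }
  is_max <- above &
    env >= c(-Inf, env[-n]) &
    env >= c(env[-1], -Inf)
  cand <- which(is_max)
  half <- max(1L, as.integer(round(search_s * record$sample_rate)))
  snapped <- vapply(cand, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    lo + which.max(xs[lo:hi]) - 1L
  }, integer(1))
  snapped <- unique(snapped)
  # Enforce the refractory period, keeping the taller peak.
  ord <- snapped[order(-xs[snapped], snapped)]
  min_gap <- refractory_s * record$sample_rate
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  sort(kept)
}

#' R-wave centres of a record
#'
#' Returns annotated beat positions when the record carries annotations
#' (synthetic ground truth or a WFDB annotation file), otherwise falls back
#' to [detect_r_peaks()].
#'
#' @param record An `ecg_record`.
#' @param ... Passed to [detect_r_peaks()] when detection is needed.
#' @return Sorted integer vector of R-centre sample indices.
#' @export
beat_r_centers <- function(record, ...) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.null(record$annotations) && nrow(record$annotations) > 0) {
    return(sort(as.integer(record$annotations$sample)))
  }
  detect_r_peaks(record, ...)
}

#' Segment a record into fixed-window beat cycles
#'
#' Cuts a window of `pre_s` seconds before to `post_s` seconds after each R
#' peak (a half-open window of fixed sample count), drops windows that cross
#' the record edges, and linearly resamples every lead of each window to a
#' common length `out_len` so cycles are commensurable across heart rates.
#' When `out_len` equals the native window length the resampling is the
#' identity. Cycle labels are taken from the record's annotations when the
#' annotation sample falls inside the window.
#'
#' @param record An `ecg_record`.
#' @param r_peaks Integer R-peak sample indices (e.g. [beat_r_centers()]).
#' @param pre_s,post_s Window extent before/after the R peak (seconds, > 0).
#' @param out_len Common output length per lead (at least 8). The default
#'   (`NULL`) keeps the native window length, leaving any length reduction
#'   to the imaging stage's block-averaging ([paa()]), which also averages
#'   out sample noise; interpolation here is only needed to reconcile
#'   differing sampling rates.
#'
#' @return List of `ecg_cycle` objects, each a list with `record_id`,
#'   `cycle_index`, `samples` (out_len x leads matrix) and `label`.
#' @export
segment_cycles <- function(record, r_peaks = beat_r_centers(record),
                           pre_s = 0.25, post_s = 0.45, out_len = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  check_number(pre_s, "pre_s", 0, strict = TRUE)
  check_number(post_s, "post_s", 0, strict = TRUE)
  fs <- record$sample_rate
  pre_n <- as.integer(round(pre_s * fs))
  win_n <- as.integer(round((pre_s + post_s) * fs))
  if (is.null(out_len)) out_len <- win_n
  if (!is_wholenumber(out_len) || out_len < 8) {
    stop_invalid("`out_len` must be a whole number >= 8.")
  }
  out_len <- as.integer(out_len)
  n <- nrow(record$samples)
  r_peaks <- as.integer(sort(r_peaks))

  grid_in <- seq(0, 1, length.out = win_n)
  grid_out <- seq(0, 1, length.out = out_len)
  ann <- record$annotations

  cycles <- list()
  idx <- 0L
  for (r in r_peaks) {
    start <- r - pre_n
    end <- start + win_n - 1L
    if (start < 1L || end > n) next # edge window dropped
    idx <- idx + 1L
    win <- record$samples[start:end, , drop = FALSE]
    out <- if (out_len == win_n) {
      win
    } else {
      apply(win, 2, function(col) approx(grid_in, col, xout = grid_out)$y)
    }
    colnames(out) <- colnames(record$samples)
    label <- NULL
    if (!is.null(ann)) {
      hit <- which(ann$sample >= start & ann$sample <= end)
      if (length(hit)) label <- ann$label[hit[which.min(abs(ann$sample[hit] - r))]]
    }
    cycles[[idx]] <- structure(
      list(
        record_id = record$record_id,
        cycle_index = idx,
        samples = out,
        label = label
      ),
      class = "ecg_cycle"
    )
  }
  cycles
}

#' @export
print.ecg_cycle <- function(x, ...) {
  cat(sprintf(
    "<ecg_cycle> #%d from '%s': %d leads x %d samples%s\n",
    x$cycle_index, x$record_id, ncol(x$samples), nrow(x$samples),
    if (is.null(x$label)) "" else sprintf(" [%s]", x$label)
  ))
  invisible(x)
}

#' Ensemble (average) cycle of a recording
#'
#' The per-lead, per-sample arithmetic mean of a set of equal-length
#' cycles — the single representative beat used when one sample per
#' recording is analysed.
#'
#' @param cycles Non-empty list of equal-shape `ecg_cycle` objects.
#' @param label Optional label for the ensemble (defaults to the most
#'   frequent cycle label, if any).
#' @return An `ecg_cycle` with `cycle_index = 0`.
#' @export
ensemble_cycle <- function(cycles, label = NULL) {
  if (!is.list(cycles) || length(cycles) == 0) {
    stop_invalid("`cycles` must be a non-empty list of ecg_cycle objects.")
  }
  stopifnot(all(vapply(cycles, inherits, logical(1), "ecg_cycle")))
  dims <- vapply(cycles, function(c) dim(c$samples), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_invalid("All cycles must have the same length and lead count.")
  }
  acc <- Reduce(`+`, lapply(cycles, `[[`, "samples")) / length(cycles)
  if (is.null(label)) {
    labs <- unlist(lapply(cycles, `[[`, "label"))
    if (length(labs)) label <- names(sort(table(labs), decreasing = TRUE))[1]
  }
  structure(
    list(
      record_id = cycles[[1]]$record_id,
      cycle_index = 0L,
      samples = acc,
      label = label
    ),
    class = "ecg_cycle"
  )
}
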