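#' Parametric heartbeat template
#'
#' A single ECG beat is modelled as a sum of five Gaussian deflections
#' (P, Q, R, S, T waves), each with an amplitude in millivolts, a centre
#' expressed as a fraction of the beat interval, and a width on the same
#' fractional scale. An additive ST-segment shift (a plateau between the end
#' of the S wave and the start of the T wave, entered and left through smooth
#' half-cosine ramps) models ST elevation or depression. The template also
#' carries the rhythm parameters used by [synthesize_stream()]: mean beat
#' period, beat-to-beat period jitter, and additive measurement noise.
#'
#' Defaults describe a plausible resting sinus beat at 75 bpm; see the
#' package vignette for how each value was chosen.
#'
#' @param amplitudes Named numeric vector of wave amplitudes (mV) for
#'   `P`, `Q`, `R`, `S`, `T`.
#' @param centers Named numeric vector of wave centres as fractions of the
#'   beat in `[0, 1]`, strictly increasing in the order P < Q < R < S < T.
#' @param widths Named numeric vector of positive wave widths (fraction of
#'   the beat).
#' @param baseline Baseline offset (mV).
#' @param st_shift ST-segment shift (mV); positive for elevation, negative
#'   for depression.
#' @param beat_period Mean beat-to-beat interval (seconds).
#' @param period_jitter_sd Standard deviation of the per-beat period
#'   (seconds).
#' @param noise_sd Standard deviation of additive Gaussian measurement noise
#'   per lead (mV).
#'
#' @return An object of class `beat_template`.
#' @seealso [morph_template()], [make_beat()], [synthesize_stream()]
#' @export
#' @examples
#' spec <- beat_template()
#' beat <- make_beat(spec, 400)
#' plot(beat, type = "l")
beat_template <- function(amplitudes = c(P = 0.15, Q = -0.1, R = 1.1, S = -0.2, T = 0.3),
                          centers = c(P = 0.18, Q = 0.38, R = 0.42, S = 0.46, T = 0.70),
                          widths = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.010, T = 0.050),
                          baseline = 0,
                          st_shift = 0,
                          beat_period = 0.8,
                          period_jitter_sd = 0.02,
                          noise_sd = 0.05) {
  waves <- c("P", "Q", "R", "S", "T")
  amplitudes <- amplitudes[waves]
  centers <- centers[waves]
  widths <- widths[waves]
  if (anyNA(amplitudes) || anyNA(centers) || anyNA(widths)) {
    stop_invalid("`amplitudes`, `centers` and `widths` must all name the waves P, Q, R, S, T.",
      class = "tensorecg_invalid_spec")
  }
  if (any(widths <= 0)) {
    stop_invalid("All wave widths must be strictly positive.",
      class = "tensorecg_invalid_spec")
  }
  if (any(diff(centers) <= 0)) {
    stop_invalid("Wave centers must be strictly increasing in the order P < Q < R < S < T.",
      class = "tensorecg_invalid_spec")
  }
  check_number(beat_period, "beat_period", 0, strict = TRUE)
  check_number(period_jitter_sd, "period_jitter_sd", 0)
  check_number(noise_sd, "noise_sd", 0)
  structure(
    list(
      amplitudes = amplitudes, centers = centers, widths = widths,
      baseline = baseline, st_shift = st_shift,
      beat_period = beat_period, period_jitter_sd = period_jitter_sd,
      noise_sd = noise_sd
    ),
    class = "beat_template"
  )
}

#' @export
print.beat_template <- function(x, ...) {
  cat("<beat_template>\n")
  tab <- rbind(amplitude_mV = x$amplitudes, center = x$centers, width = x$widths)
  print(round(tab, 4))
  cat(sprintf(
    "baseline %g mV | ST shift %g mV | period %g s (jitter sd %g s) | noise sd %g mV\n",
    x$baseline, x$st_shift, x$beat_period, x$period_jitter_sd, x$noise_sd
  ))
  invisible(x)
}

#' Disease morphology labels
#'
#' The morph labels understood by [morph_template()] and
#' [synthesize_stream()]. Each label is a deterministic transformation of a
#' base [beat_template()], emulating a hallmark of a cardiac condition:
#'
#' * `NORMAL` — the base template, unchanged.
#' * `AF_LIKE` — atrial-fibrillation-like: P-wave amplitude set to zero and
#'   beat-to-beat period jitter elevated (irregular RR intervals).
#' * `BBB_LIKE` — bundle-branch-block-like: Q/R/S widths scaled up and the
#'   R amplitude scaled down (wide, blunted QRS).
#' * `STD_LIKE` / `STE_LIKE` — ST-segment depression / elevation.
#' * `TINV_LIKE` — inverted T wave (T amplitude negated).
#' * `PREMATURE` — a premature beat: BBB-like shape with a shortened
#'   preceding inter-beat interval (handled by [synthesize_stream()]).
#'
#' @return Character vector of the recognised labels.
#' @export
morph_labels <- function() {
  c("NORMAL", "AF_LIKE", "BBB_LIKE", "STD_LIKE", "STE_LIKE", "TINV_LIKE", "PREMATURE")
}

#' Apply a disease morph to a beat template
#'
#' Deterministically transforms a base template according to a morph label;
#' see [morph_labels()] for the transformations.
#'
#' @param spec A [beat_template()].
#' @param label One of [morph_labels()].
#' @param st_shift_mV Magnitude of the ST shift used for `STD_LIKE` /
#'   `STE_LIKE` (mV).
#' @param qrs_width_factor QRS widening factor for `BBB_LIKE` / `PREMATURE`.
#' @param r_amplitude_factor R-amplitude scaling for `BBB_LIKE` / `PREMATURE`.
#' @param af_jitter_sd Elevated period jitter (seconds) for `AF_LIKE`.
#'
#' @return A transformed `beat_template`.
#' @export
morph_template <- function(spec, label,
                           st_shift_mV = 0.15,
                           qrs_width_factor = 1.8,
                           r_amplitude_factor = 0.6,
                           af_jitter_sd = 0.12) {
  stopifnot(inherits(spec, "beat_template"))
  label <- match.arg(label, morph_labels())
  out <- spec
  if (label %in% c("BBB_LIKE", "PREMATURE")) {
    out$widths[c("Q", "R", "S")] <- out$widths[c("Q", "R", "S")] * qrs_width_factor
    out$amplitudes["R"] <- out$amplitudes["R"] * r_amplitude_factor
  }
  switch(label,
    NORMAL = ,
    BBB_LIKE = ,
    PREMATURE = NULL,
    AF_LIKE = {
      out$amplitudes["P"] <- 0
      out$period_jitter_sd <- af_jitter_sd
    },
    STD_LIKE = {
      out$st_shift <- -abs(st_shift_mV)
    },
    STE_LIKE = {
      out$st_shift <- abs(st_shift_mV)
    },
    TINV_LIKE = {
      out$amplitudes["T"] <- -out$amplitudes["T"]
    }
  )
  out
}

# ST-shift weight profile on the fractional time grid t in [0,1]:
# 0 before the ramp-in, half-cosine ramps of width `ramp`, exactly 1 on the
# plateau [st_start, st_end] (so interval means are exact), 0 after ramp-out.
st_weight <- function(t, spec, ramp = 0.03) {
  lim <- st_interval(spec)
  w <- numeric(length(t))
  up <- t >= (lim[1] - ramp) & t < lim[1]
  w[up] <- 0.5 * (1 - cos(pi * (t[up] - (lim[1] - ramp)) / ramp))
  w[t >= lim[1] & t <= lim[2]] <- 1
  dn <- t > lim[2] & t <= (lim[2] + ramp)
  w[dn] <- 0.5 * (1 + cos(pi * (t[dn] - lim[2]) / ramp))
  w
}

#' ST-segment plateau of a beat template
#'
#' The fractional interval between the end of the S wave and the start of
#' the T wave (each taken at two wave widths from the wave centre) over which
#' the template's `st_shift` is applied at full amplitude. Used by tests and
#' by analyses that measure ST deviation on generated beats.
#'
#' @param spec A [beat_template()].
#' @return Numeric length-2 vector `c(start, end)` in beat fractions.
#' @export
st_interval <- function(spec) {
  stopifnot(inherits(spec, "beat_template"))
  c(
    unname(spec$centers["S"] + 2 * spec$widths["S"]),
    unname(spec$centers["T"] - 2 * spec$widths["T"])
  )
}

#' Render one noiseless beat from a template
#'
#' Evaluates the template on `n_samples` points uniformly spaced over the
#' beat, `t_i = (i - 1) / n_samples`: the sum over the five waves of
#' `amplitude * exp(-(t - center)^2 / (2 width^2))`, plus the baseline, plus
#' the ST shift over the ST plateau (with half-cosine ramps). Deterministic;
#' noise and period jitter are applied only by [synthesize_stream()].
#'
#' @param spec A [beat_template()].
#' @param n_samples Number of samples (at least 8).
#' @return Numeric vector of length `n_samples` (mV).
#' @export
make_beat <- function(spec, n_samples) {
  stopifnot(inherits(spec, "beat_template"))
  if (!is_wholenumber(n_samples) || n_samples < 8) {
    stop_invalid("`n_samples` must be a whole number >= 8.")
  }
  n_samples <- as.integer(n_samples)
  t <- (seq_len(n_samples) - 1) / n_samples
  y <- rep(spec$baseline, n_samples)
  for (w in names(spec$amplitudes)) {
    y <- y + spec$amplitudes[[w]] *
      exp(-(t - spec$centers[[w]])^2 / (2 * spec$widths[[w]]^2))
  }
  if (spec$st_shift != 0) {
    y <- y + spec$st_shift * st_weight(t, spec)
  }
  y
}
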