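#' Synthesize a multi-lead ECG stream with known beat labels
#'
#' Concatenates one beat per entry of `labels`, each rendered from the base
#' template transformed by its morph label ([morph_template()]). The i-th
#' beat occupies `round(fs * period_i)` samples, where
#' `period_i ~ Normal(beat_period, period_jitter_sd^2)` (truncated below at
#' a fifth of the mean period) using the jitter of the morphed template, so
#' `AF_LIKE` beats are irregular. A `PREMATURE` label shortens the interval
#' of the *preceding* beat by `premature_factor`. Each lead is
#' `gain * waveform + Normal(0, noise_sd^2)` noise, drawn independently per
#' lead. All randomness flows from one generator seeded with `seed`, so
#' equal inputs give bit-identical streams.
#'
#' Ground truth is recorded: beat onsets (1-based sample index of each
#' beat's first sample), per-beat labels, and the R-wave centre sample of
#' each beat.
#'
#' @param spec Base [beat_template()].
#' @param labels Character vector of morph labels, one per beat
#'   (see [morph_labels()]).
#' @param sample_rate Sampling rate in Hz (default 500, the usual rate of
#'   clinical 12-lead recorders).
#' @param lead_gains Numeric vector of per-lead gain factors; its length
#'   sets the number of leads.
#' @param seed Integer seed controlling all random draws.
#' @param premature_factor Shortening factor applied to the interval
#'   preceding a `PREMATURE` beat.
#' @param ... Morph parameters forwarded to [morph_template()].
#'
#' @return An object of class `ecg_stream`: a list with `sample_rate`,
#'   `lead_gains`, `samples` (numeric matrix, samples x leads), and
#'   ground-truth `beat_onsets`, `beat_labels`, `r_centers`, `seed`.
#' @export
#' @examples
#' stream <- synthesize_stream(beat_template(), rep("NORMAL", 5), seed = 1)
#' dim(stream$samples)
synthesize_stream <- function(spec, labels,
                              sample_rate = 500,
                              lead_gains = c(1, 0.8, 0.6),
                              seed = 1L,
                              premature_factor = 0.6,
                              ...) {
  stopifnot(inherits(spec, "beat_template"))
  if (length(labels) == 0) {
    stop_invalid("`labels` must contain at least one beat label.",
      class = "tensorecg_invalid_spec")
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), morph_labels())
  if (length(bad)) {
    stop_invalid(paste0("Unknown morph label(s): ", paste(bad, collapse = ", ")),
      class = "tensorecg_invalid_spec")
  }
  check_number(sample_rate, "sample_rate", 0, strict = TRUE)
  if (length(lead_gains) == 0 || !is.numeric(lead_gains)) {
    stop_invalid("`lead_gains` must be a non-empty numeric vector.",
      class = "tensorecg_invalid_spec")
  }

  n_beats <- length(labels)
  specs <- lapply(labels, function(l) morph_template(spec, l, ...))

  withr::with_seed(as.integer(seed), {
    periods <- vapply(specs, function(s) {
      p <- s$beat_period + (if (s$period_jitter_sd > 0) rnorm(1, 0, s$period_jitter_sd) else 0)
      max(p, 0.2 * s$beat_period)
    }, numeric(1))
    # A premature beat steals time from the preceding interval.
    for (i in which(labels == "PREMATURE")) {
      if (i > 1) periods[i - 1] <- periods[i - 1] * premature_factor
    }
    # Wave timing is rendered at the template's nominal period and the
    # jittered period only stretches or clips the diastolic tail: RR
    # variability in a real heart mostly changes the pause between beats,
    # not the QRS/T timing relative to R.
    n_samp <- pmax(8L, as.integer(round(periods * sample_rate)))
    onsets <- cumsum(c(1L, head(n_samp, -1L)))
    waveform <- unlist(lapply(seq_len(n_beats), function(i) {
      n_nom <- max(8L, as.integer(round(specs[[i]]$beat_period * sample_rate)))
      beat <- make_beat(specs[[i]], n_nom)
      n_i <- n_samp[i]
      if (n_i >= n_nom) {
        c(beat, rep(specs[[i]]$baseline, n_i - n_nom))
      } else {
        beat[seq_len(n_i)]
      }
    }), use.names = FALSE)
    r_centers <- onsets + vapply(seq_len(n_beats), function(i) {
      n_nom <- max(8L, as.integer(round(specs[[i]]$beat_period * sample_rate)))
      as.integer(round(specs[[i]]$centers[["R"]] * n_nom))
    }, integer(1))
    n_total <- length(waveform)
    samples <- vapply(lead_gains, function(g) {
      x <- g * waveform
      if (spec$noise_sd > 0) x <- x + rnorm(n_total, 0, spec$noise_sd)
      x
    }, numeric(n_total))
    colnames(samples) <- paste0("lead_", seq_along(lead_gains))
  })

  structure(
    list(
      sample_rate = sample_rate,
      lead_gains = as.numeric(lead_gains),
      samples = samples,
      beat_onsets = as.integer(onsets),
      beat_labels = labels,
      r_centers = as.integer(r_centers),
      seed = as.integer(seed)
    ),
    class = "ecg_stream"
  )
}

#' @export
print.ecg_stream <- function(x, ...) {
  cat(sprintf(
    "<ecg_stream> %d beats, %d leads, %d samples @ %g Hz (seed %d)\n",
    length(x$beat_labels), ncol(x$samples), nrow(x$samples), x$sample_rate, x$seed
  ))
  print(table(x$beat_labels))
  invisible(x)
}

#' Convert a synthetic stream to an ECG record
#'
#' Wraps an [synthesize_stream()] output as an `ecg_record` (the container
#' used by the segmentation functions), attaching the ground-truth R-wave
#' centres and labels as beat annotations.
#'
#' @param stream An `ecg_stream`.
#' @param record_id Record identifier.
#' @return An `ecg_record`; see [read_ecg_record()].
#' @export
as_ecg_record <- function(stream, record_id = "synthetic") {
  stopifnot(inherits(stream, "ecg_stream"))
  new_ecg_record(
    record_id = record_id,
    sample_rate = stream$sample_rate,
    samples = stream$samples,
    annotations = tibble::tibble(
      sample = stream$r_centers,
      label = stream$beat_labels
    )
  )
}

#' Write a stream to CSV
#'
#' Writes `time, lead_1, ..., lead_C` columns. Beat annotations (sample
#' index and label) can be written alongside as a JSON sidecar.
#'
#' @param stream An `ecg_stream`.
#' @param path Output CSV path.
#' @param annotations_path Optional path for a JSON annotation sidecar.
#' @return `path`, invisibly.
#' @export
write_stream_csv <- function(stream, path, annotations_path = NULL) {
  stopifnot(inherits(stream, "ecg_stream"))
  n <- nrow(stream$samples)
  df <- tibble::as_tibble(as.data.frame(stream$samples))
  df <- dplyr::bind_cols(
    tibble::tibble(time = (seq_len(n) - 1) / stream$sample_rate), df
  )
  readr::write_csv(df, path)
  if (!is.null(annotations_path)) {
    jsonlite::write_json(
      list(
        sample_rate = stream$sample_rate,
        r_centers = stream$r_centers,
        beat_onsets = stream$beat_onsets,
        beat_labels = stream$beat_labels
      ),
      annotations_path,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Write a stream as a WFDB-compatible record
#'
#' Emits a text header (`<record>.hea`), a 16-bit little-endian signal file
#' (`<record>.dat`, format 16, samples interleaved across leads, amplitudes
#' quantized at `gain` ADC units per mV), and a plain-text beat annotation
#' file (`<record>.ann`, one `sample label` pair per line; a simplified
#' stand-in for the binary WFDB annotation format).
#'
#' @param stream An `ecg_stream`.
#' @param dir Output directory (created if missing).
#' @param record Record name.
#' @param gain ADC units per millivolt.
#' @return The header path, invisibly.
#' @export
write_stream_wfdb <- function(stream, dir, record = "rec", gain = 200) {
  stopifnot(inherits(stream, "ecg_stream"))
  check_number(gain, "gain", 0, strict = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- nrow(stream$samples)
  C <- ncol(stream$samples)
  adc <- round(stream$samples * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  storage.mode(adc) <- "integer"

  dat <- paste0(record, ".dat")
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(t(adc)), con, size = 2L, endian = "little")

  checksums <- vapply(seq_len(C), function(j) {
    s <- sum(as.double(adc[, j])) %% 65536
    as.integer(if (s >= 32768) s - 65536 else s)
  }, integer(1))
  hdr <- c(
    sprintf("%s %d %g %d", record, C, stream$sample_rate, n),
    sprintf(
      "%s 16 %g(0)/mV 16 0 %d %d 0 lead_%d",
      dat, gain, adc[1, seq_len(C)], checksums, seq_len(C)
    )
  )
  writeLines(hdr, file.path(dir, paste0(record, ".hea")))
  writeLines(
    sprintf("%d %s", stream$r_centers, stream$beat_labels),
    file.path(dir, paste0(record, ".ann"))
  )
  invisible(file.path(dir, paste0(record, ".hea")))
}
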