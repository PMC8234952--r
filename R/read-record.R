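new_ecg_record <- function(record_id, sample_rate, samples, annotations = NULL) {
  samples <- as.matrix(samples)
  if (is.null(colnames(samples))) {
    colnames(samples) <- paste0("lead_", seq_len(ncol(samples)))
  }
  check_number(sample_rate, "sample_rate", 0, strict = TRUE)
  structure(
    list(
      record_id = record_id,
      sample_rate = sample_rate,
      leads = colnames(samples),
      samples = samples,
      annotations = annotations
    ),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record> '%s': %d leads x %d samples @ %g Hz%s\n",
    x$record_id, ncol(x$samples), nrow(x$samples), x$sample_rate,
    if (is.null(x$annotations)) "" else sprintf(", %d beat annotations", nrow(x$annotations))
  ))
  invisible(x)
}

#' Read an ECG record from disk
#'
#' Reads either a WFDB-compatible record (text `.hea` header plus format-16
#' binary signal file, as written by [write_stream_wfdb()]; amplitudes are
#' converted to millivolts via the header's per-signal `gain(baseline)`, and
#' a plain-text `.ann` beat annotation file is loaded when present) or a CSV
#' file with one `time` column and one column per lead (taken as millivolts
#' as-is; the sampling rate is inferred from the time column unless given).
#'
#' @param path Path to the `.hea` file (or record base name) for WFDB, or to
#'   the CSV file.
#' @param format `"wfdb"` or `"csv"`.
#' @param sample_rate Optional sampling rate override for CSV input.
#' @param record_id Optional record identifier; defaults to the file base name.
#'
#' @return An `ecg_record`: `record_id`, `sample_rate` (Hz), `leads`,
#'   `samples` (numeric matrix, samples x leads, mV), and `annotations`
#'   (tibble of `sample`, `label`, or `NULL`).
#' @export
read_ecg_record <- function(path, format = c("wfdb", "csv"),
                            sample_rate = NULL, record_id = NULL) {
  format <- match.arg(format)
  switch(format,
    wfdb = read_record_wfdb(path, record_id),
    csv = read_record_csv(path, sample_rate, record_id)
  )
}

read_record_csv <- function(path, sample_rate = NULL, record_id = NULL) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("File not found: %s", path), class = "tensorecg_format_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE)
  if (!"time" %in% names(df) || ncol(df) < 2) {
    stop_invalid(sprintf("%s: expected a 'time' column plus at least one lead column.", path),
      class = "tensorecg_format_error")
  }
  num <- lapply(names(df), function(nm) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !is.na(df[[nm]]))
    if (length(bad)) {
      stop_invalid(sprintf(
        "%s: non-numeric value '%s' in column '%s' at data line %d.",
        path, df[[nm]][bad[1]], nm, bad[1]
      ), class = "tensorecg_format_error")
    }
    v
  })
  names(num) <- names(df)
  leads <- setdiff(names(df), "time")
  samples <- do.call(cbind, num[leads])
  colnames(samples) <- leads
  if (is.null(sample_rate)) {
    dt <- diff(num$time)
    if (length(dt) == 0 || any(dt <= 0)) {
      stop_invalid(sprintf("%s: cannot infer sampling rate from 'time' column.", path),
        class = "tensorecg_format_error")
    }
    sample_rate <- 1 / median(dt)
  }
  new_ecg_record(
    record_id = record_id %||% sub("\\.[^.]*$", "", basename(path)),
    sample_rate = sample_rate,
    samples = samples
  )
}

read_record_wfdb <- function(path, record_id = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) {
    stop_invalid(sprintf("Header file not found: %s", hea), class = "tensorecg_format_error")
  }
  lines <- readLines(hea)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) {
    stop_invalid(sprintf("%s: malformed record line 1.", hea), class = "tensorecg_format_error")
  }
  record <- top[1]
  n_sig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n_samp <- as.integer(top[4])
  if (length(lines) < 1 + n_sig) {
    stop_invalid(sprintf("%s: header declares %d signals but has %d signal lines.",
      hea, n_sig, length(lines) - 1L), class = "tensorecg_format_error")
  }
  sig <- strsplit(trimws(lines[2:(1 + n_sig)]), "\\s+")
  files <- vapply(sig, `[[`, character(1), 1)
  fmt <- vapply(sig, `[[`, character(1), 2)
  if (any(fmt != "16")) {
    stop_invalid(sprintf("%s: only signal format 16 is supported (got %s).",
      hea, paste(unique(fmt), collapse = ",")), class = "tensorecg_format_error")
  }
  if (length(unique(files)) != 1) {
    stop_invalid(sprintf("%s: all signals must share one signal file.", hea),
      class = "tensorecg_format_error")
  }
  gain_spec <- vapply(sig, function(s) if (length(s) >= 3) s[3] else "200(0)/mV", character(1))
  gain <- as.numeric(sub("^([0-9.eE+-]+).*$", "\\1", gain_spec))
  baseline <- ifelse(grepl("\\(", gain_spec),
    as.numeric(sub("^[^(]*\\(([-0-9.eE+]+)\\).*$", "\\1", gain_spec)), 0)
  gain[!is.finite(gain) | gain == 0] <- 200
  lead_names <- vapply(seq_along(sig), function(i) {
    s <- sig[[i]]
    if (length(s) >= 9) paste(s[9:length(s)], collapse = "_") else paste0("lead_", i)
  }, character(1))

  dat_path <- file.path(dirname(hea), files[1])
  if (!file.exists(dat_path)) {
    stop_invalid(sprintf("Signal file not found: %s", dat_path),
      class = "tensorecg_format_error")
  }
  raw_n <- file.size(dat_path) / 2
  vals <- readBin(dat_path, "integer", n = raw_n, size = 2L, signed = TRUE,
    endian = "little")
  if (length(vals) < n_sig * n_samp) {
    stop_invalid(sprintf(
      "%s: signal file has %d samples but header declares %d x %d.",
      dat_path, length(vals), n_sig, n_samp
    ), class = "tensorecg_format_error")
  }
  m <- matrix(vals[seq_len(n_sig * n_samp)], nrow = n_sig)
  samples <- t((m - baseline) / gain)
  colnames(samples) <- lead_names

  ann_path <- file.path(dirname(hea), paste0(record, ".ann"))
  annotations <- NULL
  if (file.exists(ann_path)) {
    al <- strsplit(trimws(readLines(ann_path)), "\\s+")
    al <- al[lengths(al) >= 2]
    annotations <- tibble::tibble(
      sample = as.integer(vapply(al, `[[`, character(1), 1)),
      label = vapply(al, `[[`, character(1), 2)
    )
  }
  new_ecg_record(
    record_id = record_id %||% record,
    sample_rate = fs,
    samples = samples,
    annotations = annotations
  )
}
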