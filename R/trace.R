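#' EMG trace objects
#'
#' An `emg_trace` is a tibble with a `time_s` column and a single signal
#' column (`emg` for voltage-scale stages, `activation` once the signal is a
#' normalized muscle activation level), plus two attributes: the sampling
#' rate in Hz and the processing `stage`. Stages progress through
#' `raw -> highpassed -> rectified -> excitation -> activation` as the
#' pre-processing chain is applied.
#'
#' @param samples Numeric vector of signal samples (finite, length >= 1).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param stage Processing stage, one of `"raw"`, `"highpassed"`,
#'   `"rectified"`, `"excitation"`, `"activation"`.
#' @param time_s Optional time vector in seconds; defaults to a uniform grid
#'   starting at 0.
#'
#' @return A tibble of class `emg_trace` with columns `time_s` and the
#'   signal column.
#' @export
#' @examples
#' tr <- emg_trace(rnorm(100), sampling_rate = 1000)
#' emg_stage(tr)
emg_trace <- function(samples, sampling_rate, stage = "raw", time_s = NULL) {
  stage <- match.arg(stage, emg_stages())
  if (!is.numeric(samples) || length(samples) < 1L) {
    abort("`samples` must be a numeric vector of length >= 1.")
  }
  if (!all(is.finite(samples))) abort("`samples` must be finite.")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number.")
  }
  if (stage == "rectified" && any(samples < 0)) {
    abort("A rectified trace must be non-negative.")
  }
  if (stage == "activation" && (any(samples < 0) || any(samples > 1))) {
    abort("An activation trace must lie in [0, 1].")
  }
  if (is.null(time_s)) {
    time_s <- seq(0, by = 1 / sampling_rate, length.out = length(samples))
  }
  col <- if (stage == "activation") "activation" else "emg"
  out <- tibble(time_s = time_s, !!col := samples)
  new_emg_trace(out, sampling_rate, stage)
}

emg_stages <- function() {
  c("raw", "highpassed", "rectified", "excitation", "activation")
}

new_emg_trace <- function(tbl, sampling_rate, stage) {
  structure(tbl,
    class = c("emg_trace", class(tibble())),
    sampling_rate = sampling_rate,
    stage = stage
  )
}

#' @rdname emg_trace
#' @param x An `emg_trace`.
#' @export
emg_stage <- function(x) attr(x, "stage", exact = TRUE)

#' @rdname emg_trace
#' @export
sampling_rate <- function(x) attr(x, "sampling_rate", exact = TRUE)

trace_samples <- function(x) {
  col <- if (identical(emg_stage(x), "activation")) "activation" else "emg"
  x[[col]]
}

# Replace the signal values of a trace, moving it to a new stage.
retrace <- function(x, samples, stage) {
  emg_trace(samples, sampling_rate(x), stage = stage, time_s = x$time_s)
}

check_stage <- function(x, expected, op) {
  st <- emg_stage(x)
  if (!is.null(st) && !st %in% expected) {
    abort(sprintf(
      "`%s` expects a trace at stage %s, got \"%s\".",
      op, paste0('"', expected, '"', collapse = "/"), st
    ))
  }
  invisible(x)
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf(
    "# EMG trace: %d samples @ %g Hz, stage \"%s\"\n",
    nrow(x), sampling_rate(x), emg_stage(x)
  ))
  NextMethod()
}

#' Read and write delimited signal files
#'
#' Signal files are plain CSV with a header row and columns `time_s`, `emg`
#' and optionally `angle_deg`, one sample per row. The sampling rate is
#' inferred from the time column and validated for uniformity to within
#' 1e-6 s; malformed rows raise an error naming the offending line.
#'
#' @param path Path to a CSV file.
#' @return `read_emg_csv()` returns a tibble with columns `time_s`, `emg`
#'   and, when present in the file, `angle_deg`, with the inferred sampling
#'   rate stored in the `sampling_rate` attribute.
#' @export
read_emg_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  need <- c("time_s", "emg")
  if (!all(need %in% names(raw))) {
    abort(sprintf("%s: expected header columns `time_s, emg`.", path))
  }
  keep <- intersect(c("time_s", "emg", "angle_deg"), names(raw))
  out <- vector("list", length(keep))
  names(out) <- keep
  for (col in keep) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad) > 0L) {
      # +1 for the header row
      abort(sprintf(
        "%s: cannot parse column `%s` at line %d (value \"%s\").",
        path, col, bad[1L] + 1L, raw[[col]][bad[1L]]
      ))
    }
    out[[col]] <- vals
  }
  out <- as_tibble(out)
  if (nrow(out) < 2L) abort(sprintf("%s: need at least 2 samples.", path))
  dt <- diff(out$time_s)
  if (any(dt <= 0)) abort(sprintf("%s: time column must be increasing.", path))
  if (max(dt) - min(dt) > 1e-6) {
    abort(sprintf("%s: sampling is not uniform (tolerance 1e-6 s).", path))
  }
  attr(out, "sampling_rate") <- 1 / stats::median(dt)
  out
}

#' @rdname read_emg_csv
#' @param x A data frame with a `time_s` column.
#' @export
write_emg_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
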