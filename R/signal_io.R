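#' Construct a validated signal trace
#'
#' A `signal_trace` is the package's basic container: a uniformly sampled 1-D
#' physiological waveform (pressure, optical pulse, ...) together with its
#' sampling rate and free-text metadata. Every downstream stage consumes only
#' validated traces, so invalid data can never reach the model.
#'
#' @param samples Numeric vector of amplitudes (mmHg, mV, or arbitrary units).
#' @param fs Sampling rate in Hz; must be a single positive finite number.
#' @param label Optional channel name (e.g. `"ABP"`).
#' @param units Optional unit string (e.g. `"mmHg"`).
#' @return An object of class `signal_trace`: a list with elements `samples`,
#'   `fs`, `label`, `units`.
#' @examples
#' tr <- signal_trace(sin(2 * pi * seq(0, 1, by = 0.01)), fs = 100)
#' print(tr)
#' @export
signal_trace <- function(samples, fs, label = "", units = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("signal_trace: need at least 2 samples, got ", length(samples))
  if (!all(is.finite(samples)))
    stop("signal_trace: samples contain NaN/Inf at index ",
         which(!is.finite(samples))[1])
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("signal_trace: fs must be a single positive number")
  structure(
    list(samples = samples, fs = as.numeric(fs),
         label = as.character(label), units = as.character(units)),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<signal_trace> %s%s: %d samples @ %g Hz (%.2f s)\n",
              if (nzchar(x$label)) x$label else "unnamed",
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              length(x$samples), x$fs, dur))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

#' Pair a source and a target trace
#'
#' Binds the observable signal (e.g. ABP) and the signal to be predicted
#' (e.g. ICP) into one record. Lengths and sampling rates must match exactly;
#' the package performs no resampling, so mismatched inputs are rejected.
#'
#' @param source,target `signal_trace` objects of equal length and `fs`.
#' @return An object of class `paired_record` with elements `source`, `target`.
#' @export
paired_record <- function(source, target) {
  stopifnot(inherits(source, "signal_trace"), inherits(target, "signal_trace"))
  if (length(source$samples) != length(target$samples))
    stop("paired_record: length mismatch (", length(source$samples), " vs ",
         length(target$samples), ")")
  if (source$fs != target$fs)
    stop("paired_record: sampling-rate mismatch (", source$fs, " vs ",
         target$fs, " Hz)")
  structure(list(source = source, target = target), class = "paired_record")
}

#' @export
print.paired_record <- function(x, ...) {
  cat(sprintf("<paired_record> %d samples @ %g Hz: %s -> %s\n",
              length(x$source$samples), x$source$fs,
              if (nzchar(x$source$label)) x$source$label else "source",
              if (nzchar(x$target$label)) x$target$label else "target"))
  invisible(x)
}

#' Read a signal trace from a delimited text file
#'
#' Accepts two CSV layouts: a `(time, value)` pair of columns, from which the
#' sampling rate is inferred from the median time step (uniformity enforced
#' within 1% relative tolerance), or a value-only column with `fs` supplied
#' explicitly. A single header line is auto-detected. A JSON sidecar
#' (`<path>.json`) written by [write_trace()] restores `fs`, `label` and
#' `units` when present.
#'
#' @param path Path to a CSV file.
#' @param fs Sampling rate in Hz for value-only files; ignored (with a check
#'   against the inferred rate left to the caller) when a time column exists.
#' @param column Optional column name or index holding the values; defaults to
#'   the second column when two or more columns exist, else the first.
#' @return A [signal_trace()].
#' @export
read_trace <- function(path, fs = NULL, column = NULL) {
  if (!file.exists(path)) stop("read_trace: no such file: ", path)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.eE]+\\s*(,|$)", first)
  df <- read.csv(path, header = has_header, stringsAsFactors = FALSE)

  meta <- list(label = "", units = "")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sj <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta$label <- sj$label %||% ""
    meta$units <- sj$units %||% ""
    if (is.null(fs) && !is.null(sj$fs)) fs <- sj$fs
  }

  if (!is.null(column)) {
    vals <- df[[column]]
    if (is.null(vals)) stop("read_trace: no column '", column, "' in ", path)
    time <- NULL
    if (is.character(column) || column != 1L) {
      cand <- df[[1L]]
      if (is.numeric(cand) && !identical(cand, vals)) time <- cand
    }
  } else if (ncol(df) >= 2L) {
    time <- df[[1L]]
    vals <- df[[2L]]
  } else {
    time <- NULL
    vals <- df[[1L]]
  }
  vals <- suppressWarnings(as.numeric(vals))
  if (anyNA(vals) || !all(is.finite(vals)))
    stop("read_trace: non-finite or non-numeric sample values in ", path)

  if (!is.null(time) && is.numeric(time) && length(time) >= 2L) {
    dt <- diff(as.numeric(time))
    mdt <- median(dt)
    if (mdt <= 0) stop("read_trace: time column is not increasing")
    if (any(abs(dt - mdt) > 0.01 * mdt))
      stop("read_trace: non-uniform sampling beyond 1% tolerance in ", path)
    fs <- 1 / mdt
  } else if (is.null(fs)) {
    stop("read_trace: value-only file requires an explicit fs argument")
  }
  signal_trace(vals, fs = fs, label = meta$label, units = meta$units)
}

#' Write a signal trace to CSV with a JSON metadata sidecar
#'
#' Stores a `(time, value)` CSV at full double precision plus a
#' `<path>.json` sidecar carrying `fs`, `label` and `units`, so that
#' `read_trace(write_trace(tr))` round-trips samples and metadata exactly.
#'
#' @param trace A [signal_trace()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  n <- length(trace$samples)
  tm <- (seq_len(n) - 1L) / trace$fs
  lines <- c("time,value",
             paste(formatC(tm, format = "g", digits = 17),
                   formatC(trace$samples, format = "g", digits = 17),
                   sep = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("write_trace: cannot write to ", path)
  jsonlite::write_json(
    list(fs = trace$fs, label = trace$label, units = trace$units),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a source/target pair from two trace files
#'
#' @param path_source,path_target CSV paths readable by [read_trace()].
#' @param fs Optional explicit sampling rate applied to both files when they
#'   are value-only.
#' @return A [paired_record()]; lengths and sampling rates are verified equal.
#' @export
load_paired <- function(path_source, path_target, fs = NULL) {
  paired_record(read_trace(path_source, fs = fs),
                read_trace(path_target, fs = fs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
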