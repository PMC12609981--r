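#' Segment a pulsatile signal into cardiac cycles
#'
#' Detects systolic peaks as local maxima with a minimum separation of
#' `60 * fs / hr_high` samples and a topographic prominence of at least
#' 0.25 times the interquartile range of the signal amplitude. Troughs are
#' detected the same way on the inverted signal, and cycles run
#' trough-to-trough: the cycle boundaries are the troughs themselves, so each
#' complete cycle contains exactly one peak.
#'
#' @param trace A [signal_trace()] spanning at least two expected cycles.
#' @param hr_range_bpm Plausible heart-rate range in beats/min, default
#'   `c(40, 180)`; sets the minimum peak separation.
#' @return An object of class `cycle_segmentation`: a list with integer
#'   vectors `troughs` (t_v), `peaks` (t_p) and `boundaries` (t_b, equal to
#'   the troughs), all 1-based sample indices, satisfying the interleaving
#'   t_v[i] < t_p[i] < t_v[i+1].
#' @export
segment_cycles <- function(trace, hr_range_bpm = c(40, 180)) {
  stopifnot(inherits(trace, "signal_trace"),
            length(hr_range_bpm) == 2L, hr_range_bpm[1] < hr_range_bpm[2])
  s <- trace$samples
  if (diff(range(s)) == 0) stop("segment_cycles: constant signal has no cycles")
  min_sep <- max(1, floor(60 * trace$fs / hr_range_bpm[2]))
  min_prom <- 0.25 * diff(quantile(s, c(0.25, 0.75), names = FALSE))

  peaks <- find_peaks(s, min_sep, min_prom)
  troughs <- find_peaks(-s, min_sep, min_prom)
  if (length(troughs) < 2L || length(peaks) < 1L)
    stop("segment_cycles: fewer than 2 cycles detected")

  # reconcile the two landmark sets into a strict trough/peak interleaving:
  # merge trough pairs that bracket no peak (dropping the shallower trough,
  # as happens around artifacts) and keep the tallest peak per span
  repeat {
    empty <- which(vapply(seq_len(length(troughs) - 1L), function(i)
      !any(peaks > troughs[i] & peaks < troughs[i + 1L]), logical(1)))
    if (!length(empty) || length(troughs) <= 2L) break
    i <- empty[1L]
    drop_i <- if (s[troughs[i]] >= s[troughs[i + 1L]]) i else i + 1L
    troughs <- troughs[-drop_i]
  }
  kept <- integer(0)
  for (i in seq_len(length(troughs) - 1L)) {
    inside <- peaks[peaks > troughs[i] & peaks < troughs[i + 1L]]
    if (length(inside)) kept <- c(kept, inside[which.max(s[inside])])
  }
  # trim leading/trailing troughs that still bracket no peak
  while (length(troughs) > 1L && !any(kept > troughs[1L] & kept < troughs[2L]))
    troughs <- troughs[-1L]
  nt <- length(troughs)
  while (nt > 1L && !any(kept > troughs[nt - 1L] & kept < troughs[nt])) {
    troughs <- troughs[-nt]
    nt <- length(troughs)
  }
  kept <- kept[kept > troughs[1] & kept < tail(troughs, 1)]
  if (length(kept) < 2L || length(troughs) < 3L)
    stop("segment_cycles: fewer than 2 cycles detected")

  structure(list(troughs = troughs, peaks = kept, boundaries = troughs),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("<cycle_segmentation> %d cycles (%d troughs, %d peaks)\n",
              length(x$boundaries) - 1L, length(x$troughs), length(x$peaks)))
  invisible(x)
}

# local maxima with minimum separation and topographic prominence.
# prominence of a peak: height above the higher of the two valley floors
# reached before a taller sample (or the record edge) on either side.
find_peaks <- function(s, min_sep, min_prom) {
  n <- length(s)
  cand <- which(diff(sign(diff(s))) < 0) + 1L          # strict-left local maxima
  cand <- cand[s[cand] > s[pmax(cand - 1L, 1L)]]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    lo_l <- s[p]
    i <- p - 1L
    while (i >= 1L && s[i] <= s[p]) { lo_l <- min(lo_l, s[i]); i <- i - 1L }
    lo_r <- s[p]
    i <- p + 1L
    while (i <= n && s[i] <= s[p]) { lo_r <- min(lo_r, s[i]); i <- i + 1L }
    s[p] - max(lo_l, lo_r)
  }, numeric(1))
  cand <- cand[prom >= min_prom]
  if (!length(cand)) return(integer(0))
  # greedy tallest-first selection under the minimum-separation constraint
  ord <- cand[order(s[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in ord)
    if (!length(keep) || all(abs(keep - p) >= min_sep)) keep <- c(keep, p)
  sort(keep)
}

#' Per-cycle morphological features
#'
#' For each trough-to-trough cycle i computes: amplitude
#' `s[t_p,i] - s[t_v,i]` (peak minus the cycle's opening trough), pulse width
#' `(t_b,i+1 - t_b,i)/fs`, rise time `(t_p,i - t_v,i)/fs` and fall time
#' `(t_b,i+1 - t_p,i)/fs`, all durations in seconds. With the trough-boundary
#' convention, `width == rise + fall` holds exactly.
#'
#' @param trace A [signal_trace()].
#' @param seg A [segment_cycles()] result for the same trace.
#' @return A data.frame with one row per cycle and columns
#'   `amp`, `width`, `rise`, `fall`.
#' @export
cycle_features <- function(trace, seg) {
  stopifnot(inherits(trace, "signal_trace"), inherits(seg, "cycle_segmentation"))
  s <- trace$samples
  fs <- trace$fs
  b <- seg$boundaries
  p <- seg$peaks
  nc <- length(b) - 1L
  stopifnot(length(p) == nc)
  data.frame(
    amp   = s[p] - s[b[seq_len(nc)]],
    width = (b[-1L] - b[-length(b)]) / fs,
    rise  = (p - b[seq_len(nc)]) / fs,
    fall  = (b[-1L] - p) / fs
  )
}

#' First and second derivatives of a sampled signal
#'
#' Central differences scaled by `fs` (first derivative) and `fs^2` (second),
#' exact for affine and quadratic signals respectively at interior points;
#' one-sided differences at the two edges. Output lengths equal input length.
#'
#' @param trace A [signal_trace()] of length >= 3.
#' @return A list with numeric vectors `d1` (units/s) and `d2` (units/s^2).
#' @export
derivatives <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  s <- trace$samples
  n <- length(s)
  if (n < 3L) stop("derivatives: need at least 3 samples")
  fs <- trace$fs
  d1 <- c(s[2L] - s[1L],
          (s[3:n] - s[1:(n - 2L)]) / 2,
          s[n] - s[n - 1L]) * fs
  core <- (s[3:n] - 2 * s[2:(n - 1L)] + s[1:(n - 2L)]) * fs^2
  d2 <- c(core[1L], core, core[n - 2L])
  list(d1 = d1, d2 = d2)
}

#' Build the point-aligned 7-channel composite feature matrix
#'
#' Expands a 1-D waveform into a `T x 7` matrix with channel order
#' `raw, amp, width, rise, fall, d1, d2`. Channels 2-5 broadcast each cycle's
#' morphological features to every sample index in `[t_b,i, t_b,i+1)`; samples
#' before the first boundary copy the first cycle's values and samples at or
#' after the last boundary copy the last cycle's. Channels 6-7 are the
#' pointwise first and second derivatives. Channel 1 is the input verbatim.
#'
#' @param trace A [signal_trace()].
#' @param seg Optional precomputed [segment_cycles()] result; computed
#'   internally when `NULL`.
#' @param hr_range_bpm Passed to [segment_cycles()] when `seg` is `NULL`.
#' @return An object of class `feature_matrix`: a numeric `T x 7` matrix with
#'   column names and attributes `fs` and `seg`.
#' @export
build_feature_matrix <- function(trace, seg = NULL, hr_range_bpm = c(40, 180)) {
  stopifnot(inherits(trace, "signal_trace"))
  if (is.null(seg)) seg <- segment_cycles(trace, hr_range_bpm)
  feats <- cycle_features(trace, seg)
  n <- length(trace$samples)
  # cycle index per sample: nearest-cycle fill outside the covered range
  cyc <- findInterval(seq_len(n), seg$boundaries)
  cyc <- pmin(pmax(cyc, 1L), nrow(feats))
  d <- derivatives(trace)
  m <- cbind(raw = trace$samples,
             amp = feats$amp[cyc], width = feats$width[cyc],
             rise = feats$rise[cyc], fall = feats$fall[cyc],
             d1 = d$d1, d2 = d$d2)
  structure(m, fs = trace$fs, seg = seg, class = c("feature_matrix", "matrix"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d (fs = %g Hz), channels: %s\n",
              nrow(x), ncol(x), attr(x, "fs"),
              paste(colnames(x), collapse = ", ")))
  invisible(x)
}

#' Write a feature matrix as a 7-column CSV
#'
#' @param fm A [build_feature_matrix()] result.
#' @param path Destination path; the header names the channel order.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  write.csv(as.data.frame(unclass(fm)), path, row.names = FALSE)
  invisible(path)
}
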