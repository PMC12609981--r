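#' Denoising configuration
#'
#' Parameters for the three-step noise-reduction chain: spike removal by
#' cubic-spline interpolation, baseline-drift removal by grayscale
#' morphological opening/closing, and a zero-phase Butterworth bandpass.
#'
#' @param spike_mad_k Threshold multiplier on the median absolute deviation of
#'   first differences; samples adjacent to a difference exceeding
#'   `spike_mad_k * mad(diff(s))` are treated as spikes. Default 6.
#' @param spike_pad Number of samples by which each flagged spike run is
#'   widened on both sides before interpolation. Default 2.
#' @param morph_window_s Length in seconds of the flat structuring element for
#'   the morphological baseline estimate; about 1.5x a resting cardiac cycle.
#'   Default 1.5.
#' @param bp_low_hz,bp_high_hz Bandpass corner frequencies in Hz. Defaults
#'   0.5 and 10, retaining the cardiac fundamental and its first harmonics
#'   while rejecting baseline drift and electronic noise.
#' @param bp_order Butterworth prototype order (applied forward and backward,
#'   so the effective attenuation is doubled). Default 4.
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(spike_mad_k = 6, spike_pad = 2L,
                           morph_window_s = 1.5,
                           bp_low_hz = 0.5, bp_high_hz = 10, bp_order = 4L) {
  stopifnot(spike_mad_k > 0, spike_pad >= 0, morph_window_s > 0,
            bp_low_hz > 0, bp_high_hz > bp_low_hz, bp_order >= 1)
  structure(list(spike_mad_k = spike_mad_k, spike_pad = as.integer(spike_pad),
                 morph_window_s = morph_window_s,
                 bp_low_hz = bp_low_hz, bp_high_hz = bp_high_hz,
                 bp_order = as.integer(bp_order)),
            class = "denoise_config")
}

#' Remove abrupt spikes by cubic-spline interpolation
#'
#' Flags samples whose first-difference magnitude exceeds
#' `spike_mad_k` times the median absolute deviation of the first differences
#' (both endpoints of a flagged difference are marked, and each flagged run is
#' widened by `spike_pad` samples), then replaces flagged samples with a
#' natural cubic spline through the surrounding un-flagged samples. Un-flagged
#' samples are returned unchanged. A constant trace (MAD = 0) is treated as
#' spike-free.
#'
#' @param trace A [signal_trace()] of length >= 8.
#' @param cfg A [denoise_config()].
#' @return A despiked [signal_trace()].
#' @export
despike <- function(trace, cfg = denoise_config()) {
  stopifnot(inherits(trace, "signal_trace"))
  s <- trace$samples
  n <- length(s)
  if (n < 8L) stop("despike: need at least 8 samples")
  d <- diff(s)
  m <- stats::mad(d)
  if (m == 0) return(trace)  # flat or perfectly regular: nothing to flag
  bad_d <- abs(d - median(d)) > cfg$spike_mad_k * m
  flag <- logical(n)
  flag[which(bad_d)] <- TRUE
  flag[which(bad_d) + 1L] <- TRUE
  if (cfg$spike_pad > 0L && any(flag)) {
    idx <- which(flag)
    for (k in seq_len(cfg$spike_pad)) {
      flag[pmax(idx - k, 1L)] <- TRUE
      flag[pmin(idx + k, n)] <- TRUE
    }
  }
  if (!any(flag)) return(trace)
  if (mean(flag) > 0.5)
    stop("despike: more than 50% of samples flagged as spikes; ",
         "signal quality too poor to repair")
  good <- which(!flag)
  sf <- splinefun(good, s[good], method = "natural")
  s[flag] <- sf(which(flag))
  signal_trace(s, trace$fs, trace$label, trace$units)
}

# flat-element grayscale erosion (running min) / dilation (running max),
# edge-replicated so the estimate stays defined at the borders
running_extreme <- function(s, w, op = c("min", "max")) {
  op <- match.arg(op)
  n <- length(s)
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  pad <- c(rep(s[1L], half_l), s, rep(s[n], half_r))
  out <- pad[seq_len(n)]
  f <- if (op == "min") pmin else pmax
  for (k in seq_len(w - 1L)) out <- f(out, pad[seq_len(n) + k])
  out
}

morph_open  <- function(s, w) running_extreme(running_extreme(s, w, "min"), w, "max")
morph_close <- function(s, w) running_extreme(running_extreme(s, w, "max"), w, "min")

#' Remove baseline drift by morphological filtering
#'
#' Estimates the slow baseline as the mean of a grayscale opening and closing
#' with a flat structuring element of `round(morph_window_s * fs)` samples and
#' subtracts it. Averaging the two operators treats peaks and troughs
#' symmetrically, so pulse amplitude is not biased.
#'
#' @inheritParams despike
#' @return A baseline-corrected [signal_trace()].
#' @export
remove_baseline <- function(trace, cfg = denoise_config()) {
  stopifnot(inherits(trace, "signal_trace"))
  s <- trace$samples
  w <- as.integer(round(cfg$morph_window_s * trace$fs))
  if (w < 3L) stop("remove_baseline: structuring element shorter than 3 samples")
  if (w > length(s)) stop("remove_baseline: structuring element longer than signal")
  baseline <- (morph_open(s, w) + morph_close(s, w)) / 2
  signal_trace(s - baseline, trace$fs, trace$label, trace$units)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Designs a Butterworth bandpass of the configured order and applies it
#' forward and backward ([signal::filtfilt()]), so the net filter has zero
#' phase: peaks and troughs are not displaced in time. Output length equals
#' input length.
#'
#' @inheritParams despike
#' @return A filtered [signal_trace()].
#' @export
bandpass <- function(trace, cfg = denoise_config()) {
  stopifnot(inherits(trace, "signal_trace"))
  nyq <- trace$fs / 2
  if (cfg$bp_high_hz >= nyq)
    stop("bandpass: upper corner ", cfg$bp_high_hz,
         " Hz must be below Nyquist (", nyq, " Hz)")
  bf <- signal::butter(cfg$bp_order,
                       c(cfg$bp_low_hz, cfg$bp_high_hz) / nyq,
                       type = "pass")
  # odd-reflection padding before the forward-backward pass suppresses the
  # start/end transients of the low corner (which settle over ~1/bp_low_hz s)
  s <- trace$samples
  n <- length(s)
  pad <- min(n - 1L, as.integer(round(3 * trace$fs / cfg$bp_low_hz)))
  ext <- c(2 * s[1L] - s[(pad + 1L):2L], s, 2 * s[n] - s[(n - 1L):(n - pad)])
  y <- signal::filtfilt(bf, ext)[(pad + 1L):(pad + n)]
  signal_trace(y, trace$fs, trace$label, trace$units)
}

#' Full three-step denoising chain
#'
#' Applies, in order: [despike()], [remove_baseline()], [bandpass()].
#'
#' @inheritParams despike
#' @return A denoised [signal_trace()].
#' @export
denoise_pipeline <- function(trace, cfg = denoise_config()) {
  bandpass(remove_baseline(despike(trace, cfg), cfg), cfg)
}
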