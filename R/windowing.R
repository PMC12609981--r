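#' Sliding-window specification
#'
#' @param T Window length in samples (default 700, the full-scale protocol).
#' @param S Stride in samples (default 100). Must satisfy `0 < S <= T` so
#'   consecutive windows leave no coverage gap.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(T = 700L, S = 100L) {
  T <- as.integer(T); S <- as.integer(S)
  stopifnot(T >= 1L, S >= 1L, S <= T)
  structure(list(T = T, S = S), class = "window_spec")
}

#' Slice a sequence or feature matrix into sliding windows
#'
#' Produces `floor((L - T) / S) + 1` windows with starts `0, S, 2S, ...`
#' (0-based starts, as offsets into the sequence); no padding is applied, so
#' up to `T - 1` trailing samples may be left uncovered.
#'
#' @param x A numeric vector (target sequence) or a `T x C` matrix
#'   (feature matrix).
#' @param spec A [window_spec()].
#' @return A list with `starts` (0-based integer vector) and `windows`
#'   (list of length-`T` vectors or `T x C` matrices).
#' @export
make_windows <- function(x, spec) {
  stopifnot(inherits(spec, "window_spec"))
  L <- if (is.matrix(x)) nrow(x) else length(x)
  if (L < spec$T)
    stop("make_windows: sequence length ", L, " shorter than window ", spec$T)
  n_win <- (L - spec$T) %/% spec$S + 1L
  starts <- (seq_len(n_win) - 1L) * spec$S
  windows <- lapply(starts, function(s0) {
    idx <- (s0 + 1L):(s0 + spec$T)
    if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
  })
  list(starts = starts, windows = windows)
}

#' Fit a per-channel z-score normalizer
#'
#' Computes per-channel mean and standard deviation for the 7 input channels
#' and for the target, from training-partition samples only (never from test
#' or validation data, to avoid leakage). A zero-variance channel gets scale 1
#' with a warning so normalization stays invertible.
#'
#' @param training_x Numeric matrix of training-feature rows (`n x C`).
#' @param training_y Numeric vector of training-target samples.
#' @return An object of class `normalizer` with elements `x_shift`, `x_scale`,
#'   `y_shift`, `y_scale`.
#' @export
fit_normalizer <- function(training_x, training_y) {
  if (is.null(training_x) || NROW(training_x) == 0L || length(training_y) == 0L)
    stop("fit_normalizer: empty training data")
  training_x <- as.matrix(training_x)
  x_shift <- colMeans(training_x)
  x_scale <- apply(training_x, 2, sd)
  if (any(x_scale == 0)) {
    warning("fit_normalizer: zero-variance input channel(s) ",
            paste(which(x_scale == 0), collapse = ", "), "; using scale 1")
    x_scale[x_scale == 0] <- 1
  }
  y_shift <- mean(training_y)
  y_scale <- sd(training_y)
  if (is.na(y_scale) || y_scale == 0) {
    warning("fit_normalizer: zero-variance target; using scale 1")
    y_scale <- 1
  }
  structure(list(x_shift = x_shift, x_scale = x_scale,
                 y_shift = y_shift, y_scale = y_scale),
            class = "normalizer")
}

#' Apply / invert a normalizer
#'
#' @param norm A [fit_normalizer()] result.
#' @param x Feature matrix (`n x C`) to z-score, or `NULL`.
#' @param y Target vector to z-score, or `NULL`.
#' @return The normalized matrix/vector (or a list of both when both given).
#' @export
normalize_data <- function(norm, x = NULL, y = NULL) {
  stopifnot(inherits(norm, "normalizer"))
  xn <- if (!is.null(x))
    sweep(sweep(as.matrix(x), 2, norm$x_shift), 2, norm$x_scale, "/")
  yn <- if (!is.null(y)) (y - norm$y_shift) / norm$y_scale
  if (!is.null(x) && !is.null(y)) list(x = xn, y = yn)
  else if (!is.null(x)) xn else yn
}

#' @rdname normalize_data
#' @param y_norm Normalized target values to map back to physical units.
#' @export
denormalize_target <- function(norm, y_norm) {
  stopifnot(inherits(norm, "normalizer"))
  y_norm * norm$y_scale + norm$y_shift
}

#' Fuse overlapping window predictions into one sequence
#'
#' Each output sample is the weight-normalized sum of all covering windows'
#' values, using a strictly positive Hann-shaped taper per window
#' (`0.5 - 0.5 cos(2 pi (t - 0.5) / T)`, shifted half a sample so end weights
#' never vanish), with weights renormalized to sum to 1 at every covered
#' sample. A sample covered by exactly one window therefore passes through
#' unchanged, and windows that all agree reproduce their common value exactly.
#'
#' @param window_predictions List of per-window prediction vectors, all of
#'   length `spec$T`.
#' @param starts 0-based start offsets matching `window_predictions`.
#' @param L Total output length.
#' @param spec A [window_spec()].
#' @return A list with `prediction` (length `L`, `NA` where uncovered),
#'   `covered` (logical length `L`) and `weight_sum` (pre-normalization sums,
#'   for diagnostics).
#' @export
fuse_overlapping <- function(window_predictions, starts, L, spec) {
  stopifnot(inherits(spec, "window_spec"),
            length(window_predictions) == length(starts))
  Tw <- spec$T
  ord <- order(starts)
  starts <- starts[ord]
  window_predictions <- window_predictions[ord]
  # coverage must be contiguous from the first start
  if (length(starts) > 1L) {
    reach <- starts[1] + Tw
    for (i in 2L:length(starts)) {
      if (starts[i] > reach)
        stop("fuse_overlapping: coverage gap between samples ", reach,
             " and ", starts[i])
      reach <- max(reach, starts[i] + Tw)
    }
  }
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(Tw) - 0.5) / Tw)
  acc <- numeric(L)
  wsum <- numeric(L)
  for (i in seq_along(starts)) {
    w <- window_predictions[[i]]
    if (length(w) != Tw)
      stop("fuse_overlapping: window ", i, " has length ", length(w),
           ", expected ", Tw)
    idx <- (starts[i] + 1L):(starts[i] + Tw)
    acc[idx] <- acc[idx] + w * taper
    wsum[idx] <- wsum[idx] + taper
  }
  covered <- wsum > 0
  pred <- rep(NA_real_, L)
  pred[covered] <- acc[covered] / wsum[covered]
  list(prediction = pred, covered = covered, weight_sum = wsum)
}

#' Contiguous train/test/validation split of a paired record
#'
#' Reserves the final `n_val` samples as a validation block, then splits the
#' remainder into contiguous training and test blocks in `train_frac : 1 -
#' train_frac` proportion. Splitting in time (not over windows) prevents
#' overlapping windows from leaking test samples into training.
#'
#' @param n Total number of samples.
#' @param n_val Number of trailing validation samples (default 10000 at full
#'   scale; pass 0 to skip).
#' @param train_frac Fraction of the remainder used for training (default 0.8).
#' @return A list of index vectors `train`, `test`, `validation`.
#' @export
split_record <- function(n, n_val = 10000L, train_frac = 0.8) {
  stopifnot(n > n_val, train_frac > 0, train_frac < 1)
  body <- n - n_val
  n_train <- floor(body * train_frac)
  list(train = seq_len(n_train),
       test = if (n_train < body) (n_train + 1L):body else integer(0),
       validation = if (n_val > 0) (body + 1L):n else integer(0))
}
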