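#' Synthetic paired-waveform simulator configuration
#'
#' Defines the generative model for seeded source/target pairs that emulate
#' pulsatile physiological recordings: a quasi-periodic pulse train with
#' heart-rate variability, respiratory amplitude modulation, slow baseline
#' drift, sparse spike artifacts and additive white noise, plus a known
#' source-to-target transfer (delay + first-order smoothing + gain + mild
#' quadratic nonlinearity + independent noise) so prediction quality can be
#' verified against ground truth.
#'
#' @param fs Sampling rate in Hz (default 50, matching clinical multi-channel
#'   monitoring rates; must exceed 20 Hz so the 0.5-10 Hz band is supported).
#' @param duration_s Record length in seconds (default 60).
#' @param hr_bpm Mean heart rate in beats/min (default 70; allowed 40-180).
#' @param hr_jitter Fractional per-beat period variability (default 0.03).
#' @param pulse_shape List with `rise_frac` in (0,1) (fraction of the cycle
#'   spent rising, default 0.3) and `notch_depth >= 0` (relative height of the
#'   secondary dicrotic-like bump, default 0.15).
#' @param resp_hz Respiratory modulation frequency in Hz (default 0.25).
#' @param resp_depth Fractional amplitude modulation depth (default 0.1).
#' @param drift_amp Baseline drift amplitude in signal units (default 0.2).
#' @param spike_rate_hz Mean artifact rate in spikes/s (default 0.05).
#' @param noise_sd Additive white-noise standard deviation (default 0.02).
#' @param transfer List with `delay_s` (default 0.2), `smoothing_tau_s`
#'   (default 0.1), `gain` (default 1.5), `nonlin_coeff` (default 0.2) and
#'   `target_noise_sd` (default 0.02).
#' @param seed Integer seed for all randomness.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(fs = 50, duration_s = 60, hr_bpm = 70,
                         hr_jitter = 0.03,
                         pulse_shape = list(rise_frac = 0.3, notch_depth = 0.15),
                         resp_hz = 0.25, resp_depth = 0.1,
                         drift_amp = 0.2, spike_rate_hz = 0.05,
                         noise_sd = 0.02,
                         transfer = list(delay_s = 0.2, smoothing_tau_s = 0.1,
                                         gain = 1.5, nonlin_coeff = 0.2,
                                         target_noise_sd = 0.02),
                         seed = 1L) {
  stopifnot(fs > 20, duration_s > 0, hr_bpm >= 40, hr_bpm <= 180,
            hr_jitter >= 0, resp_depth >= 0, drift_amp >= 0,
            spike_rate_hz >= 0, noise_sd >= 0)
  pulse_shape <- modifyList(list(rise_frac = 0.3, notch_depth = 0.15),
                            pulse_shape)
  transfer <- modifyList(list(delay_s = 0.2, smoothing_tau_s = 0.1,
                              gain = 1.5, nonlin_coeff = 0.2,
                              target_noise_sd = 0.02), transfer)
  stopifnot(pulse_shape$rise_frac > 0, pulse_shape$rise_frac < 1,
            pulse_shape$notch_depth >= 0, transfer$target_noise_sd >= 0)
  structure(list(fs = fs, duration_s = duration_s, hr_bpm = hr_bpm,
                 hr_jitter = hr_jitter, pulse_shape = pulse_shape,
                 resp_hz = resp_hz, resp_depth = resp_depth,
                 drift_amp = drift_amp, spike_rate_hz = spike_rate_hz,
                 noise_sd = noise_sd, transfer = transfer,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# one unit-amplitude beat template on phase grid phi in [0,1):
# raised-cosine rise to 1 at phi = rise_frac, quasi-exponential decay to ~0,
# plus an optional dicrotic-like bump on the falling limb
beat_template <- function(phi, rise_frac, notch_depth) {
  y <- numeric(length(phi))
  up <- phi < rise_frac
  y[up] <- 0.5 * (1 - cos(pi * phi[up] / rise_frac))
  fr <- (phi[!up] - rise_frac) / (1 - rise_frac)
  y[!up] <- (exp(-3 * fr) - exp(-3)) / (1 - exp(-3))
  if (notch_depth > 0) {
    bump_c <- rise_frac + 0.35 * (1 - rise_frac)
    bump_w <- 0.12 * (1 - rise_frac)
    y <- y + notch_depth * exp(-0.5 * ((phi - bump_c) / bump_w)^2)
  }
  y
}

#' Generate a synthetic source waveform with ground truth
#'
#' Places per-beat template pulses at onsets whose periods are
#' `60 / hr_bpm * (1 + jitter)` with independent jitter draws, modulates the
#' amplitude by `1 + resp_depth * sin(2 pi resp_hz t)`, then adds slow
#' sinusoidal drift (random phases, 0.03-0.08 Hz), Poisson-placed spike
#' artifacts (about five times the signal range) and white noise. Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A [signal_trace()] with attributes: `clean` (the noise-free,
#'   drift-free pulse train), `segmentation` (the true trough/peak/boundary
#'   indices as a `cycle_segmentation`) and `onsets` (beat onset indices).
#' @export
gen_source <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  mean_period <- 60 / cfg$hr_bpm

  # beat onset times covering the record (extra beat at each end)
  onsets <- -mean_period
  while (tail(onsets, 1) < cfg$duration_s + mean_period) {
    p <- mean_period * (1 + cfg$hr_jitter * rnorm(1))
    p <- max(p, 0.3 * mean_period)
    onsets <- c(onsets, tail(onsets, 1) + p)
  }
  periods <- diff(onsets)

  clean <- numeric(n)
  for (i in seq_along(periods)) {
    i0 <- max(1L, floor(onsets[i] * fs) + 1L)
    i1 <- min(n, ceiling(onsets[i + 1L] * fs))
    if (i1 < i0) next
    phi <- (t[i0:i1] - onsets[i]) / periods[i]
    inside <- phi >= 0 & phi < 1
    idx <- (i0:i1)[inside]
    clean[idx] <- clean[idx] +
      beat_template(phi[inside], cfg$pulse_shape$rise_frac,
                    cfg$pulse_shape$notch_depth)
  }
  clean <- clean * (1 + cfg$resp_depth * sin(2 * pi * cfg$resp_hz * t))

  drift <- if (cfg$drift_amp > 0) {
    f1 <- runif(1, 0.03, 0.05); f2 <- runif(1, 0.05, 0.08)
    cfg$drift_amp * (0.7 * sin(2 * pi * f1 * t + runif(1, 0, 2 * pi)) +
                     0.3 * sin(2 * pi * f2 * t + runif(1, 0, 2 * pi)))
  } else numeric(n)

  spikes <- numeric(n)
  n_spk <- rpois(1, cfg$spike_rate_hz * cfg$duration_s)
  if (n_spk > 0) {
    pos <- sample.int(n, n_spk)
    mag <- 5 * diff(range(clean)) * sample(c(-1, 1), n_spk, replace = TRUE) *
      runif(n_spk, 0.8, 1.2)
    spikes[pos] <- mag
  }

  physio <- clean + drift          # the physiological signal proper
  noisy <- physio + spikes + rnorm(n, sd = cfg$noise_sd)

  # ground-truth landmarks from the construction: troughs at beat onsets,
  # peaks at onset + rise_frac * period (restricted to in-record beats)
  on_idx <- round(onsets * fs) + 1L
  pk_idx <- round((onsets[-length(onsets)] +
                   cfg$pulse_shape$rise_frac * periods) * fs) + 1L
  keep_t <- on_idx >= 1L & on_idx <= n
  troughs <- as.integer(on_idx[keep_t])
  peaks <- as.integer(pk_idx[pk_idx >= 1L & pk_idx <= n])
  peaks <- peaks[peaks > troughs[1] & peaks < tail(troughs, 1)]

  tr <- signal_trace(noisy, fs, label = "synthetic-source", units = "a.u.")
  attr(tr, "clean") <- clean
  attr(tr, "physio") <- physio
  attr(tr, "segmentation") <- structure(
    list(troughs = troughs, peaks = peaks, boundaries = troughs),
    class = "cycle_segmentation")
  attr(tr, "onsets") <- troughs
  tr
}

#' Derive the paired target waveform through a known transfer
#'
#' `target = gain * u + nonlin_coeff * u^2 + noise`, where `u` is the input
#' signal delayed by `delay_s` (leading samples hold the first value) and
#' smoothed by a first-order exponential filter with time constant
#' `smoothing_tau_s` (`tau -> 0` disables smoothing). For traces produced by
#' [gen_source()] the transfer acts on the artifact-free physiological
#' component (pulses, respiration and drift): spike artifacts and white
#' measurement noise are local to the recording channel and do not propagate
#' to the paired signal, which instead receives its own independent
#' measurement noise. For plain traces the samples are used as given. Fully
#' deterministic given `cfg$seed`.
#'
#' @param source A [signal_trace()].
#' @param cfg A [synth_config()]; only `transfer` and `seed` are used.
#' @return A [signal_trace()] of the same length and sampling rate.
#' @export
derive_target <- function(source, cfg = synth_config()) {
  stopifnot(inherits(source, "signal_trace"), inherits(cfg, "synth_config"))
  tf <- cfg$transfer
  s <- attr(source, "physio") %||% source$samples
  n <- length(s)
  fs <- source$fs
  d <- round(tf$delay_s * fs)
  if (d >= n) stop("derive_target: delay longer than signal")
  u <- if (d > 0) c(rep(s[1L], d), s[seq_len(n - d)]) else s
  if (tf$smoothing_tau_s > 0) {
    alpha <- (1 / fs) / (tf$smoothing_tau_s + 1 / fs)
    u <- as.numeric(stats::filter(alpha * u, 1 - alpha, method = "recursive",
                                  init = u[1L]))
  }
  set.seed(cfg$seed + 104729L)   # independent stream for target noise
  y <- tf$gain * u + tf$nonlin_coeff * u^2 +
    rnorm(n, sd = tf$target_noise_sd)
  signal_trace(y, fs, label = "synthetic-target", units = "a.u.")
}

#' Generate a seeded dataset of paired records
#'
#' Produces `n_records` paired source/target records with per-record derived
#' seeds (`seed + 1000 * index`), together with a manifest recording the
#' exact configuration, so regeneration from the manifest is byte-identical.
#'
#' @param cfg A [synth_config()]; its `seed` is the root seed.
#' @param n_records Number of record pairs (default 1).
#' @return A list with `records` (list of [paired_record()], each carrying a
#'   `ground_truth` attribute with the true segmentation and transfer) and
#'   `manifest` (list of root config and per-record seeds).
#' @export
make_dataset <- function(cfg = synth_config(), n_records = 1L) {
  stopifnot(n_records >= 1)
  seeds <- cfg$seed + 1000L * seq_len(n_records)
  records <- lapply(seeds, function(sd) {
    ci <- cfg
    ci$seed <- sd
    src <- gen_source(ci)
    tgt <- derive_target(src, ci)
    rec <- paired_record(src, tgt)
    attr(rec, "ground_truth") <- list(segmentation = attr(src, "segmentation"),
                                      transfer = cfg$transfer, seed = sd)
    rec
  })
  list(records = records,
       manifest = list(config = unclass(cfg), record_seeds = seeds))
}
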