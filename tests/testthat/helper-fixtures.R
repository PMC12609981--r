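# shared fixtures, all generated in code

# uniformly sampled sine trace: f_hz for dur_s seconds at fs
sine_trace <- function(f_hz = 1, fs = 100, dur_s = 10, amp = 1) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  signal_trace(amp * sin(2 * pi * f_hz * t), fs)
}

# small model for fast structural tests; ... overrides the tiny defaults
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(in_channels = 7, conv1_channels = 6, conv2_channels = 8,
         lstm_hidden = 4, lstm_layers = 2, heads = 2),
    list(...))
  do.call(model_config, args)
}

tiny_model <- function(seed = 1, ...) {
  set.seed(seed)
  init_cbanet(tiny_config(...))
}

random_window <- function(Tn, C = 7, seed = 1) {
  set.seed(seed)
  matrix(rnorm(Tn * C), Tn, C)
}

# noise-free synthetic configuration (clean landmarks, no artifacts);
# ... overrides any field, including the zeroed ones
clean_synth <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, hr_jitter = 0, noise_sd = 0, drift_amp = 0,
         spike_rate_hz = 0, resp_depth = 0),
    list(...))
  do.call(synth_config, args)
}
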