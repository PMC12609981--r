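test_that("despike repairs isolated spikes and leaves clean signals alone", {
  tr <- sine_trace()
  expect_equal(despike(tr)$samples, tr$samples)  # nothing flagged

  clean <- tr$samples
  spiked <- clean
  spiked[500] <- spiked[500] + 10 * diff(range(clean))
  out <- despike(signal_trace(spiked, tr$fs))
  expect_lt(abs(out$samples[500] - clean[500]), 0.05 * diff(range(clean)))
  # samples away from the widened flag run are untouched
  touched <- 495:505
  expect_equal(out$samples[-touched], spiked[-touched])

  const <- signal_trace(rep(2, 100), 100)
  expect_equal(despike(const)$samples, const$samples)  # MAD = 0 path

  junk <- 0.1 * sin(2 * pi * seq(0, 1, length.out = 100))
  junk[seq(5, 95, by = 6)] <- junk[seq(5, 95, by = 6)] + 50
  expect_error(despike(signal_trace(junk, 100)), "50%")
})

test_that("morphological baseline removal takes out drift and ramps", {
  z <- signal_trace(rep(0, 500), 50)
  expect_equal(remove_baseline(z)$samples, rep(0, 500))

  sc <- clean_synth(seed = 4)
  src <- gen_source(sc)
  pulse <- attr(src, "clean")
  m <- 0.01
  drifted <- pulse + m * seq_along(pulse) / sc$fs
  out <- remove_baseline(signal_trace(drifted, sc$fs))
  amp <- diff(range(pulse))
  # against the drift-free oracle passed through the same operator
  oracle <- remove_baseline(signal_trace(pulse, sc$fs))
  expect_lt(sqrt(mean((out$samples - oracle$samples)^2)), 0.05 * amp)
  # no residual trend
  slope <- unname(coef(lm(out$samples ~ seq_along(out$samples)))[2]) * sc$fs
  expect_lt(abs(slope), 0.05 * m)

  ramp <- signal_trace(seq(0, 5, length.out = 400), 50)
  rout <- remove_baseline(ramp)
  core <- rout$samples[100:300]  # away from edges
  expect_lt(max(abs(core)), 1e-8)

  expect_error(remove_baseline(signal_trace(rnorm(10), 50)),
               "longer than signal")
})

test_that("bandpass preserves the passband, rejects DC and HF, zero phase", {
  cfg <- denoise_config()
  t <- seq(0, 10, by = 0.01)

  dc <- bandpass(signal_trace(rep(1, length(t)), 100), cfg)
  expect_lt(max(abs(dc$samples)), 0.01)

  s5 <- bandpass(signal_trace(sin(2 * pi * 5 * t), 100), cfg)
  expect_lt(abs(max(abs(s5$samples[250:750])) - 1), 0.05)

  s40 <- bandpass(signal_trace(sin(2 * pi * 40 * t), 100), cfg)
  expect_lt(max(abs(s40$samples[250:750])), 0.05)

  # zero-phase: no lag between a clean in-band signal and its filtered copy
  x <- sin(2 * pi * 2 * t)
  y <- bandpass(signal_trace(x, 100), cfg)$samples
  cc <- stats::ccf(y, x, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(bandpass(signal_trace(rnorm(100), 15), cfg), "Nyquist")
})

test_that("pipeline stages are length-preserving and near-idempotent", {
  sc <- synth_config(seed = 3)
  src <- gen_source(sc)
  cfg <- denoise_config()
  rms <- function(x) sqrt(mean(x^2))
  # each stage applied at its pipeline position (despiked input and so on)
  a <- despike(src, cfg)
  b <- remove_baseline(a, cfg)
  c <- bandpass(b, cfg)
  for (x in list(a, b, c)) expect_length(x$samples, length(src$samples))
  expect_lt(rms(despike(a, cfg)$samples - a$samples), 1e-3 * rms(a$samples))
  # the morphology and the filter move residual band-edge energy when
  # reapplied; on pulse fixtures this settles within a few percent RMS
  expect_lt(rms(remove_baseline(b, cfg)$samples - b$samples),
            0.05 * rms(b$samples))
  expect_lt(rms(bandpass(c, cfg)$samples - c$samples), 0.05 * rms(c$samples))
  # for purely in-band content the filter is idempotent well below 1%
  tone <- signal_trace(sin(2 * pi * 3 * seq(0, 20, by = 0.02)), 50)
  t1 <- bandpass(tone, cfg)
  t2 <- bandpass(t1, cfg)
  expect_lt(rms(t2$samples - t1$samples), 0.01 * rms(t1$samples))
})

test_that("full chain raises SNR against the in-band clean reference", {
  cfg <- denoise_config()
  ctr <- function(x) x - mean(x)
  for (s in 1:5) {
    sc <- synth_config(seed = s)
    src <- gen_source(sc)
    oracle <- bandpass(signal_trace(attr(src, "clean"), sc$fs), cfg)$samples
    den <- denoise_pipeline(src, cfg)$samples
    rmse_raw <- sqrt(mean((ctr(src$samples) - ctr(oracle))^2))
    rmse_den <- sqrt(mean((ctr(den) - ctr(oracle))^2))
    expect_lt(rmse_den, rmse_raw)
    snr <- function(res) 10 * log10(sum(ctr(oracle)^2) / sum(res^2))
    expect_gt(snr(ctr(den) - ctr(oracle)), snr(ctr(src$samples) - ctr(oracle)))
  }
  # a clean bandlimited pulse train sails through nearly unchanged
  sc0 <- clean_synth(seed = 9)
  src0 <- gen_source(sc0)
  out <- denoise_pipeline(src0, cfg)
  expect_gt(cor(out$samples, src0$samples), 0.95)
  z <- denoise_pipeline(signal_trace(rep(0, 600), 50), cfg)
  expect_equal(z$samples, rep(0, 600))
})
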