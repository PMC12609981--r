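test_that("a 1 Hz sine segments into 9 trough-to-trough cycles", {
  tr <- sine_trace(1, 100, 10)
  seg <- segment_cycles(tr)
  expect_equal(length(seg$boundaries) - 1, 9)
  expect_equal(length(seg$peaks), 9)
  expect_true(all(abs(diff(seg$peaks) - 100) <= 1))
  # strict interleaving t_v[i] < t_p[i] < t_v[i+1]
  expect_true(all(seg$troughs[seq_along(seg$peaks)] < seg$peaks))
  expect_true(all(seg$peaks < seg$troughs[seq_along(seg$peaks) + 1]))
  expect_identical(seg$boundaries, seg$troughs)
})

test_that("degenerate inputs fail segmentation cleanly", {
  expect_error(segment_cycles(signal_trace(rep(1, 500), 100)), "constant")
  # half a cycle: no two troughs
  half <- signal_trace(sin(2 * pi * seq(0, 0.5, by = 0.01)), 100)
  expect_error(segment_cycles(half), "fewer than 2 cycles")
})

test_that("cycle features follow the peak/trough definitions", {
  tr <- sine_trace(1, 100, 10)
  seg <- segment_cycles(tr)
  cf <- cycle_features(tr, seg)
  expect_equal(cf$amp, rep(2, 9), tolerance = 1e-3)
  expect_equal(cf$width, rep(1, 9), tolerance = 0.02)
  expect_equal(cf$width, cf$rise + cf$fall)  # exact by construction

  # sawtooth with 25% rise fraction at 1 Hz
  fs <- 200
  phi <- ((0:(10 * fs - 1)) / fs) %% 1
  saw <- ifelse(phi < 0.25, phi / 0.25, 1 - (phi - 0.25) / 0.75)
  seg2 <- segment_cycles(signal_trace(saw, fs))
  cf2 <- cycle_features(signal_trace(saw, fs), seg2)
  expect_equal(median(cf2$rise), 0.25, tolerance = 0.03)
  expect_equal(median(cf2$fall), 0.75, tolerance = 0.03)

  # symmetric triangle: rise = fall = width / 2
  tri <- ifelse(phi < 0.5, phi, 1 - phi) * 2
  trt <- signal_trace(tri, fs)
  cf3 <- cycle_features(trt, segment_cycles(trt))
  expect_equal(cf3$rise, cf3$width / 2, tolerance = 0.02)
})

test_that("derivatives are exact for polynomials at interior points", {
  fs <- 100
  ramp <- signal_trace(0.5 * (0:99) / fs, fs)
  d <- derivatives(ramp)
  expect_equal(d$d1[2:99], rep(0.5, 98))
  expect_equal(d$d2[2:99], rep(0, 98), tolerance = 1e-9)

  tq <- (0:199) / fs
  quad <- signal_trace(tq^2, fs)
  dq <- derivatives(quad)
  expect_equal(dq$d2[2:199], rep(2, 198), tolerance = 1e-6)

  const <- signal_trace(rep(3, 50), fs)
  dc <- derivatives(const)
  expect_equal(dc$d1, rep(0, 50))
  expect_equal(dc$d2, rep(0, 50))

  expect_error(derivatives(signal_trace(c(1, 2), fs)), "at least 3")
})

test_that("feature matrix is point-aligned, 7-channel, deterministic", {
  tr <- sine_trace(1, 100, 10)
  fm <- build_feature_matrix(tr)
  expect_equal(dim(fm), c(1000L, 7L))
  expect_identical(colnames(fm),
                   c("raw", "amp", "width", "rise", "fall", "d1", "d2"))
  expect_equal(fm[, "raw"], tr$samples, ignore_attr = TRUE)
  expect_false(anyNA(fm))
  # amplitude channel piecewise constant, one value per cycle
  seg <- attr(fm, "seg")
  cf <- cycle_features(tr, seg)
  expect_setequal(unique(fm[, "amp"]), unique(cf$amp))
  # deterministic
  expect_identical(unclass(fm), unclass(build_feature_matrix(tr)))
})

test_that("cycles of different amplitude give a step in the amp channel", {
  fs <- 100
  t1 <- seq(0, 1 - 1 / fs, by = 1 / fs)
  p <- (1 - cos(2 * pi * t1)) / 2       # one nonnegative pulse, zero at edges
  tr <- signal_trace(c(p, p, 2 * p, 2 * p), fs)
  fm <- build_feature_matrix(tr)
  seg <- attr(fm, "seg")
  cf <- cycle_features(tr, seg)
  expect_equal(sort(unique(round(cf$amp, 6))), c(1, 2))
  amp_ch <- fm[, "amp"]
  # a two-level step function changing at the shared cycle boundary
  b <- seg$boundaries[which(diff(cf$amp) != 0) + 1]
  expect_true(all(amp_ch[1:(b - 1)] == 1))
  expect_true(all(amp_ch[b:length(amp_ch)] == 2))
})

test_that("programmed heart rate is recovered from widths", {
  for (hr in c(55, 70, 90)) {
    sc <- clean_synth(seed = hr, hr_bpm = hr)
    src <- gen_source(sc)
    fm <- build_feature_matrix(src)
    expect_equal(median(fm[, "width"]), 60 / hr, tolerance = 0.05 * 60 / hr)
  }
})
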