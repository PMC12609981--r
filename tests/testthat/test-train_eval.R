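test_that("metrics match brute-force arithmetic and known identities", {
  y <- c(1, 2, 3); p <- c(2, 2, 2)
  expect_equal(rmse(y, p), sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(rmse(y, p), 4), 0.8165)
  expect_equal(round(mae(y, p), 4), 0.6667)
  expect_equal(r2(y, p), 0)
  expect_equal(r2(y, y), 1)
  expect_equal(rmse(y, y), 0)
  expect_equal(mae(y, y), 0)
  expect_error(r2(rep(2, 5), rnorm(5)), "zero-variance")

  set.seed(33)
  for (i in 1:1000) {
    n <- sample(2:60, 1)
    y <- rnorm(n); p <- rnorm(n)
    e <- y - p
    expect_equal(rmse(y, p), sqrt(sum(e^2) / n))
    expect_equal(mae(y, p), sum(abs(e)) / n)
    expect_gte(rmse(y, p), mae(y, p))              # power-mean inequality
    if (var(y) > 0)
      expect_equal(r2(y, p), 1 - sum(e^2) / sum((y - mean(y))^2))
    expect_equal(r2(y, rep(mean(y), n)), 0)
  }
})

test_that("improvement deltas reproduce the printed worked examples", {
  d <- delta_metrics(eval_report(0.8212, 0.6647, 0.6744),
                     eval_report(0.4444, 0.3302, 0.9345))
  expect_equal(round(d$delta_rmse_pct, 1), 45.9)
  expect_equal(round(d$delta_mae_pct, 1), 50.3)
  expect_equal(round(d$delta_r2, 4), 0.2601)

  d2 <- delta_metrics(eval_report(11.8083, 8.8092, 0.7144),
                      eval_report(9.2924, 6.6348, 0.8231))
  expect_equal(round(d2$delta_rmse_pct, 1), 21.3)

  d3 <- delta_metrics(eval_report(1.3277, 1.0327, 0.4125),
                      eval_report(1.0827, 0.8407, 0.6093))
  expect_equal(round(d3$delta_rmse_pct, 1), 18.5)

  same <- eval_report(1, 0.5, 0.9)
  dz <- delta_metrics(same, same)
  expect_equal(unlist(dz), c(delta_rmse_pct = 0, delta_mae_pct = 0,
                             delta_r2 = 0))
})

test_that("Bland-Altman reproduces printed limits of agreement", {
  # from printed (bias, SD) pairs via the LoA identity
  loa <- function(bias, s) c(bias - 1.96 * s, bias + 1.96 * s)
  expect_equal(round(loa(-0.532, 0.69), 2), c(-1.88, 0.82))
  expect_equal(round(loa(-3.008, 1.037), 2), c(-5.04, -0.98))
  expect_equal(round(loa(-0.038, 3.498), 2)[2], 6.82)

  # the estimator itself: construct data with exact known bias and SD
  set.seed(9)
  ref <- rnorm(500)
  d <- scale(rnorm(500))[, 1] * 0.69 - 0.532   # sample mean/SD forced
  ba <- bland_altman(ref, ref + d)
  expect_equal(ba$bias, -0.532, tolerance = 1e-12)
  expect_equal(ba$sd, 0.69, tolerance = 1e-12)
  expect_equal(round(c(ba$loa_low, ba$loa_high), 2), c(-1.88, 0.82))
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd)
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)

  same <- bland_altman(1:10, 1:10)
  expect_equal(c(same$bias, same$sd, same$loa_low, same$loa_high),
               c(0, 0, 0, 0))
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("k-fold blocks are contiguous, disjoint, balanced and exhaustive", {
  f <- kfold_split(10, 5)
  expect_equal(f[[1]]$test, 1:2)
  expect_equal(f[[3]]$test, 5:6)
  expect_equal(f[[5]]$test, 9:10)
  for (n in c(10, 11, 57)) {
    folds <- kfold_split(n, 5)
    tests <- lapply(folds, `[[`, "test")
    expect_equal(sort(unlist(tests)), 1:n)
    expect_equal(sum(lengths(tests)), n)          # pairwise disjoint
    expect_lte(diff(range(lengths(tests))), 1)
    for (k in seq_along(folds)) {
      expect_equal(sort(c(folds[[k]]$train, folds[[k]]$test)), 1:n)
      expect_equal(folds[[k]]$test, min(folds[[k]]$test):max(folds[[k]]$test))
    }
  }
  expect_error(kfold_split(3, 5), "at least as many windows")
})

test_that("training overfits a single repeated window and is seeded", {
  set.seed(1)
  m <- init_cbanet(model_config(in_channels = 7, lstm_hidden = 16, heads = 4))
  x <- random_window(50, seed = 4)
  set.seed(5)
  y <- rnorm(50)
  tc <- train_config(epochs = 500, batch_size = 1, lr = 3e-3, seed = 1,
                     window = window_spec(50, 50))
  fit <- train_cbanet(m, list(x), list(y), tc)
  expect_lt(tail(fit$history, 1), 0.01 * fit$history[1])

  # same seed, same history; different seed, different history
  m2 <- init_cbanet(model_config(in_channels = 7, lstm_hidden = 16, heads = 4))
  tc2 <- train_config(epochs = 3, batch_size = 1, lr = 3e-3, seed = 11,
                      window = window_spec(50, 50))
  h1 <- train_cbanet(m2, list(x), list(y), tc2)$history
  h2 <- train_cbanet(m2, list(x), list(y), tc2)$history
  expect_identical(as.numeric(h1), as.numeric(h2))

  expect_error(train_cbanet(m, list(), list(), tc), "empty training set")
})

test_that("evaluating a mean-predicting model gives R2 of zero", {
  sc <- clean_synth(seed = 21, duration_s = 20)
  src <- gen_source(sc)
  tgt <- derive_target(src, sc)
  rec <- paired_record(src, tgt)
  fm <- build_feature_matrix(src)
  feats <- as.matrix(unclass(fm))
  norm <- fit_normalizer(feats, tgt$samples)
  m <- tiny_model()
  m$params <- pulsecast:::param_map(function(x) x * 0, m$params)
  spec <- window_spec(200, 50)
  ev <- evaluate_pipeline(m, rec, norm, spec, features = feats)
  # zeroed readout predicts the (normalized) zero = training target mean
  expect_equal(ev$report$r2, 0, tolerance = 1e-9)
  expect_gte(ev$report$rmse, ev$report$mae)
  expect_s3_class(ev$bland_altman, "bland_altman")
  expect_true(any(is.na(ev$prediction)) || all(ev$covered))
})
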