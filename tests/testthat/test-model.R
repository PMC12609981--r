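test_that("config invariants are enforced", {
  expect_error(model_config(kernel = 4), "odd")
  expect_error(model_config(lstm_hidden = 5, heads = 4), "divide")
  expect_error(model_config(dropout = 1), "dropout")
  expect_silent(model_config(lstm_hidden = 6, heads = 4))  # 12 / 4 = 3
})

test_that("shape contract holds along the whole chain for several T", {
  m <- tiny_model()
  h2 <- 2 * m$config$lstm_hidden
  for (Tn in c(3, 10, 700)) {
    x <- random_window(Tn, 7, seed = Tn)
    u <- lfe_forward(x, m)
    expect_equal(dim(u), c(Tn, m$config$conv2_channels))
    expect_true(all(u >= 0))                       # ReLU range
    v <- trn_forward(u, m)
    expect_equal(dim(v), c(Tn, h2))
    z <- gra_forward(v, m)
    expect_equal(dim(z), c(Tn, h2))
    y <- readout(z, m)
    expect_length(y, Tn)
    expect_equal(cbanet_forward(x, m), y)
  }
  expect_error(cbanet_forward(random_window(10, 5), m), "channels")
})

test_that("LFE is shift-equivariant away from the padded edges", {
  m <- tiny_model()
  x <- random_window(60, 7, seed = 3)
  k <- 5
  xs <- rbind(x[(k + 1):60, ], x[1:k, ])     # shift up by k
  a <- lfe_forward(x, m)
  b <- lfe_forward(xs, m)
  core <- 5:(60 - k - 5)
  expect_equal(b[core, ], a[core + k, ], tolerance = 1e-12)

  # zero input with zero biases gives zero output
  m0 <- m
  m0$params$conv1$b[] <- 0
  m0$params$conv2$b[] <- 0
  expect_equal(lfe_forward(matrix(0, 20, 7), m0), matrix(0, 20, 8))
})

test_that("bidirectional recurrence swaps halves under time reversal", {
  set.seed(8)
  m <- tiny_model()
  m$config$lstm_layers <- 1L
  m$params$lstm <- m$params$lstm[1]
  # share parameters across directions so reversal is an exact symmetry
  m$params$lstm[[1]]$bwd <- m$params$lstm[[1]]$fwd
  x <- matrix(rnorm(5 * m$config$conv2_channels), 5)
  h <- m$config$lstm_hidden
  out <- trn_forward(x, m)
  out_rev <- trn_forward(x[5:1, ], m)[5:1, ]
  expect_equal(out_rev[, 1:h], out[, (h + 1):(2 * h)], tolerance = 1e-12)
  expect_equal(out_rev[, (h + 1):(2 * h)], out[, 1:h], tolerance = 1e-12)

  # T = 1 degenerate sequence still conforms
  one <- trn_forward(matrix(rnorm(8), 1), tiny_model())
  expect_equal(dim(one), c(1L, 8L))
})

test_that("attention weights are row-stochastic across random models", {
  for (s in 1:100) {
    set.seed(s)
    m <- init_cbanet(model_config(in_channels = 3, conv1_channels = 4,
                                  conv2_channels = 4, lstm_hidden = 3,
                                  lstm_layers = 1, heads = 2))
    Tn <- sample(2:12, 1)
    v <- matrix(rnorm(Tn * 6), Tn, 6)
    z <- gra_forward(v, m, return_weights = TRUE)
    for (A in attr(z, "weights")) {
      expect_true(all(A >= 0 & A <= 1))
      expect_equal(rowSums(A), rep(1, Tn), tolerance = 1e-6)
    }
  }
  # T = 1: the only weight is exactly 1
  m <- tiny_model()
  z1 <- gra_forward(matrix(rnorm(8), 1), m, return_weights = TRUE)
  for (A in attr(z1, "weights")) expect_identical(dim(A), c(1L, 1L))
  expect_equal(attr(z1, "weights")[[1]][1, 1], 1)

  # zero keys give uniform attention
  mz <- tiny_model()
  mz$params$attn$Wk[] <- 0
  Tn <- 7
  zz <- gra_forward(matrix(rnorm(Tn * 8), Tn), mz, return_weights = TRUE)
  expect_equal(attr(zz, "weights")[[1]], matrix(1 / Tn, Tn, Tn))
})

test_that("readout applies one affine map per time step", {
  m <- tiny_model()
  m$params$out$W[] <- 0
  m$params$out$b <- 0.5
  z <- matrix(rnorm(12 * 8), 12)
  expect_equal(readout(z, m), rep(0.5, 12))
  m2 <- tiny_model(seed = 2)
  z2 <- z
  z2[4, ] <- z2[9, ]
  y <- readout(z2, m2)
  expect_equal(y[4], y[9])
})

test_that("forward pass is deterministic and parameters count up", {
  m <- tiny_model()
  x <- random_window(50)
  expect_identical(cbanet_forward(x, m), cbanet_forward(x, m))
  n1 <- count_params(m)
  expect_gt(n1, 0)
  set.seed(1)
  n2 <- count_params(init_cbanet(tiny_config(lstm_hidden = 8)))
  expect_gt(n2, n1)
  # default architecture: check the closed-form parameter count
  set.seed(1)
  md <- init_cbanet(model_config())
  h <- 64; d2 <- 128
  expected <- (7 * 3 * 32 + 32) + (32 * 3 * 64 + 64) +
    2 * (64 * 4 * h + h * 4 * h + 4 * h) +      # layer 1, both directions
    2 * (d2 * 4 * h + h * 4 * h + 4 * h) +      # layer 2, both directions
    4 * d2 * d2 + (d2 + 1)
  expect_equal(count_params(md), expected)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  cfg <- model_config(in_channels = 3, conv1_channels = 4, conv2_channels = 5,
                      lstm_hidden = 4, lstm_layers = 2, heads = 2)
  m <- init_cbanet(cfg)
  B <- 2; Tn <- 9
  Xb <- pulsecast:::stack_windows(
    lapply(1:B, function(i) matrix(rnorm(Tn * 3), Tn, 3)))
  Yb <- rnorm(B * Tn)
  lossfun <- function(model) {
    f <- pulsecast:::cbanet_forward_batch(model, Xb, B, Tn, train = FALSE)
    mean((f$Y - Yb)^2)
  }
  f <- pulsecast:::cbanet_forward_batch(m, Xb, B, Tn, train = FALSE)
  g <- pulsecast:::cbanet_backward_batch(m, f$cache,
                                         2 * (f$Y - Yb) / length(Yb))
  getv <- function(lst, path) { for (k in path) lst <- lst[[k]]; lst }
  setv <- function(lst, path, i, v) {
    if (!length(path)) { lst[i] <- v; return(lst) }
    lst[[path[[1]]]] <- setv(lst[[path[[1]]]], path[-1], i, v)
    lst
  }
  paths <- list(list("conv1", "W", 2L), list("conv2", "b"),
                list("lstm", 1L, "fwd", "Wx"), list("lstm", 1L, "bwd", "Wh"),
                list("lstm", 2L, "fwd", "b"), list("attn", "Wq"),
                list("attn", "Wv"), list("attn", "Wo"), list("out", "W"))
  for (path in paths) {
    p <- getv(m$params, path)
    ga <- getv(g, path)
    # every parameter tensor participates in the fit (no dead wiring)
    expect_true(any(ga != 0))
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- m
      fl <- function(v) {
        m2$params <- setv(m$params, path, i, v)
        lossfun(m2)
      }
      eps <- 1e-6
      gn <- (fl(p[i] + eps) - fl(p[i] - eps)) / (2 * eps)
      expect_lt(abs(gn - ga[[i]]) / max(1e-6, abs(gn) + abs(ga[[i]])), 5e-3)
    }
  }
})

test_that("dropout perturbs training but not inference", {
  set.seed(3)
  m <- init_cbanet(tiny_config(dropout = 0.3))
  x <- random_window(40)
  expect_identical(cbanet_forward(x, m), cbanet_forward(x, m))
  set.seed(10)
  y <- rnorm(40)
  tc <- train_config(epochs = 2, batch_size = 1, lr = 1e-3, seed = 2,
                     window = window_spec(40, 40))
  fit <- train_cbanet(m, list(x), list(y), tc)
  expect_true(all(is.finite(fit$history)))
})

test_that("checkpoints round-trip configuration and forward outputs", {
  m <- tiny_model(seed = 6)
  p <- withr::local_tempfile(fileext = ".rds")
  save_cbanet(m, p)
  m2 <- load_cbanet(p)
  x <- random_window(40)
  expect_lt(max(abs(cbanet_forward(x, m) - cbanet_forward(x, m2))), 1e-6)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_cbanet(bad), "not a pulsecast checkpoint")
})
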