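#' CBAnet model configuration
#'
#' Architecture hyperparameters for the local-convolution + bidirectional-LSTM
#' + self-attention network. The forward shape contract is
#' `T x in_channels -> T x conv2_channels -> T x 2h -> T x 2h -> T x 1`
#' for any window length `T >= kernel`.
#'
#' @param in_channels Input channels (7 for the composite feature matrix,
#'   1 for raw-only ablations).
#' @param conv1_channels,conv2_channels Widths of the two local feature
#'   extraction (LFE) convolutions. Defaults 32 and 64.
#' @param kernel Odd convolution kernel length; 3 gives the three-point
#'   neighborhood that smooths noise while keeping edge gradients. Default 3.
#' @param lstm_hidden Unidirectional hidden size `h`; the bidirectional
#'   concatenation is `2h` wide. Default 64.
#' @param lstm_layers Number of stacked bidirectional LSTM layers. Default 2.
#' @param heads Attention heads; must divide `2 * lstm_hidden`
#'   (single-head width `d_k = 2h / heads`). Default 4.
#' @param dropout Dropout probability in `[0, 1)` applied after the LFE stack
#'   and after attention during training. Default 0.
#' @return An object of class `model_config`.
#' @export
model_config <- function(in_channels = 7L, conv1_channels = 32L,
                         conv2_channels = 64L, kernel = 3L,
                         lstm_hidden = 64L, lstm_layers = 2L,
                         heads = 4L, dropout = 0) {
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L) stop("model_config: kernel must be odd")
  if ((2L * lstm_hidden) %% heads != 0L)
    stop("model_config: heads (", heads, ") must divide 2*lstm_hidden (",
         2 * lstm_hidden, ")")
  if (dropout < 0 || dropout >= 1) stop("model_config: dropout must be in [0,1)")
  structure(list(in_channels = as.integer(in_channels),
                 conv1_channels = as.integer(conv1_channels),
                 conv2_channels = as.integer(conv2_channels),
                 kernel = kernel, lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = as.integer(lstm_layers),
                 heads = as.integer(heads), dropout = dropout),
            class = "model_config")
}

unif_init <- function(nr, nc, fan_in) {
  b <- 1 / sqrt(fan_in)
  matrix(runif(nr * nc, -b, b), nr, nc)
}

# near-orthogonal recurrent block per gate, for stable gradient propagation
ortho_gate_init <- function(h, gates = 4L) {
  do.call(cbind, lapply(seq_len(gates), function(g) {
    qr.Q(qr(matrix(rnorm(h * h), h, h)))
  }))
}

#' Initialize a CBAnet model
#'
#' Allocates all parameters: the two LFE convolutions (`W1,b1`, `W2,b2`),
#' the stacked bidirectional LSTM (input/recurrent weights and biases per
#' direction and layer; forget-gate biases start at 1), the attention
#' projections `W^Q, W^K, W^V, W^O`, and the pointwise readout `W_out, b`.
#' Convolution and linear weights are fan-in uniform; recurrent weights are
#' per-gate orthogonal. Uses R's RNG, so wrap in `set.seed()` for
#' reproducibility.
#'
#' @param config A [model_config()].
#' @return An object of class `cbanet_model` with elements `config` and
#'   `params`.
#' @export
init_cbanet <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  K <- config$kernel
  h <- config$lstm_hidden
  d2h <- 2L * h
  conv_init <- function(cin, cout)
    list(W = lapply(seq_len(K), function(k) unif_init(cin, cout, cin * K)),
         b = numeric(cout))
  lstm_init <- function(cin)
    list(Wx = unif_init(cin, 4L * h, cin),
         Wh = ortho_gate_init(h),
         b = rep(c(0, 1, 0, 0), each = h))   # forget-gate bias 1
  layers <- vector("list", config$lstm_layers)
  cin <- config$conv2_channels
  for (l in seq_len(config$lstm_layers)) {
    layers[[l]] <- list(fwd = lstm_init(cin), bwd = lstm_init(cin))
    cin <- d2h
  }
  params <- list(
    conv1 = conv_init(config$in_channels, config$conv1_channels),
    conv2 = conv_init(config$conv1_channels, config$conv2_channels),
    lstm = layers,
    attn = list(Wq = unif_init(d2h, d2h, d2h), Wk = unif_init(d2h, d2h, d2h),
                Wv = unif_init(d2h, d2h, d2h), Wo = unif_init(d2h, d2h, d2h)),
    out = list(W = unif_init(d2h, 1L, d2h), b = 0)
  )
  structure(list(config = config, params = params), class = "cbanet_model")
}

#' @export
print.cbanet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<cbanet_model> in=%d, conv %d/%d (kernel %d), ",
                     "biLSTM %d x h=%d, %d attention heads, %d parameters\n"),
              cfg$in_channels, cfg$conv1_channels, cfg$conv2_channels,
              cfg$kernel, cfg$lstm_layers, cfg$lstm_hidden, cfg$heads,
              count_params(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model A [init_cbanet()] model.
#' @return Total number of scalar parameters.
#' @export
count_params <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.numeric(x)) n <<- n + length(x) else for (el in x) walk(el)
  }
  walk(model$params)
  n
}

## ---- batched internals -----------------------------------------------------
## Big matrices have B*T rows; row b + (t-1)*B holds window b, time t.

# shift the time axis by `o` steps (positive o reads later samples), zero-padded
shift_time <- function(M, o, B) {
  if (o == 0L) return(M)
  n <- nrow(M)
  k <- abs(o) * B
  out <- matrix(0, n, ncol(M))
  if (k < n) {
    if (o > 0) out[1:(n - k), ] <- M[(k + 1):n, , drop = FALSE]
    else out[(k + 1):n, ] <- M[1:(n - k), , drop = FALSE]
  }
  out
}

conv_fwd <- function(Xb, layer, B) {
  K <- length(layer$W)
  ctr <- (K + 1L) %/% 2L
  out <- matrix(rep(layer$b, each = nrow(Xb)), nrow(Xb))
  for (k in seq_len(K))
    out <- out + shift_time(Xb, k - ctr, B) %*% layer$W[[k]]
  out
}

conv_bwd <- function(dY, Xb, layer, B) {
  K <- length(layer$W)
  ctr <- (K + 1L) %/% 2L
  dX <- matrix(0, nrow(Xb), ncol(Xb))
  dW <- vector("list", K)
  for (k in seq_len(K)) {
    o <- k - ctr
    Xs <- shift_time(Xb, o, B)
    dW[[k]] <- crossprod(Xs, dY)
    dX <- dX + shift_time(dY %*% t(layer$W[[k]]), -o, B)
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

time_reverse_index <- function(B, T)
  as.vector(outer(seq_len(B), (rev(seq_len(T)) - 1L) * B, "+"))

bilstm_fwd <- function(Xb, layer, B, T) {
  run <- function(X, p) {
    Gx <- X %*% p$Wx
    Gx <- Gx + rep(p$b, each = nrow(Gx))
    c(lstm_forward_cpp(Gx, p$Wh, B, T), list(Gx_in = X))
  }
  rev_idx <- time_reverse_index(B, T)
  fw <- run(Xb, layer$fwd)
  bw <- run(Xb[rev_idx, , drop = FALSE], layer$bwd)
  H <- cbind(fw$H, bw$H[rev_idx, , drop = FALSE])
  list(H = H, fw = fw, bw = bw, rev_idx = rev_idx)
}

bilstm_bwd <- function(dH, cache, layer, B, T) {
  h <- ncol(cache$fw$H)
  rev_idx <- cache$rev_idx
  back <- function(dHdir, cc, p) {
    r <- lstm_backward_cpp(dHdir, p$Wh, cc$I, cc$F, cc$G, cc$O, cc$C, cc$H, B, T)
    list(dX = r$dGx %*% t(p$Wx),
         grads = list(Wx = crossprod(cc$Gx_in, r$dGx), Wh = r$dWh,
                      b = colSums(r$dGx)))
  }
  rf <- back(dH[, 1:h, drop = FALSE], cache$fw, layer$fwd)
  rb <- back(dH[rev_idx, (h + 1):(2 * h), drop = FALSE], cache$bw, layer$bwd)
  list(dX = rf$dX + rb$dX[rev_idx, , drop = FALSE],
       grads = list(fwd = rf$grads, bwd = rb$grads))
}

attn_fwd <- function(Hb, attn, heads, B, T) {
  d2h <- ncol(Hb)
  dk <- d2h %/% heads
  Q <- Hb %*% attn$Wq; K <- Hb %*% attn$Wk; V <- Hb %*% attn$Wv
  O <- matrix(0, nrow(Hb), d2h)
  A <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- seq(b, by = B, length.out = T)
    Ab <- vector("list", heads)
    for (hd in seq_len(heads)) {
      cols <- ((hd - 1L) * dk + 1L):(hd * dk)
      S <- tcrossprod(Q[rows, cols, drop = FALSE],
                      K[rows, cols, drop = FALSE]) / sqrt(dk)
      S <- S - apply(S, 1, max)           # row-wise stabilized softmax
      E <- exp(S)
      Ah <- E / rowSums(E)
      O[rows, cols] <- Ah %*% V[rows, cols, drop = FALSE]
      Ab[[hd]] <- Ah
    }
    A[[b]] <- Ab
  }
  Z <- O %*% attn$Wo
  list(Z = Z, Q = Q, K = K, V = V, O = O, A = A)
}

attn_bwd <- function(dZ, Hb, cache, attn, heads, B, T) {
  d2h <- ncol(Hb)
  dk <- d2h %/% heads
  dWo <- crossprod(cache$O, dZ)
  dO <- dZ %*% t(attn$Wo)
  dQ <- matrix(0, nrow(Hb), d2h); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- seq(b, by = B, length.out = T)
    for (hd in seq_len(heads)) {
      cols <- ((hd - 1L) * dk + 1L):(hd * dk)
      Ah <- cache$A[[b]][[hd]]
      dOh <- dO[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOh, cache$V[rows, cols, drop = FALSE])
      dV[rows, cols] <- crossprod(Ah, dOh)
      dS <- Ah * (dA - rowSums(dA * Ah))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] / sqrt(dk)
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) / sqrt(dk)
    }
  }
  list(dH = dQ %*% t(attn$Wq) + dK %*% t(attn$Wk) + dV %*% t(attn$Wv),
       grads = list(Wq = crossprod(Hb, dQ), Wk = crossprod(Hb, dK),
                    Wv = crossprod(Hb, dV), Wo = dWo))
}

# full batched forward; `train` enables dropout and keeps caches for backprop
cbanet_forward_batch <- function(model, Xb, B, T, train = FALSE) {
  p <- model$params
  cfg <- model$config
  cache <- list(Xb = Xb, B = B, T = T)

  U1p <- conv_fwd(Xb, p$conv1, B)
  U1 <- pmax(U1p, 0)
  H2p <- conv_fwd(U1, p$conv2, B)
  Hlfe <- pmax(H2p, 0)
  cache$U1p <- U1p; cache$U1 <- U1; cache$H2p <- H2p

  if (train && cfg$dropout > 0) {
    cache$mask_lfe <- matrix(
      (runif(length(Hlfe)) >= cfg$dropout) / (1 - cfg$dropout),
      nrow(Hlfe), ncol(Hlfe))
    Hlfe <- Hlfe * cache$mask_lfe
  }
  cache$Hlfe <- Hlfe

  X <- Hlfe
  cache$lstm <- vector("list", cfg$lstm_layers)
  cache$lstm_in <- vector("list", cfg$lstm_layers)
  for (l in seq_len(cfg$lstm_layers)) {
    cache$lstm_in[[l]] <- X
    r <- bilstm_fwd(X, p$lstm[[l]], B, T)
    cache$lstm[[l]] <- r
    X <- r$H
  }
  Htrn <- X
  cache$Htrn <- Htrn

  at <- attn_fwd(Htrn, p$attn, cfg$heads, B, T)
  Z <- at$Z
  cache$attn <- at
  if (train && cfg$dropout > 0) {
    cache$mask_z <- matrix(
      (runif(length(Z)) >= cfg$dropout) / (1 - cfg$dropout), nrow(Z), ncol(Z))
    Z <- Z * cache$mask_z
  }
  cache$Z <- Z

  Y <- drop(Z %*% p$out$W) + p$out$b
  list(Y = Y, cache = cache)
}

cbanet_backward_batch <- function(model, cache, dY) {
  p <- model$params
  cfg <- model$config
  B <- cache$B; T <- cache$T
  dY <- matrix(dY, ncol = 1L)

  g_out <- list(W = crossprod(cache$Z, dY), b = sum(dY))
  dZ <- dY %*% t(p$out$W)
  if (!is.null(cache$mask_z)) dZ <- dZ * cache$mask_z

  at <- attn_bwd(dZ, cache$Htrn, cache$attn, p$attn, cfg$heads, B, T)
  dH <- at$dH

  g_lstm <- vector("list", cfg$lstm_layers)
  for (l in rev(seq_len(cfg$lstm_layers))) {
    r <- bilstm_bwd(dH, cache$lstm[[l]], p$lstm[[l]], B, T)
    g_lstm[[l]] <- r$grads
    dH <- r$dX
  }
  if (!is.null(cache$mask_lfe)) dH <- dH * cache$mask_lfe

  dH2p <- dH * (cache$H2p > 0)
  c2 <- conv_bwd(dH2p, cache$U1, p$conv2, B)
  dU1p <- c2$dX * (cache$U1p > 0)
  c1 <- conv_bwd(dU1p, cache$Xb, p$conv1, B)

  list(conv1 = list(W = c1$dW, b = c1$db),
       conv2 = list(W = c2$dW, b = c2$db),
       lstm = g_lstm,
       attn = at$grads,
       out = g_out)
}

## ---- public single-window surface -----------------------------------------

as_one_window <- function(x, channels) {
  x <- as.matrix(unclass(x))
  if (ncol(x) != channels)
    stop("expected ", channels, " channels, got ", ncol(x))
  x
}

#' Local feature extraction subnet (two same-length convolutions)
#'
#' Two 1-D convolutions (kernel `config$kernel`, stride 1, zero "same"
#' padding, no subsampling), each followed by ReLU:
#' `T x in_channels -> T x conv1_channels -> T x conv2_channels`.
#'
#' @param x A `T x in_channels` numeric matrix (one window).
#' @param model A [init_cbanet()] model.
#' @return A `T x conv2_channels` matrix.
#' @export
lfe_forward <- function(x, model) {
  Xb <- as_one_window(x, model$config$in_channels)
  if (nrow(Xb) < model$config$kernel)
    stop("lfe_forward: window shorter than the convolution kernel")
  U1 <- pmax(conv_fwd(Xb, model$params$conv1, 1L), 0)
  pmax(conv_fwd(U1, model$params$conv2, 1L), 0)
}

#' Temporal representation subnet (stacked bidirectional LSTM)
#'
#' At each time step the forward and backward hidden states are concatenated,
#' giving `T x 2h`.
#'
#' @param h_lfe A `T x conv2_channels` matrix from [lfe_forward()].
#' @inheritParams lfe_forward
#' @return A `T x 2h` matrix.
#' @export
trn_forward <- function(h_lfe, model) {
  X <- as.matrix(h_lfe)
  T <- nrow(X)
  for (l in seq_len(model$config$lstm_layers))
    X <- bilstm_fwd(X, model$params$lstm[[l]], 1L, T)$H
  X
}

#' Global reweighting/alignment subnet (multi-head self-attention)
#'
#' Scaled dot-product self-attention over the whole window (no causal mask):
#' every pair of time steps is directly visible. Per-head attention weights
#' are row-stochastic; heads are concatenated and projected back to `2h`.
#'
#' @param h_trn A `T x 2h` matrix from [trn_forward()].
#' @inheritParams lfe_forward
#' @param return_weights If `TRUE`, attach the per-head `T x T` attention
#'   matrices as attribute `"weights"`.
#' @return A `T x 2h` matrix.
#' @export
gra_forward <- function(h_trn, model, return_weights = FALSE) {
  X <- as.matrix(h_trn)
  r <- attn_fwd(X, model$params$attn, model$config$heads, 1L, nrow(X))
  if (return_weights) attr(r$Z, "weights") <- r$A[[1L]]
  r$Z
}

#' Pointwise linear readout
#'
#' The same affine map applied independently at every time step:
#' `T x 2h -> T x 1`.
#'
#' @param z A `T x 2h` matrix from [gra_forward()].
#' @inheritParams lfe_forward
#' @return A numeric vector of length `T`.
#' @export
readout <- function(z, model) {
  drop(as.matrix(z) %*% model$params$out$W) + model$params$out$b
}

#' Full CBAnet forward pass (inference)
#'
#' Composition `readout(gra_forward(trn_forward(lfe_forward(x))))`;
#' deterministic for fixed weights (no dropout at inference).
#'
#' @param x A `T x in_channels` window.
#' @inheritParams lfe_forward
#' @return A numeric prediction vector of length `T`.
#' @export
cbanet_forward <- function(x, model) {
  Xb <- as_one_window(x, model$config$in_channels)
  drop(cbanet_forward_batch(model, Xb, 1L, nrow(Xb), train = FALSE)$Y)
}

#' Save / load a model checkpoint
#'
#' Stores configuration and parameters in a versioned RDS file;
#' `load_cbanet(save_cbanet(m, path))` reproduces forward outputs exactly.
#'
#' @param model A [init_cbanet()] model.
#' @param path Checkpoint path.
#' @return `save_cbanet` returns `path` invisibly; `load_cbanet` the model.
#' @export
save_cbanet <- function(model, path) {
  stopifnot(inherits(model, "cbanet_model"))
  saveRDS(list(format = "pulsecast-cbanet", version = 1L,
               config = unclass(model$config), params = model$params),
          path)
  invisible(path)
}

#' @rdname save_cbanet
#' @export
load_cbanet <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pulsecast-cbanet"))
    stop("load_cbanet: not a pulsecast checkpoint: ", path)
  structure(list(config = do.call(model_config, obj$config),
                 params = obj$params),
            class = "cbanet_model")
}
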