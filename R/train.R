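#' Training configuration
#'
#' @param epochs Training epochs (default 100 at full scale).
#' @param batch_size Windows per optimizer step (default 32).
#' @param lr AdamW learning rate (default 1e-3).
#' @param weight_decay AdamW decoupled weight decay, applied to weight
#'   matrices only (default 1e-2).
#' @param seed Integer seed keying all training randomness (initialization,
#'   shuffling, dropout).
#' @param folds Folds for [kfold_split()] (default 5).
#' @param window A [window_spec()].
#' @param loss A [loss_config()]; `loss_config(0, 0, 0)` (the default here)
#'   trains on plain MSE, the primary objective; nonzero weights enable the
#'   composite shape/spectral loss.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, lr = 1e-3,
                         weight_decay = 1e-2, seed = 1L, folds = 5L,
                         window = window_spec(), loss = loss_config(0, 0, 0)) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, weight_decay >= 0,
            folds >= 2, inherits(window, "window_spec"),
            inherits(loss, "loss_config"))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay,
                 seed = as.integer(seed), folds = as.integer(folds),
                 window = window, loss = loss),
            class = "train_config")
}

## recursive helpers over nested parameter lists (leaves = numeric arrays)
param_map <- function(f, ...) {
  ls <- list(...)
  if (is.numeric(ls[[1]])) return(do.call(f, ls))
  out <- vector("list", length(ls[[1]]))
  names(out) <- names(ls[[1]])
  for (i in seq_along(out))
    out[[i]] <- do.call(param_map, c(list(f), lapply(ls, `[[`, i)))
  out
}

zeros_like <- function(p) param_map(function(x) x * 0, p)

#' One AdamW step over a nested parameter list
#'
#' Decoupled weight decay: `p <- p - lr * (m_hat / (sqrt(v_hat) + eps)
#' + wd * p)`, with decay applied only to leaves flagged as weights (all
#' matrices; bias vectors and scalars are exempt).
#'
#' @param params,grads,state Nested lists with identical shape; `state` holds
#'   `m`, `v`, `t` and is created by `adamw_state(params)`.
#' @param lr,weight_decay,beta1,beta2,eps AdamW hyperparameters.
#' @return A list with updated `params` and `state`.
#' @keywords internal
adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- param_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- param_map(function(p, m, v) {
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    wd <- if (is.matrix(p)) weight_decay else 0
    p - lr * (upd + wd * p)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

adamw_state <- function(params)
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)

# stack a list of T x C windows (or length-T vectors) into the (B*T) x C
# time-major batch layout used by the batched forward/backward kernels
stack_windows <- function(windows) {
  if (is.null(dim(windows[[1]]))) windows <- lapply(windows, cbind)
  B <- length(windows)
  Tn <- nrow(windows[[1]])
  C <- ncol(windows[[1]])
  arr <- array(unlist(windows, use.names = FALSE), dim = c(Tn, C, B))
  matrix(aperm(arr, c(3L, 1L, 2L)), B * Tn, C)
}

#' Train a CBAnet model by mini-batch AdamW
#'
#' Optimizes the model on paired (feature window, target window) lists for
#' `cfg$epochs` epochs, shuffling window order each epoch. Both inputs are
#' expected on the normalized scale. All randomness is keyed to `cfg$seed`,
#' so identical calls yield identical loss histories. Training aborts with
#' diagnostics if the loss becomes non-finite.
#'
#' @param model A [init_cbanet()] model (trained in place functionally;
#'   the updated model is returned).
#' @param x_windows List of `T x in_channels` feature windows.
#' @param y_windows List of length-`T` target vectors, same order.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A list with `model` (trained) and `history` (per-epoch mean
#'   training loss, with per-term breakdown as attribute `"terms"`).
#' @export
train_cbanet <- function(model, x_windows, y_windows, cfg = train_config(),
                         verbose = FALSE) {
  stopifnot(inherits(model, "cbanet_model"), inherits(cfg, "train_config"))
  nw <- length(x_windows)
  if (nw == 0L) stop("train_cbanet: empty training set")
  if (length(y_windows) != nw)
    stop("train_cbanet: x/y window count mismatch")
  set.seed(cfg$seed)
  state <- adamw_state(model$params)
  history <- numeric(cfg$epochs)
  terms <- matrix(0, cfg$epochs, 4L,
                  dimnames = list(NULL, c("mse", "delta", "psd", "rho")))
  use_composite <- cfg$loss$lambda_delta > 0 || cfg$loss$lambda_psd > 0 ||
    cfg$loss$lambda_rho > 0

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(nw)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    ep_terms <- numeric(4L)
    for (bi in batches) {
      B <- length(bi)
      Xb <- stack_windows(x_windows[bi])
      Tn <- nrow(Xb) %/% B
      Yb <- stack_windows(y_windows[bi])   # (B*T) x 1
      fwd <- cbanet_forward_batch(model, Xb, B, Tn, train = TRUE)
      if (use_composite) {
        # per-window composite loss, averaged over the batch
        dY <- numeric(B * Tn)
        tot <- 0; trm <- numeric(4L)
        for (b in seq_len(B)) {
          rows <- seq(b, by = B, length.out = Tn)
          cl <- composite_loss(fwd$Y[rows], Yb[rows, 1L], cfg$loss, grad = TRUE)
          dY[rows] <- cl$grad / B
          tot <- tot + cl$total / B
          trm <- trm + c(cl$mse, cl$delta, cl$psd, cl$rho) / B
        }
        loss <- tot
      } else {
        e <- fwd$Y - Yb[, 1L]
        loss <- mean(e^2)
        trm <- c(loss, 0, 0, 0)
        dY <- 2 * e / length(e)
      }
      if (!is.finite(loss))
        stop("train_cbanet: non-finite loss at epoch ", ep,
             " (last finite epoch loss: ",
             if (ep > 1) history[ep - 1] else "none", ")")
      grads <- cbanet_backward_batch(model, fwd$cache, dY)
      st <- adamw_step(model$params, grads, state, cfg$lr, cfg$weight_decay)
      model$params <- st$params
      state <- st$state
      ep_loss <- ep_loss + loss * B / nw
      ep_terms <- ep_terms + trm * B / nw
    }
    history[ep] <- ep_loss
    terms[ep, ] <- ep_terms
    if (verbose)
      message(sprintf("epoch %3d/%d  loss %.6f", ep, cfg$epochs, ep_loss))
  }
  attr(history, "terms") <- terms
  list(model = model, history = history)
}

#' Contiguous k-fold split of window indices
#'
#' Partitions `1:n_windows` into `folds` contiguous test blocks whose sizes
#' differ by at most one; the remaining indices form each fold's training
#' set. Blocks are contiguous in time (no shuffling) so overlapping windows
#' cannot leak across the split.
#'
#' @param n_windows Number of windows (`>= folds`).
#' @param folds Number of folds.
#' @return A list of `folds` elements, each `list(train =, test =)`.
#' @export
kfold_split <- function(n_windows, folds = 5L) {
  if (n_windows < folds)
    stop("kfold_split: need at least as many windows as folds")
  sizes <- rep(n_windows %/% folds, folds)
  extra <- n_windows %% folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(folds), function(k) {
    test <- starts[k]:ends[k]
    list(train = setdiff(seq_len(n_windows), test), test = test)
  })
}
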