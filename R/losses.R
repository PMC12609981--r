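#' Composite loss configuration
#'
#' Weights for the shape/spectral consistency terms added to the mean-squared
#' error: `L = L_MSE + lambda_delta * L_delta + lambda_psd * L_psd +
#' lambda_rho * L_rho`, where `L_delta` penalizes first-difference mismatch,
#' `L_psd` the squared L2 distance between one-sided periodograms, and
#' `L_rho = 1 - cor(pred, target)`. All weights zero reduces the loss to plain
#' MSE (the primary training objective).
#'
#' @param lambda_delta,lambda_psd,lambda_rho Non-negative weights; defaults
#'   0.1, 0.01, 0.1 — weak relative to `L_MSE` on z-scored targets.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(lambda_delta = 0.1, lambda_psd = 0.01,
                        lambda_rho = 0.1) {
  stopifnot(is.finite(lambda_delta), lambda_delta >= 0,
            is.finite(lambda_psd), lambda_psd >= 0,
            is.finite(lambda_rho), lambda_rho >= 0)
  structure(list(lambda_delta = lambda_delta, lambda_psd = lambda_psd,
                 lambda_rho = lambda_rho), class = "loss_config")
}

#' Mean squared error loss
#'
#' `(1/T) * sum((pred - target)^2)`.
#'
#' @param pred,target Numeric vectors of equal length.
#' @return A non-negative scalar.
#' @export
mse_loss <- function(pred, target) {
  if (length(pred) != length(target))
    stop("mse_loss: length mismatch (", length(pred), " vs ",
         length(target), ")")
  mean((pred - target)^2)
}

# one-sided periodogram: squared magnitude of the DFT divided by T,
# bins 0 .. floor(T/2)
periodogram <- function(y) {
  Tn <- length(y)
  Fv <- fft(y)
  (Mod(Fv)^2 / Tn)[seq_len(Tn %/% 2L + 1L)]
}

#' Composite training loss with per-term breakdown
#'
#' `L = L_MSE + lambda_delta * sum((diff(pred) - diff(target))^2)
#'    + lambda_psd * ||P(pred) - P(target)||_2^2
#'    + lambda_rho * (1 - cor(pred, target))`,
#' with `P` the one-sided periodogram. If either input has zero variance the
#' correlation is undefined; the term is then set to 1 (`rho := 0`) with a
#' warning.
#'
#' @param pred,target Numeric vectors, length >= 2 (>= 4 when
#'   `lambda_psd > 0`).
#' @param cfg A [loss_config()].
#' @param grad If `TRUE`, also return the gradient of the total loss with
#'   respect to `pred`.
#' @return A list with `total`, `mse`, `delta`, `psd`, `rho` (unweighted term
#'   values) and, when requested, `grad`.
#' @export
composite_loss <- function(pred, target, cfg = loss_config(), grad = FALSE) {
  stopifnot(inherits(cfg, "loss_config"))
  Tn <- length(pred)
  if (Tn != length(target)) stop("composite_loss: length mismatch")
  if (Tn < 2L) stop("composite_loss: need length >= 2")
  if (cfg$lambda_psd > 0 && Tn < 4L)
    stop("composite_loss: spectral term needs length >= 4")
  e <- pred - target

  l_mse <- mean(e^2)
  g <- if (grad) 2 * e / Tn

  u <- diff(e)                            # diff(pred) - diff(target)
  l_delta <- sum(u^2)
  if (grad && cfg$lambda_delta > 0) {
    gd <- c(-2 * u, 0) + c(0, 2 * u)
    g <- g + cfg$lambda_delta * gd
  }

  l_psd <- 0
  if (cfg$lambda_psd > 0 || !grad) {
    Pp <- periodogram(pred)
    Pt <- periodogram(target)
    l_psd <- sum((Pp - Pt)^2)
    if (grad && cfg$lambda_psd > 0) {
      # dL/dpred_t = (4/T) Re( sum_k D_k conj(F_k) e^{-i 2pi (k-1)(t-1)/T} ),
      # i.e. a forward DFT of the zero-padded one-sided weights D * conj(F)
      D <- Pp - Pt
      Fv <- fft(pred)
      cvec <- complex(length.out = Tn)
      cvec[seq_along(D)] <- D * Conj(Fv[seq_along(D)])
      g <- g + cfg$lambda_psd * (4 / Tn) * Re(fft(cvec))
    }
  }

  sp <- sd(pred); st <- sd(target)
  if (sp == 0 || st == 0) {
    warning("composite_loss: zero-variance input; correlation term set to 1")
    rho <- 0
  } else {
    rho <- cor(pred, target)
  }
  l_rho <- 1 - rho
  if (grad && cfg$lambda_rho > 0 && sp > 0 && st > 0) {
    a <- pred - mean(pred)
    b <- target - mean(target)
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    drho <- b / (na * nb) - rho * a / na^2
    g <- g - cfg$lambda_rho * drho
  }

  total <- l_mse + cfg$lambda_delta * l_delta + cfg$lambda_psd * l_psd +
    cfg$lambda_rho * l_rho
  out <- list(total = total, mse = l_mse, delta = l_delta,
              psd = l_psd, rho = l_rho)
  if (grad) out$grad <- g
  out
}
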