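# Compact SIMPLS engine for univariate-response PLS regression.
#
# The repeated double cross-validation selector refits PLS thousands of
# times on shrinking feature sets, so the fitter is kept to bare linear
# algebra: centred SIMPLS with cumulative coefficient paths and VIP scores.
# For a single response SIMPLS and NIPALS span the same score space, which
# is what the unit-test cross-check against an external PLS fit relies on.

#' Fit a univariate-response PLS regression (SIMPLS)
#'
#' @param X numeric predictor matrix (n x p), used as-is apart from column
#'   centring (the analysis matrix is already standardized upstream).
#' @param y numeric response vector.
#' @param ncomp maximum number of latent components.
#' @return a `pls_fit` object: per-component coefficient paths `B`
#'   (p x ncomp), weights, scores, loadings, and the centres needed for
#'   prediction.
#' @export
pls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  S <- crossprod(Xc, yc)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  V <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    r <- S
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) {
      ncomp <- a - 1L
      break
    }
    t <- t / nt
    r <- r / nt
    pa <- crossprod(Xc, t)
    qa <- sum(yc * t)
    v <- pa
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pa)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    W[, a] <- r
    P[, a] <- pa
    Tm[, a] <- t
    q[a] <- qa
    V[, a] <- v
  }
  if (ncomp == 0) stop("no usable PLS component (constant predictors?)")
  keep <- seq_len(ncomp)
  B <- sapply(keep, function(a) {
    W[, seq_len(a), drop = FALSE] %*% q[seq_len(a)]
  })
  structure(list(B = matrix(B, p, ncomp), W = W[, keep, drop = FALSE],
                 P = P[, keep, drop = FALSE], Tm = Tm[, keep, drop = FALSE],
                 q = q[keep], xbar = xbar, ybar = ybar, ncomp = ncomp,
                 features = colnames(X)),
            class = "pls_fit")
}

#' @param object a `pls_fit`.
#' @param newdata matrix of predictors.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @rdname pls_fit
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  ncomp <- min(ncomp, object$ncomp)
  sweep(as.matrix(newdata), 2, object$xbar) %*% object$B[, ncomp] + object$ybar
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt(p * sum_a ss_a (w_ja / ||w_a||)^2 / sum_a ss_a)` with
#' `ss_a` the response sum of squares explained by component `a`.
#'
#' @param fit a [pls_fit()].
#' @param ncomp number of components to use.
#' @return named numeric vector of VIP scores.
#' @export
pls_vip <- function(fit, ncomp = fit$ncomp) {
  ncomp <- min(ncomp, fit$ncomp)
  W <- fit$W[, seq_len(ncomp), drop = FALSE]
  ss <- fit$q[seq_len(ncomp)]^2 # scores are unit-norm, so ss_a = q_a^2
  Wn <- sweep(W, 2, sqrt(colSums(W^2)), `/`)
  vip <- sqrt(nrow(W) * as.numeric(Wn^2 %*% ss) / sum(ss))
  names(vip) <- fit$features
  vip
}
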