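#' Fit a weighted linear mixed model with a single random intercept
#'
#' Fits the surrogate model of the IWLS algorithm,
#' `t_i = offset_i + X_i beta + b_{g(i)} + w_i^{-1/2} e_i`, with
#' `b ~ N_K(0, tau2 I)` and `e ~ N_n(0, sigma2 I)`, by restricted maximum
#' likelihood. The variance ratio `lambda = tau2 / sigma2` is profiled out:
#' for the group-indicator random-effect structure the marginal precision
#' has a closed form through the Woodbury identity, so each evaluation of
#' the profiled REML criterion costs O(n + K p^2), and `lambda` is found by
#' one-dimensional search of `log(lambda)` on `[-12, 12]`.
#'
#' @param t Numeric response vector (pseudo-response in the IWLS context).
#' @param X Fixed-effect design matrix, `n x p`, full column rank.
#' @param group Factor (or coercible) of length `n` assigning each
#'   observation to one of `K` groups.
#' @param w Positive observation weights; residual variance is
#'   `sigma2 / w_i`.
#' @param offset Known per-observation constant added to the mean.
#' @return A list of class `"wlmm_fit"`: `beta`, `beta_cov` (scaled by the
#'   REML `sigma2`), `b` (BLUPs, named by group level), `tau2`, `sigma2`,
#'   `loglik` (profiled REML criterion), `fitted` (including offset and
#'   BLUPs), `boundary` (`TRUE` when `tau2` is estimated at zero), and the
#'   group levels.
#' @export
fit_weighted_lmm <- function(t, X, group, w = rep(1, length(t)),
                             offset = rep(0, length(t))) {
  X <- as.matrix(X)
  n <- length(t)
  p <- ncol(X)
  if (nrow(X) != n || length(w) != n || length(offset) != n ||
      length(group) != n) {
    stop("dimensions of t, X, group, w, offset must conform", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(!is.finite(X)) || any(!is.finite(w)) ||
      any(!is.finite(offset))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (any(w <= 0)) stop("weights must be strictly positive", call. = FALSE)
  if (qr(X)$rank < p) {
    stop("fixed-effect design matrix is rank deficient", call. = FALSE)
  }
  group <- factor(group)
  K <- nlevels(group)
  r <- t - offset

  # weighted cross products; group sums reduce ZZ' terms to K-vectors
  s  <- as.vector(rowsum(w, group))            # sum of w per group
  Cx <- rowsum(w * X, group)                   # Z'WX  (K x p)
  cr <- as.vector(rowsum(w * r, group))        # Z'Wr  (K)
  XtWX <- crossprod(X, w * X)
  XtWr <- crossprod(X, w * r)
  rtWr <- sum(w * r * r)
  sum_log_w <- sum(log(w))

  # profiled REML criterion at variance ratio lambda = tau2/sigma2
  profile <- function(lambda) {
    d <- lambda / (1 + lambda * s)             # Woodbury middle factor
    XtVX <- XtWX - crossprod(Cx, d * Cx)
    XtVr <- XtWr - crossprod(Cx, d * cr)
    rtVr <- rtWr - sum(d * cr * cr)
    ch <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    beta <- backsolve(ch, forwardsolve(ch, XtVr, upper.tri = TRUE,
                                       transpose = TRUE))
    q <- rtVr - sum(XtVr * beta)
    q <- max(q, 1e-300)
    sigma2 <- q / (n - p)
    logdetV <- -sum_log_w + sum(log1p(lambda * s))
    logdetXtVX <- 2 * sum(log(diag(ch)))
    ll <- -0.5 * (logdetV + logdetXtVX +
                    (n - p) * (1 + log(2 * pi * sigma2)))
    list(ll = ll, beta = as.vector(beta), sigma2 = sigma2,
         XtVX = XtVX, d = d)
  }

  opt <- stats::optimize(function(ll) profile(exp(ll))$ll,
                         interval = c(-12, 12), maximum = TRUE, tol = 1e-9)
  lambda <- exp(opt$maximum)
  at_zero <- profile(0)
  boundary <- FALSE
  if (at_zero$ll >= opt$objective - 1e-8) {
    lambda <- 0
    sol <- at_zero
    boundary <- TRUE
  } else {
    sol <- profile(lambda)
  }

  beta <- sol$beta
  sigma2 <- sol$sigma2
  tau2 <- lambda * sigma2
  resid_fixed <- r - X %*% beta
  u <- as.vector(rowsum(w * as.vector(resid_fixed), group))
  b <- if (lambda > 0) lambda * u / (1 + lambda * s) else numeric(K)
  names(b) <- levels(group)
  beta_cov <- sigma2 * chol2inv(chol(sol$XtVX))
  dimnames(beta_cov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  structure(list(beta = beta, beta_cov = beta_cov, b = b,
                 tau2 = tau2, sigma2 = sigma2, loglik = sol$ll,
                 lambda = lambda, boundary = boundary,
                 fitted = as.vector(offset + X %*% beta + b[group]),
                 group_levels = levels(group)),
            class = "wlmm_fit")
}
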