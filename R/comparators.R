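#' Log relative-abundance transform
#'
#' Computes `log((y + 1) / T)`, the response of the log-transformed linear
#' mixed model comparator.
#'
#' @param y Non-negative counts.
#' @param total_reads Positive per-sample total reads.
#' @return Numeric vector.
#' @export
transform_log <- function(y, total_reads) {
  check_counts(y)
  if (any(!is.finite(total_reads)) || any(total_reads <= 0)) {
    stop("total reads must be finite and strictly positive", call. = FALSE)
  }
  log((y + 1) / total_reads)
}

#' Arcsine square root transform of relative abundance
#'
#' Computes `arcsin(sqrt(y / T))`, the variance-stabilizing transform used
#' by the arcsine linear (mixed) model comparators. Values lie in
#' `[0, pi/2]`.
#'
#' @inheritParams transform_log
#' @return Numeric vector in `[0, pi/2]`.
#' @export
transform_arcsine <- function(y, total_reads) {
  check_counts(y)
  if (any(!is.finite(total_reads)) || any(total_reads <= 0)) {
    stop("total reads must be finite and strictly positive", call. = FALSE)
  }
  if (any(y > total_reads)) {
    stop("counts exceed total reads: y / T must be a proportion",
         call. = FALSE)
  }
  asin(sqrt(y / total_reads))
}

#' Negative binomial regression without random effects
#'
#' Fits `y_i ~ NB(mu_i, theta)` with `log(mu_i) = offset_i + X_i beta` by
#' alternating IWLS updates of `beta` (weighted least squares on the
#' pseudo-data) with Newton-Raphson updates of `theta` — the same
#' machinery as the mixed model, with the random-effect term dropped.
#' The p-value for each coefficient is a Wald test against the standard
#' normal reference.
#'
#' @inheritParams fit_nbmm
#' @param coef Index of the coefficient of interest for the returned
#'   summary (the full Wald table is also attached).
#' @return A list of class `"comparator_result"` with `method = "NB"`,
#'   `beta_hat`, `se`, `p_value`, `converged`, `theta`, and the full
#'   coefficient table `wald`.
#' @export
fit_nb_glm <- function(y, X, offset = rep(0, length(y)),
                       control = nbmm_control(), coef = 2) {
  check_counts(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p) - 1)
  if (all(y == 0)) {
    stop("degenerate feature: response is all zeros", call. = FALSE)
  }
  if (qr(X)$rank < p) {
    stop("fixed-effect design matrix is rank deficient", call. = FALSE)
  }

  beta <- qr.coef(qr(X), log(y + 0.5) - offset)
  beta[!is.finite(beta)] <- 0
  theta <- control$theta_init
  eta <- offset + as.vector(X %*% beta)
  eta_sum_old <- sum(eta)
  converged <- FALSE

  XtWX <- NULL
  for (j in seq_len(control$max_iter)) {
    pd <- compute_pseudo_data(y, eta, theta, info = control$info,
                              w_floor = control$w_floor, warn = FALSE)
    XtWX <- crossprod(X, pd$w * X)
    beta <- solve(XtWX, crossprod(X, pd$w * (pd$t - offset)))
    eta_new <- offset + as.vector(X %*% beta)
    theta <- as.numeric(update_theta(y, exp(eta_new), theta_init = theta,
                                     bounds = control$theta_bounds,
                                     warn = FALSE))
    eta_sum <- sum(eta_new)
    sum_ok <- (eta_sum - eta_sum_old)^2 < control$tol * eta_sum^2
    max_ok <- max(abs(eta_new - eta)) < control$eta_tol
    eta <- eta_new
    eta_sum_old <- eta_sum
    if (sum_ok && max_ok) {
      converged <- TRUE
      break
    }
  }

  beta <- as.vector(beta)
  names(beta) <- colnames(X)
  se <- sqrt(diag(solve(XtWX)))
  stat <- beta / se
  pval <- 2 * stats::pnorm(-abs(stat))
  wald <- data.frame(coef = colnames(X), estimate = unname(beta),
                     se = unname(se), statistic = unname(stat),
                     p_value = unname(pval))
  structure(list(method = "NB", beta_hat = unname(beta[coef]),
                 se = unname(se[coef]), p_value = unname(pval[coef]),
                 converged = converged, theta = theta, wald = wald),
            class = "comparator_result")
}

#' Linear mixed model on transformed relative abundance
#'
#' Applies the log or arcsine square root transform to `y / T` and fits a
#' random-intercept linear mixed model with unit weights through the REML
#' engine. The p-value is a Wald t test on `n - p - (K - 1)` degrees of
#' freedom, matching the mixed-model testing convention used throughout.
#'
#' @inheritParams fit_nbmm
#' @param total_reads Positive per-sample total reads.
#' @param transform `"log"` or `"arcsine"`.
#' @param coef Index of the coefficient of interest.
#' @return A `"comparator_result"` with `method` `"LMM_log"` or
#'   `"LMM_arcsine"`.
#' @export
fit_lmm_transformed <- function(y, X, group, total_reads,
                                transform = c("log", "arcsine"), coef = 2) {
  transform <- match.arg(transform)
  resp <- switch(transform,
                 log = transform_log(y, total_reads),
                 arcsine = transform_arcsine(y, total_reads))
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  group <- factor(group)
  K <- nlevels(group)
  fit <- fit_weighted_lmm(resp, X, group)
  se <- sqrt(diag(fit$beta_cov))
  stat <- fit$beta / se
  df <- n - p - (K - 1)
  pval <- if (df > 0) 2 * stats::pt(-abs(stat), df = df) else
    2 * stats::pnorm(-abs(stat))
  structure(list(method = paste0("LMM_", transform),
                 beta_hat = unname(fit$beta[coef]), se = unname(se[coef]),
                 p_value = unname(pval[coef]), converged = TRUE,
                 tau2 = fit$tau2, sigma2 = fit$sigma2),
            class = "comparator_result")
}

#' Linear model on arcsine square root transformed relative abundance
#'
#' Ordinary least squares on `arcsin(sqrt(y / T))` with a classical t test
#' for each coefficient; the comparator that ignores both the count nature
#' of the data and the group structure.
#'
#' @inheritParams fit_lmm_transformed
#' @return A `"comparator_result"` with `method = "LM"`.
#' @export
fit_lm_arcsine <- function(y, X, total_reads, coef = 2) {
  resp <- transform_arcsine(y, total_reads)
  X <- as.matrix(X)
  fit <- stats::lm.fit(X, resp)
  rss <- sum(fit$residuals^2)
  df <- length(y) - fit$rank
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXinv))
  stat <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(stat), df = df)
  structure(list(method = "LM", beta_hat = unname(fit$coefficients[coef]),
                 se = unname(se[coef]), p_value = unname(pval[coef]),
                 converged = TRUE),
            class = "comparator_result")
}

#' @export
print.comparator_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.4g), p = %.4g%s\n", x$method,
              x$beta_hat, x$se, x$p_value,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}
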