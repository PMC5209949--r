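#' Control parameters for the IWLS fitting algorithm
#'
#' @param tol Relative convergence tolerance for the summed linear
#'   predictor criterion `(eta_j - eta_{j-1})^2 < tol * eta_j^2`, where
#'   `eta_j` is the sum of per-sample linear predictors at iteration `j`.
#' @param eta_tol Safeguard tolerance on the maximum absolute per-sample
#'   change in the linear predictor; the summed criterion can cancel across
#'   samples, so both must hold before the fit is declared converged.
#' @param max_iter Maximum number of IWLS iterations.
#' @param theta_init Initial shape parameter.
#' @param theta_bounds Clamp interval for the shape parameter. The maximum
#'   likelihood estimate of the shape often lacks robustness; the residual
#'   variance of the surrogate LMM absorbs leftover over-dispersion, so
#'   clamping is safe.
#' @param info Pseudo-data curvature: `"expected"` (Fisher scoring, the
#'   classical IRLS working data; default) or `"observed"` (the observed
#'   second derivative). See [compute_pseudo_data()] and the methods
#'   vignette.
#' @param w_floor Lower clamp for pseudo-weights.
#' @param verbose Print per-iteration progress.
#' @return A list of class `"nbmm_control"`.
#' @export
nbmm_control <- function(tol = 1e-5, eta_tol = 1e-4, max_iter = 50,
                         theta_init = 1, theta_bounds = c(1e-2, 1e4),
                         info = c("expected", "observed"),
                         w_floor = 1e-10, verbose = FALSE) {
  info <- match.arg(info)
  stopifnot(tol > 0, eta_tol > 0, max_iter >= 1, theta_init > 0,
            length(theta_bounds) == 2, all(theta_bounds > 0),
            theta_bounds[1] < theta_bounds[2], w_floor > 0)
  structure(list(tol = tol, eta_tol = eta_tol, max_iter = max_iter,
                 theta_init = theta_init, theta_bounds = theta_bounds,
                 info = info, w_floor = w_floor, verbose = verbose),
            class = "nbmm_control")
}

#' Fit a negative binomial mixed model by iterative weighted least squares
#'
#' Fits the model `y_i ~ NB(mu_i, theta)` with
#' `log(mu_i) = offset_i + X_i beta + b_{g(i)}`, `b ~ N_K(0, tau2 I)`,
#' where the offset is typically the log total sequence reads of each
#' sample. The algorithm alternates three steps until the linear predictor
#' stabilizes: (1) construct the pseudo-response and pseudo-weights of the
#' weighted-normal approximation at the current estimates; (2) update
#' `(beta, b, tau2, sigma2)` by fitting the weighted linear mixed model
#' surrogate via [fit_weighted_lmm()]; (3) update `theta` by Newton-Raphson
#' on the profile negative binomial likelihood via [update_theta()].
#' Fixed effects are initialized from a least-squares fit of
#' `log((y + 0.5)) - offset` on `X`, random effects at zero.
#'
#' Wald tests of `H0: beta_k = 0` use the fixed-effect covariance of the
#' final surrogate LMM with a t reference distribution on
#' `n - p - (K - 1)` degrees of freedom (standard normal when the degrees
#' of freedom are not positive).
#'
#' @param y Non-negative integer response counts for one feature.
#' @param X Fixed-effect design matrix including the intercept column.
#' @param group Grouping factor for the random intercept (length `n`).
#' @param offset Per-sample offset on the log scale, typically
#'   `log(total_reads)`.
#' @param control A list from [nbmm_control()].
#' @return An object of class `"nbmm_fit"`: a list with `beta` (estimates),
#'   `se`, `beta_cov`, `b` (random-effect predictions), `tau2`, `sigma2`,
#'   `theta`, `wald` (statistic, df, p-value per coefficient), `converged`,
#'   `n_iter`, `eta_trace` (summed linear predictor per iteration),
#'   `fitted` (mean scale), and the inputs' dimensions.
#' @seealso [wald_test()], [fit_nb_glm()] for the fixed-effects-only model.
#' @export
fit_nbmm <- function(y, X, group, offset = rep(0, length(y)),
                     control = nbmm_control()) {
  check_counts(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(p) - 1)
  }
  if (nrow(X) != n || length(group) != n || length(offset) != n) {
    stop("dimensions of y, X, group, offset must conform", call. = FALSE)
  }
  if (all(y == 0)) {
    stop("degenerate feature: response is all zeros", call. = FALSE)
  }
  if (sum(y > 0) < 2) {
    stop("degenerate feature: fewer than two positive counts",
         call. = FALSE)
  }
  if (qr(X)$rank < p) {
    stop("fixed-effect design matrix is rank deficient", call. = FALSE)
  }
  group <- factor(group)
  K <- nlevels(group)

  # initialization: least squares of log counts (offset-corrected), b = 0
  beta <- qr.coef(qr(X), log(y + 0.5) - offset)
  beta[!is.finite(beta)] <- 0
  b <- numeric(K)
  names(b) <- levels(group)
  theta <- control$theta_init
  eta <- offset + as.vector(X %*% beta) + b[group]

  eta_trace <- numeric(0)
  eta_sum_old <- sum(eta)
  converged <- FALSE
  theta_boundary <- FALSE
  n_iter <- 0
  lmm <- NULL

  for (j in seq_len(control$max_iter)) {
    n_iter <- j
    pd <- compute_pseudo_data(y, eta, theta, info = control$info,
                              w_floor = control$w_floor, warn = FALSE)
    lmm <- fit_weighted_lmm(pd$t, X, group, w = pd$w, offset = offset)
    beta <- lmm$beta
    b <- lmm$b
    eta_new <- lmm$fitted
    mu <- exp(eta_new)
    theta <- update_theta(y, mu, theta_init = theta,
                          bounds = control$theta_bounds, warn = FALSE)
    theta_boundary <- attr(theta, "boundary")
    theta <- as.numeric(theta)

    eta_sum <- sum(eta_new)
    eta_trace <- c(eta_trace, eta_sum)
    if (control$verbose) {
      message(sprintf("iter %d: sum(eta) = %.6f, theta = %.4f",
                      j, eta_sum, theta))
    }
    sum_ok <- (eta_sum - eta_sum_old)^2 < control$tol * eta_sum^2
    max_ok <- max(abs(eta_new - eta)) < control$eta_tol
    eta <- eta_new
    eta_sum_old <- eta_sum
    if (sum_ok && max_ok) {
      converged <- TRUE
      break
    }
  }

  se <- sqrt(diag(lmm$beta_cov))
  df <- n - p - (K - 1)
  stat <- lmm$beta / se
  pval <- if (df > 0) 2 * stats::pt(-abs(stat), df = df) else
    2 * stats::pnorm(-abs(stat))

  structure(list(beta = lmm$beta, se = se, beta_cov = lmm$beta_cov,
                 b = lmm$b, tau2 = lmm$tau2, sigma2 = lmm$sigma2,
                 theta = theta, theta_boundary = theta_boundary,
                 tau2_boundary = lmm$boundary,
                 wald = data.frame(coef = names(lmm$beta),
                                   estimate = unname(lmm$beta),
                                   se = unname(se),
                                   statistic = unname(stat),
                                   df = df,
                                   p_value = unname(pval)),
                 converged = converged, n_iter = n_iter,
                 eta_trace = eta_trace,
                 fitted = exp(eta), n = n, p = p, K = K,
                 control = control),
            class = "nbmm_fit")
}

#' Wald test for a fixed-effect coefficient of a fitted NBMM
#'
#' Tests `H0: beta_k = 0` using the estimate and standard error from the
#' final surrogate LMM of the IWLS fit, with a t reference distribution on
#' `n - p - (K - 1)` degrees of freedom (normal when not positive).
#'
#' @param fit An `"nbmm_fit"` object.
#' @param coef Coefficient index or name.
#' @return A list with `statistic`, `df`, and `p_value`.
#' @export
wald_test <- function(fit, coef = 2) {
  stopifnot(inherits(fit, "nbmm_fit"))
  if (!fit$converged) {
    warning("fit did not converge; Wald test may be unreliable",
            call. = FALSE)
  }
  if (is.character(coef)) coef <- match(coef, names(fit$beta))
  if (is.na(coef) || coef < 1 || coef > length(fit$beta)) {
    stop("invalid coefficient index", call. = FALSE)
  }
  se <- fit$se[coef]
  if (!is.finite(se) || se <= 0) {
    stop(sprintf("zero standard error for coefficient '%s'",
                 names(fit$beta)[coef]), call. = FALSE)
  }
  stat <- unname(fit$beta[coef] / se)
  df <- fit$n - fit$p - (fit$K - 1)
  p <- if (df > 0) 2 * stats::pt(-abs(stat), df = df) else
    2 * stats::pnorm(-abs(stat))
  list(statistic = stat, df = df, p_value = p)
}

#' @export
print.nbmm_fit <- function(x, ...) {
  cat("Negative binomial mixed model (IWLS fit)\n")
  cat(sprintf("  n = %d samples, %d fixed effects, %d groups\n",
              x$n, x$p, x$K))
  cat(sprintf("  converged: %s after %d iteration(s)\n",
              x$converged, x$n_iter))
  cat(sprintf("  theta = %.4g%s, tau2 = %.4g, sigma2 = %.4g\n",
              x$theta, if (x$theta_boundary) " (at bound)" else "",
              x$tau2, x$sigma2))
  cat("  Fixed effects:\n")
  print(x$wald, row.names = FALSE)
  invisible(x)
}

#' Serialize a fitted NBMM to JSON
#'
#' Writes estimates, random-effect predictions, the convergence trace and
#' the control settings, so a fit can be audited or archived alongside a
#' results table.
#'
#' @param fit An `"nbmm_fit"` object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
nbmm_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "nbmm_fit"))
  payload <- list(
    estimates = list(beta = as.list(fit$beta), se = as.list(fit$se),
                     b = as.list(fit$b), tau2 = fit$tau2,
                     sigma2 = fit$sigma2, theta = fit$theta),
    tests = fit$wald,
    convergence = list(converged = fit$converged, n_iter = fit$n_iter,
                       eta_trace = fit$eta_trace,
                       theta_boundary = fit$theta_boundary,
                       tau2_boundary = fit$tau2_boundary),
    dimensions = list(n = fit$n, p = fit$p, K = fit$K),
    control = unclass(fit$control))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
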