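#' Negative binomial log probability mass function
#'
#' Evaluates the log density of the negative binomial distribution
#' parameterized by a mean `mu` and a shape parameter `theta`, with
#' variance `mu + mu^2 / theta`. Computed through log-gamma functions so
#' that large counts and extreme parameters do not overflow.
#'
#' @param y Vector of non-negative integer counts.
#' @param mu Vector of positive means (recycled against `y`).
#' @param theta Positive shape parameter (scalar or vector).
#' @return Numeric vector of log probabilities.
#' @examples
#' nb_log_pmf(0, mu = 1, theta = 1)  # log(0.5)
#' @export
nb_log_pmf <- function(y, mu, theta) {
  check_counts(y)
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("`mu` must be finite and strictly positive", call. = FALSE)
  }
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    stop("`theta` must be finite and strictly positive", call. = FALSE)
  }
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * (log(theta) - log(mu + theta)) +
    y * (log(mu) - log(mu + theta))
}

#' Negative binomial mean and variance
#'
#' @inheritParams nb_log_pmf
#' @return A list with components `mean` (`mu`) and `variance`
#'   (`mu + mu^2 / theta`).
#' @export
nb_moments <- function(mu, theta) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("`mu` must be finite and strictly positive", call. = FALSE)
  }
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    stop("`theta` must be finite and strictly positive", call. = FALSE)
  }
  list(mean = mu, variance = mu + mu^2 / theta)
}

#' Derivatives of the negative binomial log likelihood in the linear
#' predictor
#'
#' First and second derivatives of `log NB(y | mu = exp(eta), theta)` with
#' respect to `eta`. Writing `p = mu / (mu + theta)` and its complement
#' `q = theta / (mu + theta)`, these are `L1 = y - (y + theta) * p` and
#' `L2 = -(y + theta) * p * q`; both are evaluated through the logistic
#' function of `eta - log(theta)` so extreme linear predictors stay finite.
#' `L2` is strictly negative for all valid inputs, which makes the
#' pseudo-weights of the IWLS algorithm strictly positive.
#'
#' @param y Vector of non-negative integer counts.
#' @param eta Vector of linear predictors (log-mean scale, offset included).
#' @param theta Positive shape parameter.
#' @return A list with numeric vectors `L1` and `L2`.
#' @export
nb_eta_derivatives <- function(y, eta, theta) {
  # derivatives extend to real y >= 0 (the score is linear in y)
  if (any(!is.finite(y)) || any(y < 0)) {
    stop("`y` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(eta))) stop("`eta` must be finite", call. = FALSE)
  if (!is.finite(theta) || theta <= 0) {
    stop("`theta` must be finite and strictly positive", call. = FALSE)
  }
  # p = mu/(mu+theta), q = theta/(mu+theta); evaluate each directly so
  # neither underflows to zero through 1 - plogis at extreme eta
  p <- stats::plogis(eta - log(theta))
  q <- stats::plogis(log(theta) - eta)
  list(L1 = y - (y + theta) * p,
       L2 = -(y + theta) * p * q)
}

#' Pseudo-response and pseudo-weights for the IWLS algorithm
#'
#' Builds the working data of the weighted-normal approximation to the
#' negative binomial likelihood: `t = eta - L1 / L2` and `w = -L2`, where
#' `L1`, `L2` are the first two derivatives of the log likelihood in the
#' linear predictor. With `info = "observed"` the curvature is evaluated
#' at the observed count; with `info = "expected"` (Fisher scoring) `L2`
#' is replaced by its expectation `-mu * theta / (mu + theta)`, which
#' reduces the pseudo-data to the classical IRLS working response
#' `t = eta + (y - mu) / mu` and working weight `w = mu * theta /
#' (mu + theta)` of the log-link negative binomial family. Fisher scoring
#' is what the standard fitting procedures for GLMs and GLMMs use, and is
#' the default of [fit_nbmm()]; see the methods vignette for why.
#' Weights are floored at `w_floor` so that near-zero curvature (e.g.
#' zero counts at very negative linear predictors) cannot make the
#' surrogate weighted LMM singular.
#'
#' @inheritParams nb_eta_derivatives
#' @param info `"observed"` for the observed second derivative,
#'   `"expected"` for its expectation (Fisher scoring).
#' @param w_floor Lower clamp for the pseudo-weights.
#' @param warn Warn when any weight is clamped at the floor.
#' @return A list with vectors `t` (pseudo-response) and `w`
#'   (pseudo-weights, strictly positive).
#' @export
compute_pseudo_data <- function(y, eta, theta,
                                info = c("observed", "expected"),
                                w_floor = 1e-10, warn = TRUE) {
  info <- match.arg(info)
  d <- nb_eta_derivatives(y, eta, theta)
  w <- if (info == "observed") {
    -d$L2
  } else {
    mu_frac <- stats::plogis(eta - log(theta))      # mu / (mu + theta)
    theta * mu_frac                                 # mu theta / (mu+theta)
  }
  clamped <- w < w_floor
  if (any(clamped)) {
    if (warn) {
      warning(sprintf("%d pseudo-weight(s) clamped at floor %g",
                      sum(clamped), w_floor), call. = FALSE)
    }
    w[clamped] <- w_floor
  }
  t <- eta + d$L1 / w  # t = eta - L1/L2 with the (floored) curvature -L2
  list(t = t, w = w)
}

#' Update the negative binomial shape parameter
#'
#' Maximizes the profile log likelihood `sum_i log NB(y_i | mu_i, theta)`
#' over `theta` for fixed fitted means, by Newton-Raphson in `log(theta)`
#' with a fall back to bounded golden-section search whenever a Newton step
#' fails or does not improve the likelihood. The result is clamped to
#' `bounds`; the returned value never has a lower likelihood than
#' `theta_init` unless the initial value itself lies outside the bounds.
#'
#' @param y Vector of non-negative integer counts.
#' @param mu Vector of positive fitted means.
#' @param theta_init Positive starting value inside `bounds`.
#' @param bounds Length-2 positive increasing vector clamping `theta`.
#' @param warn Warn when the optimum is clamped at a bound.
#' @return The updated shape parameter, a positive scalar with attribute
#'   `"boundary"` (logical) marking a clamped solution.
#' @export
update_theta <- function(y, mu, theta_init = 1, bounds = c(1e-2, 1e4),
                         warn = TRUE) {
  check_counts(y)
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("`mu` must be finite and strictly positive", call. = FALSE)
  }
  if (length(bounds) != 2 || any(bounds <= 0) || bounds[1] >= bounds[2]) {
    stop("`bounds` must be a positive increasing pair", call. = FALSE)
  }
  theta_init <- min(max(theta_init, bounds[1]), bounds[2])
  ll <- function(th) sum(nb_log_pmf(y, mu, th))

  # score and curvature of the profile likelihood in theta
  score <- function(th) {
    sum(digamma(y + th) - digamma(th) + 1 + log(th) -
          log(mu + th) - (y + th) / (mu + th))
  }
  hess <- function(th) {
    sum(trigamma(y + th) - trigamma(th) + 1 / th -
          1 / (mu + th) + (y - mu) / (mu + th)^2)
  }

  th <- theta_init
  ok <- TRUE
  for (iter in seq_len(50)) {
    g <- score(th)
    h <- hess(th)
    # Newton in log(theta): d l / d log th = th * g, d2 = th^2 * h + th * g
    g_log <- th * g
    h_log <- th^2 * h + th * g
    if (!is.finite(g_log) || !is.finite(h_log) || h_log >= 0) {
      ok <- FALSE
      break
    }
    step <- -g_log / h_log
    step <- max(min(step, 5), -5)  # damp huge steps on flat likelihoods
    th_new <- exp(log(th) + step)
    th_new <- min(max(th_new, bounds[1]), bounds[2])
    if (!is.finite(ll(th_new)) || ll(th_new) < ll(th) - 1e-10) {
      ok <- FALSE
      break
    }
    converged <- abs(log(th_new) - log(th)) < 1e-10
    th <- th_new
    if (converged) break
  }

  if (!ok || ll(th) < ll(theta_init)) {
    opt <- stats::optimize(function(lt) ll(exp(lt)),
                           interval = log(bounds), maximum = TRUE,
                           tol = 1e-10)
    th_opt <- exp(opt$maximum)
    if (ll(th_opt) > ll(th)) th <- th_opt
    if (ll(th) < ll(theta_init)) th <- theta_init
  }

  boundary <- th <= bounds[1] * (1 + 1e-8) || th >= bounds[2] * (1 - 1e-8)
  if (boundary) {
    th <- if (th <= bounds[1] * (1 + 1e-8)) bounds[1] else bounds[2]
    if (warn) {
      warning(sprintf("shape estimate clamped at bound %g", th),
              call. = FALSE)
    }
  }
  structure(th, boundary = boundary)
}

# shared validation for count vectors
check_counts <- function(y) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y))) {
    stop("counts must be finite non-negative integers", call. = FALSE)
  }
  invisible(y)
}
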