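test_that("nb_log_pmf matches closed forms and the dnbinom oracle", {
  # P(y = 0) = (theta / (mu + theta))^theta
  expect_equal(nb_log_pmf(0, mu = 1, theta = 1), log(0.5))
  expect_equal(nb_log_pmf(0, mu = 2, theta = 3), 3 * log(3 / 5))

  # independent evaluation of the same density (mean/shape parameterization)
  grid <- expand.grid(y = c(0, 1, 3, 17, 250), mu = c(0.2, 2, 40),
                      theta = c(0.1, 0.5, 1.5, 80))
  got <- with(grid, nb_log_pmf(y, mu, theta))
  oracle <- with(grid, dnbinom(y, size = theta, mu = mu, log = TRUE))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("nb_log_pmf normalizes and validates input", {
  y <- 0:2000
  expect_equal(sum(exp(nb_log_pmf(y, mu = 2, theta = 1.5))), 1,
               tolerance = 1e-10)
  expect_error(nb_log_pmf(-1, 1, 1), "non-negative")
  expect_error(nb_log_pmf(1.5, 1, 1), "integer")
  expect_error(nb_log_pmf(1, -1, 1), "mu")
  expect_error(nb_log_pmf(1, 1, 0), "theta")
})

test_that("nb_moments follows the mean-variance identity", {
  m <- nb_moments(mu = 2, theta = 1)
  expect_equal(m$mean, 2)
  expect_equal(m$variance, 6)
  # Poisson limit: variance collapses to the mean
  expect_equal(nb_moments(mu = 3, theta = 1e12)$variance, 3,
               tolerance = 1e-10)
  expect_true(all(nb_moments(mu = c(0.1, 1, 10), theta = 0.3)$variance >=
                    c(0.1, 1, 10)))
  # Monte-Carlo moment check at strong over-dispersion
  m2 <- nb_moments(mu = 5, theta = 0.1)
  expect_equal(m2$variance, 255)
  set.seed(42)
  draws <- rnbinom(1e6, size = 0.1, mu = 5)
  expect_equal(var(draws), m2$variance, tolerance = 0.02)
  expect_error(nb_moments(0, 1), "mu")
})

test_that("eta derivatives match a finite-difference oracle on a grid", {
  h <- 1e-5
  h2 <- 1e-3  # five-point stencil: avoids catastrophic cancellation
  for (y in c(0, 1, 5, 50)) {
    for (eta in c(-3, 0, 3)) {
      for (theta in c(0.1, 1, 5)) {
        d <- nb_eta_derivatives(y, eta, theta)
        f <- function(e) nb_log_pmf(y, exp(e), theta)
        L1_fd <- (f(eta + h) - f(eta - h)) / (2 * h)
        L2_fd <- (-f(eta + 2 * h2) + 16 * f(eta + h2) - 30 * f(eta) +
                    16 * f(eta - h2) - f(eta - 2 * h2)) / (12 * h2^2)
        expect_lt(abs(d$L1 - L1_fd) / max(abs(L1_fd), 1), 1e-6)
        expect_lt(abs(d$L2 - L2_fd) / max(abs(L2_fd), 1), 1e-6)
        expect_lt(d$L2, 0)
      }
    }
  }
})

test_that("eta derivatives: score zero at the mean, Poisson limit, stability", {
  eta <- c(-2, 0, 1.3)
  d <- nb_eta_derivatives(exp(eta), eta, theta = 0.8)
  expect_equal(d$L1, rep(0, 3), tolerance = 1e-12)

  d_pois <- nb_eta_derivatives(4, 0, theta = 1e10)
  expect_equal(d_pois$L1, 3, tolerance = 1e-6)  # y - exp(eta)

  d_extreme <- nb_eta_derivatives(c(0, 1000), c(-50, 50), theta = 0.5)
  expect_true(all(is.finite(d_extreme$L1)))
  expect_true(all(is.finite(d_extreme$L2)))
  expect_true(all(d_extreme$L2 < 0))
})

test_that("pseudo-data follows t = eta - L1/L2, w = -L2 and stays finite", {
  y <- c(5, 0, 12)
  eta <- c(1, -0.5, 2)
  theta <- 2
  pd <- compute_pseudo_data(y, eta, theta)
  d <- nb_eta_derivatives(y, eta, theta)
  expect_equal(pd$w, -d$L2)
  expect_equal(pd$t, eta - d$L1 / d$L2)
  expect_true(all(pd$w > 0))

  # observed count at the fitted mean: pseudo-response equals eta
  pd0 <- compute_pseudo_data(exp(1.2), 1.2, 3)
  expect_equal(pd0$t, 1.2, tolerance = 1e-12)

  # degenerate stability: zero count at a very negative linear predictor
  pd_deg <- compute_pseudo_data(0, -20, 1)
  expect_true(is.finite(pd_deg$t) && pd_deg$w >= 1e-10)
  # curvature underflow beyond the floor is clamped with a warning
  expect_warning(pd_clamp <- compute_pseudo_data(0, -40, 1), "clamped")
  expect_true(is.finite(pd_clamp$t) && pd_clamp$w == 1e-10)
})

test_that("expected-information pseudo-data is the classical IRLS working data", {
  y <- c(0, 3, 20)
  eta <- c(-1, 0.5, 2)
  theta <- 1.3
  mu <- exp(eta)
  pd <- compute_pseudo_data(y, eta, theta, info = "expected")
  expect_equal(pd$w, mu * theta / (mu + theta), tolerance = 1e-12)
  expect_equal(pd$t, eta + (y - mu) / mu, tolerance = 1e-12)
})

test_that("the gamma-Poisson mixture reproduces the NB pmf", {
  set.seed(7)
  mu <- 3
  theta <- 0.8
  n <- 1e6
  eps <- rgamma(n, shape = theta, rate = theta)
  y <- rpois(n, mu * eps)
  for (k in c(0, 1, 2, 5, 10)) {
    p_hat <- mean(y == k)
    p <- exp(nb_log_pmf(k, mu, theta))
    mc_se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(p_hat - p), 5 * mc_se)
  }
})

test_that("theta updates maximize the profile likelihood", {
  set.seed(11)
  n <- 5000
  mu <- runif(n, 2, 9)
  y <- rnbinom(n, size = 1.2, mu = mu)
  th <- update_theta(y, mu, theta_init = 1)
  # dense grid + golden-section oracle on the profile likelihood
  ll <- function(t) sum(nb_log_pmf(y, mu, t))
  grid <- exp(seq(log(0.01), log(100), length.out = 400))
  i <- which.max(vapply(grid, ll, 0))
  gold <- optimize(ll, c(grid[max(1, i - 1)], grid[min(400, i + 1)]),
                   maximum = TRUE, tol = 1e-10)
  expect_equal(as.numeric(th), gold$maximum, tolerance = 1e-4)
  expect_gte(ll(as.numeric(th)), ll(1))
})

test_that("theta update hits the upper clamp on equi-dispersed data", {
  set.seed(12)
  y <- rpois(2000, 5)
  expect_warning(th <- update_theta(y, rep(5, 2000), theta_init = 1),
                 "clamped")
  expect_equal(as.numeric(th), 1e4)
  expect_true(attr(th, "boundary"))

  # constant response with mu matched exactly: no over-dispersion either
  y2 <- rep(4, 50)
  expect_warning(th2 <- update_theta(y2, rep(4, 50), theta_init = 1),
                 "clamped")
  expect_equal(as.numeric(th2), 1e4)
})

test_that("theta update never decreases the likelihood", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 300
    mu <- exp(rnorm(n, 1, 0.7))
    theta_true <- runif(1, 0.1, 5)
    y <- rnbinom(n, size = theta_true, mu = mu)
    for (init in c(0.05, 1, 50)) {
      th <- suppressWarnings(update_theta(y, mu, theta_init = init))
      expect_gte(sum(nb_log_pmf(y, mu, as.numeric(th))),
                 sum(nb_log_pmf(y, mu, max(min(init, 1e4), 1e-2))))
    }
  }
})
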