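test_that("single-group fits reduce to the NB GLM and to glm.nb", {
  skip_if_not_installed("MASS")
  for (seed in 1:3) {
    ds <- make_single_group_counts(seed = seed)
    fit <- fit_nbmm(ds$y, ds$X, group = rep(1, length(ds$y)),
                    offset = ds$offset)
    glm_fit <- fit_nb_glm(ds$y, ds$X, offset = ds$offset)
    expect_equal(unname(fit$beta[2]), glm_fit$beta_hat, tolerance = 1e-3)
    ref <- MASS::glm.nb(ds$y ~ ds$x + offset(ds$offset))
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-3)
    expect_equal(glm_fit$theta, ref$theta, tolerance = 1e-3)
  }
})

test_that("parameters are recovered on a clustered dataset", {
  ds <- make_clustered_counts(n = 400, K = 40, beta = 0.5, theta = 2,
                              tau = 0.7, seed = 42)
  fit <- fit_nbmm(ds$y, ds$X, ds$z, offset = ds$offset)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta[["x"]] - 0.5), 0.15)
  expect_lt(abs(fit$tau2 - 0.49), 0.2)
  expect_gt(fit$theta, 0.5)
  expect_equal(length(fit$b), 40)
  expect_true(all(fit$wald$p_value >= 0 & fit$wald$p_value <= 1))
  expect_length(fit$eta_trace, fit$n_iter)
})

test_that("a huge shape parameter reproduces a Poisson mixed model", {
  # same IWLS loop with Poisson working data as an independent oracle
  sc <- sim_scenario(n = 200, K = 20, beta = 0.4, rho = 0, n_reps = 1,
                     fixed = list(theta = 1e8, tau = 0.6))
  ds <- simulate_dataset(sc, seed = 5)
  X <- cbind(1, x = ds$x)
  off <- log(ds$total_reads)
  ctrl <- nbmm_control(theta_init = 1e8, theta_bounds = c(1e8, 1e9))
  fit <- fit_nbmm(ds$y, X, ds$z, offset = off, control = ctrl)

  beta <- qr.coef(qr(X), log(ds$y + 0.5) - off)
  b <- numeric(20)
  eta <- off + as.vector(X %*% beta) + b[as.integer(ds$z)]
  for (j in 1:50) {
    mu <- exp(eta)
    lmm <- fit_weighted_lmm(eta + (ds$y - mu) / mu, X, ds$z, w = mu,
                            offset = off)
    if (max(abs(lmm$fitted - eta)) < 1e-8) break
    eta <- lmm$fitted
  }
  expect_equal(unname(fit$beta), unname(lmm$beta), tolerance = 1e-4)
})

test_that("degenerate or invalid inputs raise typed errors", {
  n <- 40
  X <- cbind(1, rbinom(n, 1, 0.5))
  g <- rep(1:4, each = 10)
  expect_error(fit_nbmm(rep(0, n), X, g), "all zeros")
  expect_error(fit_nbmm(c(3, rep(0, n - 1)), X, g), "degenerate")
  expect_error(fit_nbmm(rpois(n, 5), cbind(X, X[, 2]), g), "rank")
  expect_error(fit_nbmm(rpois(n, 5) + 0.5, X, g), "integer")
})

test_that("non-convergence is reported, never raised", {
  ds <- make_clustered_counts(n = 100, K = 10, seed = 3)
  fit <- fit_nbmm(ds$y, ds$X, ds$z, offset = ds$offset,
                  control = nbmm_control(max_iter = 1))
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 1)
  expect_s3_class(fit, "nbmm_fit")
})

test_that("Wald statistic is sign-symmetric in the covariate", {
  ds <- make_clustered_counts(n = 150, K = 15, beta = 0.6, seed = 8)
  Xn <- ds$X
  Xn[, 2] <- -Xn[, 2]
  f1 <- fit_nbmm(ds$y, ds$X, ds$z, offset = ds$offset)
  f2 <- fit_nbmm(ds$y, Xn, ds$z, offset = ds$offset)
  w1 <- wald_test(f1, 2)
  w2 <- wald_test(f2, 2)
  expect_equal(w1$statistic, -w2$statistic, tolerance = 1e-6)
  expect_equal(w1$p_value, w2$p_value, tolerance = 1e-6)
  expect_equal(w1$df, f1$n - f1$p - (f1$K - 1))
})

test_that("wald_test validates its inputs", {
  ds <- make_clustered_counts(n = 100, K = 10, seed = 9)
  fit <- fit_nbmm(ds$y, ds$X, ds$z, offset = ds$offset)
  expect_error(wald_test(fit, 99), "invalid")
  expect_equal(wald_test(fit, "x")$statistic, wald_test(fit, 2)$statistic)
  nc <- fit_nbmm(ds$y, ds$X, ds$z, offset = ds$offset,
                 control = nbmm_control(max_iter = 1))
  expect_warning(wald_test(nc, 2), "converge")
})

test_that("null p-values are approximately uniform", {
  sc <- sim_scenario(n = 100, K = 10, beta = 0, rho = 0, n_reps = 1,
                     fixed = list(theta = 1, tau = 0.7))
  set.seed(77)
  seeds <- sample.int(2^31 - 1, 300)
  p <- vapply(seeds, function(s) {
    ds <- simulate_dataset(sc, seed = s)
    fit <- fit_nbmm(ds$y, cbind(1, x = ds$x), ds$z,
                    offset = log(ds$total_reads))
    fit$wald$p_value[2]
  }, 0)
  # KS distance below the 1% critical value 1.63 / sqrt(n)
  ks <- max(abs(sort(p) - (seq_along(p) - 0.5) / length(p)))
  expect_lt(ks, 1.63 / sqrt(length(p)))
})

test_that("fits serialize to JSON with provenance and round-trip", {
  ds <- make_clustered_counts(n = 100, K = 10, seed = 2)
  fit <- fit_nbmm(ds$y, ds$X, ds$z, offset = ds$offset)
  path <- withr::local_tempfile(fileext = ".json")
  nbmm_fit_json(fit, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(parsed$estimates$theta, fit$theta)
  expect_equal(parsed$estimates$beta$x, unname(fit$beta["x"]))
  expect_equal(parsed$convergence$n_iter, fit$n_iter)
  expect_equal(parsed$control$tol, fit$control$tol)
  expect_length(parsed$convergence$eta_trace, fit$n_iter)
})
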