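# small clustered NB datasets with pinned parameters, for oracle tests
make_clustered_counts <- function(n = 200, K = 20, beta = 0.5, theta = 2,
                                  tau = 0.7, rho = 0, seed = 1) {
  sc <- sim_scenario(n = n, K = K, beta = beta, rho = rho, n_reps = 1,
                     fixed = list(theta = theta, tau = tau))
  ds <- simulate_dataset(sc, seed = seed)
  ds$X <- cbind("(Intercept)" = 1, x = ds$x)
  ds$offset <- log(ds$total_reads)
  ds
}

# single-group dataset (no group effects) for reduction-to-GLM checks
make_single_group_counts <- function(n = 250, beta = 0.4, theta = 1.5,
                                     seed = 1) {
  make_clustered_counts(n = n, K = 1, beta = beta, theta = theta,
                        tau = 0, seed = seed)
}
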