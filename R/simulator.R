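#' Define a simulation scenario for clustered microbiome counts
#'
#' Bundles the parameter ranges of the simulation design: counts are drawn
#' from a negative binomial model
#' `log(mu_i) = log(T_i) + mu0 + x_i beta + b_{z_i}` with a binary host
#' factor `x`, a grouping factor `z` of `K` groups, group effects
#' `b_k ~ N(0, tau^2)`, and a preset correlation `rho` between the latent
#' variables behind `x` and `z`. By default every nuisance parameter is
#' redrawn uniformly from its range at each replicate; any entry of
#' `fixed` pins the corresponding parameter for oracle-style checks.
#'
#' @param n Number of samples (the study sizes are 200 and 400).
#' @param K Number of groups; defaults to `n / 10`.
#' @param beta Effect regime for the binary host factor: `"null"` (0),
#'   `"low"` (uniform on \[0.2, 0.35\]), `"high"` (uniform on
#'   \[0.4, 0.55\]), or a numeric value used as-is.
#' @param rho Correlation regime between host factor and grouping:
#'   `"weak"` (\[-0.1, 0.1\]), `"positive"` (\[0.5, 0.8\]), `"negative"`
#'   (\[-0.8, -0.5\]), or a numeric value.
#' @param mu0 Overall mean on the log scale (default -7, so that
#'   `log(T_i) + mu0` spans \[0.1, 3.5\]).
#' @param logT_range Range of per-sample log total reads.
#' @param theta_range Range of the shape parameter (over-dispersion).
#' @param tau_range Range of the random-effect standard deviation.
#' @param n_reps Number of simulation replicates for [run_study()].
#' @param alpha_levels Significance levels at which rejection rates are
#'   tabulated.
#' @param fixed Optional named list pinning any of `theta`, `tau`, `rho`,
#'   `beta`, or `b` (a length-`K` vector) instead of redrawing them.
#' @return A list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(n = 200, K = n / 10, beta = "null", rho = "weak",
                         mu0 = -7, logT_range = c(7.1, 10.5),
                         theta_range = c(0.1, 5), tau_range = c(0.5, 1),
                         n_reps = 1000,
                         alpha_levels = c(0.05, 0.01, 0.005, 0.001),
                         fixed = list()) {
  stopifnot(n >= 2, K >= 1, K <= n, n_reps >= 1)
  if (is.character(beta)) {
    beta <- match.arg(beta, c("null", "low", "high"))
  } else {
    stopifnot(is.numeric(beta), length(beta) == 1)
  }
  if (is.character(rho)) {
    rho <- match.arg(rho, c("weak", "positive", "negative"))
  } else {
    stopifnot(is.numeric(rho), length(rho) == 1, abs(rho) < 1)
  }
  structure(list(n = n, K = K, beta = beta, rho = rho, mu0 = mu0,
                 logT_range = logT_range, theta_range = theta_range,
                 tau_range = tau_range, n_reps = n_reps,
                 alpha_levels = alpha_levels, fixed = fixed),
            class = "sim_scenario")
}

#' Read a simulation scenario from a YAML or JSON file
#'
#' @param path File with any subset of the [sim_scenario()] fields; the
#'   format is chosen by extension (`.yaml`/`.yml` or `.json`).
#' @return A `"sim_scenario"` object.
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = ,
                # keep keys like "n" literal instead of YAML 1.1 booleans
                yml = yaml::read_yaml(path, handlers = list(
                  "bool#yes" = function(x) x, "bool#no" = function(x) x)),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop("scenario file must be .yaml, .yml or .json",
                     call. = FALSE))
  do.call(sim_scenario, cfg)
}

#' Draw a correlated binary host factor and grouping variable
#'
#' Generates two standard normal variables with correlation `rho`, then
#' binarizes the first at its 40% sample quantile (values above the
#' quantile become 1, so about 60% of samples carry the factor) and bins
#' the second into `K` equal-frequency groups by ordered quantiles.
#'
#' @param n Number of samples.
#' @param K Number of groups (`n >= K`).
#' @param rho Latent correlation, `|rho| < 1`.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A list with `x` (0/1 integer vector) and `z` (group factor with
#'   levels `1..K`).
#' @export
draw_correlated_covariates <- function(n, K, rho, seed = NULL) {
  stopifnot(n >= K, K >= 1, abs(rho) < 1)
  with_seed(seed, {
    u1 <- stats::rnorm(n)
    u2 <- rho * u1 + sqrt(1 - rho^2) * stats::rnorm(n)
    x <- as.integer(u1 > stats::quantile(u1, 0.4))
    z <- factor(ceiling(rank(u2, ties.method = "first") * K / n),
                levels = seq_len(K))
    list(x = x, z = z)
  })
}

#' Simulate one clustered microbiome count dataset
#'
#' Draws `log(T_i)` uniformly from the scenario's range, the shape
#' parameter, random-effect standard deviation, effect size and latent
#' correlation from their regimes (unless pinned via `fixed`), group
#' effects `b_k ~ N(0, tau^2)`, and counts
#' `y_i ~ NB(mu_i, theta)` with
#' `log(mu_i) = log(T_i) + mu0 + x_i beta + b_{z_i}`.
#'
#' @param scenario A [sim_scenario()] object.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A list of class `"nbmm_sim"` with `y` (counts), `total_reads`,
#'   `x`, `z`, and `truth` (the drawn `beta`, `theta`, `tau`, `tau2`, `b`,
#'   `rho`, and `mu0`).
#' @export
simulate_dataset <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed(seed, {
    fx <- scenario$fixed
    rho <- if (!is.null(fx$rho)) fx$rho else draw_regime(scenario$rho, list(
      weak = c(-0.1, 0.1), positive = c(0.5, 0.8), negative = c(-0.8, -0.5)))
    beta <- if (!is.null(fx$beta)) fx$beta else draw_regime(scenario$beta,
      list(null = c(0, 0), low = c(0.2, 0.35), high = c(0.4, 0.55)))
    theta <- if (!is.null(fx$theta)) fx$theta else
      stats::runif(1, scenario$theta_range[1], scenario$theta_range[2])
    tau <- if (!is.null(fx$tau)) fx$tau else
      stats::runif(1, scenario$tau_range[1], scenario$tau_range[2])

    cov <- draw_correlated_covariates(scenario$n, scenario$K, rho)
    logT <- stats::runif(scenario$n, scenario$logT_range[1],
                         scenario$logT_range[2])
    b <- if (!is.null(fx$b)) fx$b else stats::rnorm(scenario$K, 0, tau)
    eta <- logT + scenario$mu0 + cov$x * beta + b[as.integer(cov$z)]
    y <- stats::rnbinom(scenario$n, size = theta, mu = exp(eta))
    structure(list(y = y, total_reads = exp(logT), x = cov$x, z = cov$z,
                   truth = list(beta = beta, theta = theta, tau = tau,
                                tau2 = tau^2, b = b, rho = rho,
                                mu0 = scenario$mu0)),
              class = "nbmm_sim")
  })
}

#' Simulate a multi-feature count table with planted signals
#'
#' Draws one set of covariates, grouping, and total reads from the
#' scenario, then simulates each feature independently from the negative
#' binomial model with its own shape parameter, random-effect standard
#' deviation and group effects, and a per-feature fixed effect taken from
#' `beta_features`. Useful for screening-pipeline studies where a known
#' subset of features carries a signal.
#'
#' @param scenario A [sim_scenario()] object (its `beta` regime is ignored
#'   in favour of `beta_features`).
#' @param beta_features Numeric vector of per-feature effect sizes; its
#'   length sets the number of features.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A list of class `"nbmm_sim_table"` with `counts` (features x
#'   samples `"count_matrix"`-compatible matrix), `total_reads`, `meta`
#'   (data frame with `x` and `group`), and `truth` (per-feature `beta`,
#'   `theta`, `tau`).
#' @export
simulate_count_table <- function(scenario, beta_features, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  m <- length(beta_features)
  with_seed(seed, {
    rho <- if (!is.null(scenario$fixed$rho)) scenario$fixed$rho else
      draw_regime(scenario$rho, list(weak = c(-0.1, 0.1),
                                     positive = c(0.5, 0.8),
                                     negative = c(-0.8, -0.5)))
    cov <- draw_correlated_covariates(scenario$n, scenario$K, rho)
    logT <- stats::runif(scenario$n, scenario$logT_range[1],
                         scenario$logT_range[2])
    counts <- matrix(0L, nrow = m, ncol = scenario$n,
                     dimnames = list(paste0("feature_", seq_len(m)),
                                     paste0("sample_", seq_len(scenario$n))))
    theta <- tau <- numeric(m)
    for (f in seq_len(m)) {
      theta[f] <- stats::runif(1, scenario$theta_range[1],
                               scenario$theta_range[2])
      tau[f] <- stats::runif(1, scenario$tau_range[1],
                             scenario$tau_range[2])
      b <- stats::rnorm(scenario$K, 0, tau[f])
      eta <- logT + scenario$mu0 + cov$x * beta_features[f] +
        b[as.integer(cov$z)]
      counts[f, ] <- stats::rnbinom(scenario$n, size = theta[f],
                                    mu = exp(eta))
    }
    meta <- data.frame(x = cov$x, group = cov$z,
                       row.names = colnames(counts))
    structure(list(counts = counts, total_reads = exp(logT), meta = meta,
                   truth = list(beta = beta_features, theta = theta,
                                tau = tau, rho = rho)),
              class = "nbmm_sim_table")
  })
}

draw_regime <- function(regime, ranges) {
  if (is.numeric(regime)) return(regime)
  r <- ranges[[regime]]
  if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
}

#' Run a type-I error / power study across methods
#'
#' Repeatedly simulates datasets from a scenario, fits the requested
#' methods to each, and tabulates the rejection rate of `H0: beta = 0` at
#' each significance level. For the NBMM the estimation errors
#' `beta_hat - beta`, `tau2_hat - tau2`, and `theta_hat - theta` are also
#' recorded, so parameter-recovery behaviour can be summarized alongside
#' operating characteristics. Replicates where a fit fails are excluded
#' from that method's denominator and counted in the summary.
#'
#' @param scenario A [sim_scenario()] object.
#' @param methods Subset of `"NBMM"`, `"NB"`, `"LMM_log"`,
#'   `"LMM_arcsine"`, `"LM"`.
#' @param seed Integer seed controlling the whole study.
#' @param control [nbmm_control()] settings for the NBMM and NB fits.
#' @return A list of class `"nbmm_study"`: `rates` (data frame with one
#'   row per method x alpha: `rejection_rate`, `n_converged`, `n_fit`),
#'   `estimation` (mean and central 95% interval of the NBMM estimation
#'   errors, when NBMM is among the methods), `per_rep` (p-values and
#'   per-replicate truth), plus the scenario and seed.
#' @export
run_study <- function(scenario, methods = c("NBMM", "NB", "LMM_log",
                                            "LMM_arcsine", "LM"),
                      seed = 1, control = nbmm_control()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  methods <- match.arg(methods, several.ok = TRUE)
  rep_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max, scenario$n_reps))

  per_rep <- vector("list", scenario$n_reps)
  est <- vector("list", scenario$n_reps)
  for (r in seq_len(scenario$n_reps)) {
    ds <- simulate_dataset(scenario, seed = rep_seeds[r])
    X <- cbind(`(Intercept)` = 1, x = ds$x)
    off <- log(ds$total_reads)
    pvals <- rep(NA_real_, length(methods))
    conv <- rep(FALSE, length(methods))
    for (m in seq_along(methods)) {
      res <- tryCatch(switch(methods[m],
        NBMM = {
          fit <- fit_nbmm(ds$y, X, ds$z, offset = off, control = control)
          if (methods[m] == "NBMM") {
            est[[r]] <- c(beta_err = unname(fit$beta[2]) - ds$truth$beta,
                          tau2_err = fit$tau2 - ds$truth$tau2,
                          theta_err = fit$theta - ds$truth$theta)
          }
          list(p = fit$wald$p_value[2], conv = fit$converged)
        },
        NB = {
          fit <- fit_nb_glm(ds$y, X, offset = off, control = control)
          list(p = fit$p_value, conv = fit$converged)
        },
        LMM_log = {
          fit <- fit_lmm_transformed(ds$y, X, ds$z, ds$total_reads, "log")
          list(p = fit$p_value, conv = fit$converged)
        },
        LMM_arcsine = {
          fit <- fit_lmm_transformed(ds$y, X, ds$z, ds$total_reads,
                                     "arcsine")
          list(p = fit$p_value, conv = fit$converged)
        },
        LM = {
          fit <- fit_lm_arcsine(ds$y, X, ds$total_reads)
          list(p = fit$p_value, conv = fit$converged)
        }), error = function(e) NULL)
      if (!is.null(res)) {
        pvals[m] <- res$p
        conv[m] <- res$conv
      }
    }
    per_rep[[r]] <- data.frame(rep = r, method = methods, p_value = pvals,
                               converged = conv,
                               beta_true = ds$truth$beta,
                               theta_true = ds$truth$theta,
                               tau2_true = ds$truth$tau2)
  }
  per_rep <- do.call(rbind, per_rep)

  rates <- do.call(rbind, lapply(methods, function(m) {
    sub <- per_rep[per_rep$method == m & !is.na(per_rep$p_value), ]
    do.call(rbind, lapply(scenario$alpha_levels, function(a) {
      data.frame(method = m, alpha = a,
                 rejection_rate = mean(sub$p_value < a),
                 n_converged = sum(sub$converged),
                 n_fit = nrow(sub), n_reps = scenario$n_reps)
    }))
  }))

  estimation <- NULL
  if ("NBMM" %in% methods) {
    em <- do.call(rbind, est[!vapply(est, is.null, logical(1))])
    if (!is.null(em) && nrow(em) > 0) {
      estimation <- data.frame(
        parameter = c("beta", "tau2", "theta"),
        mean_error = colMeans(em),
        lower = apply(em, 2, stats::quantile, 0.025),
        upper = apply(em, 2, stats::quantile, 0.975),
        row.names = NULL)
    }
  }

  structure(list(rates = rates, estimation = estimation, per_rep = per_rep,
                 scenario = scenario, seed = seed,
                 x_convention = "x = 1 above the 40% quantile"),
            class = "nbmm_study")
}

#' @export
print.nbmm_study <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf(
    "Simulation study: n = %d, K = %d, beta regime = %s, rho regime = %s, %d reps\n",
    sc$n, sc$K, as.character(sc$beta), as.character(sc$rho), sc$n_reps))
  cat("Rejection rates of H0: beta = 0\n")
  print(x$rates, row.names = FALSE)
  if (!is.null(x$estimation)) {
    cat("NBMM estimation errors (estimate - truth)\n")
    print(x$estimation, row.names = FALSE)
  }
  invisible(x)
}

#' Write study results as tidy TSV files
#'
#' Writes `rates.tsv` (one row per method x alpha) and `per_rep.tsv` (one
#' row per replicate x method, for audit) into `dir`.
#'
#' @param study An `"nbmm_study"` object.
#' @param dir Output directory, created if missing.
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "nbmm_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(study$rates, file.path(dir, "rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$per_rep, file.path(dir, "per_rep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
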