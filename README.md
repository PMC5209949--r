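# nbmm — negative binomial mixed models for clustered microbiome counts

Sequencing-based microbiome studies often collect samples that are not
independent: multiple time points from the same subject, littermates
sharing a dam, pigs sharing a pen. Counts of a taxon are over-dispersed
(the variance far exceeds the mean) and correlated within those
clusters. Ignoring either feature distorts inference — over-dispersion
alone inflates test statistics, and within-cluster correlation inflates
the type-I error of any method that treats samples as independent.

`nbmm` implements a negative binomial mixed model (NBMM) that handles
both at once, fitted by an iterated weighted least squares (IWLS)
algorithm in which each step reduces to a weighted linear mixed model
on pseudo-data. The package also implements the standard alternatives
(negative binomial regression without random effects, linear mixed
models on log or arcsine-root proportions, plain linear regression),
a simulation framework for comparing them, and a per-feature screening
pipeline for count tables.

## The model

For counts `y_i` in sample `i` with total sequencing depth `T_i`,
host covariates `X_i`, and cluster `k(i)`:

    y_i ~ NB(mu_i, theta),   Var(y_i) = mu_i + mu_i^2 / theta
    log(mu_i) = log(T_i) + X_i beta + b_{k(i)}
    b_k ~ N(0, tau^2),  independent across clusters

`log(T_i)` enters as an offset, so `beta` describes effects on relative
abundance. `theta` captures over-dispersion (small `theta` = strong
over-dispersion), `tau^2` the between-cluster variance. The association
test is a Wald test of a single coefficient against a t reference with
`n - p - (K - 1)` degrees of freedom, `K` the number of clusters.

Fitting alternates three steps until the linear predictor stabilizes:

1. Build pseudo-data from the current fit: working response
   `t_i = eta_i + (y_i - mu_i) / mu_i` with weight
   `w_i = mu_i theta / (mu_i + theta)` (Fisher scoring; an
   observed-information variant is available via
   `nbmm_control(info = "observed")`).
2. Update `beta`, the cluster effects `b`, and `tau^2` by fitting a
   weighted linear mixed model to the pseudo-data with restricted
   maximum likelihood (a self-contained engine using a profiled
   one-dimensional REML criterion; cross-checked against `nlme` and
   `lme4` in the test suite).
3. Update `theta` by Newton–Raphson on the profile likelihood.

## Worked example: one taxon

Simulate a clustered dataset with a binary host factor (effect
`beta ≈ 0.54` on the log scale) and fit the NBMM:

```r
library(nbmm)

sc  <- sim_scenario(n = 200, K = 20, beta = "high", rho = "weak")
ds  <- simulate_dataset(sc, seed = 42)
X   <- cbind(`(Intercept)` = 1, x = ds$x)
fit <- fit_nbmm(ds$y, X, group = ds$z, offset = log(ds$total_reads))
fit
```

```
Negative binomial mixed model (IWLS fit)
  n = 200 samples, 2 fixed effects, 20 groups
  converged: TRUE after 15 iteration(s)
  theta = 1.358, tau2 = 1.178, sigma2 = 0.9865
  Fixed effects:
        coef   estimate        se  statistic  df      p_value
 (Intercept) -6.8752775 0.2687181 -25.585467 179 1.073054e-61
           x  0.4798399 0.1507817   3.182348 179 1.722622e-03
```

The true values for this draw were `beta = 0.54`, `theta = 1.50`,
`tau^2 = 0.84`; the host-factor effect is recovered (estimate 0.48,
p = 0.0017).

## Worked example: screening a count table

`screen_features()` runs the per-feature association test across a
feature-by-sample count matrix, with Benjamini–Hochberg adjustment
within each method:

```r
sc  <- sim_scenario(n = 200, K = 20)
tab <- simulate_count_table(sc, beta_features = c(rep(0.8, 3), rep(0, 7)),
                            seed = 7)
cm  <- count_matrix(tab$counts, tab$total_reads)
res <- screen_features(cm, tab$meta, fixed = "x", random = "group",
                       methods = "NBMM", alpha = 0.05)
head(res[order(res$p_value),
         c("feature", "beta_hat", "se", "p_value", "p_adjust",
           "significant")], 5)
```

```
    feature beta_hat     se  p_value p_adjust significant
1 feature_1    0.658 0.0836 3.24e-13 3.24e-12        TRUE
3 feature_3    0.810 0.1077 2.46e-12 1.23e-11        TRUE
2 feature_2    0.437 0.1819 1.75e-02 5.82e-02        TRUE
7 feature_7   -0.170 0.1202 1.58e-01 3.95e-01       FALSE
5 feature_5   -0.118 0.0952 2.19e-01 4.37e-01       FALSE
```

The three planted signals (features 1–3) rank first; the seven null
features are not flagged. On-disk TSV count tables (features in rows,
optional `total_reads` row) and sample metadata load through
`read_count_table()` / `read_sample_metadata()`, and results write back
with a provenance header via `write_results()`.

A thin command-line front end with `simulate`, `benchmark`, and
`test-all` subcommands is installed at
`system.file("scripts", "nbmm", package = "nbmm")`.

## Simulation framework

`sim_scenario()` describes a study: sample size `n`, `K = n/10` equal
clusters, baseline log relative abundance `-7`, log totals uniform on
[7.1, 10.5], `theta ~ U(0.1, 5)`, `tau ~ U(0.5, 1)`, effect regimes
`"null"`, `"low"` (U[0.2, 0.35]), `"high"` (U[0.4, 0.55]), and a
covariate–cluster correlation regime (`"weak"`, `"positive"`,
`"negative"`). `run_study()` replicates the scenario, fits the chosen
methods, and reports rejection rates and (for NBMM) estimation errors.
Headline behavior, measured at seed 1:

- Type-I error at the nominal 0.05 level is controlled for NBMM under
  weak correlation (≈ 0.056 over 1000 replicates, n = 200), while the
  negative binomial model without a random effect inflates badly under
  positive covariate–cluster correlation (≈ 0.22 vs ≈ 0.045 for NBMM).
- Power is highest for NBMM at both n = 200 and n = 400 among NBMM,
  NB, and the two transformed linear mixed models, and grows with n
  for every method.
- `beta` and `tau^2` are estimated with negligible bias; `theta` runs
  slightly high, compensated by the surrogate residual variance.

## Limitations

The model uses a single random intercept (one grouping factor), no
zero-inflation component, and a Wald test rather than a likelihood
ratio test. See the vignette (`vignettes/nbmm-methods.Rmd`) for the
algorithm in detail, the Fisher-vs-observed information design choice,
and the simulator's scope.
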