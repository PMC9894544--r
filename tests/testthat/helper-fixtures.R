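# Shared fixtures: small parameter worlds used across test files.
# All stochastic tests run under fixed seeds; Monte-Carlo comparisons use
# 3-standard-error tolerances.

# A fast benign K=0 world (no trends, constant rates).
fix_p0 <- function() growth_params(K = 0, X_PI0 = 0.5, alpha0 = 10,
                                   gamma0 = 0.5, sex = "F", shape = "sessile")

# K=1 stratum used for recovery tests; ADR ~ 23% at typical screening ages.
fix_p1 <- function() growth_params(K = 1, X_PI0 = 1.2, alpha0 = 20,
                                   gamma0 = 0.05, rho0 = 1e-3,
                                   sex = "F", shape = "sessile")

# K=2 stratum with all three age trends active.
fix_p2 <- function() growth_params(K = 2, X_PI0 = 0.08, alpha0 = 20,
                                   gamma0 = 0.05, rho0 = 1e-3,
                                   trend = age_trend(-0.3, -0.05, -0.05),
                                   sex = "M", shape = "all")

fix_g2 <- function() geometry(d = 2, y_r = 800, y0 = 30)
fix_g3 <- function() geometry(d = 3, y_r = 3200, y0 = 30)

# single-stratum cohort at one or more fixed ages
sim_fix_cohort <- function(p, g, n, seed, ages = NULL, oracle = FALSE) {
  ap <- if (is.null(ages)) NULL else
    data.frame(age = ages, prob = rep(1 / length(ages), length(ages)))
  simulate_cohort(cohort_spec(n, list(params = p, geometry = g),
                              age_probs = ap, seed = seed), oracle = oracle)
}

# 3-SE band check helper for a proportion
expect_within_3se <- function(p_hat, p_model, n, label = "") {
  se <- sqrt(pmax(p_model * (1 - p_model), 1e-12) / n)
  expect_lt(max(abs(p_hat - p_model) - 3 * se), 0, label = label)
}
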