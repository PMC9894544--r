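# Transformation rate, hazard, Poisson regression, transition probability
# and the interval-cancer hazard-ratio curve.

test_that("transformation rate: centering, constant case, ratio identity", {
  cp <- cancer_params(2e-6, 0.4)
  expect_equal(transformation_rate(cp, 65), 2e-6)
  expect_equal(transformation_rate(cp, 75) / transformation_rate(cp, 65),
               exp(0.4))
  cp0 <- cancer_params(2e-6, 0)
  expect_equal(transformation_rate(cp0, c(40, 65, 90)), rep(2e-6, 3))
})

test_that("hazard: zero rate, linearity in nu0, additivity over strata", {
  p <- fix_p2()
  expect_equal(cancer_hazard(p, cancer_params(0, 0.4), c(60, 70)), c(0, 0))
  h1 <- cancer_hazard(p, cancer_params(1e-6, 0.4), 70)
  h3 <- cancer_hazard(p, cancer_params(3e-6, 0.4), 70)
  expect_equal(h3, 3 * h1, tolerance = 1e-12)
  # two strata with identical parameters = twice one stratum
  h2 <- cancer_hazard(list(p, p),
                      list(cancer_params(1e-6, 0.4), cancer_params(1e-6, 0.4)),
                      70)
  expect_equal(h2, 2 * h1, tolerance = 1e-12)
})

test_that("single age group: closed-form one-parameter Poisson MLE", {
  p <- fix_p1()
  rt <- crude_rates(60, 70, patients = 5e4, cases = 37)
  fh <- fit_hazard(rt, p)
  EC <- mean_initiated_cells(p, 65)
  expect_equal(fh$params$nu0, 37 / (EC * 5e4), tolerance = 1e-10)
  expect_equal(fh$params$b_n, 0)
})

test_that("fit_hazard recovers (nu0, b_n) from simulated group counts", {
  p <- fix_p1()
  cp_true <- cancer_params(nu0 = 15e-4 / mean_initiated_cells(p, 65),
                           b_n = 0.4)
  groups <- data.frame(age_lo = seq(55, 90, 5), age_hi = seq(60, 95, 5),
                       patients = 25000)
  rt <- simulate_cancer_counts(p, cp_true, groups, seed = 31)
  fh <- fit_hazard(rt, p)
  se <- sqrt(diag(fh$vcov))        # log(nu0), b_n scales
  expect_lt(abs(log(fh$params$nu0) - log(cp_true$nu0)), 3 * se[1])
  expect_lt(abs(fh$params$b_n - cp_true$b_n), 3 * se[2])
})

test_that("simulation-inverted crude-rate CI matches Garwood within 5%", {
  for (cases in c(5, 20, 80)) {
    ci <- crude_rate_ci(cases, persontime = 1e4, n_sim = 4e4, seed = 8)
    garwood <- c(stats::qgamma(0.025, cases),
                 stats::qgamma(0.975, cases + 1))
    expect_equal(unname(ci[c("lower", "upper")]), garwood,
                 tolerance = 0.05)
  }
})

test_that("transition probability: trivial cases and monotonicity", {
  p <- fix_p2()
  expect_equal(transition_probability(p, cancer_params(0), 100, 60, 5), 0)
  cp <- cancer_params(2e-6, 0.4)
  expect_error(transition_probability(p, cp, 0, 60, 5), ">= 1")
  Py <- transition_probability(p, cp, c(10, 100, 1000, 10000), 60, 5)
  expect_true(all(diff(Py) > 0))
  Pd <- vapply(c(1, 3, 6, 10), function(d)
    transition_probability(p, cp, 500, 60, d), numeric(1))
  expect_true(all(diff(Pd) > 0))
  Pn <- vapply(c(1, 2, 4) * 1e-6, function(nu)
    transition_probability(p, cancer_params(nu, 0.4), 500, 60, 5), numeric(1))
  expect_true(all(diff(Pn) > 0))
  # lower bound: at least the no-growth no-death transformation mass
  intnu <- stats::integrate(function(u) transformation_rate(cp, u),
                            60, 65)$value
  expect_gte(transition_probability(p, cp, 500, 60, 5),
             1 - exp(-500 * intnu))
  expect_true(all(Py >= 0 & Py <= 1))
})

test_that("transition probability matches the constant-rate Riccati closed form", {
  # independent derivation: u = -w'/(alpha w) linearizes the backward
  # Riccati equation to w'' + (a+b+nu) w' + a b w = 0; with u(T) = 1 the
  # closed form follows from the characteristic roots.
  p <- suppressWarnings(growth_params(K = 0, X_PI0 = 1, alpha0 = 10,
                                      gamma0 = 0.5))  # no trends: constant
  cp <- cancer_params(5e-4, 0)
  a <- 10; b <- 9.5; nu <- 5e-4
  closed_u <- function(tau) {
    # in time-to-go tau: w'' + (a+b+nu) w' + a b w = 0, u = -w'/(a w),
    # u(0) = 1 fixes the constants
    disc <- sqrt((a + b + nu)^2 - 4 * a * b)
    l1 <- (-(a + b + nu) + disc) / 2
    l2 <- (-(a + b + nu) - disc) / 2
    c1 <- l2 + a
    c2 <- -(l1 + a)
    w  <- c1 * exp(l1 * tau) + c2 * exp(l2 * tau)
    wp <- c1 * l1 * exp(l1 * tau) + c2 * l2 * exp(l2 * tau)
    -wp / (a * w)
  }
  for (tau in c(1, 5, 10)) {
    u_pkg <- 1 - transition_probability(p, cp, 1, 65, tau)
    expect_equal(u_pkg, closed_u(tau), tolerance = 1e-7)
  }
  y <- 200
  expect_equal(transition_probability(p, cp, y, 65, 5),
               1 - closed_u(5)^y, tolerance = 1e-6)
})

test_that("transition probability matches the Gillespie oracle", {
  p <- suppressWarnings(growth_params(K = 0, X_PI0 = 1, alpha0 = 10,
                                      gamma0 = 0.5))
  cp <- cancer_params(5e-4, 0)
  n <- 2e4
  sim <- gillespie_clone(p, 60, 65, n_rep = n, n_init = 200, cp = cp,
                         seed = 55)
  frac <- mean(sim$transformed)
  pt <- transition_probability(p, cp, 200, 60, 5)
  expect_within_3se(frac, pt, n, "transformation fraction")
})

test_that("HR curve: normalization, ADR monotonicity, r_Y ordering", {
  p <- default_growth_params("M", "all")
  g <- default_geometry("all", 2)
  # stay below the model-expected ADR so the removal factor is feasible
  adr <- seq(0.1, 0.4, 0.05)
  h1 <- hr_curve(p, g, t = 65, r_Y = 1, adr_grid = adr, adr_ref = 0.25)
  expect_equal(h1$hr_eff[h1$adr == 0.25], 1, tolerance = 1e-10)
  expect_true(all(diff(h1$hr_eff) < 0))
  h05 <- hr_curve(p, g, t = 65, r_Y = 0.5, adr_grid = adr, adr_ref = 0.25)
  expect_true(all(h05$hr_eff > h1$hr_eff))
  # APC / ADR identity behind the curve
  expect_equal(-log(1 - h1$adr),
               h1$r_N_eff * expected_detectable_number(p, g, 65),
               tolerance = 1e-10)
  # infeasible ADR flagged
  expect_warning(hr_curve(p, g, adr_grid = 0.99), "outside")
})
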