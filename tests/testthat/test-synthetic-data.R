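# Cohort generator, Gillespie oracle behavior, and the packaged fixture.

test_that("Gillespie: frozen process and Yule limit", {
  # (near-)frozen: vanishing rates leave the initial cells untouched
  p_frozen <- suppressWarnings(growth_params(K = 0, X_PI0 = 1, alpha0 = 1e-9,
                                             gamma0 = 5e-10))
  sim <- gillespie_clone(p_frozen, 60, 70, n_rep = 500, n_init = 4, seed = 1)
  expect_true(all(sim$count == 4))
  expect_false(any(sim$transformed))

  # (near-)pure birth: final counts follow the Yule geometric law
  alpha <- 1; tau <- 1.5
  p_yule <- suppressWarnings(growth_params(K = 0, X_PI0 = 1, alpha0 = alpha,
                                           gamma0 = alpha * (1 - 1e-9)))
  n <- 2e4
  sim <- gillespie_clone(p_yule, 65, 65 + tau, n_rep = n, seed = 2)
  expect_equal(min(sim$count), 1)   # no extinction under pure birth
  brk <- c(1:8, Inf)
  obs <- vapply(seq_along(brk), function(i)
    if (is.infinite(brk[i])) sum(sim$count >= 9) else sum(sim$count == brk[i]),
    numeric(1))
  pr1 <- exp(-alpha * tau)
  pmf <- pr1 * (1 - pr1)^(0:7)
  expected <- n * c(pmf, (1 - pr1)^8)
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, stats::qchisq(0.99, df = length(obs) - 1))
})

test_that("Gillespie extinction fraction matches the analytic p0", {
  p <- fix_p0()
  n <- 2e4
  sim <- gillespie_clone(p, 60, 63, n_rep = n, seed = 3)
  p0 <- clone_size_law(60, 63, params = p)$p0
  expect_within_3se(mean(sim$count == 0), p0, n, "extinction fraction")
})

test_that("cohort spec validation", {
  p <- fix_p1(); g <- fix_g2()
  expect_error(cohort_spec(100, list(params = p, geometry = g)),
               "seed is mandatory")
  expect_error(cohort_spec(100, list(params = p, geometry = g),
                           sex_probs = c(F = 0.6, M = 0.6), seed = 1),
               "sum to 1")
})

test_that("infinite detection limit produces an adenoma-free cohort", {
  p <- fix_p1()
  g <- fix_g2(); g$y0 <- 1e12
  rec <- sim_fix_cohort(p, g, 2000, seed = 4)
  expect_true(all(rec$count_cat == "0"))
  expect_true(all(is.na(rec$size_cat)))
})

test_that("observed APC and ADR match the model at a fixed age", {
  p <- fix_p1(); g <- fix_g2()
  n <- 1e5
  rec <- sim_fix_cohort(p, g, n, seed = 5, ages = 65)
  Lam <- expected_detectable_number(p, g, 65)
  n_hat <- c(`0` = 0, `1` = 1, `2-4` = 2, `5+` = 5)[rec$count_cat]
  # ADR within 3 binomial SE
  expect_within_3se(mean(rec$count_cat != "0"), 1 - exp(-Lam), n, "ADR")
  # categorized APC (counts capped at category representatives) vs the same
  # functional of the Poisson model
  pmodel <- c(stats::dpois(0:1, Lam), sum(stats::dpois(2:4, Lam)),
              stats::ppois(4, Lam, lower.tail = FALSE))
  apc_model <- sum(c(0, 1, 2, 5) * pmodel)
  se <- stats::sd(n_hat) / sqrt(n)
  expect_lt(abs(mean(n_hat) - apc_model), 3 * se)
})

test_that("the oracle (Gillespie) cohort path agrees with the analytic path", {
  # slow-growth short-horizon world keeps exact event-by-event simulation
  # tractable (clone sizes stay modest)
  p <- suppressWarnings(growth_params(K = 0, X_PI0 = 0.5, alpha0 = 1,
                                      gamma0 = 0.1, sex = "F",
                                      shape = "sessile"))
  g <- geometry(2, 800, 5)
  n <- 4000
  rec_o <- sim_fix_cohort(p, g, n, seed = 6, ages = 30, oracle = TRUE)
  Lam <- expected_detectable_number(p, g, 30)
  expect_within_3se(mean(rec_o$count_cat != "0"), 1 - exp(-Lam), n,
                    "oracle-path ADR")
})

test_that("count-category representatives are the most probable values", {
  # under Poisson counts in the fitted range the mode within {2,3,4} is 2
  # and within {5,...} is 5
  for (Lam in seq(0.2, 1.6, 0.2)) {
    expect_true(all(diff(stats::dpois(2:4, Lam)) < 0))
    expect_true(all(diff(stats::dpois(5:9, Lam)) < 0))
  }
})

test_that("fixture is seed-reproducible and matches configured marginals", {
  d1 <- tempfile("fx1"); d2 <- tempfile("fx2")
  dir.create(d1); dir.create(d2)
  fx1 <- bavarian_fixture(seed = 42, scale = 0.02, dir = d1)
  fx2 <- bavarian_fixture(seed = 42, scale = 0.02, dir = d2)
  expect_identical(readLines(fx1$record_file), readLines(fx2$record_file))
  expect_identical(readLines(fx1$rate_file), readLines(fx2$rate_file))

  rec <- fx1$records
  pos <- rec[rec$count_cat != "0", ]
  shares <- vapply(c("sessile", "peduncular", "flat"), function(sh)
    sum(pos$multiplicity[pos$shape == sh]) / sum(pos$multiplicity),
    numeric(1))
  expect_lt(max(abs(shares - c(0.70, 0.18, 0.12))), 0.05)
  # ADR higher in men
  adr <- vapply(c("F", "M"), function(sx) {
    m <- rec[rec$sex == sx, ]
    sum(m$multiplicity[m$count_cat != "0"]) / sum(m$multiplicity)
  }, numeric(1))
  expect_gt(adr[["M"]], adr[["F"]])
  # round trip through the reader is lossless
  back <- read_records(fx1$record_file)
  data.table::setkey(back, sex, shape, age, count_cat, size_cat)
  expect_equal(as.data.frame(back), as.data.frame(fx1$records))
})

test_that("simulated cancer counts: zero hazard and mean recovery", {
  p <- fix_p1()
  groups <- data.frame(age_lo = c(60, 70), age_hi = c(65, 75),
                       patients = c(5e5, 5e5))
  rt0 <- simulate_cancer_counts(p, cancer_params(0), groups, seed = 9)
  expect_true(all(rt0$cases == 0))
  cp <- cancer_params(nu0 = 15e-4 / mean_initiated_cells(p, 65), b_n = 0.4)
  rt <- simulate_cancer_counts(p, cp, groups, seed = 10)
  mu <- cancer_hazard(p, cp, c(62.5, 72.5)) * groups$patients
  expect_true(all(abs(rt$cases - mu) < 3 * sqrt(mu)))
  # strained rare-event regime warns
  cp_hot <- cancer_params(0.15 / mean_initiated_cells(p, 65), 0)
  expect_warning(simulate_cancer_counts(p, cp_hot, groups, seed = 11),
                 "rare-event")
})
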