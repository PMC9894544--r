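# Core MSCE mathematics: age trends, size law, clone-size distribution,
# initiation intensity, detectable-number/size integrals, extinction.

test_that("age trends: centering identity, no-trend case, ratio identities", {
  p <- growth_params(K = 1, X_PI0 = 2, alpha0 = 20, gamma0 = 0.05,
                     rho0 = 1e-3, trend = age_trend(0.3, -0.1, 0.1))
  r65 <- params_at_age(p, 65)
  expect_equal(r65$X_P, 2)
  expect_equal(r65$alpha, 20)
  expect_equal(r65$gamma, 0.05)
  expect_equal(r65$rho, 1e-3)
  expect_equal(r65$beta, 20 - 0.05)

  p0 <- growth_params(K = 0, X_PI0 = 2, alpha0 = 20, gamma0 = 0.05)
  for (a in c(0, 40, 65, 90)) {
    r <- params_at_age(p0, a)
    expect_equal(r$X_P, 2)
    expect_equal(r$alpha, 20)
  }

  # one decade above centering: alpha up e^ba, rho down e^-ba, product fixed
  r75 <- params_at_age(p, 75)
  expect_equal(r75$alpha / r65$alpha, exp(0.1))
  expect_equal(r75$rho / r65$rho, exp(-0.1))
  expect_equal(r75$rho * r75$alpha, r65$rho * r65$alpha)

  expect_error(params_at_age(p, -1), "negative age")
  # strong positive trend can push gamma above... never: shared trend keeps
  # beta = (alpha0-gamma0) e^{ba z} > 0; invalid base values are rejected
  expect_error(growth_params(K = 0, X_PI0 = 1, alpha0 = 10, gamma0 = 10),
               "gamma0 < alpha0")
  expect_error(growth_params(K = 1, X_PI0 = 1, alpha0 = 10, gamma0 = 1),
               "rho0")
})

test_that("size law: reference point, printed detection limits, round trip", {
  g <- geometry(2, 800, 30)
  expect_equal(cells_to_size(g, 800), 1)
  expect_equal(round(cells_to_size(g, 30), 2), 0.19)
  expect_equal(round(cells_to_size(geometry(3, 3200, 30), 30), 2), 0.21)
  expect_equal(round(cells_to_size(geometry(2, 200, 40), 40), 2), 0.45)
  for (gg in list(g, geometry(3, 3200, 30), geometry(2, 200, 40))) {
    S <- c(0.05, 0.3, 1, 2.7)
    expect_equal(cells_to_size(gg, size_to_cells(gg, S)), S)
  }
  expect_error(cells_to_size(g, 0), "positive")
  expect_error(size_to_cells(g, -1), "positive")
})

test_that("clone-size law reproduces the constant-rate closed form to 1e-8", {
  p <- fix_p0()                               # alpha 10, gamma 0.5, no trend
  a <- 10; b <- 9.5
  for (tau in c(0.3, 2, 8)) {
    law <- clone_size_law(60, 60 + tau, params = p)
    D <- a * exp(0.5 * tau) - b
    expect_equal(law$p0, b * (exp(0.5 * tau) - 1) / D, tolerance = 1e-8)
    expect_equal(law$q, a * (exp(0.5 * tau) - 1) / D, tolerance = 1e-8)
    expect_equal(law$mean, exp(0.5 * tau), tolerance = 1e-10)
  }
})

test_that("clone-size law: zero elapsed time is a point mass at one cell", {
  law <- clone_size_law(60, 60, params = fix_p2())
  expect_equal(clone_size_pmf(law, 1), 1)
  expect_equal(clone_size_pmf(law, 0), 0)
  expect_equal(clone_size_pmf(law, 2), 0)
})

test_that("pure-birth (Yule) limit via the generic rate-function path", {
  alpha <- 0.8; tau <- 1.5
  law <- clone_size_law(0, tau, alpha = function(u) rep(alpha, length(u)),
                        beta = function(u) rep(0, length(u)))
  expect_equal(law$p0, 0, tolerance = 1e-10)
  y <- 1:12
  yule <- exp(-alpha * tau) * (1 - exp(-alpha * tau))^(y - 1)
  expect_equal(clone_size_pmf(law, y), yule, tolerance = 1e-7)
})

test_that("normalization and mean identity across an (s, t) grid", {
  for (p in list(fix_p0(), fix_p2())) {
    for (s in c(20, 45, 60)) for (t in c(61, 75, 90)) {
      law <- clone_size_law(s, t, params = p)
      ymax <- 2e5
      pm <- clone_size_pmf(law, 0:ymax)
      # enumerated mass plus the analytic tail must close to 1
      expect_equal(sum(pm) + clone_survival(law, ymax + 1), 1,
                   tolerance = 1e-6)
      if (clone_survival(law, ymax + 1) < 1e-10)
        expect_equal(sum((0:ymax) * pm), law$mean,
                     tolerance = 1e-4 * max(law$mean, 1))
      # mean identity: E[Y] = exp(integral of gamma), independent quadrature
      Rnum <- stats::integrate(function(u) params_at_age(p, u)$gamma,
                               s, t, rel.tol = 1e-10)$value
      expect_equal(law$mean, exp(Rnum), tolerance = 1e-7)
    }
  }
})

test_that("generic quadrature path agrees with the closed-form trend path", {
  p <- fix_p2()
  rate <- function(nm) function(u) params_at_age(p, u)[[nm]]
  for (st in list(c(30, 70), c(55, 90), c(64.5, 65.5))) {
    l1 <- clone_size_law(st[1], st[2], params = p)
    l2 <- clone_size_law(st[1], st[2], alpha = rate("alpha"),
                         beta = rate("beta"))
    expect_equal(l1$p0, l2$p0, tolerance = 1e-7)
    expect_equal(l1$q, l2$q, tolerance = 1e-7)
  }
})

test_that("clone-size pmf matches the Gillespie oracle (near-critical)", {
  p <- suppressWarnings(growth_params(K = 0, X_PI0 = 1, alpha0 = 10,
                                      gamma0 = 0.5))
  n <- 1e5
  sim <- gillespie_clone(p, 60, 62, n_rep = n, seed = 101)
  law <- clone_size_law(60, 62, params = p)
  # bin sizes 0,1,...,9, 10+ and compare within 3 binomial SE per bin
  brk <- c(0:9, Inf)
  obs <- vapply(seq_along(brk), function(i) {
    if (is.infinite(brk[i])) mean(sim$count >= 10) else mean(sim$count == brk[i])
  }, numeric(1))
  mod <- c(clone_size_pmf(law, 0:9), clone_survival(law, 10))
  expect_within_3se(obs, mod, n, "pmf bins vs Gillespie")
})

test_that("initiation intensity: K = 0/1/2 structure and oracle", {
  p0 <- growth_params(K = 0, X_PI0 = 0.7, alpha0 = 20, gamma0 = 0.05)
  expect_equal(initiation_intensity(p0, c(0, 30, 80)), rep(0.7, 3))

  p1 <- growth_params(K = 1, X_PI0 = 0.7, alpha0 = 20, gamma0 = 0.05,
                      rho0 = 2e-3)
  s <- c(0, 10, 50)
  expect_equal(initiation_intensity(p1, s), 0.7 * 2e-3 * 20 * s)

  p2 <- growth_params(K = 2, X_PI0 = 0.7, alpha0 = 20, gamma0 = 0.05,
                      rho0 = 2e-3)
  expect_equal(initiation_intensity(p2, s), 2e-3 * 20 * 0.7 * s^2 / 2)
  expect_equal(initiation_intensity(p2, 0), 0)

  # age-varying Poisson strength: double integral via independent quadrature
  p2t <- modify_params(p2, bx1 = -0.4, bx2 = -0.08)
  XP <- function(u) params_at_age(p2t, u)$X_P
  inner <- Vectorize(function(u) stats::integrate(XP, 0, u,
                                                  rel.tol = 1e-10)$value)
  for (ss in c(25, 60, 85)) {
    outer_int <- stats::integrate(inner, 0, ss, rel.tol = 1e-9)$value
    expect_equal(initiation_intensity(p2t, ss), 2e-3 * 20 * outer_int,
                 tolerance = 1e-6)
  }
})

test_that("Lambda: independent quadrature oracle and y0 monotonicity", {
  p <- fix_p2(); g <- fix_g2()
  inten <- function(s) initiation_intensity(p, s)
  for (t in c(60, 80)) {
    oracle <- stats::integrate(function(s) {
      vapply(s, function(si) {
        law <- clone_size_law(si, t, params = p)
        inten(si) * clone_survival(law, g$y0)
      }, numeric(1))
    }, 0, t, rel.tol = 1e-9)$value
    expect_equal(expected_detectable_number(p, g, t), oracle,
                 tolerance = 1e-6)
  }
  # nested events: Lambda nonincreasing in the detection limit
  L <- vapply(c(1, 10, 30, 100, 1000), function(y0) {
    gg <- g; gg$y0 <- y0
    expected_detectable_number(p, gg, 70)
  }, numeric(1))
  expect_true(all(diff(L) < 0))
})

test_that("detectable size CDF is a proper CDF with correct boundaries", {
  p <- fix_p2(); g <- fix_g2()
  expect_error(detectable_size_cdf(p, g, 65, 10), "below the detection")
  y <- c(30, 50, 100, 200, 800, 3200, 1e5, Inf)
  F <- detectable_size_cdf(p, g, 65, y)
  expect_true(all(diff(F) >= 0))
  expect_equal(F[length(F)], 1)
  expect_true(all(F >= 0 & F <= 1))
})

test_that("mean initiated cells: near-zero growth limit and monotonicity", {
  # gamma -> 0: pure accumulation, E[C](t) = X_PI0 * t
  p <- suppressWarnings(growth_params(K = 0, X_PI0 = 0.4, alpha0 = 10,
                                      gamma0 = 1e-9))
  expect_equal(mean_initiated_cells(p, c(10, 50)), 0.4 * c(10, 50),
               tolerance = 1e-6)
  EC <- mean_initiated_cells(fix_p2(), seq(40, 90, 10))
  expect_true(all(diff(EC) > 0))
})

test_that("extinction probability: limits, modes and monotonicity", {
  p <- fix_p0()   # constant rates alpha 10, beta 9.5
  expect_equal(extinction_probability(p, 1:5, 60, 0), rep(0, 5))
  expect_error(extinction_probability(p, 0, 60, 1), ">= 1")
  # supercritical long-run limit (beta/alpha)^y
  expect_equal(extinction_probability(p, c(1, 10, 30), 30, 200),
               (9.5 / 10)^c(1, 10, 30), tolerance = 1e-6)
  # frozen-rate mode equals the constant-rate closed form at t0 rates
  pt <- fix_p2()
  r <- params_at_age(pt, 60)
  gam <- r$alpha - r$beta
  D <- r$alpha * exp(gam * 5) - r$beta
  expect_equal(extinction_probability(pt, 7, 60, 5, frozen = TRUE),
               (r$beta * (exp(gam * 5) - 1) / D)^7, tolerance = 1e-9)
  # monotone: nonincreasing in y, nondecreasing in dt
  Py <- extinction_probability(pt, c(1, 5, 20, 80), 60, 5)
  expect_true(all(diff(Py) < 0))
  Pd <- extinction_probability(pt, 10, 60, c(0.5, 1, 3, 8))
  expect_true(all(diff(Pd) > 0))
})

test_that("extinction probability matches the Gillespie oracle", {
  p <- suppressWarnings(growth_params(K = 0, X_PI0 = 1, alpha0 = 10,
                                      gamma0 = 0.5))
  n <- 2e4
  sim <- gillespie_clone(p, 60, 65, n_rep = n, n_init = 30, seed = 77)
  frac <- mean(sim$count == 0)
  pext <- extinction_probability(p, 30, 60, 5)
  expect_within_3se(frac, pext, n, "30-cell clone extinction")
})
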