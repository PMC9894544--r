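# Simple cancer-risk layer on top of the growth model.
#
# The full MSCE cancer model (malignant clonal expansion) is out of scope:
# too few cases to identify its parameters. Instead each initiated cell
# acquires the transforming mutation at an age-dependent rate
# nu(t) = nu0 * exp(b_n (t - 65)/10), and the population hazard is
# h(t) = nu(t) * E[C(t)] with E[C(t)] the mean number of initiated cells per
# person. nu(t) thereby absorbs all downstream processes (tumor growth,
# clinical detection) that turn a benign adenoma into a recorded cancer.

#' Transformation-rate parameters of the simple cancer risk model
#'
#' @param nu0 base transformation rate at age 65 (per initiated cell per yr).
#' @param b_n per-decade log-linear age coefficient.
#' @export
cancer_params <- function(nu0, b_n = 0) {
  stopifnot(is.finite(nu0), nu0 >= 0, is.finite(b_n))
  structure(list(nu0 = nu0, b_n = b_n), class = "cancer_params")
}

#' Transformation rate at an attained age
#'
#' `nu(t) = nu0 * exp(b_n * (t - 65) / 10)`.
#'
#' @param cp a [cancer_params()] object.
#' @param t age(s) in years.
#' @export
transformation_rate <- function(cp, t) {
  stopifnot(inherits(cp, "cancer_params"))
  if (any(t < 0)) stop("age must be nonnegative")
  cp$nu0 * exp(cp$b_n * (t - 65) / 10)
}

#' Cancer hazard of the simple risk model
#'
#' `h(t) = nu(t) * E[C(t)]` per person-year. For several shape strata the
#' all-shapes hazard is the sum of the shape-specific hazards: pass lists of
#' equal length for `p` and `cp`.
#'
#' @param p a [growth_params()] object, or a list of them (shape strata).
#' @param cp a [cancer_params()] object, or a list matching `p`.
#' @param t age(s) in years.
#' @export
cancer_hazard <- function(p, cp, t) {
  if (inherits(p, "growth_params")) { p <- list(p); cp <- list(cp) }
  stopifnot(length(p) == length(cp))
  h <- 0
  for (i in seq_along(p))
    h <- h + transformation_rate(cp[[i]], t) * mean_initiated_cells(p[[i]], t)
  h
}

#' Crude cancer-rate table constructor
#'
#' One row per 5-yr age group: bounds, patients under observation, observed
#' cases, and the implied crude rate per 10^4 persons per year.
#'
#' @param age_lo,age_hi age-group bounds (years).
#' @param patients,cases nonnegative counts, `cases <= patients`.
#' @param sex optional label column.
#' @param years observation years per patient (default 1).
#' @export
crude_rates <- function(age_lo, age_hi, patients, cases, sex = NA_character_,
                        years = 1) {
  stopifnot(all(age_hi > age_lo), all(patients >= 0), all(cases >= 0),
            all(cases <= patients))
  data.table::data.table(
    age_lo = age_lo, age_hi = age_hi, sex = sex,
    patients = patients, cases = cases,
    rate_per_10k = 1e4 * cases / (patients * years))
}

#' Fit the transformation rate to crude cancer rates by Poisson regression
#'
#' With the growth parameters fixed, maximizes the Poisson likelihood of the
#' age-group case counts with mean
#' `h(midpoint) * patients * years = nu(midpoint) * E[C(midpoint)] * persontime`.
#' Because `h` is linear in `nu0`, the profile over `b_n` is one-dimensional
#' and the fit is a stable two-parameter optimization. Wald and profile
#' confidence intervals are reported.
#'
#' @param rates a [crude_rates()] table.
#' @param p fixed [growth_params()] for the stratum.
#' @param years observation years per patient per row (default 1).
#' @param integrate_groups if `TRUE`, average the hazard over each age group
#'   (5 Gauss-Legendre points) instead of evaluating at the midpoint.
#' @param level confidence level.
#' @return list with `params` ([cancer_params()]), `loglik`, `vcov`,
#'   `wald_ci`, `profile_ci` (2 x 2 matrices), `boundary` flag.
#' @export
fit_hazard <- function(rates, p, years = 1, integrate_groups = FALSE,
                       level = 0.95) {
  stopifnot(inherits(p, "growth_params"), nrow(rates) >= 1)
  mid <- (rates$age_lo + rates$age_hi) / 2
  persontime <- rates$patients * years
  if (integrate_groups) {
    # mean over the group of nu(t)E[C(t)] given (nu0=1, b_n); depends on b_n,
    # so fold into the objective
    grp <- lapply(seq_len(nrow(rates)), function(i) {
      gl <- gl_rescale(rates$age_lo[i], rates$age_hi[i], n = 5L)
      list(ages = gl$x[1, ],
           w = gl$w[1, ] / (rates$age_hi[i] - rates$age_lo[i]),
           EC = mean_initiated_cells(p, gl$x[1, ]))
    })
    unit_mean <- function(b_n) vapply(grp, function(gg)
      sum(gg$w * exp(b_n * (gg$ages - 65) / 10) * gg$EC), numeric(1))
  } else {
    EC <- mean_initiated_cells(p, mid)
    unit_mean <- function(b_n) exp(b_n * (mid - 65) / 10) * EC
  }
  cases <- rates$cases
  if (all(cases == 0)) {
    warning("all case counts zero: nu0 estimated at the boundary 0")
    return(list(params = cancer_params(0, 0), loglik = 0,
                vcov = matrix(NA, 2, 2), wald_ci = NULL, profile_ci = NULL,
                boundary = TRUE))
  }
  if (nrow(rates) == 1L) {
    # one age group: b_n unidentifiable, closed-form one-parameter MLE
    nu0 <- cases / (unit_mean(0) * persontime)
    z <- stats::qnorm(1 - (1 - level) / 2)
    wald <- rbind(nu0 = nu0 * exp(c(-1, 1) * z / sqrt(cases)),
                  b_n = c(NA, NA))
    colnames(wald) <- c("lower", "upper")
    return(list(params = cancer_params(nu0, 0),
                loglik = stats::dpois(cases, cases, log = TRUE),
                vcov = matrix(NA, 2, 2), wald_ci = wald, profile_ci = NULL,
                boundary = FALSE))
  }
  nll <- function(th) {
    mu <- exp(th[1]) * unit_mean(th[2]) * persontime
    if (any(!is.finite(mu)) || any(mu <= 0)) return(1e10)
    -sum(stats::dpois(cases, mu, log = TRUE))
  }
  th0 <- c(log(sum(cases) / sum(unit_mean(0) * persontime)), 0)
  opt <- stats::optim(th0, nll, method = "BFGS", hessian = TRUE,
                      control = list(reltol = 1e-12, maxit = 500))
  nu0 <- exp(opt$par[1]); b_n <- opt$par[2]
  V <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA, 2, 2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  wald <- rbind(
    nu0 = exp(opt$par[1] + c(-1, 1) * z * sqrt(V[1, 1])),
    b_n = opt$par[2] + c(-1, 1) * z * sqrt(V[2, 2]))
  colnames(wald) <- c("lower", "upper")
  # profile CIs by bisection on each coordinate
  crit <- stats::qchisq(level, 1)
  prof_one <- function(j) {
    pro <- function(x) {
      f <- function(y) nll(if (j == 1) c(x, y) else c(y, x))
      stats::optimize(f, interval = if (j == 1) c(-10, 10)
                      else c(opt$par[1] - 10, opt$par[1] + 10))$objective
    }
    bound <- function(dir) {
      x0 <- opt$par[j]; step <- max(0.2, sqrt(abs(V[j, j])))
      for (i in 1:30) {
        x1 <- x0 + dir * step * i
        if (2 * (pro(x1) - opt$value) >= crit) {
          r <- stats::uniroot(function(x) 2 * (pro(x) - opt$value) - crit,
                              sort(c(opt$par[j], x1)), tol = 1e-4)
          return(r$root)
        }
      }
      dir * Inf
    }
    c(bound(-1), bound(1))
  }
  prof <- rbind(nu0 = exp(prof_one(1)), b_n = prof_one(2))
  colnames(prof) <- c("lower", "upper")
  list(params = cancer_params(nu0, b_n), loglik = -opt$value, vcov = V,
       wald_ci = wald, profile_ci = prof, boundary = FALSE)
}

#' Probability of an adenoma transiting to cancer
#'
#' Probability that a clone of `y` initiated cells present at age `t0`
#' produces at least one transformation event within waiting time `dt`.
#' Cells evolve independently as a birth-death process with killing: the
#' single-cell no-transformation probability `u` solves the backward Riccati
#' equation `du/ds = alpha(s) u^2 - (alpha+beta+nu)(s) u + beta(s)` with
#' `u(t0+dt) = 1`, integrated here by fixed-step RK4; then
#' `P_trans = 1 - u(t0)^y`. Competing mortality is not modeled.
#'
#' @param p a [growth_params()] object.
#' @param cp a [cancer_params()] object.
#' @param y clone size(s) in cells at `t0`, `>= 1`.
#' @param t0 age at observation (yr).
#' @param dt waiting time(s) (yr), nonnegative.
#' @param step RK4 step size in years (default 0.01).
#' @return transition probability in `[0, 1]`.
#' @export
transition_probability <- function(p, cp, y, t0, dt, step = 0.01) {
  stopifnot(inherits(p, "growth_params"), inherits(cp, "cancer_params"))
  if (any(y < 1)) stop("y must be >= 1")
  if (any(dt < 0)) stop("dt must be nonnegative")
  u_single <- function(dti) {
    if (dti == 0) return(1)
    n <- max(2L, ceiling(dti / step))
    h <- dti / n
    f <- function(s, u) {
      r <- params_at_age(p, s)
      nu <- transformation_rate(cp, s)
      r$alpha * u^2 - (r$alpha + r$beta + nu) * u + r$beta
    }
    # In time-to-go tau = (t0 + dt) - s the backward equation reads
    # du/dtau = alpha u^2 - (alpha+beta+nu) u + beta, u(tau = 0) = 1.
    u <- 1
    s <- t0 + dti
    for (i in seq_len(n)) {
      k1 <- f(s, u)
      k2 <- f(s - h / 2, u + h / 2 * k1)
      k3 <- f(s - h / 2, u + h / 2 * k2)
      k4 <- f(s - h, u + h * k3)
      u <- u + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      s <- s - h
    }
    min(max(u, 0), 1)
  }
  u <- vapply(dt, u_single, numeric(1))
  out <- 1 - rep(u, length.out = max(length(y), length(dt)))^y
  pmin(pmax(out, 0), 1)
}

#' Interval-cancer hazard ratio as a function of the adenoma detection rate
#'
#' After a screening colonoscopy at age `t`, interval-cancer risk stems from
#' undetected or incompletely removed adenoma. With the effective removal
#' factor `r_N^eff` (fraction of detectable adenoma removed; linked to the
#' detection rate via `APC = r_N^eff * E_N^{y0}(t)` and
#' `APC = -log(1 - ADR)`) and the effective size-reduction factor `r_Y^eff`,
#' the hazard ratio is evaluated as
#' `HR_eff ∝ (1 - x z) / (1 - x)` with
#' `x = r_N^eff E_N^{y0}/E_N^{0}` and `z = r_Y^eff E_Y^{y0}/E_Y^{0}`
#' (residual initiated-cell burden per residual adenoma). All curves share a
#' single normalization constant: the reference scenario is full size
#' removal (`r_Y = 1`) at the reference ADR, so the `r_Y = 1` curve equals 1
#' there and incomplete removal (`r_Y < 1`) shifts the whole curve up.
#'
#' @param p a [growth_params()] object (all-shapes stratum).
#' @param g a [geometry()] object.
#' @param t age at examination (yr), default 65.
#' @param r_Y effective size reduction factor in `(0, 1]`.
#' @param adr_grid ADR values to evaluate.
#' @param adr_ref reference ADR where `HR_eff = 1`; defaults to the
#'   model-expected ADR at age `t`.
#' @return data.table with columns `adr`, `r_N_eff`, `hr_eff`.
#' @export
hr_curve <- function(p, g, t = 65, r_Y = 1, adr_grid = seq(0.1, 0.6, 0.05),
                     adr_ref = NULL) {
  stopifnot(r_Y > 0, r_Y <= 1, all(adr_grid > 0), all(adr_grid < 1))
  EN_det <- expected_detectable_number(p, g, t)
  g1 <- g; g1$y0 <- 1
  EN_all <- expected_detectable_number(p, g1, t)
  EY_det <- expected_detectable_size(p, g, t)
  EY_all <- expected_detectable_size(p, g, t, y0 = 1)
  if (is.null(adr_ref)) adr_ref <- 1 - exp(-EN_det)
  raw <- function(adr, rY) {
    apc <- -log(1 - adr)
    r_N <- apc / EN_det
    x <- r_N * EN_det / EN_all
    z <- rY * EY_det / EY_all
    list(r_N = r_N, hr = (1 - x * z) / (1 - x))
  }
  # single normalization shared across r_Y settings: the reference scenario
  # is full size removal (r_Y = 1) at the reference ADR
  ref <- raw(adr_ref, 1)$hr
  res <- raw(adr_grid, r_Y)
  bad <- res$r_N <= 0 | res$r_N >= 1
  if (any(bad))
    warning("ADR value(s) ", paste(adr_grid[bad], collapse = ", "),
            " imply an effective removal factor outside (0, 1)")
  data.table::data.table(adr = adr_grid, r_N_eff = res$r_N,
                         hr_eff = res$hr / ref)
}

#' Confidence interval for a crude rate by Poisson test inversion
#'
#' Interval for the Poisson mean behind an observed case count, derived by
#' simulation: the bounds are the mean values at which the Monte-Carlo
#' estimated tail probability of observing a count at least (resp. at most)
#' as extreme equals `(1 - level)/2` (stochastic test inversion, located by
#' bisection). Converges to the exact Garwood interval as `n_sim` grows.
#' Returned on the rate scale (per `per` person-years).
#'
#' @param cases observed case count.
#' @param persontime person-years of observation.
#' @param level confidence level.
#' @param n_sim Monte-Carlo replicates per tail evaluation.
#' @param per rate denominator (default `1e4`).
#' @param seed optional seed.
#' @return named vector `lower`, `upper`, `rate`.
#' @export
crude_rate_ci <- function(cases, persontime, level = 0.95, n_sim = 20000L,
                          per = 1e4, seed = NULL) {
  stopifnot(cases >= 0, persontime > 0)
  if (!is.null(seed)) set.seed(seed)
  a <- (1 - level) / 2
  upper_f <- function(lam) mean(stats::rpois(n_sim, lam) <= cases) - a
  lower_f <- function(lam) mean(stats::rpois(n_sim, lam) >= cases) - a
  hi <- stats::uniroot(upper_f, c(cases + 1e-9, 5 * cases + 20),
                       tol = 1e-3)$root
  lo <- if (cases == 0) 0 else
    stats::uniroot(lower_f, c(1e-9, cases + 1e-9), tol = 1e-3)$root
  c(lower = lo * per / persontime, upper = hi * per / persontime,
    rate = cases * per / persontime)
}
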