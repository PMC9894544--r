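# Time-inhomogeneous linear birth-death clone-size law.
#
# A clone founded by a single initiated cell at age s and observed at age t
# under division rate alpha(u) and inactivation rate beta(u) has a
# generating function of linear-fractional form at all times, so its size
# distribution is always geometric with an extinction atom:
#   P(Y = 0) = p0,   P(Y = y) = (1 - p0)(1 - q) q^(y-1),  y >= 1,
# with
#   R(s,t) = int_s^t gamma(u) du,          gamma = alpha - beta
#   J(s,t) = int_s^t alpha(u) e^{-R(s,u)} du
#   p0 = 1 - 1 / (e^{-R} + J),   q = 1 - (1 - p0) e^{-R}.
# The unconditional mean is E[Y] = e^R.
#
# Because alpha and gamma share the age-trend factor exp(ba*acen), the ratio
# alpha(u)/gamma(u) = alpha0/gamma0 is constant and J has the closed form
# J = (alpha0/gamma0) (1 - e^{-R}); no quadrature is needed on the pipeline
# path. The generic constructor below accepts arbitrary rate functions (grid
# quadrature) for oracle work and the frozen-rate extinction mode.

# Net-growth integral R(s,t) for the shared-trend family; s, t vectors
# (broadcast).
growth_integral <- function(p, s, t) {
  ba <- p$trend$ba
  if (abs(ba) < 1e-12) {
    p$gamma0 * (t - s)
  } else {
    10 * p$gamma0 / ba * (exp(ba * (t - 65) / 10) - exp(ba * (s - 65) / 10))
  }
}

# Vectorized (p0, q, R) for clones initiated at s, observed at t.
bd_kernel <- function(p, s, t) {
  R <- growth_integral(p, s, t)
  emR <- exp(-R)
  J <- (p$alpha0 / p$gamma0) * (1 - emR)
  surv <- 1 / (emR + J)           # 1 - p0
  q <- 1 - surv * emR
  list(R = R, p0 = 1 - surv, q = q)
}

#' Clone-size distribution of a single initiated cell
#'
#' Constructs the distribution of the number of cells at age `t` in a clone
#' founded by one initiated cell at age `s`, under a linear birth-death
#' process with age-varying rates. Supply either MSCE growth parameters
#' (closed-form path) or arbitrary rate functions `alpha` and `beta`
#' (evaluated by cumulative Simpson quadrature on `n_grid` points). With
#' `frozen = TRUE` the rates are frozen at their age-`s` values.
#'
#' @param s initiation age (yr).
#' @param t observation age (yr), `t >= s`.
#' @param params a [growth_params()] object (closed-form path), or `NULL`.
#' @param alpha,beta vectorized rate functions of age (used when `params` is
#'   `NULL`); must be positive and bounded on `[s, t]`.
#' @param frozen freeze rates at their age-`s` values.
#' @param n_grid quadrature grid size for the function-based path.
#' @return object of class `clone_size_law` with elements `s`, `t`, `p0`
#'   (extinction mass), `q` (geometric parameter) and `mean` (`= exp(R)`,
#'   the unconditional mean including extinct clones).
#' @examples
#' p <- growth_params(K = 0, X_PI0 = 1, alpha0 = 10, gamma0 = 0.5)
#' law <- clone_size_law(60, 70, params = p)
#' clone_size_pmf(law, 0:5)
#' @export
clone_size_law <- function(s, t, params = NULL, alpha = NULL, beta = NULL,
                           frozen = FALSE, n_grid = 2001L) {
  if (any(t < s)) stop("observation age t must satisfy t >= s")
  if (!is.null(params)) {
    stopifnot(inherits(params, "growth_params"))
    if (frozen) {
      r <- params_at_age(params, s)
      law <- bd_law_const(r$alpha, r$beta, t - s)
    } else {
      law <- bd_kernel(params, s, t)
    }
  } else {
    stopifnot(is.function(alpha), is.function(beta),
              length(s) == 1L, length(t) == 1L)
    if (frozen) {
      law <- bd_law_const(alpha(s), beta(s), t - s)
    } else if (t == s) {
      law <- list(R = 0, p0 = 0, q = 0)
    } else {
      u <- seq(s, t, length.out = n_grid)
      a <- alpha(u); b <- beta(u)
      if (any(!is.finite(a)) || any(!is.finite(b)) || any(a < 0) || any(b < 0))
        stop("rate functions must be finite and nonnegative on [s, t]")
      g <- a - b
      Ru <- cum_simpson(u, g)
      J <- cum_simpson(u, a * exp(-Ru))
      R <- Ru[n_grid]
      emR <- exp(-R)
      surv <- 1 / (emR + J[n_grid])
      law <- list(R = R, p0 = 1 - surv, q = 1 - surv * emR)
    }
  }
  structure(list(s = s, t = t, p0 = law$p0, q = law$q,
                 mean = exp(law$R)), class = "clone_size_law")
}

# Constant-rate closed form (tau = elapsed time); handles gamma -> 0.
bd_law_const <- function(alpha, beta, tau) {
  gamma <- alpha - beta
  crit <- abs(gamma * tau) < 1e-10
  R <- gamma * tau
  egt <- exp(R)
  D <- alpha * egt - beta
  p0 <- ifelse(crit & tau > 0, alpha * tau / (1 + alpha * tau) * (beta / pmax(alpha, .Machine$double.xmin)),
               beta * (egt - 1) / D)
  q <- ifelse(crit & tau > 0, alpha * tau / (1 + alpha * tau),
              alpha * (egt - 1) / D)
  p0[tau == 0] <- 0
  q[tau == 0] <- 0
  list(R = R, p0 = p0, q = q)
}

#' Probability mass function of the clone-size law
#'
#' @param law a [clone_size_law()] object.
#' @param y nonnegative integer cell counts.
#' @return `P(Y = y)`; `y = 0` returns the extinction mass.
#' @export
clone_size_pmf <- function(law, y) {
  stopifnot(inherits(law, "clone_size_law"))
  if (any(y < 0) || any(y != floor(y))) stop("y must be a nonnegative integer")
  ifelse(y == 0, law$p0,
         (1 - law$p0) * (1 - law$q) * law$q^(y - 1))
}

#' Survival function of the clone-size law
#'
#' `P(Y >= y)`; fractional `y` is rounded up (a clone of integer size
#' reaches a fractional bound iff it reaches the next integer).
#'
#' @inheritParams clone_size_pmf
#' @export
clone_survival <- function(law, y) {
  stopifnot(inherits(law, "clone_size_law"))
  y <- ceiling(y)
  ifelse(y <= 0, 1, (1 - law$p0) * law$q^(y - 1))
}

#' Extinction probability of an existing clone
#'
#' Probability that a clone of `y` initiated cells present at age `t0` is
#' extinct after a waiting time `dt`. Cell lineages die out independently, so
#' `P_ext(y, dt) = p0(t0, t0 + dt)^y` with `p0` the single-cell extinction
#' probability under the age-varying rates along `[t0, t0 + dt]`
#' (or, with `frozen = TRUE`, under the rates frozen at `t0`).
#'
#' @param p a [growth_params()] object.
#' @param y clone size in cells at `t0` (positive integer(s)).
#' @param t0 age at observation (yr).
#' @param dt waiting time(s) (yr), nonnegative.
#' @param frozen freeze rates at their age-`t0` values.
#' @return extinction probability in `[0, 1]`.
#' @export
extinction_probability <- function(p, y, t0, dt, frozen = FALSE) {
  stopifnot(inherits(p, "growth_params"))
  if (any(y < 1)) stop("y must be >= 1 (no clone)")
  if (any(dt < 0)) stop("dt must be nonnegative")
  law <- clone_size_law(t0, t0 + dt, params = p, frozen = frozen)
  law$p0^y
}
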