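# Initiation intensity and the age integrals built on it.
#
# New clones of initiated cells arise in a patient as an inhomogeneous
# Poisson process. Its intensity at age s depends on the number K of
# pre-initiating mutation stages; pre-initiation stages accumulate
# deterministically (mean-field, valid for mu_K/alpha << 1):
#   K = 0: nu(s) = X_P(s)
#   K = 1: nu(s) = mu * int_0^s X_P(u) du
#   K = 2: nu(s) = mu * int_0^s int_0^u X_PI(v) dv du,  X_PI = X_P * mu_1
# with mu = rho0 * alpha0 (age-constant because rho and alpha carry opposite
# trends). Integrals start at birth (age 0); a configurable start age is
# exposed on the cohort side.

.INTENSITY_GRID_H <- 0.05
.INTENSITY_AMAX <- 100

# Returns a vectorized function s -> intensity(s) on [0, amax].
intensity_fun <- function(p, amax = .INTENSITY_AMAX) {
  tr <- p$trend
  mu <- if (p$K >= 1) p$rho0 * p$alpha0 else NA_real_
  if (p$K == 0L) {
    function(s) params_at_age(p, s)$X_P
  } else if (tr$bx1 == 0 && tr$bx2 == 0) {
    # constant Poisson strength: polynomial accumulation, exact
    if (p$K == 1L) function(s) mu * p$X_PI0 * s
    else function(s) mu * p$X_PI0 * s^2 / 2
  } else {
    u <- seq(0, amax, by = .INTENSITY_GRID_H)
    G1 <- cum_simpson(u, params_at_age(p, u)$X_P)
    G <- if (p$K == 1L) G1 else cum_simpson(u, G1)
    sf <- stats::splinefun(u, G, method = "hyman")
    function(s) mu * sf(s)
  }
}

#' Initiation intensity: rate of new initiated clones
#'
#' Rate (per year) at which new clones of initiated cells arise at age `s`,
#' for the `K = 0, 1, 2` model versions. Pre-initiating stages accumulate
#' deterministically from birth.
#'
#' @param p a [growth_params()] object.
#' @param s age(s) in years, nonnegative.
#' @export
initiation_intensity <- function(p, s) {
  stopifnot(inherits(p, "growth_params"))
  if (any(s < 0)) stop("age must be nonnegative")
  intensity_fun(p)(s)
}

# Core quadrature: for each observation age t (vector) integrate
# intensity(s) * weight(s, t) over s in [0, t] with a fixed Gauss-Legendre
# rule. `bounds` is a vector of cell-number bounds; returns
#   I[k, b] = int_0^t_k intensity(s) (1 - p0) q^(b - 1) ds   (P(Y >= bound))
# plus optional mean-burden and size-numerator integrals.
model_integrals <- function(p, g = NULL, ages, bounds = NULL,
                            want_EC = FALSE, want_EYnum = FALSE,
                            n_nodes = 128L) {
  inten <- intensity_fun(p)
  gl <- gl_rescale(rep(0, length(ages)), ages, n = n_nodes)
  s <- gl$x                                   # ages x nodes
  tmat <- matrix(ages, nrow = length(ages), ncol = n_nodes)
  ker <- bd_kernel(p, s, tmat)
  iw <- gl$w * inten(as.vector(s))            # weight * intensity
  dim(iw) <- dim(s)
  surv1 <- iw * (1 - ker$p0)                  # contribution of surviving clones
  out <- list()
  if (!is.null(bounds)) {
    I <- matrix(NA_real_, length(ages), length(bounds))
    for (b in seq_along(bounds)) {
      yb <- ceiling(bounds[b])
      I[, b] <- if (is.infinite(yb)) 0 else rowSums(surv1 * ker$q^(yb - 1))
    }
    colnames(I) <- as.character(bounds)
    out$I <- I
  }
  if (want_EC) out$EC <- rowSums(iw * exp(ker$R))
  if (want_EYnum) {
    # int intensity(s) E[Y 1{Y >= y0}] ds, per-clone truncated first moment
    y0 <- ceiling(g$y0)
    q <- ker$q
    out$EYnum <- rowSums(surv1 * q^(y0 - 1) * (y0 * (1 - q) + q) / (1 - q))
  }
  out
}

#' Expected number of detectable adenoma (model APC)
#'
#' The Poisson mean `Lambda(t)` of adenoma above the detection limit at
#' screening age `t`:
#' `Lambda(t) = int_0^t intensity(s) P(Y(t) >= y0 | init at s) ds`.
#' Under the model, adenoma counts are Poisson with mean `Lambda`, so
#' `Lambda` is the expected adenoma-per-colonoscopy (APC) and the adenoma
#' detection rate is `ADR = 1 - exp(-Lambda)`.
#'
#' @param p a [growth_params()] object.
#' @param g a [geometry()] object (supplies the detection limit `y0`).
#' @param t screening age(s) in years.
#' @param check if `TRUE`, re-evaluate with a finer quadrature rule and warn
#'   when the two disagree beyond `1e-6` relative.
#' @return `Lambda(t)`, same length as `t`.
#' @export
expected_detectable_number <- function(p, g, t, check = FALSE) {
  stopifnot(inherits(p, "growth_params"), inherits(g, "adenoma_geometry"))
  if (any(t < 0)) stop("age must be nonnegative")
  L <- unname(model_integrals(p, g, ages = t, bounds = g$y0)$I[, 1])
  if (check) {
    L2 <- model_integrals(p, g, ages = t, bounds = g$y0, n_nodes = 192L)$I[, 1]
    bad <- abs(L2 - L) > 1e-6 * pmax(abs(L2), 1e-12)
    if (any(bad))
      warning("quadrature not converged at ages ",
              paste(t[bad], collapse = ", "),
              "; max relative discrepancy ",
              signif(max(abs(L2 - L) / pmax(abs(L2), 1e-12)), 3))
  }
  L
}

#' Size distribution of detectable adenoma
#'
#' CDF of the cell number of a detectable adenoma at age `t`:
#' `F(y) = P(y0 <= Y <= y | Y >= y0)`, mixing over clone initiation ages with
#' the initiation intensity. `F` is nondecreasing and tends to 1 as
#' `y -> Inf`.
#'
#' @param p a [growth_params()] object.
#' @param g a [geometry()] object.
#' @param t screening age (yr), scalar.
#' @param y cell number(s) `>= y0` (fractional allowed; `Inf` gives 1).
#' @export
detectable_size_cdf <- function(p, g, t, y) {
  stopifnot(inherits(p, "growth_params"), inherits(g, "adenoma_geometry"),
            length(t) == 1L, t >= 0)
  if (any(y < g$y0)) stop("y below the detection limit y0")
  # P(Y <= y) counts integer sizes up to floor(y)
  I <- model_integrals(p, g, ages = t, bounds = c(g$y0, floor(y) + 1))$I
  Lam <- I[1, 1]
  if (Lam <= 0) stop("no detectable adenoma expected at this age")
  unname(pmin(pmax((Lam - I[1, -1, drop = TRUE]) / Lam, 0), 1))
}

#' Expected size of detectable adenoma, in cells
#'
#' Mean cell number of adenoma above a detection bound `y0` at age `t`
#' (the quantity entering the interval-cancer hazard ratio). With
#' `y0 = 1` this is the mean size of all surviving clones.
#'
#' @inheritParams detectable_size_cdf
#' @param y0 detection bound in cells; defaults to the geometry's limit.
#' @export
expected_detectable_size <- function(p, g, t, y0 = NULL) {
  stopifnot(length(t) == 1L)
  gg <- g
  if (!is.null(y0)) gg$y0 <- y0
  res <- model_integrals(p, gg, ages = t, bounds = gg$y0, want_EYnum = TRUE)
  res$EYnum[1] / res$I[1, 1]
}

#' Mean number of initiated cells per person
#'
#' `E[C(t)] = int_0^t intensity(s) exp(int_s^t gamma(u) du) ds` -- the
#' unconditional mean total burden of initiated cells, counting clones below
#' the detection limit and averaging over extinct clones. This is the
#' quantity the transformation rate multiplies in the cancer hazard.
#'
#' @param p a [growth_params()] object.
#' @param t age(s) in years.
#' @export
mean_initiated_cells <- function(p, t) {
  stopifnot(inherits(p, "growth_params"))
  if (any(t < 0)) stop("age must be nonnegative")
  model_integrals(p, NULL, ages = t, want_EC = TRUE)$EC
}
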