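#' Age trends of the growth-model parameters
#'
#' Rates are modulated by attained age `a` through the centered, decade-scaled
#' age `acen = (a - 65) / 10`:
#' \itemize{
#'   \item Poisson strength `X_P(a) = X_PI0 * exp(bx1*acen + bx2*acen^2)`,
#'   \item division `alpha(a) = alpha0 * exp(ba*acen)`,
#'   \item net growth `gamma(a) = gamma0 * exp(ba*acen)`,
#'   \item initiation ratio `rho(a) = rho0 * exp(-ba*acen)`.
#' }
#' The shared coefficient `ba` enters the initiation ratio with opposite sign
#' so the initiating mutation rate `mu_K(a) = rho(a)*alpha(a) = rho0*alpha0`
#' stays age-constant by construction. Zero coefficients reduce every rate to
#' its base value.
#'
#' @param bx1,bx2 per-decade linear and quadratic coefficients of the Poisson
#'   strength.
#' @param ba per-decade coefficient shared by division and net growth.
#' @export
age_trend <- function(bx1 = 0, bx2 = 0, ba = 0) {
  stopifnot(is.finite(bx1), is.finite(bx2), is.finite(ba))
  structure(list(bx1 = bx1, bx2 = bx2, ba = ba), class = "age_trend")
}

#' Identifiable MSCE growth parameters for one sex-by-shape stratum
#'
#' Parametrizes one of the three adenoma growth model versions: `K` counts the
#' pre-initiating mutation stages before clonal expansion starts. For `K = 0`
#' the Poisson strength `X_PI0` (units 1/yr) directly drives initiation; for
#' `K = 1` it feeds a deterministically accumulating intermediate stage; for
#' `K = 2` `X_PI0` is the composite `X_P * mu_1` (units 1/yr^2). Clonal
#' expansion is a linear birth-death process with symmetric division rate
#' `alpha0`, net growth `gamma0 = alpha0 - beta0` and implied inactivation
#' rate `beta0 = alpha0 - gamma0 > 0`. The initiation ratio
#' `rho0 = mu_K / alpha` (dimensionless, `K >= 1` only) sets the last
#' pre-clonal mutation rate relative to the division rate.
#'
#' `alpha0` outside the biologically plausible 5-50 /yr window and `rho0`
#' outside the small-ratio approximation regime trigger warnings, not errors.
#'
#' @param K number of pre-initiating stages, 0, 1 or 2.
#' @param X_PI0 base Poisson strength / pre-initiation composite.
#' @param alpha0 base symmetric division rate (1/yr).
#' @param gamma0 base net clonal growth rate (1/yr), `0 < gamma0 < alpha0`.
#' @param rho0 base initiation ratio (`K >= 1`).
#' @param trend an [age_trend()] object.
#' @param sex,shape optional stratum labels carried along for bookkeeping.
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(K, X_PI0, alpha0, gamma0, rho0 = NULL,
                          trend = age_trend(), sex = NA_character_,
                          shape = NA_character_) {
  stopifnot(K %in% 0:2, is.finite(X_PI0), X_PI0 >= 0,
            is.finite(alpha0), alpha0 > 0,
            is.finite(gamma0), inherits(trend, "age_trend"))
  if (gamma0 <= 0 || gamma0 >= alpha0)
    stop("need 0 < gamma0 < alpha0 (implied inactivation rate beta must be positive)")
  if (K >= 1) {
    if (is.null(rho0) || !is.finite(rho0) || rho0 <= 0)
      stop("rho0 > 0 required for K >= 1")
    if (rho0 > 0.1)
      warning("rho0 = ", rho0, " is outside the small-ratio approximation regime (rho << 1)")
  } else {
    rho0 <- NA_real_
  }
  if (alpha0 < 5 || alpha0 > 50)
    warning("alpha0 = ", alpha0, " /yr is outside the biologically plausible 5-50 /yr range")
  structure(list(K = as.integer(K), X_PI0 = X_PI0, alpha0 = alpha0,
                 gamma0 = gamma0, rho0 = rho0, trend = trend,
                 sex = sex, shape = shape),
            class = "growth_params")
}

#' Instantaneous model rates at an attained age
#'
#' Evaluates the age-modulated rates (see [age_trend()]): Poisson strength
#' `X_P(a)`, division `alpha(a)`, net growth `gamma(a)`, initiation ratio
#' `rho(a)` and the implied inactivation rate `beta(a) = alpha(a) - gamma(a)`.
#'
#' @param p a [growth_params()] object.
#' @param a attained age(s) in years, nonnegative.
#' @return list of numeric vectors `X_P`, `alpha`, `gamma`, `rho`, `beta`.
#' @export
params_at_age <- function(p, a) {
  stopifnot(inherits(p, "growth_params"))
  if (any(a < 0)) stop("negative age rejected")
  z <- (a - 65) / 10
  tr <- p$trend
  alpha <- p$alpha0 * exp(tr$ba * z)
  gamma <- p$gamma0 * exp(tr$ba * z)
  beta <- alpha - gamma
  if (any(beta <= 0)) stop("beta(a) <= 0: division rate must exceed net growth")
  list(
    X_P = p$X_PI0 * exp(tr$bx1 * z + tr$bx2 * z^2),
    alpha = alpha,
    gamma = gamma,
    rho = if (p$K >= 1) p$rho0 * exp(-tr$ba * z) else rep(NA_real_, length(a)),
    beta = beta
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "MSCE growth parameters (K = %d%s%s)\n  X_PI0 = %g %s, alpha0 = %g /yr, gamma0 = %g /yr%s\n  trends: bx1 = %g, bx2 = %g, ba = %g (per decade, centered at 65 yr)\n",
    x$K,
    if (!is.na(x$sex)) paste0(", sex = ", x$sex) else "",
    if (!is.na(x$shape)) paste0(", shape = ", x$shape) else "",
    x$X_PI0, if (x$K == 2) "/yr^2" else "/yr",
    x$alpha0, x$gamma0,
    if (x$K >= 1) sprintf(", rho0 = %g", x$rho0) else "",
    x$trend$bx1, x$trend$bx2, x$trend$ba))
  invisible(x)
}

# Replace selected base parameters / trend coefficients, revalidating.
modify_params <- function(p, ...) {
  upd <- list(...)
  tr <- p$trend
  for (nm in intersect(names(upd), c("bx1", "bx2", "ba")))
    tr[[nm]] <- upd[[nm]]
  growth_params(
    K = if (!is.null(upd$K)) upd$K else p$K,
    X_PI0 = if (!is.null(upd$X_PI0)) upd$X_PI0 else p$X_PI0,
    alpha0 = if (!is.null(upd$alpha0)) upd$alpha0 else p$alpha0,
    gamma0 = if (!is.null(upd$gamma0)) upd$gamma0 else p$gamma0,
    rho0 = if (!is.null(upd$rho0)) upd$rho0 else
      (if (is.na(p$rho0)) NULL else p$rho0),
    trend = age_trend(tr$bx1, tr$bx2, tr$ba),
    sex = p$sex, shape = p$shape)
}
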