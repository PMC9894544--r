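# Maximum-likelihood fitting and the three-level selection protocol.
#
# Level I estimates the age-constant parameters with detection limits fixed
# in cm (0.25 sessile/flat/all, 0.45 peduncular). Level II fixes the division
# rate (and initiation ratio) at the level-I estimates to stabilize the fit
# and frees the three age-trend coefficients. Level III re-runs the level-II
# configuration over a small grid of detection limits in cells and keeps the
# best AIC. Positivity-constrained parameters are optimized in log space;
# the net growth rate is optimized on a logistic scale so that
# 0 < gamma0 < alpha0 holds by construction.

#' Specification of one model fit
#'
#' @param K number of pre-initiating stages (0, 1, 2).
#' @param d growth dimension (2 or 3).
#' @param shape,sex stratum labels; `shape` selects default geometry.
#' @param level protocol level 1, 2 or 3.
#' @param free character vector of free parameters; defaults per level:
#'   level 1 `c("X_PI0", "alpha0", "gamma0")`, levels 2-3
#'   `c("X_PI0", "gamma0", "bx1", "bx2", "ba")`. For `K >= 1` the initiation
#'   ratio `rho0` is kept fixed by default: with deterministic pre-initiation
#'   the likelihood depends on it only through the product `rho0 * alpha0 *
#'   X_PI0`, so freeing it alongside `X_PI0` is non-identifiable. Add
#'   `"rho0"` explicitly to override.
#' @param fixed named list of parameter values to hold fixed (overrides
#'   starting defaults).
#' @param detect_cm level-I/II detection limit in cm; default 0.25
#'   (0.45 for peduncular adenoma).
#' @param y0_cells detection limit in cells (overrides `detect_cm`; the
#'   level-III setting).
#' @param y_r reference cell number; defaults from [default_geometry()].
#' @param level3_grid candidate detection limits (cells) for level III.
#' @export
fit_spec <- function(K, d = 2, shape = "all", sex = NA_character_, level = 1,
                     free = NULL, fixed = list(), detect_cm = NULL,
                     y0_cells = NULL, y_r = NULL,
                     level3_grid = c(20, 30, 40, 50)) {
  stopifnot(K %in% 0:2, d %in% c(2, 3), level %in% 1:3)
  gd <- default_geometry(shape, d)
  if (is.null(y_r)) y_r <- gd$y_r
  if (is.null(detect_cm)) detect_cm <- if (shape == "peduncular") 0.45 else 0.25
  if (is.null(free)) {
    free <- if (level == 1) c("X_PI0", "alpha0", "gamma0")
            else c("X_PI0", "gamma0", "bx1", "bx2", "ba")
  }
  structure(list(K = K, d = d, shape = shape, sex = sex, level = level,
                 free = free, fixed = fixed, detect_cm = detect_cm,
                 y0_cells = y0_cells, y_r = y_r, level3_grid = level3_grid),
            class = "fit_spec")
}

spec_geometry <- function(spec) {
  g <- geometry(spec$d, spec$y_r, y0 = 1)
  g$y0 <- if (!is.null(spec$y0_cells)) spec$y0_cells
          else size_to_cells(g, spec$detect_cm)
  g
}

# All tunable quantities as a flat named vector (base rates + trends).
params_to_vec <- function(p) {
  c(X_PI0 = p$X_PI0, alpha0 = p$alpha0, gamma0 = p$gamma0,
    rho0 = if (is.na(p$rho0)) NA_real_ else p$rho0,
    bx1 = p$trend$bx1, bx2 = p$trend$bx2, ba = p$trend$ba)
}

vec_to_params <- function(v, K, sex = NA_character_, shape = NA_character_) {
  growth_params(K = K, X_PI0 = v[["X_PI0"]], alpha0 = v[["alpha0"]],
                gamma0 = v[["gamma0"]],
                rho0 = if (K >= 1) v[["rho0"]] else NULL,
                trend = age_trend(v[["bx1"]], v[["bx2"]], v[["ba"]]),
                sex = sex, shape = shape)
}

# transform free parameters to the unconstrained optimizer scale
to_opt_scale <- function(v, free) {
  th <- numeric(length(free)); names(th) <- free
  for (nm in free) {
    th[nm] <- switch(nm,
      X_PI0 = log(v[["X_PI0"]]),
      alpha0 = log(v[["alpha0"]]),
      gamma0 = stats::qlogis(v[["gamma0"]] / v[["alpha0"]]),
      rho0 = log(v[["rho0"]]),
      v[[nm]])
  }
  th
}

from_opt_scale <- function(th, v) {
  for (nm in names(th)) {
    v[[nm]] <- switch(nm,
      X_PI0 = exp(th[[nm]]),
      alpha0 = exp(th[[nm]]),
      gamma0 = NA_real_,   # filled after alpha0 is known
      rho0 = exp(th[[nm]]),
      th[[nm]])
  }
  if ("gamma0" %in% names(th))
    v[["gamma0"]] <- v[["alpha0"]] * stats::plogis(th[["gamma0"]])
  v
}

default_start_vec <- function(data, spec, g) {
  dt <- aggregate_records(data)
  n_hat <- c(`0` = 0, `1` = 1, `2-4` = 2, `5+` = 5)[dt$count_cat]
  apc_obs <- sum(dt$multiplicity * n_hat) / sum(dt$multiplicity)
  v <- c(X_PI0 = 1, alpha0 = 20, gamma0 = 0.05,
         rho0 = if (spec$K >= 1) 1e-3 else NA_real_,
         bx1 = 0, bx2 = 0, ba = 0)
  for (nm in names(spec$fixed)) v[[nm]] <- spec$fixed[[nm]]
  # method of moments on Lambda (linear in X_PI0) at the mean age
  if (!"X_PI0" %in% names(spec$fixed)) {
    tbar <- sum(dt$multiplicity * dt$age) / sum(dt$multiplicity)
    p1 <- suppressWarnings(vec_to_params(v, spec$K))
    L1 <- expected_detectable_number(p1, g, tbar)
    v[["X_PI0"]] <- max(apc_obs, 1e-4) / max(L1, 1e-300)
  }
  v
}

#' Fit a growth model to screening records by maximum likelihood
#'
#' Maximizes [dataset_loglik()] over the free parameters of `spec` with
#' Nelder-Mead followed by a BFGS polish, on transformed scales that enforce
#' positivity and `gamma0 < alpha0`. Deterministic given data and starting
#' values.
#'
#' @param data screening records of one sex/shape stratum.
#' @param spec a [fit_spec()].
#' @param start optional named vector of starting values (natural scale)
#'   overriding the defaults.
#' @param control list: `maxit` (Nelder-Mead iterations, default 800) and
#'   `polish` (logical, default TRUE).
#' @return object of class `msce_fit`: `params` (fitted [growth_params()]),
#'   `estimates`, `loglik`, `D_I`, `D_count`, `D_size`, `AIC`,
#'   `convergence` (0 = converged), `boundary` flag, `spec`, `geometry`.
#' @export
fit_growth_model <- function(data, spec, start = NULL, control = list()) {
  stopifnot(inherits(spec, "fit_spec"))
  maxit <- control$maxit %||% 800L
  polish <- control$polish %||% TRUE
  g <- spec_geometry(spec)
  dt <- aggregate_records(data)
  if (length(unique(dt$sex)) > 1L || length(unique(dt$shape)) > 1L)
    stop("records mix sex/shape strata")
  v0 <- default_start_vec(dt, spec, g)
  if (!is.null(start)) for (nm in names(start)) v0[[nm]] <- start[[nm]]
  free <- spec$free
  ages <- sort(unique(dt$age))
  k <- match(dt$age, ages)
  cell <- record_cell(dt$count_cat, dt$size_cat)
  mult <- dt$multiplicity

  nll <- function(th) {
    names(th) <- free
    v <- from_opt_scale(th, v0)
    p <- try(suppressWarnings(vec_to_params(v, spec$K, spec$sex, spec$shape)),
             silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    cp <- try(suppressWarnings(category_prob_matrix(p, g, ages)),
              silent = TRUE)
    if (inherits(cp, "try-error")) return(1e10)
    pr <- cp$P[cbind(k, match(cell, colnames(cp$P)))]
    if (any(!is.finite(pr)) || any(pr <= 0)) return(1e10)
    -sum(mult * log(pr))
  }

  th0 <- to_opt_scale(v0, free)
  opt <- stats::optim(th0, nll, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-12))
  if (polish) {
    opt2 <- try(stats::optim(opt$par, nll, method = "BFGS",
                             control = list(maxit = 200, reltol = 1e-12)),
                silent = TRUE)
    if (!inherits(opt2, "try-error") && opt2$value <= opt$value) opt <- opt2
  }
  conv <- opt$convergence
  if (conv != 0)
    warning("optimizer did not report convergence (code ", conv,
            "); best point returned")
  th <- opt$par; names(th) <- free
  v_hat <- from_opt_scale(th, v0)
  p_hat <- suppressWarnings(vec_to_params(v_hat, spec$K, spec$sex, spec$shape))
  boundary <- p_hat$gamma0 > 0.99 * p_hat$alpha0 ||
    p_hat$gamma0 < 1e-6 * p_hat$alpha0
  if (boundary) warning("estimate at/near a boundary (gamma0 vs alpha0)")
  dev <- deviance_and_aic(dt, p_hat, g, n_par = length(free))
  structure(list(params = p_hat, estimates = v_hat[free],
                 loglik = dev$loglik, D_I = dev$D_I, D_count = dev$D_count,
                 D_size = dev$D_size, AIC = dev$AIC,
                 n_par = length(free), convergence = conv,
                 boundary = boundary, spec = spec, geometry = g,
                 start = v0, opt = opt, data = dt),
            class = "msce_fit")
}

#' @export
print.msce_fit <- function(x, ...) {
  cat(sprintf("MSCE growth fit (K = %d, d = %d, shape = %s, level %s)\n",
              x$spec$K, x$spec$d, x$spec$shape, x$spec$level))
  cat(sprintf("  logLik = %.3f, D_I = %.3f (count %.3f + size %.3f), AIC = %.3f\n",
              x$loglik, x$D_I, x$D_count, x$D_size, x$AIC))
  est <- x$estimates
  cat("  estimates:", paste(sprintf("%s = %.4g", names(est), est),
                            collapse = ", "), "\n")
  if (x$convergence != 0) cat("  WARNING: convergence code", x$convergence, "\n")
  invisible(x)
}

#' Profile-likelihood confidence interval for one fitted parameter
#'
#' Profiles the deviance over `param`, refitting all other free parameters
#' at each value (warm-started from the optimum), and locates the bounds
#' where the profile deviance rises by the chi-square(1) quantile (3.84 at
#' 95%) via bisection. Also reports a likelihood-ratio p-value against the
#' null value 0 for trend coefficients (for positivity-constrained rates no
#' meaningful null exists within the model and the p-value is `NA`).
#'
#' @param data records used in `result`.
#' @param result an `msce_fit` object.
#' @param param name of one free parameter.
#' @param level confidence level (default 0.95).
#' @return list with `lower`, `upper` (may be `-Inf`/`Inf` when the profile
#'   stays flat: an open interval), `estimate`, `se` (width-based normal
#'   approximation), `p_value`.
#' @export
profile_ci <- function(data, result, param, level = 0.95) {
  stopifnot(inherits(result, "msce_fit"), param %in% result$spec$free)
  spec <- result$spec
  g <- result$geometry
  dt <- aggregate_records(data)
  ages <- sort(unique(dt$age))
  k <- match(dt$age, ages)
  cell <- record_cell(dt$count_cat, dt$size_cat)
  mult <- dt$multiplicity
  v_base <- result$start
  for (nm in spec$free) v_base[[nm]] <- result$estimates[[nm]]
  other <- setdiff(spec$free, param)
  crit <- stats::qchisq(level, df = 1)

  nll_at <- function(theta_p, th_other_start) {
    # theta_p on the optimizer scale of `param`
    nll_inner <- function(th) {
      names(th) <- other
      v <- from_opt_scale(c(stats::setNames(theta_p, param), th), v_base)
      p <- try(suppressWarnings(vec_to_params(v, spec$K)), silent = TRUE)
      if (inherits(p, "try-error")) return(1e10)
      cp <- try(suppressWarnings(category_prob_matrix(p, g, ages)),
                silent = TRUE)
      if (inherits(cp, "try-error")) return(1e10)
      pr <- cp$P[cbind(k, match(cell, colnames(cp$P)))]
      if (any(!is.finite(pr)) || any(pr <= 0)) return(1e10)
      -sum(mult * log(pr))
    }
    if (!length(other)) return(list(value = nll_inner(numeric(0)),
                                    par = numeric(0)))
    o <- stats::optim(th_other_start, nll_inner, method = "Nelder-Mead",
                      control = list(maxit = 250, reltol = 1e-9))
    list(value = o$value, par = o$par)
  }

  th_hat <- to_opt_scale(v_base, spec$free)
  nll_min <- -result$loglik
  th_p_hat <- th_hat[[param]]
  th_other_hat <- th_hat[other]

  side <- function(dir) {
    step <- 0.1
    th_prev <- th_p_hat
    warm <- th_other_hat
    for (i in 1:40) {
      th_try <- th_p_hat + dir * step
      r <- nll_at(th_try, warm)
      warm <- if (length(other)) r$par else warm
      d <- 2 * (r$value - nll_min)
      if (!is.finite(d)) return(dir * Inf)
      if (d >= crit) {
        f <- function(x) 2 * (nll_at(x, warm)$value - nll_min) - crit
        root <- stats::uniroot(f, sort(c(th_prev, th_try)), tol = 1e-4)
        return(root$root)
      }
      th_prev <- th_try
      step <- step * 1.7
    }
    dir * Inf   # profile never crossed: open interval
  }
  lo_th <- side(-1)
  hi_th <- side(+1)

  to_nat <- function(th_p) {
    v <- from_opt_scale(stats::setNames(th_p, param), v_base)
    v[[param]]
  }
  natural_bound <- function(th_p) {
    if (is.finite(th_p)) return(to_nat(th_p))
    # open interval endpoints on the natural scale
    if (param %in% c("X_PI0", "alpha0", "rho0"))
      return(if (th_p < 0) 0 else Inf)
    if (param == "gamma0")
      return(if (th_p < 0) 0 else v_base[["alpha0"]])
    th_p
  }
  lower <- natural_bound(lo_th)
  upper <- natural_bound(hi_th)
  est <- result$estimates[[param]]
  se <- if (is.finite(lower) && is.finite(upper))
    (upper - lower) / (2 * stats::qnorm(1 - (1 - level) / 2)) else NA_real_
  p_value <- NA_real_
  if (param %in% c("bx1", "bx2", "ba")) {
    r0 <- nll_at(0, th_other_hat)
    p_value <- stats::pchisq(2 * (r0$value - nll_min), df = 1,
                             lower.tail = FALSE)
  }
  list(lower = lower, upper = upper, estimate = est, se = se,
       p_value = p_value, level = level)
}

#' Run the three-level model-selection protocol
#'
#' For every combination of stage count `K` and growth dimension `d`:
#' level I (age-constant parameters, cm detection limits), level II (division
#' rate and initiation ratio fixed at level-I estimates, trend coefficients
#' freed), level III (level-II configuration refit over a grid of
#' detection-limit cell numbers, best AIC kept). Returns an AIC table with
#' one row per (K, d, level) and the underlying fits.
#'
#' @param data screening records of one sex/shape stratum.
#' @param K,d vectors of stage counts and growth dimensions to scan.
#' @param shape,sex stratum labels passed to [fit_spec()].
#' @param level3_grid candidate detection limits in cells.
#' @param control passed to [fit_growth_model()].
#' @return list with `table` (data.table: K, d, level, y0_cells, n_par,
#'   loglik, AIC, convergence) and `fits` (named list of `msce_fit`).
#' @export
run_protocol <- function(data, K = 0:2, d = c(2, 3), shape = "all",
                         sex = NA_character_,
                         level3_grid = c(20, 30, 40, 50), control = list()) {
  fits <- list()
  rows <- list()
  for (dd in d) for (kk in K) {
    key <- sprintf("K%d_d%d", kk, dd)
    s1 <- fit_spec(kk, dd, shape = shape, sex = sex, level = 1)
    f1 <- try(fit_growth_model(data, s1, control = control), silent = TRUE)
    if (inherits(f1, "try-error")) {
      rows[[paste0(key, "_L1")]] <- data.table::data.table(
        K = kk, d = dd, level = 1L, y0_cells = NA_real_, n_par = NA_integer_,
        loglik = NA_real_, AIC = NA_real_, convergence = NA_integer_,
        error = as.character(f1))
      next
    }
    fits[[paste0(key, "_L1")]] <- f1
    rows[[paste0(key, "_L1")]] <- data.table::data.table(
      K = kk, d = dd, level = 1L, y0_cells = f1$geometry$y0,
      n_par = f1$n_par, loglik = f1$loglik, AIC = f1$AIC,
      convergence = f1$convergence, error = NA_character_)
    # level II: fix alpha0 (and rho0) at level-I estimates
    fixed2 <- list(alpha0 = f1$params$alpha0)
    if (kk >= 1) fixed2$rho0 <- f1$params$rho0
    s2 <- fit_spec(kk, dd, shape = shape, sex = sex, level = 2,
                   fixed = fixed2)
    f2 <- fit_growth_model(data, s2,
                           start = c(X_PI0 = f1$params$X_PI0,
                                     gamma0 = f1$params$gamma0),
                           control = control)
    fits[[paste0(key, "_L2")]] <- f2
    rows[[paste0(key, "_L2")]] <- data.table::data.table(
      K = kk, d = dd, level = 2L, y0_cells = f2$geometry$y0,
      n_par = f2$n_par, loglik = f2$loglik, AIC = f2$AIC,
      convergence = f2$convergence, error = NA_character_)
    # level III: detection-limit grid, same free set as level II
    best <- NULL
    for (y0c in level3_grid) {
      s3 <- fit_spec(kk, dd, shape = shape, sex = sex, level = 3,
                     fixed = fixed2, y0_cells = y0c)
      f3 <- try(fit_growth_model(data, s3,
                                 start = c(X_PI0 = f2$params$X_PI0,
                                           gamma0 = f2$params$gamma0,
                                           bx1 = f2$params$trend$bx1,
                                           bx2 = f2$params$trend$bx2,
                                           ba = f2$params$trend$ba),
                                 control = control), silent = TRUE)
      if (inherits(f3, "try-error")) next
      if (is.null(best) || f3$AIC < best$AIC) best <- f3
    }
    if (!is.null(best)) {
      fits[[paste0(key, "_L3")]] <- best
      rows[[paste0(key, "_L3")]] <- data.table::data.table(
        K = kk, d = dd, level = 3L, y0_cells = best$geometry$y0,
        n_par = best$n_par, loglik = best$loglik, AIC = best$AIC,
        convergence = best$convergence, error = NA_character_)
    }
  }
  list(table = data.table::rbindlist(rows), fits = fits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
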