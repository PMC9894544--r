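# Synthetic screening cohorts and the exact stochastic oracle.
#
# The generator reproduces the statistical structure the likelihood assumes:
# clone initiations follow the model's inhomogeneous Poisson intensity,
# clone sizes at screening age follow the birth-death size law (fast path:
# analytic geometric sampling; oracle path: exact Gillespie simulation),
# only clones above the detection limit are reported, counts and the largest
# clone's size are categorized, and in multi-shape mixtures the largest
# adenoma's shape is assigned to the whole record (the reporting
# miss-classification present in the source registry).

#' Exact Gillespie simulation of clone growth
#'
#' Event-driven simulation of the time-inhomogeneous linear
#' birth-death(-transformation) process by thinning against a dominating
#' constant rate, for the exponential age-trend rate family of
#' [growth_params()]. Used throughout the test suite as the correctness
#' oracle for the analytic clone-size, extinction and transformation
#' results.
#'
#' @param p a [growth_params()] object (supplies `alpha`, `beta` and their
#'   age trend).
#' @param s initiation age(s): scalar, or one per replicate.
#' @param t observation age (scalar, `>= max(s)`).
#' @param n_rep number of replicate clones.
#' @param n_init initial cell number per clone.
#' @param cp optional [cancer_params()]: cells additionally acquire the
#'   transforming mutation at rate `nu(t)`; simulation stops at the first
#'   transformation when `stop_at_transform`.
#' @param stop_at_transform stop a replicate at its first transformation.
#' @param seed optional seed (`set.seed` is called when supplied).
#' @return list with integer vector `count` (final cell numbers, 0 =
#'   extinct) and logical vector `transformed`.
#' @export
gillespie_clone <- function(p, s, t, n_rep = 1L, n_init = 1L, cp = NULL,
                            stop_at_transform = TRUE, seed = NULL) {
  stopifnot(inherits(p, "growth_params"), length(t) == 1L, all(t >= s),
            n_init >= 1)
  if (!is.null(seed)) set.seed(seed)
  nu0 <- 0; bn <- 0
  if (!is.null(cp)) {
    stopifnot(inherits(cp, "cancer_params"))
    nu0 <- cp$nu0; bn <- cp$b_n
  }
  cpp_gillespie(as.integer(n_rep), p$alpha0, p$gamma0, p$trend$ba,
                as.numeric(s), t, as.integer(n_init), nu0, bn,
                stop_at_transform)
}

#' Default synthetic age distribution of screened patients
#'
#' Discrete triangular-decay distribution over ages 55-94 peaking at 65
#' (screening ages range 55-94 with mean about 65).
#'
#' @return data.frame with columns `age` and `prob`.
#' @export
default_age_distribution <- function() {
  age <- 55:94
  w <- ifelse(age <= 65, (age - 54) / 11, (95 - age) / 30)
  data.frame(age = age, prob = w / sum(w))
}

#' Specification of a synthetic screening cohort
#'
#' @param n_patients cohort size.
#' @param strata either a single-stratum list `list(params=, geometry=)`
#'   (applied to both sexes), or a named list `list(F=, M=)` whose elements
#'   are named lists of shape strata, each `list(params=, geometry=)`.
#' @param age_probs data.frame `age`/`prob`; default
#'   [default_age_distribution()].
#' @param sex_probs sampling weights for sexes, must sum to 1.
#' @param seed mandatory random seed.
#' @export
cohort_spec <- function(n_patients, strata, age_probs = NULL,
                        sex_probs = c(F = 0.5, M = 0.5), seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_patients >= 1)
  if (abs(sum(sex_probs) - 1) > 1e-8) stop("sex mixture weights must sum to 1")
  if (is.null(age_probs)) age_probs <- default_age_distribution()
  if (abs(sum(age_probs$prob) - 1) > 1e-8)
    stop("age distribution must sum to 1")
  if (!is.null(strata$params)) {   # single stratum shorthand
    sh <- strata$params$shape
    if (is.na(sh)) sh <- "all"
    one <- stats::setNames(list(strata), sh)
    sx <- strata$params$sex
    if (!is.na(sx)) {              # single-sex stratum
      strata <- stats::setNames(list(one), sx)
      sex_probs <- stats::setNames(1, sx)
    } else {
      strata <- list(F = one, M = one)
    }
  }
  structure(list(n_patients = as.integer(n_patients), strata = strata,
                 age_probs = age_probs, sex_probs = sex_probs,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Sample detectable clone sizes for patients of one stratum.
# ages: per-patient screening age. Returns list(patient, cells).
sample_stratum_clones <- function(params, geom, ages, oracle = FALSE) {
  amax <- max(ages)
  u <- seq(0, amax, by = 0.05)
  inten <- intensity_fun(params)
  Cum <- cum_simpson(u, inten(u))
  Itot <- stats::approx(u, Cum, xout = ages)$y
  M <- stats::rpois(length(ages), Itot)
  if (sum(M) == 0)
    return(list(patient = integer(0), cells = numeric(0)))
  pat <- rep(seq_along(ages), M)
  # initiation ages by inverse-CDF of the cumulative intensity
  uu <- stats::runif(sum(M)) * Itot[pat]
  s <- stats::approx(Cum, u, xout = uu, ties = "ordered")$y
  t_pat <- ages[pat]
  s <- pmin(s, t_pat)
  if (oracle) {
    cells <- numeric(length(s))
    for (a in unique(t_pat)) {
      i <- which(t_pat == a)
      cells[i] <- cpp_gillespie(length(i), params$alpha0, params$gamma0,
                                params$trend$ba, s[i], a, 1L, 0, 0,
                                TRUE)$count
    }
  } else {
    ker <- bd_kernel(params, s, t_pat)
    alive <- stats::runif(length(s)) > ker$p0
    cells <- ifelse(alive, 1 + stats::rgeom(length(s), prob = 1 - ker$q), 0)
  }
  keep <- cells >= geom$y0
  list(patient = pat[keep], cells = cells[keep])
}

bin_count <- function(n) {
  cut(n, breaks = c(-0.5, 0.5, 1.5, 4.5, Inf),
      labels = COUNT_CATEGORIES) |> as.character()
}

bin_size <- function(cm) {
  cut(cm, breaks = c(0, 0.5, 1, 2, Inf), right = FALSE,
      labels = SIZE_CATEGORIES) |> as.character()
}

#' Simulate a screening cohort
#'
#' Draws patient ages and sexes, generates clones per shape stratum from the
#' initiation intensity, samples clone sizes at the screening age, keeps
#' clones above the detection limit, and reports each patient's count
#' category and the size and shape of the largest adenoma (assigning its
#' shape to the whole record, as the source registry did). With
#' `oracle = TRUE` clone sizes come from the exact Gillespie simulator
#' instead of the analytic size law.
#'
#' @param spec a [cohort_spec()].
#' @param oracle use the Gillespie path for clone sizes.
#' @return a validated record `data.table` (one row per patient;
#'   `multiplicity = 1`), with negative records carrying shape `"all"` when
#'   several shape strata are mixed.
#' @export
simulate_cohort <- function(spec, oracle = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  ages <- spec$age_probs$age[sample.int(nrow(spec$age_probs), n,
                                        replace = TRUE,
                                        prob = spec$age_probs$prob)]
  sexes <- sample(names(spec$sex_probs), n, replace = TRUE,
                  prob = spec$sex_probs)
  count <- integer(n)
  best_cells <- numeric(n)
  best_cm <- rep(NA_real_, n)
  best_shape <- rep(NA_character_, n)
  for (sx in names(spec$strata)) {
    idx <- which(sexes == sx)
    if (!length(idx)) next
    for (sh in names(spec$strata[[sx]])) {
      st <- spec$strata[[sx]][[sh]]
      cl <- sample_stratum_clones(st$params, st$geometry, ages[idx],
                                  oracle = oracle)
      if (!length(cl$patient)) next
      gidx <- idx[cl$patient]
      cnt <- tabulate(cl$patient, nbins = length(idx))
      count[idx] <- count[idx] + cnt
      agg <- tapply(cl$cells, gidx, max)
      pat <- as.integer(names(agg))
      cm <- cells_to_size(st$geometry, as.numeric(agg))
      better <- cm > ifelse(is.na(best_cm[pat]), -Inf, best_cm[pat])
      upd <- pat[better]
      best_cm[upd] <- cm[better]
      best_cells[upd] <- as.numeric(agg)[better]
      best_shape[upd] <- sh
    }
  }
  single_shape <- length(unique(unlist(lapply(spec$strata, names)))) == 1L
  shape_col <- ifelse(count > 0, best_shape,
                      if (single_shape) names(spec$strata[[1]])[1] else "all")
  rec <- data.table::data.table(
    age = as.integer(ages), sex = sexes, shape = shape_col,
    count_cat = bin_count(count),
    size_cat = ifelse(count > 0, bin_size(best_cm), NA_character_),
    multiplicity = 1L)
  screening_records(rec)
}

#' Simulate crude cancer-count tables
#'
#' Poisson draws of case counts per age group with mean
#' `h(midpoint) * patients * years` (rare-event regime; a warning is issued
#' when `h * years` exceeds 0.1).
#'
#' @param p,cp growth and cancer parameters (lists allowed, see
#'   [cancer_hazard()]).
#' @param groups data.frame with `age_lo`, `age_hi`, `patients`.
#' @param years observation years per patient.
#' @param seed optional seed.
#' @param sex label stored in the output.
#' @return a [crude_rates()] table.
#' @export
simulate_cancer_counts <- function(p, cp, groups, years = 1, seed = NULL,
                                   sex = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  mid <- (groups$age_lo + groups$age_hi) / 2
  h <- cancer_hazard(p, cp, mid)
  if (any(h * years > 0.1))
    warning("h * years > 0.1: rare-event approximation strained")
  cases <- stats::rpois(nrow(groups), h * groups$patients * years)
  crude_rates(groups$age_lo, groups$age_hi, groups$patients, cases,
              sex = sex, years = years)
}

#' Build the default synthetic screening fixture
#'
#' Generates a scaled synthetic cohort emulating the format and marginal
#' structure of the source registry (sex-specific ADR levels with higher
#' detection in men; shape mixture about 70% sessile / 18% peduncular /
#' 12% flat among detected adenoma; ages 55-94) and a matching crude
#' cancer-rate table, and writes both as CSV. Fully determined by `seed`.
#'
#' @param seed random seed.
#' @param scale cohort fraction of the full 197,347-record registry size.
#' @param dir output directory (default `tempdir()`); set `NULL` to skip
#'   writing.
#' @return list with `records` (aggregated), `rates` (one table per sex) and
#'   the written `record_file`/`rate_file` paths (or `NULL`).
#' @export
bavarian_fixture <- function(seed, scale = 0.05, dir = tempdir()) {
  n <- max(100L, round(197347 * scale))
  strata <- lapply(c(F = "F", M = "M"), function(sx) {
    lapply(c(sessile = "sessile", peduncular = "peduncular", flat = "flat"),
           function(sh) list(
             params = default_growth_params(sx, sh, target = "recorded"),
             geometry = default_geometry(sh, 2)))
  })
  spec <- cohort_spec(n, strata, seed = seed)
  rec <- simulate_cohort(spec)
  agg <- aggregate_records(rec)
  data.table::setkey(agg, sex, shape, age, count_cat, size_cat)
  groups <- data.frame(age_lo = seq(55, 90, 5), age_hi = seq(60, 95, 5))
  rates <- data.table::rbindlist(lapply(c("F", "M"), function(sx) {
    pat <- vapply(seq_len(nrow(groups)), function(i)
      sum(rec$sex == sx & rec$age >= groups$age_lo[i] &
            rec$age < groups$age_hi[i]), numeric(1))
    g <- cbind(groups, patients = pat)
    p_all <- default_growth_params(sx, "all", target = "recorded")
    simulate_cancer_counts(p_all, default_cancer_params(sx, p_all), g,
                           seed = NULL, sex = sx)
  }))
  out <- list(records = agg, rates = rates,
              record_file = NULL, rate_file = NULL)
  if (!is.null(dir)) {
    out$record_file <- file.path(dir, sprintf("records_seed%d.csv", seed))
    out$rate_file <- file.path(dir, sprintf("crude_rates_seed%d.csv", seed))
    write_records(agg, out$record_file)
    write_crude_rates(rates, out$rate_file)
  }
  out
}
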