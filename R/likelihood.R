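# Interval-censored likelihood for categorical adenoma counts and sizes.
#
# A screening record reports, per patient: attained age (integer years), sex,
# shape, the adenoma count in categories {0, 1, 2-4, >=5} and, when at least
# one adenoma was found, the size category of the most advanced (largest)
# adenoma among {<0.5, 0.5-1, 1-2, >2 cm}. Counts are Poisson with mean
# Lambda(age) (the model APC); conditional on n detected adenoma, sizes are
# iid draws from the detectable-size distribution, and the record's size
# category constrains the largest: all n lie below the upper bound and at
# least one reaches the lower bound, giving F(y_h)^n - F(y_l)^n.

COUNT_CATEGORIES <- c("0", "1", "2-4", "5+")
SIZE_CATEGORIES <- c("lt0.5", "0.5-1", "1-2", "gt2")
SIZE_BOUNDS_CM <- c(0.5, 1, 2)

#' Size-category boundaries in cells for a geometry
#'
#' Converts the reporting boundaries 0.5, 1, 2 cm into cell numbers via the
#' size law; the lowest boundary is the detection limit `y0`. Fractional cell
#' boundaries are kept exact (category membership rounds up: lower bounds
#' inclusive, upper bounds exclusive).
#'
#' @param g a [geometry()] object.
#' @return numeric vector of length 5: `y0`, cells(0.5), cells(1), cells(2),
#'   `Inf`.
#' @export
category_scheme <- function(g) {
  b <- c(g$y0, size_to_cells(g, SIZE_BOUNDS_CM), Inf)
  if (any(diff(b) <= 0))
    stop("category boundaries not strictly increasing; detection limit y0 = ",
         g$y0, " cells conflicts with the 0.5 cm bound (",
         signif(size_to_cells(g, 0.5), 4), " cells)")
  names(b) <- c("y0", "0.5cm", "1cm", "2cm", "Inf")
  b
}

# Probability of every observable category at each age.
# Returns a list with Lambda (vector) and P, a matrix n_ages x 13 with
# columns "0" and "<count>:<size>"; rows sum to 1.
category_prob_matrix <- function(p, g, ages, n_max = Inf) {
  b <- category_scheme(g)
  I <- model_integrals(p, g, ages = ages, bounds = b)$I
  Lam <- I[, 1]
  Fb <- (Lam - I) / Lam            # P(Y < bound | detectable), ages x 5
  Fb[Lam <= 0, ] <- 0              # degenerate: no detectable adenoma
  cols <- c("0", as.vector(outer(COUNT_CATEGORIES[-1], SIZE_CATEGORIES,
                                 paste, sep = ":")))
  P <- matrix(0, length(ages), length(cols), dimnames = list(NULL, cols))
  P[, "0"] <- exp(-Lam)
  for (j in seq_len(4)) {
    Fl <- Fb[, j]; Fh <- Fb[, j + 1]
    sc <- SIZE_CATEGORIES[j]
    P[, paste0("1:", sc)] <- stats::dpois(1, Lam) * (Fh - Fl)
    acc <- 0
    for (n in 2:4) acc <- acc + stats::dpois(n, Lam) * (Fh^n - Fl^n)
    P[, paste0("2-4:", sc)] <- acc
    if (is.infinite(n_max)) {
      tail_mass <- function(F)
        exp(-Lam * (1 - F)) * stats::ppois(4, Lam * F, lower.tail = FALSE)
      P[, paste0("5+:", sc)] <- tail_mass(Fh) - tail_mass(Fl)
    } else {
      acc5 <- 0
      for (n in 5:n_max) acc5 <- acc5 + stats::dpois(n, Lam) * (Fh^n - Fl^n)
      P[, paste0("5+:", sc)] <- acc5
    }
  }
  list(Lambda = Lam, P = P)
}

# --- records ---------------------------------------------------------------

#' Validate a table of screening records
#'
#' Checks the closed category vocabularies and the count/size consistency
#' rule (a size category is present iff the count category is not `"0"`).
#' A `multiplicity` column (positive integers) is added when absent.
#'
#' @param df data.frame with columns `age`, `sex`, `shape`, `count_cat`,
#'   `size_cat` and optionally `multiplicity`.
#' @return a validated `data.table`.
#' @export
screening_records <- function(df) {
  req <- c("age", "sex", "shape", "count_cat", "size_cat")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  dt <- data.table::as.data.table(df)
  if (!"multiplicity" %in% names(dt)) dt[, "multiplicity" := 1L]
  bad_row <- function(cond, what) {
    if (any(cond)) stop("invalid record(s) at row(s) ",
                        paste(utils::head(which(cond), 5), collapse = ", "),
                        ": ", what)
  }
  bad_row(!is.finite(dt$age) | dt$age < 0 | dt$age != floor(dt$age),
          "age must be a nonnegative integer year")
  bad_row(!dt$sex %in% c("F", "M"), "sex must be 'F' or 'M'")
  bad_row(!dt$shape %in% c("sessile", "peduncular", "flat", "all"),
          "unknown shape")
  bad_row(!dt$count_cat %in% COUNT_CATEGORIES, "unknown count category")
  bad_row(!(is.na(dt$size_cat) | dt$size_cat %in% SIZE_CATEGORIES),
          "unknown size category")
  bad_row(dt$count_cat == "0" & !is.na(dt$size_cat),
          "count category 0 must not carry a size category")
  bad_row(dt$count_cat != "0" & is.na(dt$size_cat),
          "positive count category requires a size category")
  bad_row(!is.finite(dt$multiplicity) | dt$multiplicity < 1 |
            dt$multiplicity != floor(dt$multiplicity),
          "multiplicity must be a positive integer")
  dt
}

#' Aggregate identical records
#'
#' Collapses records sharing age, sex, shape and categories into one row with
#' summed multiplicity; the likelihood is invariant under this aggregation.
#'
#' @param df a record table (see [screening_records()]).
#' @export
aggregate_records <- function(df) {
  dt <- screening_records(df)
  dt[, list(multiplicity = sum(multiplicity)),
     by = c("age", "sex", "shape", "count_cat", "size_cat")]
}

record_cell <- function(count_cat, size_cat) {
  ifelse(count_cat == "0", "0", paste0(count_cat, ":", size_cat))
}

#' Log-probability of screening records
#'
#' Log-probability of each record's observed (count category, size category)
#' cell under the growth model, at the record's age.
#'
#' @param rec record table (single sex/shape stratum assumed).
#' @param p a [growth_params()] object.
#' @param g a [geometry()] object.
#' @param n_max if finite, sum the open count category explicitly up to
#'   `n_max` instead of using the closed Poisson tail.
#' @return numeric vector of per-record log-probabilities (not weighted by
#'   multiplicity).
#' @export
record_logprob <- function(rec, p, g, n_max = Inf) {
  dt <- screening_records(rec)
  ages <- sort(unique(dt$age))
  cp <- category_prob_matrix(p, g, ages, n_max = n_max)
  k <- match(dt$age, ages)
  cell <- record_cell(dt$count_cat, dt$size_cat)
  log(cp$P[cbind(k, match(cell, colnames(cp$P)))])
}

#' Total log-likelihood of a dataset
#'
#' Multiplicity-weighted sum of [record_logprob()]; identical on raw and
#' aggregated records. All records must share one sex/shape stratum.
#'
#' @inheritParams record_logprob
#' @export
dataset_loglik <- function(rec, p, g, n_max = Inf) {
  dt <- screening_records(rec)
  if (nrow(dt) == 0L) return(0)
  if (length(unique(dt$sex)) > 1L || length(unique(dt$shape)) > 1L)
    stop("records mix sex/shape strata; fit strata separately")
  sum(dt$multiplicity * record_logprob(dt, p, g, n_max = n_max))
}

#' Deviance, its count/size decomposition, and AIC
#'
#' The individual-likelihood deviance is `D_I = -2 * log L`. By the chain
#' rule it splits exactly into a count component (marginal Poisson
#' count-category probabilities) and a size component (size-category
#' probabilities conditional on the count category);
#' `AIC = D_I + 2 * n_par`.
#'
#' @inheritParams record_logprob
#' @param n_par number of free model parameters.
#' @return list with `D_I`, `D_count`, `D_size`, `AIC`, `loglik`.
#' @export
deviance_and_aic <- function(rec, p, g, n_par, n_max = Inf) {
  dt <- screening_records(rec)
  ages <- sort(unique(dt$age))
  cp <- category_prob_matrix(p, g, ages, n_max = n_max)
  k <- match(dt$age, ages)
  cell <- record_cell(dt$count_cat, dt$size_cat)
  p_cell <- cp$P[cbind(k, match(cell, colnames(cp$P)))]
  # marginal count-category probability at each record's age
  count_cols <- lapply(COUNT_CATEGORIES, function(cc) {
    if (cc == "0") "0" else paste0(cc, ":", SIZE_CATEGORIES)
  })
  names(count_cols) <- COUNT_CATEGORIES
  p_count <- vapply(seq_len(nrow(dt)), function(i) {
    sum(cp$P[k[i], count_cols[[dt$count_cat[i]]]])
  }, numeric(1))
  ll_count <- sum(dt$multiplicity * log(p_count))
  ll_size <- sum(dt$multiplicity * (log(p_cell) - log(p_count)))
  D_count <- -2 * ll_count
  D_size <- -2 * ll_size
  list(D_I = D_count + D_size, D_count = D_count, D_size = D_size,
       AIC = D_count + D_size + 2 * n_par, loglik = ll_count + ll_size)
}
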