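# Readers/writers and the command-line dispatch layer. No numerics live
# here: everything is validation, (de)serialization and plumbing.

#' Read and write screening-record CSV files
#'
#' Dialect: header `age,sex,shape,count_cat,size_cat,multiplicity`;
#' `count_cat` in `0,1,2-4,5+`; `size_cat` in `lt0.5,0.5-1,1-2,gt2` or `NA`
#' (empty) for negative records; UTF-8. Malformed rows are reported with
#' their line numbers.
#'
#' @param path CSV file path.
#' @return validated record `data.table`.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- names(data.table::fread(path, nrows = 0))
  chr <- intersect(c("sex", "shape", "count_cat", "size_cat"), hdr)
  dt <- data.table::fread(path, colClasses = stats::setNames(
    rep("character", length(chr)), chr), na.strings = c("NA", ""))
  tryCatch(screening_records(dt), error = function(e)
    stop("parse error in ", path, ": ", conditionMessage(e),
         " (row numbers refer to data rows, header excluded)", call. = FALSE))
}

#' @rdname read_records
#' @param records a validated record table.
#' @export
write_records <- function(records, path) {
  dt <- screening_records(records)
  data.table::fwrite(dt, path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read and write crude cancer-rate CSV files
#'
#' Dialect: header `age_lo,age_hi,sex,patients,cases,rate_per_10k`.
#'
#' @param path CSV file path.
#' @export
read_crude_rates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  req <- c("age_lo", "age_hi", "patients", "cases")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  crude_rates(dt$age_lo, dt$age_hi, dt$patients, dt$cases,
              sex = if ("sex" %in% names(dt)) dt$sex else NA_character_)
}

#' @rdname read_crude_rates
#' @param rates a [crude_rates()] table.
#' @export
write_crude_rates <- function(rates, path) {
  data.table::fwrite(rates, path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read and write growth-parameter configuration files
#'
#' Plain-text key:value blocks (Debian-control style, one stratum per
#' block separated by blank lines) with fields `sex`, `shape`, `K`, `d`,
#' `y_r`, `y0`, `X_PI0`, `alpha0`, `gamma0`, `rho0`, `bx1`, `bx2`, `ba` and
#' optionally `nu0`, `b_n`.
#'
#' @param path config file path.
#' @return list of strata, each `list(params=, geometry=, cancer=)`.
#' @export
read_growth_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- read.dcf(path)
  lapply(seq_len(nrow(m)), function(i) {
    row <- as.list(m[i, ])
    num <- function(nm, default = NULL) {
      if (!nm %in% names(row) || is.na(row[[nm]])) return(default)
      as.numeric(row[[nm]])
    }
    K <- as.integer(num("K", 2))
    p <- growth_params(
      K = K, X_PI0 = num("X_PI0"), alpha0 = num("alpha0"),
      gamma0 = num("gamma0"), rho0 = if (K >= 1) num("rho0", 1e-3),
      trend = age_trend(num("bx1", 0), num("bx2", 0), num("ba", 0)),
      sex = if ("sex" %in% names(row)) row$sex else NA_character_,
      shape = if ("shape" %in% names(row)) row$shape else NA_character_)
    g <- geometry(d = num("d", 2), y_r = num("y_r", 800), y0 = num("y0", 30))
    cc <- if (!is.null(num("nu0"))) cancer_params(num("nu0"), num("b_n", 0))
    list(params = p, geometry = g, cancer = cc)
  })
}

#' @rdname read_growth_config
#' @param strata list of strata as returned by [read_growth_config()], or a
#'   single `list(params=, geometry=, cancer=)`.
#' @export
write_growth_config <- function(strata, path) {
  if (!is.null(strata$params)) strata <- list(strata)
  rows <- lapply(strata, function(st) {
    p <- st$params; g <- st$geometry
    out <- c(sex = p$sex, shape = p$shape, K = p$K, d = g$d, y_r = g$y_r,
             y0 = g$y0, X_PI0 = p$X_PI0, alpha0 = p$alpha0,
             gamma0 = p$gamma0, rho0 = p$rho0,
             bx1 = p$trend$bx1, bx2 = p$trend$bx2, ba = p$trend$ba)
    if (!is.null(st$cancer))
      out <- c(out, nu0 = st$cancer$nu0, b_n = st$cancer$b_n)
    out
  })
  nm <- unique(unlist(lapply(rows, names)))
  m <- do.call(rbind, lapply(rows, function(r) r[nm]))
  colnames(m) <- nm
  write.dcf(m, path)
  invisible(path)
}

#' Run configuration for the command-line pipeline
#'
#' @param subcommand one of `simulate`, `fit`, `select`, `predict`.
#' @param seed integer seed, recorded in every artifact.
#' @param out_dir output directory.
#' @param records path to a record CSV (fit/select).
#' @param config path to a growth config (predict), or `NULL` for the
#'   built-in stand-in parameters.
#' @param sex,shape stratum selectors.
#' @param K,d,level model selectors (fit).
#' @param n cohort size (simulate).
#' @param verbose print progress.
#' @export
run_config <- function(subcommand = c("simulate", "fit", "select", "predict"),
                       seed = 1L, out_dir = ".", records = NULL,
                       config = NULL, sex = "F", shape = "all", K = 2L,
                       d = 2L, level = 1L, n = 10000L, verbose = FALSE) {
  subcommand <- match.arg(subcommand)
  if (!is.null(records) && !file.exists(records))
    stop("records file not found: ", records)
  if (!is.null(config) && !file.exists(config))
    stop("config file not found: ", config)
  structure(list(subcommand = subcommand, seed = as.integer(seed),
                 out_dir = out_dir, records = records, config = config,
                 sex = sex, shape = shape, K = as.integer(K),
                 d = as.integer(d), level = as.integer(level),
                 n = as.integer(n), verbose = isTRUE(verbose)),
            class = "run_config")
}

# No timestamp: artifacts must be byte-identical for identical config + seed.
provenance_header <- function(cfg) {
  key <- paste(unlist(cfg[c("subcommand", "sex", "shape", "K", "d", "level",
                            "n")]), collapse = "|")
  sprintf("# adenomsce %s | subcommand=%s seed=%d | config=%s",
          as.character(utils::packageVersion("adenomsce")),
          cfg$subcommand, cfg$seed, key)
}

write_artifact <- function(dt, cfg, name) {
  path <- file.path(cfg$out_dir, name)
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(provenance_header(cfg), con)
  close(con)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE, na = "NA")
  if (cfg$verbose) message("wrote ", path)
  path
}

#' Execute a configured pipeline run
#'
#' Dispatches to the simulate / fit / select / predict stages; every output
#' CSV carries a provenance comment line (package version, subcommand,
#' seed, timestamp).
#'
#' @param cfg a [run_config()].
#' @return (invisibly) named character vector of artifact paths.
#' @export
run <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  arts <- c()
  if (cfg$subcommand == "simulate") {
    fx <- bavarian_fixture(cfg$seed, scale = cfg$n / 197347, dir = NULL)
    arts["records"] <- write_artifact(fx$records, cfg, "records.csv")
    arts["rates"] <- write_artifact(fx$rates, cfg, "crude_rates.csv")
  } else if (cfg$subcommand %in% c("fit", "select")) {
    if (is.null(cfg$records)) stop("fit/select require --records")
    rec <- read_records(cfg$records)
    rec <- rec[rec$sex == cfg$sex &
                 rec$shape %in% c(cfg$shape, if (cfg$shape != "all") "all"), ]
    rec$shape <- cfg$shape
    if (cfg$subcommand == "fit") {
      spec <- fit_spec(cfg$K, cfg$d, shape = cfg$shape, sex = cfg$sex,
                       level = cfg$level)
      f <- fit_growth_model(rec, spec)
      est <- data.table::data.table(
        parameter = names(f$estimates), estimate = unname(f$estimates))
      arts["parameters"] <- write_artifact(est, cfg, "parameters.csv")
      gof <- data.table::data.table(
        K = cfg$K, d = cfg$d, level = cfg$level, n_par = f$n_par,
        loglik = f$loglik, D_I = f$D_I, AIC = f$AIC,
        convergence = f$convergence)
      arts["gof"] <- write_artifact(gof, cfg, "gof.csv")
    } else {
      pr <- run_protocol(rec, shape = cfg$shape, sex = cfg$sex)
      arts["aic_table"] <- write_artifact(pr$table, cfg, "aic_table.csv")
    }
  } else if (cfg$subcommand == "predict") {
    st <- if (!is.null(cfg$config)) {
      sts <- read_growth_config(cfg$config)
      sts[[1]]
    } else {
      p <- default_growth_params(cfg$sex, cfg$shape)
      list(params = p, geometry = default_geometry(cfg$shape, cfg$d),
           cancer = default_cancer_params(cfg$sex, p))
    }
    p <- st$params; g <- st$geometry
    cc <- st$cancer %||% default_cancer_params(cfg$sex, p)
    ages <- 55:90
    Lam <- expected_detectable_number(p, g, ages)
    arts["apc_adr"] <- write_artifact(data.table::data.table(
      age = ages, apc = Lam, adr = 1 - exp(-Lam),
      hazard = cancer_hazard(p, cc, ages)), cfg, "apc_adr_hazard.csv")
    dtg <- 0:10
    tab <- data.table::rbindlist(lapply(c(0.25, 0.5, 1), function(cm) {
      y <- max(1, round(size_to_cells(g, cm)))
      data.table::data.table(size_cm = cm, dt = dtg,
        p_ext = extinction_probability(p, y, 60, dtg))
    }))
    arts["extinction"] <- write_artifact(tab, cfg, "extinction.csv")
    tab2 <- data.table::rbindlist(lapply(c(0.5, 1, 2), function(cm) {
      y <- max(1, round(size_to_cells(g, cm)))
      data.table::data.table(size_cm = cm, dt = dtg,
        p_trans = transition_probability(p, cc, y, 60, dtg))
    }))
    arts["transition"] <- write_artifact(tab2, cfg, "transition.csv")
    # ADR grid capped below the model-expected ADR (removal factor < 1)
    adr_max <- 1 - exp(-expected_detectable_number(p, g, 65))
    adr_grid <- seq(0.05, 0.95 * adr_max, length.out = 10)
    arts["hr"] <- write_artifact(
      cbind(r_Y = rep(c(1, 0.5), each = length(adr_grid)),
            data.table::rbindlist(list(
              hr_curve(p, g, r_Y = 1, adr_grid = adr_grid),
              hr_curve(p, g, r_Y = 0.5, adr_grid = adr_grid)))),
      cfg, "hr_vs_adr.csv")
  }
  invisible(arts)
}
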