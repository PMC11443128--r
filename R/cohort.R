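#' Specification of a synthetic surgical registry
#'
#' Defines the generative model behind the synthetic registry: per sex and
#' age band, a piecewise-constant all-cause mortality hazard `mu`, a
#' first-surgery hazard `lambda` (both per person-year, acting on the
#' event-free population) and a recurrence rate `rho` (subsequent surgeries
#' per person-year after the first), plus the fraction of female events
#' labelled `"obstetric"` per band, the per-sex cohort size, the calendar
#' years to emit and the master seed.
#'
#' @param hazards Data frame with columns `sex`, `band`, `lambda`, `mu`,
#'   `rho`, covering every (sex, band) of the schema once.
#' @param schema The [age_band_schema()].
#' @param obstetric_fraction Named numeric vector (by band label) of the
#'   probability that a female event is obstetric; missing bands are 0.
#'   Always 0 for males.
#' @param cohort_size Individuals simulated per sex and calendar year.
#' @param years Calendar years to emit.
#' @param seed Master integer seed; per-(year, sex) streams are split from
#'   it deterministically, so draws for one sex do not perturb the other's.
#' @return An object of class `cohort_spec`.
#' @seealso [default_cohort_spec()], [simulate_registry()],
#'   [analytic_lifetime_risk()]
#' @export
cohort_spec <- function(hazards, schema = default_age_bands(),
                        obstetric_fraction = NULL, cohort_size = 100000,
                        years = 2016:2020, seed = 1L) {
  need <- c("sex", "band", "lambda", "mu", "rho")
  if (!all(need %in% names(hazards))) {
    stop("hazards needs columns sex, band, lambda, mu, rho")
  }
  check_sex(hazards$sex)
  match_bands(hazards$band, schema, "hazards")
  if (any(hazards$lambda < 0) || any(hazards$mu < 0) || any(hazards$rho < 0)) {
    stop("hazard rates must be non-negative")
  }
  obf <- stats::setNames(rep(0, nrow(schema)), schema$label)
  if (!is.null(obstetric_fraction)) {
    match_bands(names(obstetric_fraction), schema, "obstetric_fraction")
    if (any(obstetric_fraction < 0 | obstetric_fraction > 1)) {
      stop("obstetric_fraction must lie in [0, 1]")
    }
    obf[names(obstetric_fraction)] <- obstetric_fraction
  }
  if (cohort_size <= 0) stop("cohort_size must be positive")
  out <- list(schema = schema, hazards = hazards,
              obstetric_fraction = obf,
              cohort_size = as.integer(cohort_size),
              years = as.integer(years), seed = as.integer(seed),
              year_scaling = list())
  class(out) <- "cohort_spec"
  out
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Cohort spec: %d bands, cohort %d per sex, years %s-%s, seed %d\n",
    nrow(x$schema), x$cohort_size, min(x$years), max(x$years), x$seed))
  if (length(x$year_scaling)) {
    cat("  scaled years:", paste(names(x$year_scaling), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default synthetic registry: an England-like surgical population
#'
#' Frozen default hazards emulating the English 2016-2019 surgical
#' epidemiology: per-band first-surgery hazards were inverted from the
#' published cumulative first-surgery risk profile under an England-like
#' all-cause mortality schedule (men at 1.25x, women at 0.85x a common
#' base), so the analytic lifetime risks of first surgery are about 0.59
#' for men and 0.60 for women. Recurrence rates are 1.0x (men) and 1.45x
#' (women) the first-surgery hazard, calibrated so that the ratio of all
#' to first events is about 1.96, matching the national registry totals.
#' Obstetric fractions are concentrated in the female 15-44 bands.
#'
#' @inheritParams cohort_spec
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(cohort_size = 100000, years = 2016:2020,
                                seed = 1L) {
  schema <- default_age_bands()
  mu_base <- c(0.0009, 0.0001, 0.0001, 0.0003, 0.0004, 0.0005, 0.0007,
               0.0010, 0.0015, 0.0023, 0.0036, 0.0056, 0.0087, 0.0137,
               0.0220, 0.0370, 0.0650, 0.1150, 0.2200)
  lam_m <- c(0.00632, 0.00420, 0.00429, 0.00506, 0.00543, 0.00583, 0.00603,
             0.00650, 0.00678, 0.00793, 0.00931, 0.01135, 0.01441, 0.01798,
             0.02326, 0.03199, 0.04731, 0.09410, 0.38747)
  lam_f <- c(0.00425, 0.00310, 0.00315, 0.00493, 0.00754, 0.01069, 0.01183,
             0.01073, 0.00884, 0.00903, 0.00958, 0.01061, 0.01230, 0.01460,
             0.01853, 0.02391, 0.03048, 0.04267, 0.04753)
  hazards <- rbind(
    data.frame(sex = "F", band = schema$label, lambda = lam_f,
               mu = mu_base * 0.85, rho = 1.45 * lam_f,
               stringsAsFactors = FALSE),
    data.frame(sex = "M", band = schema$label, lambda = lam_m,
               mu = mu_base * 1.25, rho = 1.00 * lam_m,
               stringsAsFactors = FALSE))
  obf <- c("15-19" = 0.15, "20-24" = 0.35, "25-29" = 0.50, "30-34" = 0.50,
           "35-39" = 0.35, "40-44" = 0.15)
  cohort_spec(hazards, schema = schema, obstetric_fraction = obf,
              cohort_size = cohort_size, years = years, seed = seed)
}

#' Apply a pandemic scenario to a cohort specification
#'
#' Scales the first-surgery (and recurrence) hazards down and inflates
#' mortality for one calendar year, emulating the pandemic year: surgical
#' activity fell while all-cause mortality rose. Other years are untouched.
#'
#' @param spec A `cohort_spec`.
#' @param year The calendar year to modify (must be in `spec$years`).
#' @param lambda_scale Multiplier (< 1) on `lambda` and `rho`.
#' @param mu_scale Multiplier (> 1) on `mu`.
#' @return The modified `cohort_spec`.
#' @export
pandemic_scenario <- function(spec, year = 2020, lambda_scale = 0.66,
                              mu_scale = 1.14) {
  if (!year %in% spec$years) stop("year not in spec$years")
  spec$year_scaling[[as.character(year)]] <-
    c(lambda = lambda_scale, mu = mu_scale)
  spec
}

hazards_for <- function(spec, sex, year = NULL) {
  h <- spec$hazards[spec$hazards$sex == sex, , drop = FALSE]
  idx <- match(spec$schema$label, h$band)
  if (anyNA(idx)) stop(sprintf("hazards missing band(s) for sex %s", sex))
  h <- h[idx, , drop = FALSE]
  if (!is.null(year)) {
    sc <- spec$year_scaling[[as.character(year)]]
    if (!is.null(sc)) {
      h$lambda <- h$lambda * sc[["lambda"]]
      h$rho <- h$rho * sc[["lambda"]]
      h$mu <- h$mu * sc[["mu"]]
    }
  }
  h
}

# Piecewise-exponential sampler over the schema's bands: n waiting times
# (ages) under per-band rates; Inf where the total hazard is exhausted.
rpwexp <- function(n, rates, schema) {
  k <- nrow(schema)
  inc <- rates * schema$width
  inc[k] <- if (rates[k] > 0) Inf else 0
  H <- c(0, cumsum(inc[-k]))
  E <- stats::rexp(n)
  j <- findInterval(E, H)
  t <- schema$lower[j] + (E - H[j]) / rates[j]
  t[rates[j] == 0] <- Inf
  t
}

# Exposure (years) of the interval [from, to) within each band: n x k matrix.
band_exposure <- function(from, to, schema) {
  k <- nrow(schema)
  upper <- schema$lower + schema$width
  out <- matrix(0, length(from), k)
  for (j in seq_len(k)) {
    e <- pmin(to, upper[j]) - pmax(from, schema$lower[j])
    out[, j] <- pmax(e, 0)
  }
  out
}

simulate_year_sex <- function(spec, sex, year, stream_seed) {
  h <- hazards_for(spec, sex, year)
  schema <- spec$schema
  k <- nrow(schema)
  open_h <- h$lambda[k] + h$mu[k]
  if (open_h == 0) {
    stop("open band with zero total hazard: cohort cannot be followed to extinction")
  }
  with_seed(stream_seed, {
    n <- spec$cohort_size
    td <- rpwexp(n, h$mu, schema)
    ts <- rpwexp(n, h$lambda, schema)
    realised <- ts < td
    end <- pmin(ts, td)                     # exit from the event-free state
    firsts <- tabulate(band_of_age(ts[realised], schema), nbins = k)
    dth <- tabulate(band_of_age(td[td < ts], schema), nbins = k)
    pt <- colSums(band_exposure(rep(0, n), end, schema))
    # recurrent surgeries: Poisson on the post-first-surgery exposure
    if (any(realised)) {
      expo <- colSums(band_exposure(ts[realised], td[realised], schema))
    } else {
      expo <- numeric(k)
    }
    rec_rate <- h$rho * expo
    rec_rate[h$rho == 0] <- 0               # 0 * Inf exposure is no hazard
    if (any(!is.finite(rec_rate))) {
      stop("recurrence rate positive but some individuals never die")
    }
    rec <- stats::rpois(k, rec_rate)
    obf <- if (sex == "F") spec$obstetric_fraction else rep(0, k)
    f_ob <- stats::rbinom(k, firsts, obf)
    r_ob <- stats::rbinom(k, rec, obf)
    list(firsts = firsts, deaths = dth, person_time = pt, rec = rec,
         f_ob = f_ob, r_ob = r_ob)
  })
}

#' Simulate a synthetic registry
#'
#' Generates the three aggregated input tables of the pipeline from
#' individual life histories. For every calendar year and sex, a fresh
#' birth cohort of `cohort_size` individuals is simulated under the spec's
#' piecewise-constant hazards: a death age from `mu`, a first-surgery age
#' from `lambda` (realised only if it precedes death) and subsequent
#' surgeries as a Poisson process at rate `rho` between first surgery and
#' death. The cohort's full life course is tallied as that year's
#' stationary cross-section: the population and death tables describe the
#' event-free (at-risk) population, so that events, population and deaths
#' are mutually consistent and the pipeline's rates estimate the
#' generative hazards without bias. Deterministic given the spec's seed.
#'
#' @param spec A `cohort_spec`.
#' @return A `simulated_registry`: list with `events`, `population`,
#'   `deaths` (registry tables) and `truth` (named per-sex analytic
#'   lifetime risk of first surgery, as a fraction, under the unscaled
#'   hazards).
#' @export
simulate_registry <- function(spec) {
  schema <- spec$schema
  ev <- list(); po <- list(); de <- list()
  for (yi in seq_along(spec$years)) {
    year <- spec$years[yi]
    for (si in 1:2) {
      sex <- c("F", "M")[si]
      sim <- simulate_year_sex(spec, sex, year,
                               sub_seed(spec$seed, yi, si))
      n_other_first <- sim$firsts - sim$f_ob
      n_other_all <- n_other_first + (sim$rec - sim$r_ob)
      ev[[length(ev) + 1L]] <- data.frame(
        year = year, sex = sex, band = schema$label, category = "other",
        all_events = n_other_all, first_events = n_other_first,
        stringsAsFactors = FALSE)
      ob_all <- sim$f_ob + sim$r_ob
      if (any(ob_all > 0)) {
        keep <- ob_all > 0
        ev[[length(ev) + 1L]] <- data.frame(
          year = year, sex = sex, band = schema$label[keep],
          category = "obstetric", all_events = ob_all[keep],
          first_events = sim$f_ob[keep], stringsAsFactors = FALSE)
      }
      pop <- round(sim$person_time)
      # keep strata with activity visible in the denominator
      active <- (n_other_all + ob_all + sim$deaths) > 0
      pop[active & pop == 0] <- 1
      po[[length(po) + 1L]] <- data.frame(
        year = year, sex = sex, band = schema$label,
        midyear_population = pop, stringsAsFactors = FALSE)
      de[[length(de) + 1L]] <- data.frame(
        year = year, sex = sex, band = schema$label, deaths = sim$deaths,
        stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, ev); po <- do.call(rbind, po); de <- do.call(rbind, de)
  out <- list(
    events = event_table(ev$year, ev$sex, ev$band, ev$all_events,
                         ev$first_events, ev$category, schema = schema),
    population = population_table(po$year, po$sex, po$band,
                                  po$midyear_population, schema = schema),
    deaths = mortality_table(de$year, de$sex, de$band, de$deaths,
                             schema = schema),
    truth = c(F = analytic_lifetime_risk(spec, "F"),
              M = analytic_lifetime_risk(spec, "M")))
  class(out) <- "simulated_registry"
  out
}

#' @export
print.simulated_registry <- function(x, ...) {
  cat(sprintf(
    "Simulated registry: %d event rows, years %s-%s; truth F=%.4f M=%.4f\n",
    nrow(x$events), min(x$events$year), max(x$events$year),
    x$truth[["F"]], x$truth[["M"]]))
  invisible(x)
}

#' Analytic lifetime risk of first surgery under a cohort spec
#'
#' Exact first-passage probability of the generative model: the
#' probability that the first-surgery time precedes death under the spec's
#' piecewise-constant hazards,
#' `sum_x S_x (lambda_x/h_x) (1 - exp(-h_x n_x))` with
#' `h_x = lambda_x + mu_x`, `S_x` the event-free survival to the band
#' start and the open band contributing `S * lambda/h`.
#'
#' @param spec A `cohort_spec`.
#' @param sex `"F"` or `"M"`.
#' @return The lifetime risk as a fraction in `[0, 1]`.
#' @export
analytic_lifetime_risk <- function(spec, sex) {
  h <- hazards_for(spec, sex)
  tr <- band_transition(h$lambda, h$mu, spec$schema$width)
  S <- cumprod(c(1, tr$s[-length(tr$s)]))
  sum(S * tr$a)
}

#' Monte-Carlo lifetime risk under a cohort spec
#'
#' Brute-force companion of [analytic_lifetime_risk()]: simulates
#' `n_individuals` independent (first-surgery, death) time pairs and
#' reports the fraction whose first surgery precedes death (and an
#' optional age cap), with its binomial standard error.
#'
#' @param spec A `cohort_spec`.
#' @param sex `"F"` or `"M"`.
#' @param n_individuals Number of simulated individuals.
#' @param seed Integer seed (deterministic result).
#' @param max_age Optional age cap: events after this age do not count
#'   (used to mirror the truncated cumulative-incidence method).
#' @return List with `estimate` and `mc_se` (fractions).
#' @export
mc_lifetime_risk <- function(spec, sex, n_individuals = 1e6, seed = 1L,
                             max_age = Inf) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  h <- hazards_for(spec, sex)
  with_seed(seed, {
    td <- rpwexp(n_individuals, h$mu, spec$schema)
    ts <- rpwexp(n_individuals, h$lambda, spec$schema)
    p <- mean(ts < td & ts < max_age)
    list(estimate = p, mc_se = sqrt(p * (1 - p) / n_individuals))
  })
}

#' Write a simulated registry to disk
#'
#' Emits `events.csv`, `population.csv`, `deaths.csv` and `truth.json`.
#'
#' @param registry A `simulated_registry`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_registry <- function(registry, dir) {
  write_tables(registry, dir)
  jsonlite::write_json(as.list(registry$truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort specification from YAML
#'
#' Expects keys `band_lower` (band lower bounds in years), `hazards` (a
#' list of records with `sex`, `band`, `lambda`, `mu`, `rho`),
#' `obstetric_fraction` (named by band, optional), `cohort_size`, `years`
#' and `seed`.
#'
#' @param path YAML file.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  schema <- age_band_schema(unlist(y$band_lower))
  hz <- do.call(rbind, lapply(y$hazards, function(r) {
    data.frame(sex = r$sex, band = r$band, lambda = r$lambda, mu = r$mu,
               rho = r$rho, stringsAsFactors = FALSE)
  }))
  cohort_spec(hz, schema = schema,
              obstetric_fraction = unlist(y$obstetric_fraction),
              cohort_size = y$cohort_size %||% 100000,
              years = unlist(y$years) %||% 2016:2020,
              seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
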