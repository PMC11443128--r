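#' Round half away from zero
#'
#' Presentation-layer rounding used for reported risks (1 decimal) and
#' relative changes (nearest integer): ties round up in magnitude, unlike
#' base R's round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seed from a master seed and small indices.
sub_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in idx) s <- (s * 69069 + 10007 * as.double(i) + 1) %% 2147483647
  as.integer(s)
}

#' Average yearly lifetime-risk estimates with a t-interval
#'
#' Combines yearly lifetime-risk estimates for a multi-year period into a
#' single estimate: the arithmetic mean, with a two-sided t confidence
#' interval `mean +/- t_{(1+level)/2, k-1} * sd / sqrt(k)` across the `k`
#' years. Per-band risks are averaged (and intervalled) the same way.
#'
#' @param yearly List of `lifetime_risk_estimate` objects (>= 2), same sex,
#'   method and event definition.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A `lifetime_risk_estimate` whose `period` spans the input years
#'   and whose `risk_by_age_ci` holds the per-band intervals.
#' @export
average_years <- function(yearly, level = 0.95) {
  k <- length(yearly)
  if (k < 2L) stop("need at least 2 yearly estimates to average")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  meta <- function(f) unique(vapply(yearly, `[[`, character(1), f))
  for (f in c("method", "event_definition", "sex")) {
    if (length(meta(f)) > 1L) {
      stop(sprintf("yearly estimates disagree on %s", f))
    }
  }
  tq <- stats::qt((1 + level) / 2, df = k - 1L)
  vals <- vapply(yearly, `[[`, numeric(1), "value")
  m <- mean(vals)
  half <- tq * stats::sd(vals) / sqrt(k)
  rba <- do.call(rbind, lapply(yearly, `[[`, "risk_by_age"))
  rba_m <- colMeans(rba)
  rba_half <- tq * apply(rba, 2L, stats::sd) / sqrt(k)
  periods <- vapply(yearly, `[[`, character(1), "period")
  yrs <- suppressWarnings(as.integer(periods))
  period <- if (!anyNA(yrs)) paste0(min(yrs), "-", max(yrs)) else
    paste(periods, collapse = ",")
  new_lifetime_risk_estimate(
    value = m, risk_by_age = rba_m,
    method = meta("method"), event_definition = meta("event_definition"),
    sex = meta("sex"), period = period,
    ci_low = m - half, ci_high = m + half,
    risk_by_age_ci = data.frame(band = names(rba_m),
                                ci_low = rba_m - rba_half,
                                ci_high = rba_m + rba_half,
                                stringsAsFactors = FALSE))
}

#' Single-year confidence interval by parametric bootstrap
#'
#' For a period of a single year no between-year dispersion exists, so the
#' interval is obtained by parametric resampling: event and death counts in
#' every stratum are redrawn independently as Poisson with the observed
#' counts as means, the lifetime risk is recomputed for each replicate, and
#' the percentile 2.5/97.5 bounds are reported around the point estimate
#' from the observed counts. Deterministic given `seed`.
#'
#' @param events,population,deaths Registry tables containing the year.
#' @param year The single calendar year.
#' @param sex `"F"` or `"M"`.
#' @param schema The [age_band_schema()].
#' @param method `"lifetable"` or `"cumulative"`.
#' @param event_definition `"first"` or `"all"`.
#' @param reps Bootstrap replicates (>= 1000).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @param final_band_width Open-band truncation for the cumulative method.
#' @param exclude_categories Event categories to drop first.
#' @return A `lifetime_risk_estimate` with percentile `ci_low`/`ci_high`.
#' @export
single_year_ci <- function(events, population, deaths, year, sex,
                           schema = default_age_bands(),
                           method = c("lifetable", "cumulative"),
                           event_definition = c("first", "all"),
                           reps = 5000, seed = 1L, level = 0.95,
                           final_band_width = 10,
                           exclude_categories = character()) {
  method <- match.arg(method)
  event_definition <- match.arg(event_definition)
  if (length(year) != 1L) stop("single_year_ci needs exactly one year")
  if (reps < 1000) stop("reps must be >= 1000")
  ev <- filter_events(events[events$year == year & events$sex == sex, ,
                             drop = FALSE], exclude_categories)
  de <- deaths[deaths$year == year & deaths$sex == sex, , drop = FALSE]
  po <- population[population$year == year & population$sex == sex, ,
                   drop = FALSE]
  py <- person_years(po, year)
  col <- if (event_definition == "first") "first_events" else "all_events"
  ecnt <- pool_counts(ev, col)
  dcnt <- pool_counts(de, "deaths")
  idx <- match(schema$label, py$band)
  if (anyNA(idx)) stop("population table does not cover every band")
  P <- py$person_years[idx]
  E <- ecnt$count[match(schema$label, ecnt$band)]
  E[is.na(E)] <- 0
  D <- dcnt$count[match(schema$label, dcnt$band)]
  D[is.na(D)] <- 0
  if (any(P == 0 & (E > 0 | D > 0))) stop("counts in zero-population stratum")
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  point <- risk_from_rate_matrix(safe_div(E, P), safe_div(D, P), schema,
                                 method = method,
                                 final_band_width = final_band_width)
  if (all(E == 0) && all(D == 0)) {
    warning("all counts zero: degenerate interval")
    qs <- c(0, 0)
    reps_risk <- numeric(0)
  } else {
    k <- length(P)
    reps_risk <- with_seed(seed, {
      Eb <- matrix(stats::rpois(reps * k, rep(E, each = reps)), reps, k)
      Db <- matrix(stats::rpois(reps * k, rep(D, each = reps)), reps, k)
      lam <- sweep(Eb, 2L, P, safe_div_mat)
      mu <- sweep(Db, 2L, P, safe_div_mat)
      risk_from_rate_matrix(lam, mu, schema, method = method,
                            final_band_width = final_band_width)
    })
    qs <- stats::quantile(reps_risk, c((1 - level) / 2, (1 + level) / 2),
                          names = FALSE, type = 7)
  }
  new_lifetime_risk_estimate(
    value = 100 * point,
    risk_by_age = band_cum_risks(safe_div(E, P), safe_div(D, P), schema,
                                 method, final_band_width),
    method = method, event_definition = event_definition, sex = sex,
    period = as.character(year),
    ci_low = 100 * qs[1L], ci_high = 100 * qs[2L])
}

# Elementwise x/p with 0 where p = 0 (sweep passes same-shape arrays).
safe_div_mat <- function(x, p) ifelse(p > 0, x / p, 0)

# Per-band cumulative risks (percent) for one rate vector.
band_cum_risks <- function(lambda, mu, schema, method, final_band_width) {
  if (method == "cumulative") {
    w <- schema$width; w[!is.finite(w)] <- final_band_width
    return(stats::setNames(100 * (1 - exp(-cumsum(lambda * w))), schema$label))
  }
  tr <- band_transition(lambda, mu, schema$width)
  l <- cumprod(c(1, tr$s[-length(tr$s)]))
  stats::setNames(100 * cumsum(l * tr$a), schema$label)
}

#' Compare a pre-pandemic and a pandemic estimate
#'
#' Computes the absolute change (percentage points, pre minus post), the
#' relative change (percent of the pre value), whether the two confidence
#' intervals overlap, and a two-sided paired t-test across the per-band
#' cumulative risks (pairing unit: age band).
#'
#' @param pre,post `lifetime_risk_estimate` objects sharing sex, method,
#'   event definition and band schema, with `risk_by_age` present.
#' @return A `period_comparison`: list with `pre`, `post`,
#'   `absolute_change`, `relative_change`, `ci_overlap`, `t_statistic`,
#'   `df`, `p_value` and `pairing_unit`.
#' @export
compare_periods <- function(pre, post) {
  for (f in c("method", "event_definition", "sex")) {
    if (!identical(pre[[f]], post[[f]])) {
      stop(sprintf("estimates disagree on %s", f))
    }
  }
  if (is.null(pre$risk_by_age) || is.null(post$risk_by_age)) {
    stop("both estimates need risk_by_age")
  }
  if (!identical(names(pre$risk_by_age), names(post$risk_by_age))) {
    stop("estimates use different band schemas")
  }
  diffs <- pre$risk_by_age - post$risk_by_age
  n <- length(diffs)
  if (n < 2L) {
    warning("fewer than 2 band pairs: paired t-test not defined")
    t_stat <- NA_real_
    p <- NA_real_
  } else if (stats::sd(diffs) == 0) {
    warning("zero-variance differences: t undefined")
    t_stat <- 0
    p <- if (mean(diffs) == 0) 1 else 0
  } else {
    tt <- stats::t.test(pre$risk_by_age, post$risk_by_age, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  overlap <- if (is.na(pre$ci_low) || is.na(post$ci_low)) NA else
    pre$ci_low <= post$ci_high && post$ci_low <= pre$ci_high
  out <- list(
    pre = pre, post = post,
    absolute_change = pre$value - post$value,
    relative_change = if (pre$value > 0)
      100 * (pre$value - post$value) / pre$value else NA_real_,
    ci_overlap = overlap, t_statistic = t_stat, df = n - 1L, p_value = p,
    pairing_unit = "age band")
  class(out) <- "period_comparison"
  out
}

#' @export
print.period_comparison <- function(x, ...) {
  cat(sprintf(
    "Period comparison [%s, %s surgery, %s]: %s -> %s\n",
    x$pre$method, x$pre$event_definition, x$pre$sex, x$pre$period,
    x$post$period))
  cat(sprintf("  %.1f%% -> %.1f%%: change %.1f points (%.0f%% of pre)\n",
              round_half_up(x$pre$value, 1), round_half_up(x$post$value, 1),
              round_half_up(x$absolute_change, 1),
              round_half_up(x$relative_change, 0)))
  cat(sprintf("  paired t (%s, df=%d): t=%.3f, p=%.3g; CIs %s\n",
              x$pairing_unit, x$df, x$t_statistic, x$p_value,
              if (isTRUE(x$ci_overlap)) "overlap" else
                if (isFALSE(x$ci_overlap)) "disjoint" else "not available"))
  invisible(x)
}

#' Serialise a period comparison to JSON
#'
#' @param x A `period_comparison`.
#' @param path Output path (`.json`).
#' @param provenance Optional named list (seed, reps, ...) stored alongside.
#' @return Invisibly, `path`.
#' @export
write_comparison <- function(x, path, provenance = list()) {
  jsonlite::write_json(write_comparison_payload(x, provenance), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Largest increase in risk between successive age bands
#'
#' Scans the per-band cumulative risks for the largest increase between
#' consecutive bands. Ties (within 1e-8) are broken toward the older pair.
#'
#' @param risk_by_age Named numeric vector of per-band cumulative risks
#'   (percent), in schema order.
#' @return A list with `from_band`, `to_band` and `increase` (points).
#' @export
max_successive_increase <- function(risk_by_age) {
  if (length(risk_by_age) < 2L) stop("need at least 2 bands")
  d <- diff(risk_by_age)
  ties <- which(d >= max(d) - 1e-8)
  i <- ties[length(ties)]
  list(from_band = names(risk_by_age)[i], to_band = names(risk_by_age)[i + 1L],
       increase = unname(d[i]))
}

#' Female minus male risk in one band
#'
#' @param f,m `lifetime_risk_estimate` objects for women and men with the
#'   same method, event definition and period.
#' @param band Band label.
#' @return Difference in percentage points (`f - m`).
#' @export
sex_difference <- function(f, m, band) {
  for (fd in c("method", "event_definition", "period")) {
    if (!identical(f[[fd]], m[[fd]])) {
      stop(sprintf("estimates disagree on %s", fd))
    }
  }
  if (!band %in% names(f$risk_by_age) || !band %in% names(m$risk_by_age)) {
    stop(sprintf("band %s absent from risk_by_age", band))
  }
  unname(f$risk_by_age[band] - m$risk_by_age[band])
}
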