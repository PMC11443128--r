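#' Person-years of exposure
#'
#' Approximates person-years per (sex, band) stratum as the sum over the
#' requested calendar years of the mid-year population times one year —
#' the standard demographic exposure approximation. Additive over disjoint
#' year sets.
#'
#' @param population A `population_table`.
#' @param years Calendar years to pool; every year must be present.
#' @return A data frame with columns `sex`, `band`, `person_years`.
#' @export
person_years <- function(population, years) {
  years <- as.integer(years)
  missing <- setdiff(years, unique(population$year))
  if (length(missing)) {
    stop(sprintf("year(s) absent from population table: %s",
                 paste(missing, collapse = ", ")))
  }
  sub <- population[population$year %in% years, , drop = FALSE]
  out <- stats::aggregate(list(person_years = sub$midyear_population),
                          by = list(sex = sub$sex, band = sub$band), FUN = sum)
  out[order(out$sex, out$band), c("sex", "band", "person_years")]
}

pool_counts <- function(df, value_col) {
  out <- stats::aggregate(list(count = df[[value_col]]),
                          by = list(sex = df$sex, band = df$band), FUN = sum)
  out
}

rate_from_counts <- function(counts, py, what) {
  # counts, py: aligned on (sex, band); py is the person-years frame
  key_c <- paste(counts$sex, counts$band)
  key_p <- paste(py$sex, py$band)
  cnt <- counts$count[match(key_p, key_c)]
  cnt[is.na(cnt)] <- 0
  rate <- numeric(length(cnt))
  pos <- py$person_years > 0
  rate[pos] <- cnt[pos] / py$person_years[pos]
  if (any(!pos & cnt > 0)) {
    bad <- which(!pos & cnt > 0)[1L]
    stop(sprintf("%s in stratum (%s, %s) with zero person-years",
                 what, py$sex[bad], py$band[bad]))
  }
  if (any(!pos)) {
    warning(sprintf("%d stratum(s) with zero person-years and zero %s; rate set to 0",
                    sum(!pos), what))
  }
  rate
}

#' Age- and sex-specific incidence rates
#'
#' Divides pooled event counts by pooled person-years per (sex, band)
#' stratum. Counts are summed over all years and categories present in
#' `events` (apply [filter_events()] first for a sensitivity analysis), so a
#' multi-year period is pooled, not an average of yearly rates.
#'
#' @param events An `event_table`, already restricted to the period's years.
#' @param person_years Data frame from [person_years()] for the same period.
#' @param event_definition `"first"` (first surgeries) or `"all"` (every
#'   procedure, so the rate may exceed one per person-year).
#' @param period Text label stored on the output (e.g. `"2016-2019"`).
#' @return A rate table: data frame with columns `period`, `sex`, `band`,
#'   `event_definition`, `person_years`, `incidence_rate`.
#' @export
incidence_rates <- function(events, person_years,
                            event_definition = c("first", "all"),
                            period = "") {
  event_definition <- match.arg(event_definition)
  col <- if (event_definition == "first") "first_events" else "all_events"
  counts <- pool_counts(events, col)
  data.frame(period = period, sex = person_years$sex,
             band = person_years$band, event_definition = event_definition,
             person_years = person_years$person_years,
             incidence_rate = rate_from_counts(counts, person_years, "events"),
             stringsAsFactors = FALSE)
}

#' Age- and sex-specific all-cause mortality rates
#'
#' Same construction as [incidence_rates()] with death counts in the
#' numerator.
#'
#' @param deaths A `mortality_table`, restricted to the period's years.
#' @param person_years Data frame from [person_years()].
#' @param period Text label stored on the output.
#' @return Data frame with columns `period`, `sex`, `band`, `person_years`,
#'   `mortality_rate`.
#' @export
mortality_rates <- function(deaths, person_years, period = "") {
  counts <- pool_counts(deaths, "deaths")
  data.frame(period = period, sex = person_years$sex,
             band = person_years$band,
             person_years = person_years$person_years,
             mortality_rate = rate_from_counts(counts, person_years, "deaths"),
             stringsAsFactors = FALSE)
}

#' Assemble the full rate table for a period
#'
#' Convenience wrapper combining [person_years()], [incidence_rates()] and
#' [mortality_rates()] into the single table consumed by the risk
#' estimators: one row per (sex, band) per event definition.
#'
#' @param events,population,deaths The three registry tables.
#' @param years Calendar years of the period.
#' @param event_definition `"first"`, `"all"`, or both.
#' @param period Label; defaults to the year range.
#' @param exclude_categories Event categories to drop before pooling.
#' @return A rate table with columns `period`, `sex`, `band`,
#'   `event_definition`, `person_years`, `incidence_rate`, `mortality_rate`.
#' @export
build_rate_table <- function(events, population, deaths, years,
                             event_definition = c("first", "all"),
                             period = NULL,
                             exclude_categories = character()) {
  if (is.null(period)) {
    period <- if (length(years) > 1L)
      paste0(min(years), "-", max(years)) else as.character(years)
  }
  ev <- filter_events(events[events$year %in% years, , drop = FALSE],
                      exclude_categories)
  de <- deaths[deaths$year %in% years, , drop = FALSE]
  py <- person_years(population, years)
  mu <- mortality_rates(de, py, period = period)
  out <- lapply(event_definition, function(def) {
    lam <- incidence_rates(ev, py, event_definition = def, period = period)
    lam$mortality_rate <- mu$mortality_rate
    lam
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Extract per-band lambda and mu vectors, ordered by schema, for one stratum.
rates_for_stratum <- function(rates, sex, event_definition, schema) {
  sub <- rates[rates$sex == sex & rates$event_definition == event_definition, ,
               drop = FALSE]
  idx <- match(schema$label, sub$band)
  if (anyNA(idx)) {
    stop(sprintf("rate table missing band(s) for sex %s: %s", sex,
                 paste(schema$label[is.na(idx)], collapse = ", ")))
  }
  if (nrow(sub) != nrow(schema)) {
    stop("rate table must cover every band exactly once per stratum")
  }
  list(lambda = sub$incidence_rate[idx], mu = sub$mortality_rate[idx])
}
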