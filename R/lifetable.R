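#' Within-band first-event and survival probabilities
#'
#' Converts a pair of constant hazards — first-event incidence `lambda` and
#' competing all-cause mortality `mu` — into the conditional probability
#' `a` of a first event within a band and the probability `s` of reaching
#' the next band alive and event-free. Assumes exponential waiting times
#' within the band: with total hazard `h = lambda + mu`,
#' `a = (lambda/h) * (1 - exp(-h * width))` and `s = exp(-h * width)` for a
#' finite band; for the open final band the cohort is followed to
#' extinction, so `a = lambda / h` and `s = 0`.
#'
#' @param lambda,mu Non-negative hazards per person-year (vectorised).
#' @param width Band width in years; `Inf` for the open final band.
#' @return A list with numeric components `a` and `s`.
#' @examples
#' band_transition(0.02, 0.01, 5)   # a = 0.0928614, s = 0.8607080
#' band_transition(0.01, 0.01, Inf) # a = 0.5 by symmetry
#' @export
band_transition <- function(lambda, mu, width) {
  if (any(lambda < 0) || any(mu < 0)) stop("rates must be non-negative")
  if (any(width <= 0)) stop("band width must be positive")
  k <- max(length(lambda), length(mu), length(width))
  lambda <- rep_len(lambda, k); mu <- rep_len(mu, k)
  width <- rep_len(width, k)
  h <- lambda + mu
  a <- numeric(k); s <- numeric(k)
  fin <- is.finite(width)
  pos <- h > 0
  i <- fin & pos
  a[i] <- lambda[i] / h[i] * (1 - exp(-h[i] * width[i]))
  s[i] <- exp(-h[i] * width[i])
  s[fin & !pos] <- 1                      # no hazard: certain survival
  i <- !fin & pos
  a[i] <- lambda[i] / h[i]                # eventual first event vs death
  s[i] <- 0
  if (any(!fin & !pos)) {
    warning("open band with zero total hazard: event-free, immortal tail")
    s[!fin & !pos] <- 1
  }
  list(a = a, s = s)
}

#' Build a competing-risk abridged life table
#'
#' Constructs, band by band, the life-table columns for the first-event
#' process under competing mortality: `l` (event-free survivors at band
#' start, radix `l_0`), `a` (conditional first-event probability within the
#' band), `s` (probability of reaching the next band event-free), `d`
#' (expected first events, `l * a`) and `cum_risk` (cumulative first-event
#' probability by end of band, `sum(d)/radix`).
#'
#' @param rates A rate table (see [build_rate_table()]) restricted to one
#'   sex, period and event definition, or any data frame with `band`,
#'   `incidence_rate` and `mortality_rate` columns covering every band.
#' @param schema The [age_band_schema()].
#' @param radix Notional starting cohort (persons); results are
#'   radix-invariant.
#' @return A data frame of class `life_table` with columns `band`, `l`,
#'   `a`, `s`, `d`, `cum_risk`.
#' @export
build_life_table <- function(rates, schema = default_age_bands(),
                             radix = 100000) {
  sexes <- unique(rates$sex)
  defs <- unique(rates$event_definition)
  if (length(sexes) > 1L || length(defs) > 1L) {
    stop("rates must be restricted to a single sex and event definition")
  }
  idx <- match(schema$label, rates$band)
  if (anyNA(idx)) {
    stop(sprintf("missing band(s): %s",
                 paste(schema$label[is.na(idx)], collapse = ", ")))
  }
  lambda <- rates$incidence_rate[idx]
  mu <- rates$mortality_rate[idx]
  tr <- band_transition(lambda, mu, schema$width)
  l <- radix * cumprod(c(1, tr$s[-length(tr$s)]))
  d <- l * tr$a
  out <- data.frame(band = schema$label, l = l, a = tr$a, s = tr$s, d = d,
                    cum_risk = cumsum(d) / radix, stringsAsFactors = FALSE)
  class(out) <- c("life_table", "data.frame")
  out
}

new_lifetime_risk_estimate <- function(value, risk_by_age, method,
                                       event_definition, sex, period,
                                       ci_low = NA_real_, ci_high = NA_real_,
                                       risk_by_age_ci = NULL) {
  out <- list(value = value, ci_low = ci_low, ci_high = ci_high,
              method = method, event_definition = event_definition,
              sex = sex, period = period, risk_by_age = risk_by_age,
              risk_by_age_ci = risk_by_age_ci)
  class(out) <- "lifetime_risk_estimate"
  out
}

#' @export
print.lifetime_risk_estimate <- function(x, ...) {
  ci <- if (!is.na(x$ci_low)) {
    sprintf(" (95%% CI %.1f-%.1f)", x$ci_low, x$ci_high)
  } else ""
  cat(sprintf("Lifetime risk [%s, %s surgery, %s, %s]: %.1f%%%s\n",
              x$method, x$event_definition, x$sex, x$period,
              round_half_up(x$value, 1), ci))
  invisible(x)
}

#' Lifetime risk from a life table
#'
#' Extracts the headline lifetime-risk statistic (cumulative first-event
#' probability over the whole table, in percent) and the per-band
#' cumulative risks from a competing-risk life table. Confidence intervals
#' are attached by the inference functions, not here.
#'
#' @param lt A `life_table` from [build_life_table()].
#' @param event_definition,sex,period Metadata labels carried on the result.
#' @return A `lifetime_risk_estimate`: list with `value` (percent),
#'   `risk_by_age` (named percent vector, nondecreasing), `method`
#'   (`"lifetable"`) and the metadata labels.
#' @export
lifetime_risk_lifetable <- function(lt, event_definition = "first",
                                    sex = NA_character_,
                                    period = NA_character_) {
  rba <- stats::setNames(100 * lt$cum_risk, lt$band)
  new_lifetime_risk_estimate(value = 100 * lt$cum_risk[nrow(lt)],
                             risk_by_age = rba, method = "lifetable",
                             event_definition = event_definition,
                             sex = sex, period = period)
}

#' Lifetime risk by the cumulative-incidence method
#'
#' The alternative estimator using incidence rates only: lifetime risk is
#' `1 - exp(-sum(lambda * width))`, ignoring the competing risk of death,
#' so it overestimates relative to the life-table method whenever mortality
#' is positive. The open final band has no natural width; it is truncated
#' at `final_band_width` years (default 10, i.e. following the cohort to
#' roughly age 100 under the default schema). Per-band cumulative risks use
#' the same transform on partial sums.
#'
#' @param rates Rate table restricted to one sex, period and event
#'   definition (as for [build_life_table()]).
#' @param schema The [age_band_schema()].
#' @param final_band_width Truncation width in years for the open band.
#' @param event_definition,sex,period Metadata labels; defaults taken from
#'   `rates` where available.
#' @return A `lifetime_risk_estimate` with `method = "cumulative"`.
#' @export
cumulative_incidence <- function(rates, schema = default_age_bands(),
                                 final_band_width = 10,
                                 event_definition = NULL, sex = NULL,
                                 period = NULL) {
  if (final_band_width <= 0) stop("final_band_width must be positive")
  if (is.null(event_definition)) {
    event_definition <- unique(rates$event_definition)
  }
  if (is.null(sex)) sex <- unique(rates$sex)
  if (is.null(period)) period <- unique(as.character(rates$period))
  if (length(sex) > 1L || length(event_definition) > 1L) {
    stop("rates must be restricted to a single sex and event definition")
  }
  idx <- match(schema$label, rates$band)
  if (anyNA(idx)) {
    stop(sprintf("missing band(s): %s",
                 paste(schema$label[is.na(idx)], collapse = ", ")))
  }
  lambda <- rates$incidence_rate[idx]
  width <- schema$width
  width[!is.finite(width)] <- final_band_width
  cum_rate <- cumsum(lambda * width)
  rba <- stats::setNames(100 * (1 - exp(-cum_rate)), schema$label)
  new_lifetime_risk_estimate(value = rba[[length(rba)]], risk_by_age = rba,
                             method = "cumulative",
                             event_definition = event_definition,
                             sex = if (length(sex)) sex else NA_character_,
                             period = if (length(period)) period else NA_character_)
}

# Vectorised lifetime risk over matrices of rates (reps x n_bands), used by
# the parametric bootstrap. Returns a vector of risks (fractions).
risk_from_rate_matrix <- function(lambda, mu, schema,
                                  method = c("lifetable", "cumulative"),
                                  final_band_width = 10) {
  method <- match.arg(method)
  lambda <- rbind(lambda); mu <- rbind(mu)
  k <- ncol(lambda)
  width <- schema$width
  if (method == "cumulative") {
    w <- width; w[!is.finite(w)] <- final_band_width
    return(1 - exp(-as.vector(lambda %*% w)))
  }
  h <- lambda + mu
  a <- matrix(0, nrow(lambda), k)
  fin <- is.finite(width)
  hw <- sweep(h[, fin, drop = FALSE], 2L, width[fin], `*`)
  pos <- h[, fin, drop = FALSE] > 0
  af <- ifelse(pos, lambda[, fin, drop = FALSE] / h[, fin, drop = FALSE] *
                 (1 - exp(-hw)), 0)
  a[, fin] <- af
  if (any(!fin)) {
    j <- which(!fin)
    hp <- h[, j] > 0
    a[, j] <- ifelse(hp, lambda[, j] / h[, j], 0)
  }
  # survival to band start: cumulative sum of h*width over preceding bands
  tri <- matrix(0, k, k)
  tri[upper.tri(tri)] <- 1                     # column j sums bands < j
  hw_full <- h
  hw_full[, fin] <- hw
  hw_full[, !fin] <- 0
  S <- exp(-(hw_full %*% tri))
  as.vector(rowSums(S * a))
}
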