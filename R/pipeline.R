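#' Analysis configuration
#'
#' Bundles every tunable of the end-to-end analysis. Defaults follow the
#' study design: pre-pandemic years 2016-2019 averaged with a t-interval,
#' pandemic year 2020 with a parametric bootstrap interval.
#'
#' @param events,population,deaths Paths to the three input CSVs.
#' @param pre_years Pre-pandemic calendar years (non-empty).
#' @param post_years Pandemic years, or `NULL` to skip the comparison.
#' @param methods Estimators to run: `"lifetable"`, `"cumulative"` or both.
#' @param event_definitions `"first"`, `"all"` or both.
#' @param exclude_categories Event categories dropped before analysis.
#' @param final_band_width Open-band truncation for the cumulative method.
#' @param level Confidence level.
#' @param seed Seed for the bootstrap.
#' @param reps Bootstrap replicates.
#' @param out_dir Output directory.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(events, population, deaths,
                            pre_years = 2016:2019, post_years = 2020,
                            methods = c("lifetable", "cumulative"),
                            event_definitions = c("first", "all"),
                            exclude_categories = character(),
                            final_band_width = 10, level = 0.95,
                            seed = 1L, reps = 5000,
                            out_dir = "results") {
  if (length(pre_years) == 0L) stop("pre_years must be non-empty")
  if (!is.null(post_years) && length(intersect(pre_years, post_years))) {
    stop("pre and post year sets must be disjoint")
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  methods <- match.arg(methods, several.ok = TRUE)
  event_definitions <- match.arg(event_definitions,
                                 c("first", "all"), several.ok = TRUE)
  out <- list(events = events, population = population, deaths = deaths,
              pre_years = as.integer(pre_years),
              post_years = if (is.null(post_years)) NULL else
                as.integer(post_years),
              methods = methods, event_definitions = event_definitions,
              exclude_categories = exclude_categories,
              final_band_width = final_band_width, level = level,
              seed = as.integer(seed), reps = as.integer(reps),
              out_dir = out_dir)
  class(out) <- "analysis_config"
  out
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; `overrides` (e.g.
#' from command-line flags) take precedence over file values.
#'
#' @param path YAML file.
#' @param overrides Named list of values overriding the file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  do.call(analysis_config, cfg)
}

estimate_year <- function(tables, year, sex, method, def, cfg, schema) {
  rates <- build_rate_table(tables$events, tables$population, tables$deaths,
                            years = year, event_definition = def,
                            exclude_categories = cfg$exclude_categories)
  sub <- rates[rates$sex == sex, , drop = FALSE]
  if (method == "lifetable") {
    lifetime_risk_lifetable(build_life_table(sub, schema),
                            event_definition = def, sex = sex,
                            period = as.character(year))
  } else {
    cumulative_incidence(sub, schema,
                         final_band_width = cfg$final_band_width,
                         event_definition = def, sex = sex,
                         period = as.character(year))
  }
}

#' Run the full analysis
#'
#' Validates the inputs, computes pooled pre-period rates and life tables,
#' yearly lifetime-risk estimates averaged into the pre-period estimate
#' with its t-interval, and — when a post period is configured — the
#' post-period estimate with a parametric bootstrap interval and the
#' paired pre/post comparison. Writes `rates.csv`,
#' `lifetable_<sex>_<def>.csv`, `estimates.csv` and `comparison.json`
#' under the configured output directory. No outputs are written if
#' validation fails.
#'
#' @param config An [analysis_config()].
#' @param schema The [age_band_schema()].
#' @return Invisibly, a list with `estimates` (data frame),
#'   `comparisons` (list of `period_comparison`) and `validation`.
#' @export
run_analysis <- function(config, schema = default_age_bands()) {
  tables <- read_tables(config$events, config$population, config$deaths,
                        schema = schema)
  all_years <- c(config$pre_years, config$post_years)
  report <- validate_grid(tables$events, tables$population, tables$deaths,
                          all_years, schema = schema)
  if (!report$ok) {
    print(report)
    stop("input validation failed; no outputs written")
  }
  message(sprintf(
    "run_analysis: pre=%s post=%s methods=%s defs=%s exclude=[%s] seed=%d reps=%d",
    paste(range(config$pre_years), collapse = "-"),
    if (is.null(config$post_years)) "none" else
      paste(config$post_years, collapse = ","),
    paste(config$methods, collapse = ","),
    paste(config$event_definitions, collapse = ","),
    paste(config$exclude_categories, collapse = ","),
    config$seed, config$reps))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  pre_label <- paste0(min(config$pre_years), "-", max(config$pre_years))
  ev <- filter_events(tables$events, config$exclude_categories)
  rates_pre <- build_rate_table(ev, tables$population, tables$deaths,
                                years = config$pre_years,
                                event_definition = config$event_definitions)
  utils::write.csv(rates_pre, file.path(config$out_dir, "rates.csv"),
                   row.names = FALSE, quote = FALSE)

  rows <- list(); comparisons <- list()
  for (sex in c("F", "M")) {
    for (def in config$event_definitions) {
      sub <- rates_pre[rates_pre$sex == sex &
                         rates_pre$event_definition == def, , drop = FALSE]
      lt <- build_life_table(sub, schema)
      utils::write.csv(
        data.frame(band = lt$band, l_x = lt$l, a_x = lt$a, s_x = lt$s,
                   d_x = lt$d, cum_risk = lt$cum_risk),
        file.path(config$out_dir, sprintf("lifetable_%s_%s.csv", sex, def)),
        row.names = FALSE, quote = FALSE)
      for (method in config$methods) {
        yearly <- lapply(config$pre_years, estimate_year, tables = tables,
                         sex = sex, method = method, def = def,
                         cfg = config, schema = schema)
        pre_est <- average_years(yearly, level = config$level)
        pre_est$period <- pre_label
        rows[[length(rows) + 1L]] <- data.frame(
          period = pre_label, sex = sex, event_definition = def,
          method = method, band = names(pre_est$risk_by_age),
          risk = as.numeric(pre_est$risk_by_age),
          ci_low = pre_est$risk_by_age_ci$ci_low,
          ci_high = pre_est$risk_by_age_ci$ci_high,
          stringsAsFactors = FALSE)
        if (!is.null(config$post_years)) {
          post_est <- single_year_ci(
            ev, tables$population, tables$deaths,
            year = config$post_years[1L], sex = sex, schema = schema,
            method = method, event_definition = def, reps = config$reps,
            seed = sub_seed(config$seed, match(sex, c("F", "M")),
                            match(method, c("lifetable", "cumulative")),
                            match(def, c("first", "all"))),
            level = config$level,
            final_band_width = config$final_band_width)
          comparisons[[paste(sex, def, method, sep = "_")]] <-
            compare_periods(pre_est, post_est)
        }
      }
    }
  }
  estimates <- do.call(rbind, rows)
  utils::write.csv(estimates, file.path(config$out_dir, "estimates.csv"),
                   row.names = FALSE, quote = FALSE)
  if (length(comparisons)) {
    payload <- lapply(comparisons, write_comparison_payload,
                      provenance = list(seed = config$seed,
                                        reps = config$reps))
    jsonlite::write_json(payload, file.path(config$out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(list(estimates = estimates, comparisons = comparisons,
                 validation = report))
}

write_comparison_payload <- function(x, provenance = list()) {
  list(
    pre = list(period = x$pre$period, value = x$pre$value,
               ci_low = x$pre$ci_low, ci_high = x$pre$ci_high),
    post = list(period = x$post$period, value = x$post$value,
                ci_low = x$post$ci_low, ci_high = x$post$ci_high),
    method = x$pre$method, event_definition = x$pre$event_definition,
    sex = x$pre$sex, absolute_change = x$absolute_change,
    relative_change = x$relative_change, ci_overlap = x$ci_overlap,
    t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
    pairing_unit = x$pairing_unit, provenance = provenance)
}

#' Published lifetime-risk reference table for England
#'
#' Loads the packaged reference table of published lifetime-risk estimates
#' for NHS surgery in England (per-band cumulative risks for 2016-2019 by
#' sex and event definition, plus the 2020 pandemic-year headline values),
#' used by the reporting-layer worked examples.
#'
#' @return Data frame with columns `period`, `sex`, `event_definition`,
#'   `band`, `risk`, `ci_low`, `ci_high`.
#' @export
england_reference_risks <- function() {
  path <- system.file("extdata", "england_published_lifetime_risk.csv",
                      package = "liferisk", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
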