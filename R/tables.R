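#' Stratified registry tables
#'
#' Constructors and validators for the three raw inputs of the analysis:
#' an event table (all and first events per stratum, with a category label
#' used by the obstetric-exclusion sensitivity analysis), a mid-year
#' population table and an all-cause deaths table. All are plain data frames
#' carrying a class tag; constructors check the type invariants.
#'
#' @param year Integer calendar years.
#' @param sex Character or factor, coded `"F"` / `"M"`.
#' @param band Character band labels, resolved against `schema` when given.
#' @param all_events,first_events Non-negative integer counts per stratum;
#'   `first_events <= all_events` row-wise.
#' @param category Character tag per event row (default `"other"`;
#'   `"obstetric"` marks rows for the sensitivity exclusion).
#' @param midyear_population Non-negative population counts.
#' @param deaths Non-negative death counts.
#' @param schema Optional [age_band_schema()] to resolve band labels against.
#'
#' @return A data frame of class `event_table`, `population_table` or
#'   `mortality_table`.
#' @name registry_tables
NULL

check_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- setdiff(unique(sex), c("F", "M"))
  if (length(bad)) {
    stop(sprintf("sex must be coded F or M; found: %s",
                 paste(bad, collapse = ", ")))
  }
  sex
}

check_counts <- function(x, what) {
  if (any(is.na(x))) stop(sprintf("missing values in %s", what))
  if (any(x < 0)) stop(sprintf("negative count in %s", what))
  x
}

#' @rdname registry_tables
#' @export
event_table <- function(year, sex, band, all_events, first_events,
                        category = "other", schema = NULL) {
  df <- data.frame(year = as.integer(year), sex = check_sex(sex),
                   band = as.character(band),
                   category = as.character(rep_len(category, length(year))),
                   all_events = check_counts(as.numeric(all_events), "all_events"),
                   first_events = check_counts(as.numeric(first_events), "first_events"),
                   stringsAsFactors = FALSE)
  if (!is.null(schema)) match_bands(df$band, schema, "event table")
  bad <- which(df$first_events > df$all_events)
  if (length(bad)) {
    stop(sprintf("first_events exceeds all_events in stratum (%d, %s, %s)",
                 df$year[bad[1L]], df$sex[bad[1L]], df$band[bad[1L]]))
  }
  key <- interaction(df$year, df$sex, df$band, df$category, drop = TRUE)
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE]
    stop(sprintf("duplicate event stratum (%d, %s, %s, %s)",
                 d$year[1L], d$sex[1L], d$band[1L], d$category[1L]))
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' @rdname registry_tables
#' @export
population_table <- function(year, sex, band, midyear_population,
                             schema = NULL) {
  df <- data.frame(year = as.integer(year), sex = check_sex(sex),
                   band = as.character(band),
                   midyear_population = check_counts(
                     as.numeric(midyear_population), "midyear_population"),
                   stringsAsFactors = FALSE)
  if (!is.null(schema)) match_bands(df$band, schema, "population table")
  key <- interaction(df$year, df$sex, df$band, drop = TRUE)
  if (anyDuplicated(key)) stop("duplicate population stratum")
  class(df) <- c("population_table", "data.frame")
  df
}

#' @rdname registry_tables
#' @export
mortality_table <- function(year, sex, band, deaths, schema = NULL) {
  df <- data.frame(year = as.integer(year), sex = check_sex(sex),
                   band = as.character(band),
                   deaths = check_counts(as.numeric(deaths), "deaths"),
                   stringsAsFactors = FALSE)
  if (!is.null(schema)) match_bands(df$band, schema, "mortality table")
  key <- interaction(df$year, df$sex, df$band, drop = TRUE)
  if (anyDuplicated(key)) stop("duplicate mortality stratum")
  class(df) <- c("mortality_table", "data.frame")
  df
}

read_one_table <- function(path, required, constructor, schema) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  tryCatch(constructor(df, schema),
           error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                                    call. = FALSE))
}

#' Read the three registry input files
#'
#' Reads comma-separated event, population and death tables (UTF-8, one
#' header row) and validates them against an age-band schema. Expected
#' columns are `year,sex,band,category,all_events,first_events` for events,
#' `year,sex,band,midyear_population` for population and
#' `year,sex,band,deaths` for deaths.
#'
#' @param events_path,population_path,deaths_path Paths to the CSV files.
#' @param schema An [age_band_schema()]; band labels in the files must all
#'   resolve against it.
#' @return A list with elements `events`, `population`, `deaths`.
#' @seealso [write_tables()], [validate_grid()]
#' @export
read_tables <- function(events_path, population_path, deaths_path,
                        schema = default_age_bands()) {
  events <- read_one_table(
    events_path,
    c("year", "sex", "band", "category", "all_events", "first_events"),
    function(df, s) event_table(df$year, df$sex, df$band, df$all_events,
                                df$first_events, df$category, schema = s),
    schema)
  population <- read_one_table(
    population_path,
    c("year", "sex", "band", "midyear_population"),
    function(df, s) population_table(df$year, df$sex, df$band,
                                     df$midyear_population, schema = s),
    schema)
  deaths <- read_one_table(
    deaths_path,
    c("year", "sex", "band", "deaths"),
    function(df, s) mortality_table(df$year, df$sex, df$band, df$deaths,
                                    schema = s),
    schema)
  list(events = events, population = population, deaths = deaths)
}

#' Write registry tables to CSV
#'
#' Inverse of [read_tables()]: writes the three tables in the documented
#' column order so that a write/read round trip reproduces them exactly.
#'
#' @param tables A list with `events`, `population` and `deaths` elements.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("events.csv", "population.csv", "deaths.csv"))
  ev <- tables$events[, c("year", "sex", "band", "category",
                          "all_events", "first_events")]
  utils::write.csv(ev, paths[1L], row.names = FALSE, quote = FALSE)
  utils::write.csv(tables$population[, c("year", "sex", "band",
                                         "midyear_population")],
                   paths[2L], row.names = FALSE, quote = FALSE)
  utils::write.csv(tables$deaths[, c("year", "sex", "band", "deaths")],
                   paths[3L], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Cross-table completeness checks
#'
#' Verifies that every (year, sex, band) stratum of the requested years is
#' present in all three tables, and that no stratum has events or deaths but
#' zero population. Findings are returned as a report, not raised as errors.
#'
#' @param events An `event_table`.
#' @param population A `population_table`.
#' @param deaths A `mortality_table`.
#' @param years Calendar years the analysis will use.
#' @param schema The [age_band_schema()] defining the expected bands.
#' @return A `validation_report`: list with `ok` (logical) and `issues`
#'   (data frame with columns `severity`, `stratum`, `message`). `ok` is
#'   `TRUE` iff no issue has severity `"error"`.
#' @export
validate_grid <- function(events, population, deaths, years,
                          schema = default_age_bands()) {
  issues <- list()
  add <- function(severity, stratum, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, stratum = stratum, message = message,
      stringsAsFactors = FALSE)
  }
  grid <- expand.grid(year = as.integer(years), sex = c("F", "M"),
                      band = schema$label, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  key <- function(y, s, b) paste(y, s, b, sep = "|")
  gkey <- key(grid$year, grid$sex, grid$band)
  have <- list(
    events = unique(key(events$year, events$sex, events$band)),
    population = unique(key(population$year, population$sex, population$band)),
    deaths = unique(key(deaths$year, deaths$sex, deaths$band)))
  for (tab in names(have)) {
    miss <- setdiff(gkey, have[[tab]])
    for (m in miss) add("error", m, sprintf("stratum missing from %s table", tab))
  }
  if (nrow(events) == 0L && nrow(population) == 0L && nrow(deaths) == 0L) {
    add("warning", "(all)", "no strata")
  }
  # events without population exposure
  if (nrow(events)) {
    ev <- stats::aggregate(cbind(all_events = events$all_events),
                           by = list(year = events$year, sex = events$sex,
                                     band = events$band), FUN = sum)
    pk <- key(population$year, population$sex, population$band)
    pop <- population$midyear_population[match(key(ev$year, ev$sex, ev$band), pk)]
    zero <- which(!is.na(pop) & pop == 0 & ev$all_events > 0)
    for (i in zero) {
      add("error", key(ev$year[i], ev$sex[i], ev$band[i]),
          "events without population")
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), stratum = character(),
               message = character(), stringsAsFactors = FALSE)
  out <- list(ok = !any(issues$severity == "error"), issues = issues)
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation:", if (x$ok) "OK" else "FAILED", "-",
      nrow(x$issues), "issue(s)\n")
  if (nrow(x$issues)) {
    show <- utils::head(x$issues, 20L)
    for (i in seq_len(nrow(show))) {
      cat(sprintf("  [%s] %s: %s\n", show$severity[i], show$stratum[i],
                  show$message[i]))
    }
    if (nrow(x$issues) > 20L) cat("  ...\n")
  }
  invisible(x)
}

#' Serialise a validation report
#'
#' @param report A `validation_report` from [validate_grid()].
#' @param path Output file; format chosen by extension (`.json` or text).
#' @return Invisibly, `path`.
#' @export
write_validation_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(ok = report$ok, issues = report$issues),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    sink(con); print(report); sink()
  }
  invisible(path)
}

#' Drop event categories (sensitivity analysis)
#'
#' Removes event rows whose category is in `exclude_categories`, leaving all
#' other rows untouched. With `exclude_categories = "obstetric"` this
#' reproduces the obstetric-exclusion sensitivity analysis. Idempotent.
#'
#' @param events An `event_table`.
#' @param exclude_categories Character vector of categories to drop (may be
#'   empty).
#' @return The filtered `event_table`.
#' @export
filter_events <- function(events, exclude_categories = character()) {
  if (length(exclude_categories) == 0L) return(events)
  keep <- !(events$category %in% exclude_categories)
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}
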