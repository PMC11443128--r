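# Shared fixtures: a tiny two-band schema and small complete table sets.

two_band_schema <- function() age_band_schema(c(0, 5))

# Complete one-year, two-sex tables over a schema, with constant counts.
small_tables <- function(schema = two_band_schema(), year = 2016,
                         all_events = 8, first_events = 5,
                         population = 1000, deaths = 2) {
  grid <- expand.grid(year = year, sex = c("F", "M"), band = schema$label,
                      stringsAsFactors = FALSE)
  list(
    events = event_table(grid$year, grid$sex, grid$band,
                         all_events, first_events, schema = schema),
    population = population_table(grid$year, grid$sex, grid$band,
                                  population, schema = schema),
    deaths = mortality_table(grid$year, grid$sex, grid$band, deaths,
                             schema = schema))
}

# A random valid cohort spec on the default schema (rates bounded away
# from pathological regimes); deterministic given seed.
random_cohort_spec <- function(seed, cohort_size = 10000, years = 2016) {
  schema <- default_age_bands()
  set.seed(seed)
  k <- nrow(schema)
  hazards <- rbind(
    data.frame(sex = "F", band = schema$label,
               lambda = runif(k, 0, 0.05), mu = runif(k, 0.0005, 0.1),
               rho = runif(k, 0, 0.05), stringsAsFactors = FALSE),
    data.frame(sex = "M", band = schema$label,
               lambda = runif(k, 0, 0.05), mu = runif(k, 0.0005, 0.1),
               rho = runif(k, 0, 0.05), stringsAsFactors = FALSE))
  cohort_spec(hazards, schema = schema, cohort_size = cohort_size,
              years = years, seed = seed)
}

# Rate table for one sex/definition built directly from per-band vectors.
rates_from_vectors <- function(lambda, mu, schema,
                               sex = "F", def = "first", period = "p") {
  data.frame(period = period, sex = sex, band = schema$label,
             event_definition = def, person_years = 1,
             incidence_rate = lambda, mortality_rate = mu,
             stringsAsFactors = FALSE)
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}
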