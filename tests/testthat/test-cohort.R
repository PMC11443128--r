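test_that("simulation is deterministic in the seed and sensitive to it", {
  spec <- default_cohort_spec(cohort_size = 2000, years = 2016, seed = 5)
  a <- simulate_registry(spec)
  b <- simulate_registry(spec)
  expect_identical(a$events, b$events)
  expect_identical(a$population, b$population)
  expect_identical(a$deaths, b$deaths)
  spec2 <- default_cohort_spec(cohort_size = 2000, years = 2016, seed = 6)
  expect_false(identical(simulate_registry(spec2)$events, a$events))
})

test_that("zero incidence yields an event-free registry", {
  spec <- default_cohort_spec(cohort_size = 1000, years = 2016)
  spec$hazards$lambda <- 0
  spec$hazards$rho <- 0
  reg <- simulate_registry(spec)
  expect_true(all(reg$events$all_events == 0))
  expect_true(all(reg$events$first_events == 0))
  expect_equal(unname(reg$truth), c(0, 0))
})

test_that("first-event counts match the binomial expectation", {
  # incidence confined to the first band, no mortality there: the count of
  # first events in band 1 is Binomial(n, a) with a = (lam/h)(1-exp(-5h))
  s <- two_band_schema()
  hz <- rbind(
    data.frame(sex = "F", band = s$label, lambda = c(0.05, 0),
               mu = c(0, 0.5), rho = 0, stringsAsFactors = FALSE),
    data.frame(sex = "M", band = s$label, lambda = c(0.05, 0),
               mu = c(0, 0.5), rho = 0, stringsAsFactors = FALSE))
  spec <- cohort_spec(hz, schema = s, cohort_size = 10000, years = 2016,
                      seed = 3)
  reg <- simulate_registry(spec)
  p <- (1 - exp(-0.05 * 5))
  for (sex in c("F", "M")) {
    got <- sum(reg$events$first_events[reg$events$sex == sex &
                                         reg$events$band == "0-4"])
    expect_lt(abs(got - 10000 * p), 3 * sqrt(10000 * p * (1 - p)))
  }
})

test_that("monte-carlo risk agrees with the analytic first-passage formula", {
  for (seed in 1:6) {
    spec <- random_cohort_spec(seed)
    sex <- c("F", "M")[1 + seed %% 2]
    mc <- mc_lifetime_risk(spec, sex, n_individuals = 50000, seed = seed)
    truth <- analytic_lifetime_risk(spec, sex)
    expect_lt(abs(mc$estimate - truth), 3 * max(mc$mc_se, 1e-4))
  }
  spec0 <- default_cohort_spec(cohort_size = 10)
  spec0$hazards$lambda <- 0
  mc0 <- mc_lifetime_risk(spec0, "F", 1000, seed = 1)
  expect_equal(mc0$estimate, 0)
  expect_equal(mc0$mc_se, 0)
  one <- mc_lifetime_risk(default_cohort_spec(), "F", 1, seed = 2)
  expect_true(one$estimate %in% c(0, 1))
})

test_that("analytic risk has the expected closed-form limits", {
  s <- age_band_schema(0)  # single open band
  hz <- rbind(data.frame(sex = "F", band = "0+", lambda = 0.02, mu = 0.02,
                         rho = 0, stringsAsFactors = FALSE),
              data.frame(sex = "M", band = "0+", lambda = 0.02, mu = 0.02,
                         rho = 0, stringsAsFactors = FALSE))
  spec <- cohort_spec(hz, schema = s, cohort_size = 10, years = 2016)
  expect_equal(analytic_lifetime_risk(spec, "F"), 0.5)  # symmetric race
  spec_im <- default_cohort_spec()
  spec_im$hazards$mu <- 0
  expect_equal(suppressWarnings(analytic_lifetime_risk(spec_im, "M")), 1)
})

test_that("simulated registries pass grid validation and conserve totals", {
  for (seed in c(2, 9)) {
    spec <- random_cohort_spec(seed, cohort_size = 5000, years = 2016:2017)
    reg <- simulate_registry(spec)
    rep <- validate_grid(reg$events, reg$population, reg$deaths,
                         spec$years, spec$schema)
    expect_true(rep$ok)
    # closed per-year cohorts: first events cannot exceed the cohort size
    per <- stats::aggregate(first_events ~ year + sex, data = reg$events,
                            FUN = sum)
    expect_true(all(per$first_events <= spec$cohort_size))
  }
})

test_that("pipeline on simulated data recovers the generating risk", {
  spec <- default_cohort_spec(cohort_size = 50000, years = 2016, seed = 11)
  reg <- simulate_registry(spec)
  rates <- build_rate_table(reg$events, reg$population, reg$deaths, 2016)
  for (sex in c("F", "M")) {
    lt <- build_life_table(rates[rates$sex == sex &
                                   rates$event_definition == "first", ])
    est <- lifetime_risk_lifetable(lt)$value / 100
    expect_equal(est, unname(reg$truth[sex]), tolerance = 0.02)
  }
})

test_that("excluding obstetric events lowers female risk, leaves males alone", {
  spec <- default_cohort_spec(cohort_size = 30000, years = 2016, seed = 13)
  reg <- simulate_registry(spec)
  est_all <- function(events, sex) {
    rates <- build_rate_table(events, reg$population, reg$deaths, 2016,
                              event_definition = "all")
    lifetime_risk_lifetable(build_life_table(
      rates[rates$sex == sex & rates$event_definition == "all", ]))$value
  }
  filtered <- filter_events(reg$events, "obstetric")
  expect_lt(est_all(filtered, "F"), est_all(reg$events, "F"))
  expect_equal(est_all(filtered, "M"), est_all(reg$events, "M"))
})

test_that("pandemic scenario rescales only the chosen year", {
  spec <- default_cohort_spec(cohort_size = 20000, years = 2019:2020,
                              seed = 17)
  pand <- pandemic_scenario(spec, 2020, lambda_scale = 0.5, mu_scale = 1.2)
  reg_base <- simulate_registry(spec)
  reg_pand <- simulate_registry(pand)
  f2019 <- function(r) sum(r$events$first_events[r$events$year == 2019])
  f2020 <- function(r) sum(r$events$first_events[r$events$year == 2020])
  expect_identical(f2019(reg_base), f2019(reg_pand))
  expect_lt(f2020(reg_pand), 0.8 * f2020(reg_base))
  expect_error(pandemic_scenario(spec, 1999), "not in spec")
})

test_that("cohort specs round-trip through YAML", {
  dir <- withr_local_tempdir()
  path <- file.path(dir, "spec.yaml")
  yaml::write_yaml(list(
    band_lower = c(0, 5),
    hazards = list(
      list(sex = "F", band = "0-4", lambda = 0.02, mu = 0.001, rho = 0.01),
      list(sex = "F", band = "5+", lambda = 0.01, mu = 0.05, rho = 0.01),
      list(sex = "M", band = "0-4", lambda = 0.02, mu = 0.001, rho = 0),
      list(sex = "M", band = "5+", lambda = 0.01, mu = 0.05, rho = 0)),
    obstetric_fraction = list(`0-4` = 0.1),
    cohort_size = 500, years = 2016, seed = 4), path)
  spec <- read_cohort_spec(path)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(nrow(spec$schema), 2L)
  expect_equal(spec$cohort_size, 500L)
  expect_equal(unname(spec$obstetric_fraction), c(0.1, 0))
  reg <- simulate_registry(spec)
  expect_true(validate_grid(reg$events, reg$population, reg$deaths, 2016,
                            spec$schema)$ok)
})
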