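test_that("config validation names the offending field and requires a seed", {
  expect_error(simConfig(n_persons = 100), "rng_seed")
  expect_error(simConfig(n_persons = 100, rng_seed = 1, p_gap = 1.4), "p_gap")
  expect_error(simConfig(n_persons = 100, rng_seed = 1,
                         reporting_completeness = -0.1),
               "reporting_completeness")
  bad_inc <- flat_incidence()
  bad_inc$rate_per_100k[1] <- -5
  expect_error(simConfig(n_persons = 100, rng_seed = 1, incidence = bad_inc),
               "incidence")
})

test_that("population generation is seeded-deterministic and honors the gap model", {
  cfg <- simConfig(n_persons = 400, year_range = c(2004, 2008), rng_seed = 7)
  a <- simulatePopulation(cfg)
  b <- simulatePopulation(cfg)
  expect_identical(a, b)

  # no gaps: one spell spanning the whole range for everyone
  cfg0 <- simConfig(n_persons = 200, year_range = c(2004, 2008),
                    p_gap = 0, rng_seed = 3)
  p0 <- simulatePopulation(cfg0)
  expect_equal(nrow(p0$spells), 200)
  expect_true(all(p0$spells$start_date == as.Date("2004-01-01")))
  expect_true(all(p0$spells$end_date == as.Date("2008-12-31")))

  # gap probability recovered within 3 binomial SDs at n = 10,000
  cfgg <- simConfig(n_persons = 10000, year_range = c(2004, 2008),
                    p_gap = 0.1, rng_seed = 11)
  pg <- simulatePopulation(cfgg)
  # a person has a gap iff their spells cover fewer days than the full range
  span <- as.integer(as.Date("2008-12-31") - as.Date("2004-01-01")) + 1L
  cov <- dplyr::summarise(
    dplyr::group_by(pg$spells, person_id),
    covered = sum(as.integer(end_date - start_date) + 1L)
  )
  n_gapped <- sum(cov$covered < span)
  sd3 <- 3 * sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(n_gapped / 10000 - 0.1), sd3)
})

test_that("event generation follows the configured incidence", {
  # null process
  cfg0 <- simConfig(n_persons = 500, year_range = c(2004, 2006),
                    incidence = flat_incidence(0, 0, 0), rng_seed = 5)
  pop <- simulatePopulation(cfg0)
  expect_equal(nrow(simulateEvents(pop$persons, cfg0)), 0)

  # Poisson count: flat 100/100k over 100,000 person-years -> ~100 events
  cfgp <- simConfig(n_persons = 25000, year_range = c(2004, 2007),
                    incidence = flat_incidence(40, 30, 30),
                    iv_annual_trend = 0, prevalent_fraction = 0, rng_seed = 9)
  popp <- simulatePopulation(cfgp)
  ev <- simulateEvents(popp$persons, cfgp)
  expect_lt(abs(nrow(ev) - 100), 3 * sqrt(100))

  # prevalent fraction 1: every event dated before the simulated window
  cfg1 <- simConfig(n_persons = 5000, year_range = c(2004, 2006),
                    incidence = flat_incidence(200, 100, 100),
                    prevalent_fraction = 1, rng_seed = 13)
  pop1 <- simulatePopulation(cfg1)
  ev1 <- simulateEvents(pop1$persons, cfg1)
  ev1 <- ev1[ev1$prevalent_flag, ]
  expect_gt(nrow(ev1), 0)
  expect_true(all(ev1$diagnosis_date < as.Date("2004-01-01")))
})

test_that("claims emission respects stage-specific coding rules", {
  # stage III with zero C77 emission -> no lymph-node codes at all
  cfg <- perfect_config(n = 3000, years = c(2004, 2006), seed = 17,
                        incidence = flat_incidence(0, 300, 0))
  cfg$p_c77_given_III <- 0
  pop <- simulatePopulation(cfg)
  ev <- simulateEvents(pop$persons, cfg)
  bundle <- emitClaims(pop$persons, pop$spells, ev, cfg)
  expect_false(any(startsWith(bundle$outpatient$icd_code, "C77")))
  expect_false(any(startsWith(bundle$inpatient$icd_code, "C77")))

  # metastasis-code quarter lags follow the configured multinomial
  cfg2 <- perfect_config(n = 60000, years = c(2004, 2005), seed = 19,
                         incidence = flat_incidence(0, 0, 1000))
  cfg2$stage_code_lag_probs <- c(0.6, 0.3, 0.1)
  pop2 <- simulatePopulation(cfg2)
  ev2 <- simulateEvents(pop2$persons, cfg2)
  bundle2 <- emitClaims(pop2$persons, pop2$spells, ev2, cfg2)
  met <- bundle2$inpatient[startsWith(bundle2$inpatient$icd_code, "C78") |
                             startsWith(bundle2$inpatient$icd_code, "C79"), ]
  met_q <- 4 * as.integer(format(met$date, "%Y")) +
    (as.integer(format(met$date, "%m")) - 1) %/% 3
  ev_q <- 4 * ev2$diagnosis_year +
    (as.integer(format(ev2$diagnosis_date, "%m")) - 1) %/% 3
  lag <- met_q - ev_q[match(met$person_id, ev2$person_id)]
  n <- length(lag)
  expect_gt(n, 500)
  for (l in 0:2) {
    p <- c(0.6, 0.3, 0.1)[l + 1]
    expect_lt(abs(mean(lag == l) - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("every claims code maps back to a simulated person", {
  cfg <- messy_config(n = 300, seed = 23)
  sim <- simulateClaimsRegistry(cfg)
  ids <- sim$bundle$persons$person_id
  expect_true(all(sim$bundle$outpatient$person_id %in% ids))
  expect_true(all(sim$bundle$inpatient$person_id %in% ids))
  expect_true(all(sim$bundle$dispensations$person_id %in% ids))
  expect_true(all(sim$registry$person_id %in% sim$truth$person_id))
  expect_false(anyDuplicated(sim$registry$person_id) > 0)
})

test_that("registry emission reproduces the reporting mechanisms", {
  # faithful registry: recorded N/M match the true stage exactly
  cfg <- perfect_config(n = 4000, years = c(2004, 2006), seed = 29,
                        incidence = flat_incidence(200, 100, 100))
  pop <- simulatePopulation(cfg)
  ev <- simulateEvents(pop$persons, cfg)
  reg <- emitRegistry(ev, cfg)
  expect_equal(nrow(reg), nrow(ev))
  tr <- ev$true_stage[match(reg$person_id, ev$person_id)]
  expect_true(all(reg$n_status[tr == "non_advanced"] == "N0"))
  expect_true(all(reg$m_status[tr == "non_advanced"] == "M0"))
  expect_true(all(reg$n_status[tr == "III"] == "N_plus"))
  expect_true(all(reg$m_status[tr == "III"] == "M0"))
  expect_true(all(reg$m_status[tr == "IV"] == "M1"))

  # pathologist-only notification blanks both statuses
  cfg_p <- perfect_config(n = 1000, years = c(2004, 2006), seed = 31,
                          incidence = flat_incidence(200, 100, 100))
  cfg_p$p_pathologist_only <- 1
  reg_p <- emitRegistry(ev, cfg_p)
  expect_true(all(reg_p$n_status == "missing"))
  expect_true(all(reg_p$m_status == "missing"))

  # premature M0 hits the configured fraction of true stage-IV cancers
  cfg_m <- perfect_config(n = 30000, years = c(2004, 2005), seed = 37,
                          incidence = flat_incidence(0, 0, 2000))
  cfg_m$p_premature_M0 <- 0.3
  pop_m <- simulatePopulation(cfg_m)
  ev_m <- simulateEvents(pop_m$persons, cfg_m)
  reg_m <- emitRegistry(ev_m, cfg_m)
  n_iv <- nrow(reg_m)
  expect_gt(n_iv, 800)
  frac_m0 <- mean(reg_m$m_status == "M0")
  expect_lt(abs(frac_m0 - 0.3), 3 * sqrt(0.3 * 0.7 / n_iv))
})

test_that("the full generator is deterministic and round-trips through CSV", {
  cfg <- messy_config(n = 150, seed = 41)
  s1 <- simulateClaimsRegistry(cfg)
  s2 <- simulateClaimsRegistry(cfg)
  expect_identical(s1$bundle$outpatient, s2$bundle$outpatient)
  expect_identical(s1$bundle$inpatient, s2$bundle$inpatient)
  expect_identical(s1$registry, s2$registry)

  dir <- withr::local_tempdir()
  writeBundle(s1, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  b <- readBundle(dir)
  expect_equal(nrow(b$outpatient), nrow(s1$bundle$outpatient))
  expect_equal(attr(b, "registry")$n_status, s1$registry$n_status)
  expect_equal(attr(b, "truth")$diagnosis_date, s1$truth$diagnosis_date)
})
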