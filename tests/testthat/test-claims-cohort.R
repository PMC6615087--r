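# Hand-built micro-bundles around analysis year 2014 (coverage 2004-2015).

mk_persons <- function(ids, sex = "male", birth_year = 1950) {
  tibble::tibble(person_id = ids, sex = sex, birth_year = birth_year)
}

mk_spells <- function(ids, start = "2004-01-01", end = "2015-12-31") {
  tibble::tibble(person_id = ids, start_date = as.Date(start),
                 end_date = as.Date(end))
}

mk_out <- function(person_id = integer(), year = integer(),
                   quarter = integer(), icd_code = character(),
                   certainty = character()) {
  tibble::tibble(person_id = person_id, year = year, quarter = quarter,
                 icd_code = icd_code, certainty = certainty)
}

mk_inp <- function(person_id = integer(), date = character(),
                   icd_code = character(), position = character()) {
  tibble::tibble(person_id = person_id, date = as.Date(date),
                 icd_code = icd_code, position = position)
}

mk_disp <- function(person_id = integer(), date = character(),
                    agent_code = character()) {
  tibble::tibble(person_id = person_id, date = as.Date(date),
                 agent_code = agent_code)
}

mk_bundle <- function(persons, spells = NULL, outpatient = mk_out(),
                      inpatient = mk_inp(), dispensations = mk_disp()) {
  if (is.null(spells)) spells <- mk_spells(persons$person_id)
  claimsBundle(persons, spells, outpatient, inpatient, dispensations)
}

test_that("a single CRC code without confirmation is not a case", {
  b <- mk_bundle(mk_persons(1L),
                 outpatient = mk_out(1L, 2014L, 2L, "C18.9", "confirmed"))
  expect_equal(nrow(identifyIncidentCases(b, 2014)), 0)
})

test_that("confirmation works up to two quarters later; entry stays at the first code", {
  b <- mk_bundle(mk_persons(1L),
                 outpatient = mk_out(c(1L, 1L), c(2014L, 2014L), c(2L, 4L),
                                     c("C20", "C18.9"),
                                     c("confirmed", "confirmed")))
  cases <- identifyIncidentCases(b, 2014)
  expect_equal(nrow(cases), 1)
  expect_equal(cases$entry_quarter, 2L)
  expect_equal(cases$cohort_entry_date, as.Date("2014-04-01"))

  # three quarters later is outside the confirmation window
  b2 <- mk_bundle(mk_persons(1L),
                  outpatient = mk_out(c(1L, 1L), c(2014L, 2015L), c(2L, 1L),
                                      c("C20", "C18.9"),
                                      c("confirmed", "confirmed")))
  expect_equal(nrow(identifyIncidentCases(b2, 2014)), 0)
})

test_that("suspected and excluded outpatient codes neither start nor confirm a case", {
  b <- mk_bundle(mk_persons(1L),
                 outpatient = mk_out(c(1L, 1L, 1L),
                                     c(2014L, 2014L, 2014L), c(1L, 2L, 3L),
                                     c("C18.9", "C18.9", "C18.2"),
                                     c("suspected", "confirmed", "excluded")))
  expect_equal(nrow(identifyIncidentCases(b, 2014)), 0)
})

test_that("an old status-post CRC code washes out the case as prevalent", {
  out <- mk_out(c(1L, 1L, 1L), c(2011L, 2014L, 2014L), c(1L, 2L, 3L),
                c("C18.9", "C20", "C18.9"),
                c("status_post", "confirmed", "confirmed"))
  b <- mk_bundle(mk_persons(1L), outpatient = out)
  expect_equal(nrow(identifyIncidentCases(b, 2014)), 0)

  # the same code more than 4 years before entry does not
  out$year[1] <- 2008L
  b2 <- mk_bundle(mk_persons(1L), outpatient = out)
  expect_equal(nrow(identifyIncidentCases(b2, 2014)), 1)
})

test_that("inpatient admission diagnoses are ignored throughout", {
  b <- mk_bundle(mk_persons(1L),
                 inpatient = mk_inp(c(1L, 1L), c("2014-02-10", "2014-05-01"),
                                    c("C18.9", "C18.9"),
                                    c("admission", "admission")))
  expect_equal(nrow(identifyIncidentCases(b, 2014)), 0)
})

test_that("the first inpatient code in the entry quarter dates the cohort entry", {
  b <- mk_bundle(mk_persons(1L),
                 outpatient = mk_out(1L, 2014L, 1L, "C18.9", "confirmed"),
                 inpatient = mk_inp(1L, "2014-02-15", "C18.9", "main"))
  cases <- identifyIncidentCases(b, 2014)
  expect_equal(cases$cohort_entry_date, as.Date("2014-02-15"))
  expect_equal(cases$entry_quarter, 1L)
})

test_that("insurance interruptions are tolerated up to exactly 15 days", {
  # 16-day gap inside the look-back window -> out of the denominator
  sp16 <- tibble::tibble(person_id = c(1L, 1L),
                         start_date = as.Date(c("2004-01-01", "2012-06-18")),
                         end_date = as.Date(c("2012-06-01", "2015-12-31")))
  persons <- mk_persons(1L)
  d16 <- eligiblePersons(persons, sp16, 2014)
  expect_equal(sum(d16$person_count), 0)

  # 15-day gap (uncovered 2012-06-02 .. 2012-06-16) -> still in
  sp15 <- tibble::tibble(person_id = c(1L, 1L),
                         start_date = as.Date(c("2004-01-01", "2012-06-17")),
                         end_date = as.Date(c("2012-06-01", "2015-12-31")))
  d15 <- eligiblePersons(persons, sp15, 2014)
  expect_equal(sum(d15$person_count), 1)

  # full single-spell coverage: eligible every year once 4 look-back years exist
  dall <- lapply(2008:2015, function(y)
    sum(eligiblePersons(persons, mk_spells(1L), y)$person_count))
  expect_true(all(unlist(dall) == 1))

  expect_error(eligiblePersons(persons, tibble::tibble(
    person_id = c(1L, 1L),
    start_date = as.Date(c("2004-01-01", "2010-01-01")),
    end_date = as.Date(c("2011-01-01", "2015-12-31"))), 2014),
    "overlap")
})

case_bundle <- function(stage_out = mk_out(), stage_inp = mk_inp()) {
  out <- dplyr::bind_rows(
    mk_out(c(1L, 1L), c(2014L, 2014L), c(2L, 3L), c("C18.9", "C18.9"),
           c("confirmed", "confirmed")),
    stage_out
  )
  mk_bundle(mk_persons(1L), outpatient = out, inpatient = stage_inp)
}

test_that("staging partitions cases with distant codes taking precedence", {
  # C77 and C79 both in window -> IV
  b <- case_bundle(mk_out(c(1L, 1L), c(2014L, 2014L), c(2L, 3L),
                          c("C77.0", "C79.5"), c("confirmed", "confirmed")))
  cases <- identifyIncidentCases(b, 2014)
  expect_equal(stageCases(cases, b)$stage, "IV")

  # no stage codes at all -> non-advanced
  b0 <- case_bundle()
  cases0 <- identifyIncidentCases(b0, 2014)
  expect_equal(stageCases(cases0, b0)$stage, "non_advanced")

  # suspected C79 never stages
  bs <- case_bundle(mk_out(1L, 2014L, 2L, "C79.5", "suspected"))
  expect_equal(stageCases(identifyIncidentCases(bs, 2014), bs)$stage,
               "non_advanced")

  expect_error(stageCases(cases0, b0, n_following_quarters = 3),
               "n_following_quarters")
})

test_that("the staging window bounds which metastasis codes count", {
  # C79 two quarters after entry: invisible at window 1, IV at window 2
  b <- case_bundle(mk_out(1L, 2014L, 4L, "C79.5", "confirmed"))
  cases <- identifyIncidentCases(b, 2014)
  expect_equal(stageCases(cases, b, n_following_quarters = 1)$stage,
               "non_advanced")
  expect_equal(stageCases(cases, b, n_following_quarters = 2)$stage, "IV")
})

test_that("inpatient evidence summary covers the boundary situations", {
  # the only IV case has an inpatient C78 code -> (1, NA)
  b <- case_bundle(stage_inp = mk_inp(1L, "2014-05-10", "C78.0", "secondary"))
  staged <- stageCases(identifyIncidentCases(b, 2014), b)
  s <- inpatientEvidenceSummary(staged, b)
  expect_equal(s$prop_IV_with_inpatient_code, 1)
  expect_true(is.na(s$prop_remaining_with_2plus_outpatient))

  # only two confirmed outpatient C79 records -> (0, 1)
  b2 <- case_bundle(mk_out(c(1L, 1L), c(2014L, 2014L), c(2L, 3L),
                           c("C79.5", "C79.0"), c("confirmed", "confirmed")))
  staged2 <- stageCases(identifyIncidentCases(b2, 2014), b2)
  s2 <- inpatientEvidenceSummary(staged2, b2)
  expect_equal(s2$prop_IV_with_inpatient_code, 0)
  expect_equal(s2$prop_remaining_with_2plus_outpatient, 1)

  # no IV cases -> both undefined
  b3 <- case_bundle()
  staged3 <- stageCases(identifyIncidentCases(b3, 2014), b3)
  s3 <- inpatientEvidenceSummary(staged3, b3)
  expect_true(is.na(s3$prop_IV_with_inpatient_code))
})

test_that("medication cross-check counts flagged non-advanced cases", {
  staged <- tibble::tibble(
    person_id = 1:10,
    cohort_entry_date = as.Date("2015-02-01"),
    stage = rep(c("non_advanced", "IV"), c(4, 6)),
    calendar_year = 2015L
  )
  disp <- mk_disp(1:4, rep("2015-03-01", 4), rep("L01XC07", 4))
  res <- medicationCrosscheck(staged, disp)
  expect_equal(res$n_subsample, 10)
  expect_equal(res$n_non_advanced, 4)
  expect_equal(res$n_flagged, 4)
  expect_equal(res$pct_of_subsample, 40.00)

  # a dispensation outside the window does not flag
  late <- mk_disp(1L, "2015-08-01", "L01XC07")
  expect_equal(medicationCrosscheck(staged, late)$n_flagged, 0)

  # no dispensations at all
  res0 <- medicationCrosscheck(staged, mk_disp())
  expect_equal(res0$n_flagged, 0)
  expect_equal(res0$pct_of_subsample, 0.00)

  expect_error(medicationCrosscheck(staged[0, ], disp), "empty")
})

test_that("washout soundness and denominator containment hold on messy data", {
  sim <- simulateClaimsRegistry(messy_config(n = 400, seed = 101))
  b <- sim$bundle
  cl <- codeLists()
  lb <- 1461L
  for (y in 2008:2009) {
    staged <- stageCases(identifyIncidentCases(b, y), b)
    denom <- eligiblePersons(b$persons, b$spells, y)
    if (nrow(staged) == 0) next
    # re-scan: no case may have a CRC code in its look-back window
    for (i in seq_len(nrow(staged))) {
      pid <- staged$person_id[i]
      entry <- staged$cohort_entry_date[i]
      entry_qi <- 4L * y + staged$entry_quarter[i] - 1L
      o <- b$outpatient[b$outpatient$person_id == pid, ]
      o <- o[startsWith(o$icd_code, "C18") | startsWith(o$icd_code, "C19") |
               startsWith(o$icd_code, "C20"), ]
      o <- o[o$certainty %in% c("confirmed", "status_post"), ]
      o_qi <- 4L * o$year + o$quarter - 1L
      o_qend <- as.Date(sprintf("%d-%02d-01",
                                o$year + (o$quarter == 4L),
                                ifelse(o$quarter == 4L, 1L, o$quarter * 3L + 1L))) - 1
      expect_false(any(o_qi < entry_qi & o_qend >= entry - lb))
      ip <- b$inpatient[b$inpatient$person_id == pid, ]
      ip <- ip[ip$position %in% c("main", "secondary") &
                 (startsWith(ip$icd_code, "C18") |
                    startsWith(ip$icd_code, "C19") |
                    startsWith(ip$icd_code, "C20")), ]
      expect_false(any(ip$date >= entry - lb & ip$date <= entry - 1))
    }
    # every case is counted in the denominator of its year/sex/age band
    counts <- dplyr::count(
      tibble::tibble(sex = staged$sex, age_band = ageBand(staged$age_at_entry)),
      sex, age_band)
    m <- dplyr::left_join(counts, denom, by = c("sex", "age_band"))
    expect_true(all(m$person_count >= m$n))
  }
})

test_that("perfect coding recovers exactly the true incident cases", {
  cfg <- perfect_config(n = 8000, years = c(2004, 2008), seed = 103,
                        incidence = flat_incidence(100, 60, 60))
  sim <- simulateClaimsRegistry(cfg)
  staged <- stageCases(identifyIncidentCases(sim$bundle, 2008), sim$bundle)
  truth <- sim$truth[sim$truth$diagnosis_year == 2008 &
                       !sim$truth$prevalent_flag, ]
  truth <- truth[attainedAge(2008, truth$birth_year) >= 5, ]
  expect_equal(sort(staged$person_id), sort(truth$person_id))
  m <- match(staged$person_id, truth$person_id)
  expect_equal(staged$stage, truth$true_stage[m])
})
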