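# Claims-based ascertainment and staging of incident colorectal cancer.
#
# Time conventions used throughout (documented in the methods vignette):
# * outpatient diagnoses are quarter-granular; their effective date for
#   ordering is the first day of the quarter;
# * the look-back ("preobservation") window of `lookback_years` years is
#   measured as round(lookback_years * 365.25) days;
# * ages are attained ages (calendar year minus birth year), identically in
#   numerator and denominator.

# For each row of `windows` (person_id, wstart, wend), TRUE if the person's
# spells cover the window with no uncovered stretch longer than
# `max_gap_days` (leading, internal and trailing interruptions all count).
covered_in_window <- function(spells, windows, max_gap_days) {
  if (nrow(windows) == 0) return(logical(0))
  j <- dplyr::inner_join(spells, windows, by = "person_id",
                         relationship = "many-to-many")
  j$cs <- pmax(j$start_date, j$wstart)
  j$ce <- pmin(j$end_date, j$wend)
  j <- j[j$cs <= j$ce, ]
  j <- dplyr::arrange(j, .data$person_id, .data$cs)
  g <- dplyr::summarise(
    dplyr::group_by(j, .data$person_id),
    lead_gap = as.integer(dplyr::first(.data$cs) - dplyr::first(.data$wstart)),
    trail_gap = as.integer(dplyr::first(.data$wend) - dplyr::last(.data$ce)),
    max_internal = if (dplyr::n() > 1) {
      max(as.integer(.data$cs[-1] - .data$ce[-dplyr::n()] - 1L))
    } else 0L,
    .groups = "drop"
  )
  ok <- g$person_id[g$lead_gap <= max_gap_days &
                      g$trail_gap <= max_gap_days &
                      g$max_internal <= max_gap_days]
  windows$person_id %in% ok
}

#' Denominator: continuously insured persons by sex and age band
#'
#' Counts the persons that enter the denominator of the claims-based rates
#' for one calendar year: insured from `lookback_years` years before the
#' reference date (December 31 of the year) through the reference date with
#' no insurance interruption longer than `max_gap_days` days, and of age at
#' least `min_age` (attained age in the year).
#'
#' @param persons,spells Persons and insurance spells (as in a
#'   [claimsBundle()]).
#' @param year Calendar year.
#' @param lookback_years Continuous-insurance look-back, in years.
#' @param max_gap_days Longest tolerated interruption, in days.
#' @param min_age Minimum age in years.
#' @return Tibble `year`, `sex`, `age_band` (complete 2 x 18 grid),
#'   `person_count`.
#' @export
eligiblePersons <- function(persons, spells, year, lookback_years = 4,
                            max_gap_days = 15, min_age = 5) {
  validateSpells(spells)
  ref <- as.Date(sprintf("%d-12-31", year))
  windows <- tibble::tibble(person_id = persons$person_id,
                            wstart = ref - lookback_days(lookback_years),
                            wend = ref)
  ok <- covered_in_window(spells, windows, max_gap_days)
  age <- attainedAge(year, persons$birth_year)
  keep <- ok & age >= min_age
  kept <- tibble::tibble(sex = persons$sex[keep],
                         age_band = ageBand(age[keep]))
  grid <- tidyr::expand_grid(year = as.integer(year),
                             sex = c("male", "female"), age_band = 0:17)
  counts <- dplyr::count(kept, .data$sex, .data$age_band,
                         name = "person_count")
  out <- dplyr::left_join(grid, counts, by = c("sex", "age_band"))
  out$person_count[is.na(out$person_count)] <- 0L
  out
}

# Qualifying CRC code records across the whole bundle: outpatient records
# need certainty "confirmed"; inpatient records need position main or
# secondary. `priority` breaks same-day ties (inpatient main < secondary <
# outpatient), then the code string.
qualifying_crc_records <- function(bundle, code_lists) {
  out <- bundle$outpatient
  o <- out[out$certainty == "confirmed" &
             matches_prefix(out$icd_code, code_lists$crc_codes), ]
  oq <- tibble::tibble(
    person_id = o$person_id,
    qi = q_index(o$year, o$quarter),
    eff_date = quarter_start(o$year, o$quarter),
    exact_date = as.Date(NA),
    priority = 2L,
    icd_code = o$icd_code
  )
  inp <- bundle$inpatient
  i <- inp[inp$position %in% c("main", "secondary") &
             matches_prefix(inp$icd_code, code_lists$crc_codes), ]
  iq <- tibble::tibble(
    person_id = i$person_id,
    qi = q_index(as.integer(format(i$date, "%Y")), quarter_of_date(i$date)),
    eff_date = i$date,
    exact_date = i$date,
    priority = ifelse(i$position == "main", 0L, 1L),
    icd_code = i$icd_code
  )
  dplyr::bind_rows(oq, iq)
}

#' Ascertain incident CRC cases in one calendar year
#'
#' Implements the claims-based incident-case algorithm. For every person,
#' cohort entry is the first qualifying CRC (C18--C20) code in the year
#' (outpatient codes only with certainty "confirmed"; inpatient codes only
#' in main/secondary position). When the first code is outpatient its
#' quarter is known but not its day, so the entry date is the first day of
#' the entry quarter -- unless a qualifying inpatient code exists in that
#' quarter, whose exact date is then used. A person becomes a case iff
#'
#' 1. at least one additional qualifying CRC code record exists in the entry
#'    quarter or the `confirm_quarters` following quarters (confirmation of
#'    the initial diagnosis);
#' 2. no CRC code -- outpatient "confirmed" or "status post", or inpatient
#'    main/secondary -- occurs in the `lookback_years`-year preobservation
#'    window before the entry date (washout against prevalent cancers; a
#'    quarter-granular outpatient code from an earlier quarter counts as
#'    inside the window if its quarter overlaps it);
#' 3. the person is continuously insured (no interruption longer than
#'    `max_gap_days`) from `lookback_years` years before entry through
#'    December 31 of the year, which also places every case in the
#'    denominator of [eligiblePersons()] for that year;
#' 4. attained age in the year is at least `min_age`.
#'
#' @param bundle A [claimsBundle()].
#' @param year Calendar year to ascertain.
#' @param code_lists A [codeLists()] object.
#' @param lookback_years Washout / continuous-insurance look-back in years.
#' @param confirm_quarters Number of quarters after the entry quarter in
#'   which a confirmatory code may occur (default 2, i.e. within 6--9
#'   months).
#' @param max_gap_days Longest tolerated insurance interruption, days.
#' @param min_age Minimum age in years.
#' @return Tibble of incident cases: `person_id`, `cohort_entry_date`,
#'   `entry_year`, `entry_quarter`, `age_at_entry`, `sex`, `calendar_year`.
#' @export
identifyIncidentCases <- function(bundle, year, code_lists = codeLists(),
                                  lookback_years = 4, confirm_quarters = 2,
                                  max_gap_days = 15, min_age = 5) {
  stopifnot(inherits(bundle, "claims_bundle"))
  year <- as.integer(year)
  empty <- tibble::tibble(person_id = integer(),
                          cohort_entry_date = as.Date(character()),
                          entry_year = integer(), entry_quarter = integer(),
                          age_at_entry = integer(), sex = character(),
                          calendar_year = integer())
  yrs <- c(as.integer(format(bundle$spells$start_date, "%Y")),
           as.integer(format(bundle$spells$end_date, "%Y")))
  if (length(yrs) == 0 || year < min(yrs) || year > max(yrs)) {
    warning("year ", year, " is outside the data coverage; returning no cases")
    return(empty)
  }

  lb <- lookback_days(lookback_years)
  qual <- qualifying_crc_records(bundle, code_lists)
  ty <- qual[q_index_year(qual$qi) == year, ]
  if (nrow(ty) == 0) return(empty)

  cand <- dplyr::distinct(
    dplyr::arrange(ty, .data$person_id, .data$eff_date, .data$priority,
                   .data$icd_code),
    .data$person_id, .keep_all = TRUE
  )
  cand <- cand[, c("person_id", "qi")]
  names(cand)[2] <- "entry_qi"

  # exact entry date from inpatient codes in the entry quarter, if any
  inp_q <- qual[!is.na(qual$exact_date), c("person_id", "qi", "exact_date")]
  fi <- dplyr::inner_join(inp_q, cand, by = "person_id")
  fi <- fi[fi$qi == fi$entry_qi, ]
  if (nrow(fi) > 0) {
    first_inp <- dplyr::summarise(dplyr::group_by(fi, .data$person_id),
                                  d = min(.data$exact_date), .groups = "drop")
    cand <- dplyr::left_join(cand, first_inp, by = "person_id")
  } else {
    cand$d <- as.Date(NA)
  }
  cand$entry_date <- dplyr::coalesce(cand$d, q_index_start(cand$entry_qi))
  cand$d <- NULL

  # (1) confirmation: >= 2 qualifying records in the confirmation window
  cc <- dplyr::count(
    dplyr::filter(
      dplyr::inner_join(qual, cand, by = "person_id"),
      .data$qi >= .data$entry_qi,
      .data$qi <= .data$entry_qi + confirm_quarters
    ),
    .data$person_id
  )
  confirmed_ids <- cc$person_id[cc$n >= 2]

  # (2) washout: CRC codes in the preobservation window
  out <- bundle$outpatient
  wo <- out[out$certainty %in% c("confirmed", "status_post") &
              matches_prefix(out$icd_code, code_lists$crc_codes), ]
  wo <- tibble::tibble(person_id = wo$person_id,
                       qi = q_index(wo$year, wo$quarter))
  wo$qend <- q_index_end(wo$qi)
  w1 <- dplyr::filter(
    dplyr::inner_join(wo, cand, by = "person_id"),
    .data$qi < .data$entry_qi, .data$qend >= .data$entry_date - lb
  )
  inp <- bundle$inpatient
  wi <- inp[inp$position %in% c("main", "secondary") &
              matches_prefix(inp$icd_code, code_lists$crc_codes), ]
  w2 <- dplyr::filter(
    dplyr::inner_join(wi[, c("person_id", "date")], cand, by = "person_id"),
    .data$date >= .data$entry_date - lb, .data$date <= .data$entry_date - 1L
  )
  washed_ids <- union(w1$person_id, w2$person_id)

  # (3) insurance continuity through year end (keeps cases inside the
  # denominator of the same year)
  ref <- as.Date(sprintf("%d-12-31", year))
  windows <- tibble::tibble(person_id = cand$person_id,
                            wstart = cand$entry_date - lb, wend = ref)
  cont_ok <- covered_in_window(bundle$spells, windows, max_gap_days)

  cand <- dplyr::left_join(cand, bundle$persons, by = "person_id")
  cand$age <- attainedAge(year, cand$birth_year)

  keep <- cand$person_id %in% confirmed_ids &
    !cand$person_id %in% washed_ids &
    cont_ok &
    cand$age >= min_age
  cand <- cand[keep, ]

  tibble::tibble(
    person_id = cand$person_id,
    cohort_entry_date = cand$entry_date,
    entry_year = q_index_year(cand$entry_qi),
    entry_quarter = q_index_quarter(cand$entry_qi),
    age_at_entry = cand$age,
    sex = cand$sex,
    calendar_year = year
  )
}

#' Assign stage to ascertained cases from metastasis codes
#'
#' Scans the staging window -- the entry quarter plus `n_following_quarters`
#' following quarters -- for qualifying C77 (lymph nodes) and C78--C79
#' (distant metastases) codes. Qualifying records are inpatient
#' main/secondary diagnoses or outpatient diagnoses with certainty
#' "confirmed". Any distant code makes the case stage IV; otherwise any
#' lymph-node code makes it stage III; otherwise it is non-advanced. The
#' three labels form an exhaustive, mutually exclusive partition.
#'
#' @param cases Output of [identifyIncidentCases()].
#' @param bundle The same [claimsBundle()].
#' @param code_lists A [codeLists()] object.
#' @param n_following_quarters Staging window length beyond the entry
#'   quarter: 0, 1 (default, codes within 3--6 months) or 2.
#' @return `cases` with columns `stage` (`"non_advanced"`, `"III"`, `"IV"`)
#'   and `staging_window_quarters` added.
#' @export
stageCases <- function(cases, bundle, code_lists = codeLists(),
                       n_following_quarters = 1) {
  if (!length(n_following_quarters) == 1 ||
      !n_following_quarters %in% 0:2) {
    stop("`n_following_quarters` must be 0, 1 or 2", call. = FALSE)
  }
  stage_rec <- staging_records(bundle, code_lists)
  entry <- tibble::tibble(person_id = cases$person_id,
                          entry_qi = q_index(cases$calendar_year,
                                             cases$entry_quarter))
  hits <- dplyr::filter(
    dplyr::inner_join(stage_rec, entry, by = "person_id"),
    .data$qi >= .data$entry_qi,
    .data$qi <= .data$entry_qi + n_following_quarters
  )
  agg <- dplyr::summarise(dplyr::group_by(hits, .data$person_id),
                          any_distant = any(.data$distant),
                          any_lymph = any(!.data$distant), .groups = "drop")
  out <- dplyr::left_join(cases, agg, by = "person_id")
  out$stage <- dplyr::case_when(
    !is.na(out$any_distant) & out$any_distant ~ "IV",
    !is.na(out$any_lymph) & out$any_lymph ~ "III",
    TRUE ~ "non_advanced"
  )
  out$any_distant <- NULL
  out$any_lymph <- NULL
  out$staging_window_quarters <- as.integer(n_following_quarters)
  out
}

# qualifying C77/C78-C79 records: inpatient main/secondary or outpatient
# "confirmed"
staging_records <- function(bundle, code_lists) {
  stage_codes <- c(code_lists$lymph_only_codes, code_lists$distant_codes)
  out <- bundle$outpatient
  o <- out[out$certainty == "confirmed" &
             matches_prefix(out$icd_code, stage_codes), ]
  inp <- bundle$inpatient
  i <- inp[inp$position %in% c("main", "secondary") &
             matches_prefix(inp$icd_code, stage_codes), ]
  dplyr::bind_rows(
    tibble::tibble(person_id = o$person_id, qi = q_index(o$year, o$quarter),
                   distant = matches_prefix(o$icd_code,
                                            code_lists$distant_codes),
                   inpatient = FALSE),
    tibble::tibble(person_id = i$person_id,
                   qi = q_index(as.integer(format(i$date, "%Y")),
                                quarter_of_date(i$date)),
                   distant = matches_prefix(i$icd_code,
                                            code_lists$distant_codes),
                   inpatient = TRUE)
  )
}

#' Inpatient evidence behind stage-IV assignments
#'
#' Of the cases staged IV, what fraction has at least one distant-metastasis
#' code recorded as an inpatient (main/secondary) discharge diagnosis in the
#' staging window; and of the IV cases lacking such inpatient evidence, what
#' fraction has two or more confirmed outpatient distant-metastasis records
#' there. Both proportions are `NA` when their denominator is empty.
#'
#' @param staged_cases Output of [stageCases()].
#' @param bundle The same [claimsBundle()].
#' @param code_lists A [codeLists()] object.
#' @return List with `prop_IV_with_inpatient_code` and
#'   `prop_remaining_with_2plus_outpatient`.
#' @export
inpatientEvidenceSummary <- function(staged_cases, bundle,
                                     code_lists = codeLists()) {
  iv <- staged_cases[staged_cases$stage == "IV", ]
  if (nrow(iv) == 0) {
    return(list(prop_IV_with_inpatient_code = NA_real_,
                prop_remaining_with_2plus_outpatient = NA_real_))
  }
  nfq <- iv$staging_window_quarters[1]
  rec <- staging_records(bundle, code_lists)
  rec <- rec[rec$distant, ]
  entry <- tibble::tibble(person_id = iv$person_id,
                          entry_qi = q_index(iv$calendar_year,
                                             iv$entry_quarter))
  hits <- dplyr::filter(
    dplyr::inner_join(rec, entry, by = "person_id"),
    .data$qi >= .data$entry_qi, .data$qi <= .data$entry_qi + nfq
  )
  agg <- dplyr::summarise(dplyr::group_by(hits, .data$person_id),
                          has_inpat = any(.data$inpatient),
                          n_outpat = sum(!.data$inpatient), .groups = "drop")
  agg <- dplyr::left_join(entry["person_id"], agg, by = "person_id")
  has_inpat <- !is.na(agg$has_inpat) & agg$has_inpat
  p1 <- mean(has_inpat)
  rem <- agg[!has_inpat, ]
  p2 <- if (nrow(rem) == 0) NA_real_ else {
    mean(!is.na(rem$n_outpat) & rem$n_outpat >= 2)
  }
  list(prop_IV_with_inpatient_code = p1,
       prop_remaining_with_2plus_outpatient = p2)
}

#' Medication cross-check of the non-advanced classification
#'
#' Counts the cases classified as non-advanced that nevertheless received a
#' drug essentially only given in advanced CRC (e.g. bevacizumab) within
#' `window_days` days after cohort entry -- a rough upper bound on how many
#' advanced cancers the diagnosis-code algorithm misses. The printed
#' percentage uses the full CRC subsample as denominator by default; set
#' `denominator = "non_advanced"` to relate the flagged count to the
#' non-advanced cases instead.
#'
#' @param staged_cases Output of [stageCases()] for the subsample with
#'   medication data.
#' @param dispensations Dispensation table (`person_id`, `date`,
#'   `agent_code`).
#' @param code_lists A [codeLists()] object (supplies
#'   `advanced_therapy_codes`).
#' @param window_days Days after entry in which a dispensation counts.
#' @param denominator `"subsample"` (default) or `"non_advanced"`.
#' @return List with `n_subsample`, `n_non_advanced`, `n_flagged`,
#'   `pct_of_subsample` (rounded to two decimals, half away from zero).
#' @export
medicationCrosscheck <- function(staged_cases, dispensations,
                                 code_lists = codeLists(), window_days = 90,
                                 denominator = c("subsample", "non_advanced")) {
  denominator <- match.arg(denominator)
  if (nrow(staged_cases) == 0) {
    stop("empty CRC subsample", call. = FALSE)
  }
  na_cases <- staged_cases[staged_cases$stage == "non_advanced", ]
  d <- dispensations[matches_prefix(dispensations$agent_code,
                                    code_lists$advanced_therapy_codes), ]
  hits <- dplyr::inner_join(
    na_cases[, c("person_id", "cohort_entry_date")], d,
    by = "person_id", relationship = "many-to-many"
  )
  hits <- hits[hits$date >= hits$cohort_entry_date &
                 hits$date <= hits$cohort_entry_date + window_days, ]
  n_flagged <- dplyr::n_distinct(hits$person_id)
  n_den <- if (denominator == "subsample") nrow(staged_cases) else nrow(na_cases)
  list(
    n_subsample = nrow(staged_cases),
    n_non_advanced = nrow(na_cases),
    n_flagged = n_flagged,
    pct_of_subsample = round_half_away(100 * n_flagged / n_den, 2)
  )
}

#' Run the claims pipeline over several years
#'
#' Convenience wrapper: ascertains and stages incident cases and collects
#' eligible-person denominators for each year in `years`.
#'
#' @param bundle A [claimsBundle()].
#' @param years Calendar years to analyse.
#' @param code_lists A [codeLists()] object.
#' @param n_following_quarters Staging window (see [stageCases()]).
#' @param ... Passed on to [identifyIncidentCases()] and
#'   [eligiblePersons()] (`lookback_years`, `max_gap_days`, `min_age`).
#' @return List with `staged_cases` and `denominators` tibbles.
#' @export
claimsPipeline <- function(bundle, years, code_lists = codeLists(),
                           n_following_quarters = 1, lookback_years = 4,
                           max_gap_days = 15, min_age = 5) {
  staged <- list()
  denoms <- list()
  for (y in years) {
    cases <- identifyIncidentCases(bundle, y, code_lists,
                                   lookback_years = lookback_years,
                                   max_gap_days = max_gap_days,
                                   min_age = min_age)
    staged[[as.character(y)]] <- stageCases(cases, bundle, code_lists,
                                            n_following_quarters)
    denoms[[as.character(y)]] <- eligiblePersons(bundle$persons,
                                                 bundle$spells, y,
                                                 lookback_years = lookback_years,
                                                 max_gap_days = max_gap_days,
                                                 min_age = min_age)
  }
  list(staged_cases = dplyr::bind_rows(staged),
       denominators = dplyr::bind_rows(denoms))
}
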