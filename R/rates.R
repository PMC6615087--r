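#' Old European Standard Population weights
#'
#' The 1976 ("old") European Standard Population on 18 five-year age bands
#' (0--4, 5--9, ..., 80--84, 85+), expressed per 100,000 and summing to
#' 100,000. These are the weights used for direct age standardization of all
#' incidence rates in this package.
#'
#' @return Named numeric vector of length 18 (names are the age-band labels).
#' @examples
#' sum(espWeights())  # 100000
#' @export
espWeights <- function() {
  w <- c(8000, 7000, 7000, 7000, 7000, 7000, 7000, 7000, 7000, 7000,
         7000, 6000, 5000, 4000, 3000, 2000, 1000, 1000)
  names(w) <- ageBandLabels()
  w
}

#' Age-band labels
#'
#' @return Character vector of the 18 five-year band labels ("0-4" ... "85+").
#' @export
ageBandLabels <- function() {
  c(paste(seq(0, 80, by = 5), seq(4, 84, by = 5), sep = "-"), "85+")
}

#' Five-year age band index
#'
#' Maps an age in years to the index (0--17) of its five-year band; ages 85
#' and above fall in the open-ended terminal band.
#'
#' @param age Age(s) in completed years; must be non-negative.
#' @return Integer band index (0 = ages 0--4, ..., 17 = ages 85+).
#' @examples
#' ageBand(c(0, 67, 84, 85))
#' @export
ageBand <- function(age) {
  if (anyNA(age) || any(age < 0)) {
    stop("`age` must be non-negative and non-missing", call. = FALSE)
  }
  pmin(as.integer(age) %/% 5L, 17L)
}

#' Directly age-standardized rate per 100,000
#'
#' Computes the age-standardized incidence rate from 18 band-specific case
#' counts and person denominators,
#' \deqn{ASIR = \frac{\sum_b w_b (c_b/n_b)}{\sum_b w_b} \times 100{,}000,}
#' where \eqn{w_b} are the standard-population weights. Bands with zero
#' denominator and zero cases contribute zero; a band with cases but no
#' denominator is an error.
#'
#' @param cases Integer vector of length 18: case counts per age band.
#' @param denominators Numeric vector of length 18: persons per age band.
#' @param weights Standard weights, default [espWeights()].
#' @return The ASIR per 100,000 (single number, full precision).
#' @examples
#' w <- c(7000, 3000, rep(0, 16))
#' asir(c(10, 20, rep(0, 16)), c(1e5, 1e5, rep(0, 16)), espWeights())
#' @export
asir <- function(cases, denominators, weights = espWeights()) {
  stopifnot(length(cases) == 18, length(denominators) == 18,
            length(weights) == 18)
  if (any(weights <= 0)) stop("standard weights must be positive", call. = FALSE)
  bad <- cases > 0 & denominators <= 0
  if (any(bad)) {
    stop("age band ", paste(which(bad) - 1L, collapse = ", "),
         " has cases but a zero person denominator", call. = FALSE)
  }
  r <- ifelse(denominators > 0, cases / denominators * 1e5, 0)
  sum(weights * r) / sum(weights)
}

#' Crude and age-standardized rate table
#'
#' Tabulates case counts, person denominators, crude rates and ASIRs per
#' 100,000 for every combination of calendar year, sex and stage (or registry
#' class) present in `cases`.
#'
#' @param cases Tibble with one row per case and columns `year`, `sex`,
#'   `stage`, `age_band` (0--17); see [caseStrata()] and [registryStrata()].
#' @param denominators Tibble with columns `year`, `sex`, `age_band`,
#'   `person_count` (from [eligiblePersons()] or [populationDenominators()]).
#' @param weights Standard-population weights, default [espWeights()].
#' @return Tibble with columns `year`, `sex`, `stage`, `case_count`,
#'   `person_denominator`, `crude_rate`, `asir` (rates per 100,000, full
#'   precision).
#' @export
rateTable <- function(cases, denominators, weights = espWeights()) {
  stopifnot(all(c("year", "sex", "stage", "age_band") %in% names(cases)),
            all(c("year", "sex", "age_band", "person_count") %in% names(denominators)))

  need <- dplyr::distinct(cases, .data$year, .data$sex)
  have <- dplyr::distinct(denominators, .data$year, .data$sex)
  miss <- dplyr::anti_join(need, have, by = c("year", "sex"))
  if (nrow(miss) > 0) {
    stop("no denominator stratum for year=", miss$year[1], ", sex=",
         miss$sex[1], call. = FALSE)
  }

  strata <- tidyr::expand_grid(
    dplyr::distinct(cases, .data$year, .data$sex, .data$stage),
    age_band = 0:17
  )
  counts <- dplyr::count(cases, .data$year, .data$sex, .data$stage,
                         .data$age_band, name = "case_count")
  tab <- dplyr::left_join(strata, counts,
                          by = c("year", "sex", "stage", "age_band"))
  tab$case_count[is.na(tab$case_count)] <- 0L
  tab <- dplyr::left_join(
    tab,
    denominators[, c("year", "sex", "age_band", "person_count")],
    by = c("year", "sex", "age_band")
  )
  tab$person_count[is.na(tab$person_count)] <- 0

  out <- dplyr::reframe(
    dplyr::group_by(dplyr::arrange(tab, .data$age_band),
                    .data$year, .data$sex, .data$stage),
    asir = asir(.data$case_count, .data$person_count, weights),
    crude_rate = 1e5 * sum(.data$case_count) / sum(.data$person_count),
    person_denominator = sum(.data$person_count),
    case_count = sum(.data$case_count)
  )
  out[, c("year", "sex", "stage", "case_count", "person_denominator",
          "crude_rate", "asir")]
}

#' Case strata for rate computation (claims pipeline)
#'
#' Reduces staged claims cases to the year x sex x stage x age-band rows that
#' [rateTable()] consumes. Ages are attained ages in the entry year, matching
#' the denominator convention. With `add_advanced = TRUE`, stage III and IV
#' rows are duplicated under the aggregate label `"advanced"` so that rates
#' for advanced CRC overall can be tabulated alongside the stage-specific
#' ones.
#'
#' @param staged_cases Output of [stageCases()].
#' @param add_advanced Also emit an `"advanced"` aggregate stratum.
#' @return Tibble with columns `year`, `sex`, `stage`, `age_band`.
#' @export
caseStrata <- function(staged_cases, add_advanced = TRUE) {
  out <- tibble::tibble(
    year = staged_cases$calendar_year,
    sex = staged_cases$sex,
    stage = staged_cases$stage,
    age_band = ageBand(staged_cases$age_at_entry)
  )
  if (add_advanced) {
    adv <- out[out$stage %in% c("III", "IV"), ]
    if (nrow(adv) > 0) adv$stage <- "advanced"
    out <- dplyr::bind_rows(out, adv)
  }
  out
}

#' Full-population denominators by year, sex and age band
#'
#' Counts all simulated persons per calendar year, sex and attained-age band,
#' the denominator concept used for registry-based rates (inhabitants, no
#' insurance-continuity requirement).
#'
#' @param persons Persons table with `sex` and `birth_year`.
#' @param years Calendar years to tabulate.
#' @return Tibble with columns `year`, `sex`, `age_band`, `person_count`
#'   (complete grid, zero-filled).
#' @export
populationDenominators <- function(persons, years) {
  grid <- tidyr::expand_grid(year = as.integer(years),
                             sex = c("male", "female"), age_band = 0:17)
  rows <- tidyr::expand_grid(year = as.integer(years),
                             idx = seq_len(nrow(persons)))
  rows$sex <- persons$sex[rows$idx]
  rows$age <- attainedAge(rows$year, persons$birth_year[rows$idx])
  rows <- rows[rows$age >= 0, ]
  rows$age_band <- ageBand(rows$age)
  counts <- dplyr::count(rows, .data$year, .data$sex, .data$age_band,
                         name = "person_count")
  out <- dplyr::left_join(grid, counts, by = c("year", "sex", "age_band"))
  out$person_count[is.na(out$person_count)] <- 0L
  out
}
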