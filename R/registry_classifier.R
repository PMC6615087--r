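#' Registry stage classes
#'
#' The five classes a registry tumor record can receive from its recorded
#' N and M status.
#'
#' @return Character vector of the class labels.
#' @export
registryClasses <- function() {
  c("non_advanced", "advanced_III", "advanced_IV",
    "advanced_unstratifiable", "not_classifiable")
}

#' Classify registry records from N and M status
#'
#' Assigns each tumor record one of five classes based solely on the recorded
#' nodal (N) and metastasis (M) status, with missingness explicit:
#'
#' * `M1` (any N) -> `advanced_IV`: distant metastases present.
#' * `N_plus` and `M0` -> `advanced_III`: regional nodes only.
#' * `N_plus` and M missing -> `advanced_unstratifiable`: advanced, but III
#'   vs IV cannot be resolved.
#' * `N0` and `M0` -> `non_advanced`.
#' * Anything else (N missing with M not M1, or N0 with M missing) ->
#'   `not_classifiable`.
#'
#' T status plays no role: advanced vs non-advanced is defined by nodes and
#' metastases only. The function is total: every record receives exactly one
#' class.
#'
#' @param records Tibble of registry records with columns `n_status`
#'   (`"N0"`, `"N_plus"`, `"missing"`) and `m_status` (`"M0"`, `"M1"`,
#'   `"missing"`).
#' @return The input with a `cls` column added (one of [registryClasses()]).
#' @examples
#' r <- tibble::tibble(record_id = 1:3,
#'                     n_status = c("N0", "N_plus", "missing"),
#'                     m_status = c("M0", "missing", "M0"))
#' classifyTnm(r)$cls
#' @export
classifyTnm <- function(records) {
  stopifnot(all(c("n_status", "m_status") %in% names(records)))
  n <- records$n_status
  m <- records$m_status
  if (!all(n %in% c("N0", "N_plus", "missing"))) {
    stop("n_status must be one of 'N0', 'N_plus', 'missing'", call. = FALSE)
  }
  if (!all(m %in% c("M0", "M1", "missing"))) {
    stop("m_status must be one of 'M0', 'M1', 'missing'", call. = FALSE)
  }
  records$cls <- dplyr::case_when(
    m == "M1" ~ "advanced_IV",
    n == "N_plus" & m == "M0" ~ "advanced_III",
    n == "N_plus" & m == "missing" ~ "advanced_unstratifiable",
    n == "N0" & m == "M0" ~ "non_advanced",
    TRUE ~ "not_classifiable"
  )
  records
}

#' Tabulate registry classes by stratum
#'
#' Counts and within-stratum proportions of the five registry classes, by
#' default per diagnosis year and sex. Proportions sum to one within each
#' stratum; empty strata report zero counts and `NA` proportions.
#'
#' @param classified Output of [classifyTnm()].
#' @param by Character vector of stratum columns (default
#'   `c("diagnosis_year", "sex")`).
#' @return Tibble with the stratum columns, `cls`, `count`, `proportion`
#'   (complete over classes within each observed stratum).
#' @export
tabulateClasses <- function(classified, by = c("diagnosis_year", "sex")) {
  stopifnot("cls" %in% names(classified), all(by %in% names(classified)))
  counts <- dplyr::count(classified, dplyr::across(dplyr::all_of(by)),
                         .data$cls, name = "count")
  grid <- tidyr::expand_grid(
    dplyr::distinct(classified, dplyr::across(dplyr::all_of(by))),
    cls = registryClasses()
  )
  out <- dplyr::left_join(grid, counts, by = c(by, "cls"))
  out$count[is.na(out$count)] <- 0L
  out <- dplyr::mutate(dplyr::group_by(out, dplyr::across(dplyr::all_of(by))),
                       total = sum(.data$count))
  out <- dplyr::ungroup(out)
  out$proportion <- ifelse(out$total > 0, out$count / out$total, NA_real_)
  out$total <- NULL
  out
}

#' Missing-data scenarios for registry classes
#'
#' Reclassifies registry records under one of the enumerated assumptions
#' about records with incomplete N/M information:
#'
#' * `as_observed`: identity; classes as recorded.
#' * `drop_nonclassifiable`: removes `not_classifiable` records from the case
#'   counts (population denominators are left untouched).
#' * `nonclassifiable_as_nonadvanced`: assumes every not-classifiable tumor
#'   was in fact non-advanced.
#' * `unstratifiable_as_IV`: the extreme assumption that every advanced tumor
#'   that could not be split into III vs IV was stage IV.
#'
#' @param classified Output of [classifyTnm()].
#' @param scenario One of the four scenario names.
#' @return The reclassified (possibly row-filtered) tibble.
#' @export
applyScenario <- function(classified,
                          scenario = c("as_observed", "drop_nonclassifiable",
                                       "nonclassifiable_as_nonadvanced",
                                       "unstratifiable_as_IV")) {
  stopifnot("cls" %in% names(classified))
  scenario <- match.arg(scenario)
  switch(
    scenario,
    as_observed = classified,
    drop_nonclassifiable = classified[classified$cls != "not_classifiable", ],
    nonclassifiable_as_nonadvanced = {
      classified$cls[classified$cls == "not_classifiable"] <- "non_advanced"
      classified
    },
    unstratifiable_as_IV = {
      classified$cls[classified$cls == "advanced_unstratifiable"] <- "advanced_IV"
      classified
    }
  )
}

#' Case strata for rate computation (registry pipeline)
#'
#' Reduces classified registry records to year x sex x stage x age-band rows
#' for [rateTable()]. Classes are mapped onto the stage labels used on the
#' claims side (`advanced_III` -> `"III"`, `advanced_IV` -> `"IV"`); with
#' `add_advanced = TRUE` an `"advanced"` aggregate is added comprising III,
#' IV and the unstratifiable-advanced records.
#'
#' @param classified Output of [classifyTnm()] (optionally after
#'   [applyScenario()]).
#' @param add_advanced Also emit the `"advanced"` aggregate stratum.
#' @return Tibble with columns `year`, `sex`, `stage`, `age_band`.
#' @export
registryStrata <- function(classified, add_advanced = TRUE) {
  stopifnot(all(c("cls", "sex", "diagnosis_year", "age_at_diagnosis")
                %in% names(classified)))
  stage <- dplyr::recode(classified$cls,
                         advanced_III = "III", advanced_IV = "IV")
  out <- tibble::tibble(
    year = classified$diagnosis_year,
    sex = classified$sex,
    stage = stage,
    age_band = ageBand(classified$age_at_diagnosis)
  )
  if (add_advanced) {
    adv <- out[out$stage %in% c("III", "IV", "advanced_unstratifiable"), ]
    if (nrow(adv) > 0) adv$stage <- "advanced"
    out <- dplyr::bind_rows(out, adv)
  }
  out
}
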