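#' Default population age structure
#'
#' Relative weights of the 18 five-year age bands used to draw ages at the
#' start of the simulated period. The shape approximates the German adult-
#' heavy population pyramid (mean age in the mid-40s).
#'
#' @return Numeric vector of length 18 summing to 1.
#' @export
defaultAgeBandWeights <- function() {
  w <- c(4.2, 4.5, 4.8, 5.3, 5.8, 6.2, 6.0, 5.8, 6.8, 8.2,
         8.4, 7.2, 5.7, 5.0, 5.6, 4.4, 2.9, 3.2)
  w / sum(w)
}

#' Default stage-specific CRC incidence schedule
#'
#' Annual colorectal-cancer incidence per 100,000 person-years by five-year
#' age band, sex and stage at diagnosis (`non_advanced`, `III`, `IV`). The
#' age shape is the steep exponential rise typical of CRC (essentially zero
#' before age 20); the stage- and sex-specific levels are scaled so that the
#' resulting age-standardized rates (old European Standard Population) match
#' the claims-based 2008 benchmark values: per 100,000, stage IV 15.2 (men)
#' and 10.4 (women), stage III 6.4 and 4.0, non-advanced 38 and 23.
#'
#' @return Tibble with columns `age_band` (0--17), `sex`, `stage`,
#'   `rate_per_100k`.
#' @export
defaultIncidence <- function() {
  shape <- c(0, 0, 0, 0, 0.2, 0.4, 0.8, 1.5, 3, 6,
             11, 19, 32, 52, 78, 105, 130, 145)
  w <- espWeights()
  std_of_shape <- sum(w * shape) / sum(w)
  targets <- tibble::tribble(
    ~sex, ~stage, ~target_asir,
    "male", "non_advanced", 38.0,
    "male", "III", 6.4,
    "male", "IV", 15.2,
    "female", "non_advanced", 23.0,
    "female", "III", 4.0,
    "female", "IV", 10.4
  )
  out <- tidyr::expand_grid(targets, age_band = 0:17)
  out$rate_per_100k <- shape[out$age_band + 1L] *
    out$target_asir / std_of_shape
  out[, c("age_band", "sex", "stage", "rate_per_100k")]
}

#' Simulation configuration
#'
#' Collects and validates every parameter of the synthetic claims + registry
#' generator. The generator emulates the structure of German statutory
#' health-insurance claims (quarter-granular outpatient diagnoses with a
#' certainty flag, exact-dated inpatient discharge diagnoses, insurance
#' gaps) and of population-based cancer-registry TNM reporting (pathologist-
#' only notifications, premature M0, independent N/M missingness), with a
#' known ground truth for every simulated cancer.
#'
#' @param n_persons Number of persons.
#' @param year_range Length-2 integer vector, first and last simulated
#'   calendar year (claims analyses start 4 years in, after the look-back).
#' @param sex_prob_female Probability a person is female.
#' @param age_band_weights Length-18 age-band weights for ages at the start
#'   of the period (normalized internally).
#' @param incidence Tibble `age_band`, `sex`, `stage`, `rate_per_100k`:
#'   annual stage-specific incidence per 100,000 person-years.
#' @param iv_annual_trend Multiplicative annual change of stage-IV incidence
#'   relative to the first analysis year (default -2.3%/year, reproducing the
#'   observed 15--18% decline in metastatic CRC over 2008--2015).
#' @param prevalent_fraction Fraction of cancers that are prevalent, i.e.
#'   diagnosed before the simulated period.
#' @param p_confirmation_code Probability that an incident cancer gets an
#'   additional (confirmatory) CRC code within the entry quarter or the two
#'   following quarters.
#' @param confirmation_lag_probs Length-3 probabilities of a confirmation lag
#'   of 0, 1 or 2 quarters.
#' @param p_initial_inpatient Probability the initial CRC code is an
#'   inpatient (main) discharge diagnosis rather than an outpatient code.
#' @param p_c77_given_III Probability a true stage-III cancer emits a C77
#'   (lymph node) code.
#' @param p_c78_given_IV Probability a true stage-IV cancer emits a C78/C79
#'   (distant metastasis) code.
#' @param p_c77_given_IV Probability a true stage-IV cancer additionally
#'   emits a C77 code.
#' @param stage_code_lag_probs Length-3 probabilities that a C77/C78--C79
#'   code lags the entry quarter by 0, 1 or 2 quarters.
#' @param p_inpatient_metastasis_code Probability a stage-IV metastasis code
#'   is recorded as an inpatient discharge diagnosis.
#' @param p_second_outpatient_metastasis_code Probability that an outpatient-
#'   only metastasis coding is duplicated (second confirmed outpatient
#'   record).
#' @param p_gap Probability a person has one insurance interruption.
#' @param gap_mean_days Mean length (days) of an insurance interruption.
#' @param p_prevalent_recode Per-year probability a prevalent cancer gets a
#'   "status post" outpatient CRC code.
#' @param noise_dx_per_person_year Expected number of non-cancer outpatient
#'   noise diagnoses per person-year.
#' @param suspected_crc_per_person_year Expected number of outpatient CRC
#'   codes with certainty "suspected" (diagnostic work-ups) per person-year.
#' @param p_admission_code Probability an incident cancer also leaves an
#'   inpatient admission-position CRC code (ignored by the algorithm).
#' @param p_advanced_therapy Probability a true stage-IV cancer receives an
#'   advanced-CRC agent (e.g. bevacizumab) dispensation.
#' @param therapy_window_days Days after diagnosis within which that
#'   dispensation occurs.
#' @param reporting_completeness Probability a cancer is reported to the
#'   registry.
#' @param p_pathologist_only Probability a registry report comes from a
#'   pathologist only, leaving both N and M status missing.
#' @param p_premature_M0 Probability a true stage-IV cancer is reported M0
#'   (metastasis work-up not completed at notification), N recorded
#'   correctly.
#' @param p_N_missing,p_M_missing Independent missingness of the N / M
#'   status, applied after the mechanisms above.
#' @param rng_seed Mandatory integer seed; every generator draw derives from
#'   it, so identical configurations give identical data.
#' @return Validated object of class `sim_config` (a named list).
#' @export
simConfig <- function(n_persons = 100000,
                      year_range = c(2004L, 2015L),
                      sex_prob_female = 0.51,
                      age_band_weights = defaultAgeBandWeights(),
                      incidence = defaultIncidence(),
                      iv_annual_trend = -0.023,
                      prevalent_fraction = 0.15,
                      p_confirmation_code = 0.9,
                      confirmation_lag_probs = c(0.5, 0.3, 0.2),
                      p_initial_inpatient = 0.6,
                      p_c77_given_III = 0.85,
                      p_c78_given_IV = 0.95,
                      p_c77_given_IV = 0.3,
                      stage_code_lag_probs = c(0.7, 0.2, 0.1),
                      p_inpatient_metastasis_code = 0.85,
                      p_second_outpatient_metastasis_code = 0.67,
                      p_gap = 0.05,
                      gap_mean_days = 30,
                      p_prevalent_recode = 0.7,
                      noise_dx_per_person_year = 0.3,
                      suspected_crc_per_person_year = 0.001,
                      p_admission_code = 0.2,
                      p_advanced_therapy = 0.6,
                      therapy_window_days = 90,
                      reporting_completeness = 0.95,
                      p_pathologist_only = 0.1,
                      p_premature_M0 = 0.1,
                      p_N_missing = 0.1,
                      p_M_missing = 0.1,
                      rng_seed) {
  if (missing(rng_seed) || is.null(rng_seed)) {
    stop("`rng_seed` is mandatory", call. = FALSE)
  }
  cfg <- list(
    n_persons = as.integer(n_persons),
    year_range = as.integer(year_range),
    sex_prob_female = sex_prob_female,
    age_band_weights = age_band_weights / sum(age_band_weights),
    incidence = incidence,
    iv_annual_trend = iv_annual_trend,
    prevalent_fraction = prevalent_fraction,
    p_confirmation_code = p_confirmation_code,
    confirmation_lag_probs = confirmation_lag_probs / sum(confirmation_lag_probs),
    p_initial_inpatient = p_initial_inpatient,
    p_c77_given_III = p_c77_given_III,
    p_c78_given_IV = p_c78_given_IV,
    p_c77_given_IV = p_c77_given_IV,
    stage_code_lag_probs = stage_code_lag_probs / sum(stage_code_lag_probs),
    p_inpatient_metastasis_code = p_inpatient_metastasis_code,
    p_second_outpatient_metastasis_code = p_second_outpatient_metastasis_code,
    p_gap = p_gap,
    gap_mean_days = gap_mean_days,
    p_prevalent_recode = p_prevalent_recode,
    noise_dx_per_person_year = noise_dx_per_person_year,
    suspected_crc_per_person_year = suspected_crc_per_person_year,
    p_admission_code = p_admission_code,
    p_advanced_therapy = p_advanced_therapy,
    therapy_window_days = as.integer(therapy_window_days),
    reporting_completeness = reporting_completeness,
    p_pathologist_only = p_pathologist_only,
    p_premature_M0 = p_premature_M0,
    p_N_missing = p_N_missing,
    p_M_missing = p_M_missing,
    rng_seed = as.integer(rng_seed)
  )
  validateSimConfig(cfg)
  structure(cfg, class = "sim_config")
}

validateSimConfig <- function(cfg) {
  prob_fields <- c("sex_prob_female", "prevalent_fraction",
                   "p_confirmation_code", "p_initial_inpatient",
                   "p_c77_given_III", "p_c78_given_IV", "p_c77_given_IV",
                   "p_inpatient_metastasis_code",
                   "p_second_outpatient_metastasis_code", "p_gap",
                   "p_prevalent_recode", "p_admission_code",
                   "p_advanced_therapy", "reporting_completeness",
                   "p_pathologist_only", "p_premature_M0",
                   "p_N_missing", "p_M_missing")
  for (f in prob_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("invalid config field `", f, "`: must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (cfg$n_persons < 1) {
    stop("invalid config field `n_persons`: must be >= 1", call. = FALSE)
  }
  if (length(cfg$year_range) != 2 || cfg$year_range[1] > cfg$year_range[2]) {
    stop("invalid config field `year_range`: need c(first, last) with first <= last",
         call. = FALSE)
  }
  if (length(cfg$age_band_weights) != 18 || any(cfg$age_band_weights < 0)) {
    stop("invalid config field `age_band_weights`: need 18 non-negative weights",
         call. = FALSE)
  }
  inc <- cfg$incidence
  need <- c("age_band", "sex", "stage", "rate_per_100k")
  if (!is.data.frame(inc) || !all(need %in% names(inc))) {
    stop("invalid config field `incidence`: need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(inc$rate_per_100k < 0)) {
    stop("invalid config field `incidence`: rates must be >= 0", call. = FALSE)
  }
  if (!all(inc$stage %in% c("non_advanced", "III", "IV"))) {
    stop("invalid config field `incidence`: stage must be non_advanced/III/IV",
         call. = FALSE)
  }
  for (f in c("confirmation_lag_probs", "stage_code_lag_probs")) {
    v <- cfg[[f]]
    if (length(v) != 3 || any(v < 0)) {
      stop("invalid config field `", f, "`: need 3 non-negative probabilities",
           call. = FALSE)
    }
  }
  if (cfg$gap_mean_days < 1) {
    stop("invalid config field `gap_mean_days`: must be >= 1", call. = FALSE)
  }
  if (is.na(cfg$rng_seed)) {
    stop("invalid config field `rng_seed`: must be an integer", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic claims/registry configuration\n")
  cat("  persons:", x$n_persons, " years:", x$year_range[1], "-",
      x$year_range[2], " seed:", x$rng_seed, "\n")
  cat("  prevalent fraction:", x$prevalent_fraction,
      " confirmation p:", x$p_confirmation_code, "\n")
  cat("  registry: pathologist-only", x$p_pathologist_only,
      ", premature M0", x$p_premature_M0, "\n")
  invisible(x)
}

# Independent deterministic sub-seed per generator stage, so each stage is
# reproducible on its own from the configured seed.
op_seed <- function(cfg, k) (cfg$rng_seed + 104729L * k) %% .Machine$integer.max

# First analysis year: the first year with a full 4-year look-back behind it
# (also the reference year of the stage-IV incidence trend).
reference_year <- function(cfg) cfg$year_range[1] + 4L
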