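# Shared simulation configurations for the tests.

# flat stage-specific incidence (per 100,000 person-years) across all age
# bands and both sexes
flat_incidence <- function(non_advanced = 30, III = 10, IV = 10) {
  tidyr::expand_grid(age_band = 0:17, sex = c("male", "female"),
                     stage = c("non_advanced", "III", "IV")) |>
    dplyr::mutate(rate_per_100k = dplyr::case_when(
      stage == "non_advanced" ~ non_advanced,
      stage == "III" ~ III,
      TRUE ~ IV
    ))
}

# perfect-coding configuration: every non-prevalent cancer is fully and
# immediately coded, no gaps, no noise, faithful registry
perfect_config <- function(n = 5000, years = c(2004, 2008), seed = 1,
                           incidence = flat_incidence(), ...) {
  simConfig(
    n_persons = n, year_range = years, rng_seed = seed,
    incidence = incidence, iv_annual_trend = 0,
    prevalent_fraction = 0,
    p_confirmation_code = 1, confirmation_lag_probs = c(1, 0, 0),
    p_c77_given_III = 1, p_c78_given_IV = 1, p_c77_given_IV = 0,
    stage_code_lag_probs = c(1, 0, 0),
    p_gap = 0, noise_dx_per_person_year = 0,
    suspected_crc_per_person_year = 0, p_admission_code = 0,
    reporting_completeness = 1, p_pathologist_only = 0,
    p_premature_M0 = 0, p_N_missing = 0, p_M_missing = 0,
    ...
  )
}

# small messy configuration exercising all mechanisms at once
messy_config <- function(n = 200, years = c(2004, 2009), seed = 1, ...) {
  simConfig(
    n_persons = n, year_range = years, rng_seed = seed,
    incidence = flat_incidence(300, 150, 150),
    prevalent_fraction = 0.3, p_confirmation_code = 0.8,
    confirmation_lag_probs = c(0.4, 0.3, 0.3),
    p_c77_given_III = 0.8, p_c78_given_IV = 0.9, p_c77_given_IV = 0.4,
    stage_code_lag_probs = c(0.5, 0.3, 0.2),
    p_gap = 0.2, gap_mean_days = 60,
    suspected_crc_per_person_year = 0.02,
    noise_dx_per_person_year = 0.5,
    ...
  )
}
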