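#' Simulate the insured population
#'
#' Draws persons (sex, birth year) and their insurance spells over the
#' configured calendar range. Every person is covered from the first to the
#' last simulated day except for at most one simulated insurance
#' interruption (probability `p_gap`, geometric length with mean
#' `gap_mean_days`). Ages are drawn from the configured age-band weights at
#' the first simulated year.
#'
#' @param config A [simConfig()] object.
#' @return List with tibbles `persons` (`person_id`, `sex`, `birth_year`)
#'   and `spells` (`person_id`, `start_date`, `end_date`; sorted,
#'   non-overlapping).
#' @export
simulatePopulation <- function(config) {
  validateSimConfig(config)
  set.seed(op_seed(config, 1L))
  n <- config$n_persons
  yr <- config$year_range

  sex <- ifelse(stats::runif(n) < config$sex_prob_female, "female", "male")
  band <- sample(0:17, n, replace = TRUE, prob = config$age_band_weights)
  within5 <- sample.int(5L, n, replace = TRUE) - 1L
  within10 <- sample.int(10L, n, replace = TRUE) - 1L
  age0 <- band * 5L + ifelse(band == 17L, within10, within5)
  persons <- tibble::tibble(
    person_id = seq_len(n),
    sex = sex,
    birth_year = yr[1] - age0
  )

  range_start <- as.Date(sprintf("%d-01-01", yr[1]))
  range_end <- as.Date(sprintf("%d-12-31", yr[2]))
  span <- as.integer(range_end - range_start) + 1L

  has_gap <- stats::runif(n) < config$p_gap
  gap_off <- floor(stats::runif(n) * span)
  gap_len <- stats::rgeom(n, 1 / config$gap_mean_days) + 1L
  gap_start <- range_start + gap_off
  gap_end <- pmin(gap_start + gap_len - 1L, range_end)

  left <- tibble::tibble(person_id = persons$person_id,
                         start_date = range_start,
                         end_date = dplyr::if_else(has_gap, gap_start - 1L,
                                                   range_end))
  right <- tibble::tibble(person_id = persons$person_id[has_gap],
                          start_date = gap_end[has_gap] + 1L,
                          end_date = range_end)
  spells <- dplyr::bind_rows(left, right)
  spells <- spells[spells$start_date <= spells$end_date, ]
  spells <- dplyr::arrange(spells, .data$person_id, .data$start_date)

  list(persons = persons, spells = spells)
}

#' Simulate ground-truth cancer events
#'
#' Draws at most one colorectal cancer per person from the configured
#' age-, sex- and stage-specific annual incidence (per 100,000 person-years;
#' the stage-IV schedule additionally follows the configured annual trend).
#' A configured fraction of cancers is made prevalent by relocating the
#' diagnosis to the three years before the simulated period.
#'
#' @param persons Persons table from [simulatePopulation()].
#' @param config The [simConfig()] object.
#' @return Tibble of events: `person_id`, `sex`, `birth_year`,
#'   `diagnosis_date`, `diagnosis_year`, `true_stage` (`non_advanced`,
#'   `III`, `IV`), `prevalent_flag`.
#' @export
simulateEvents <- function(persons, config) {
  validateSimConfig(config)
  set.seed(op_seed(config, 2L))
  yr <- config$year_range
  years <- yr[1]:yr[2]
  ref <- reference_year(config)

  inc <- tidyr::pivot_wider(config$incidence, names_from = "stage",
                            values_from = "rate_per_100k", values_fill = 0)
  for (s in c("non_advanced", "III", "IV")) {
    if (!s %in% names(inc)) inc[[s]] <- 0
  }

  grid <- tidyr::expand_grid(idx = seq_len(nrow(persons)), year = years)
  grid$person_id <- persons$person_id[grid$idx]
  grid$sex <- persons$sex[grid$idx]
  grid$birth_year <- persons$birth_year[grid$idx]
  grid$age_band <- ageBand(pmax(attainedAge(grid$year, grid$birth_year), 0L))
  grid <- dplyr::left_join(grid, inc, by = c("age_band", "sex"))
  grid$IV <- grid$IV * (1 + config$iv_annual_trend)^(grid$year - ref)
  lambda <- (grid$non_advanced + grid$III + grid$IV) / 1e5
  hit <- stats::runif(nrow(grid)) < 1 - exp(-lambda)

  ev <- grid[hit, ]
  ev <- dplyr::distinct(dplyr::arrange(ev, .data$person_id, .data$year),
                        .data$person_id, .keep_all = TRUE)
  if (nrow(ev) == 0) {
    return(tibble::tibble(person_id = integer(), sex = character(),
                          birth_year = integer(),
                          diagnosis_date = as.Date(character()),
                          diagnosis_year = integer(),
                          true_stage = character(), prevalent_flag = logical()))
  }

  tot <- ev$non_advanced + ev$III + ev$IV
  u <- stats::runif(nrow(ev)) * tot
  stage <- ifelse(u < ev$non_advanced, "non_advanced",
                  ifelse(u < ev$non_advanced + ev$III, "III", "IV"))

  year_start <- as.Date(sprintf("%d-01-01", ev$year))
  ndays <- as.integer(as.Date(sprintf("%d-01-01", ev$year + 1L)) - year_start)
  date <- year_start + floor(stats::runif(nrow(ev)) * ndays)

  range_start <- as.Date(sprintf("%d-01-01", yr[1]))
  prev <- stats::runif(nrow(ev)) < config$prevalent_fraction
  prev_date <- range_start - 1L - floor(stats::runif(nrow(ev)) * 1095)
  # a cancer cannot predate its person's birth year
  prev_ok <- as.integer(format(prev_date, "%Y")) >= ev$birth_year
  prev <- prev & prev_ok
  date[prev] <- prev_date[prev]

  tibble::tibble(
    person_id = ev$person_id,
    sex = ev$sex,
    birth_year = ev$birth_year,
    diagnosis_date = date,
    diagnosis_year = as.integer(format(date, "%Y")),
    true_stage = stage,
    prevalent_flag = prev
  )
}

# sample exact inpatient dates inside the quarter containing q-index `qi`,
# never earlier than `floor_date` when the quarter is the floor's quarter
inpatient_date_in_quarter <- function(qi, floor_date) {
  qs <- q_index_start(qi)
  qe <- q_index_end(qi)
  lo <- pmax(qs, floor_date)
  lo + floor(stats::runif(length(qi)) * (as.integer(qe - lo) + 1L))
}

#' Emit claims for simulated cancers
#'
#' Translates ground-truth cancer events into the five claims tables the way
#' German statutory health-insurance data record them: an initial C18--C20
#' code (inpatient main discharge diagnosis or outpatient "confirmed"), a
#' confirmatory CRC code within the two following quarters, stage-dependent
#' C77 / C78--C79 codes at configured quarter lags, advanced-CRC drug
#' dispensations for true stage-IV disease, recurring "status post" codes
#' for prevalent cancers, and non-cancer / "suspected" noise codes. Events
#' whose diagnosis date falls inside an insurance gap leave no codes; they
#' are recorded in the `uncoded_events` attribute of the result.
#'
#' @param persons,spells From [simulatePopulation()].
#' @param events From [simulateEvents()].
#' @param config The [simConfig()] object.
#' @return A [claimsBundle()] with attribute `uncoded_events`.
#' @export
emitClaims <- function(persons, spells, events, config) {
  validateSimConfig(config)
  set.seed(op_seed(config, 3L))
  yr <- config$year_range
  years <- yr[1]:yr[2]
  n_py <- config$n_persons * length(years)

  out_list <- list()
  inp_list <- list()
  disp_list <- list()

  crc_subcodes <- c("C18.0", "C18.2", "C18.7", "C18.9", "C19", "C20")
  crc_probs <- c(0.15, 0.2, 0.15, 0.3, 0.08, 0.12)
  met_subcodes <- c("C78.0", "C78.7", "C79.0", "C79.5", "C79.9")
  lymph_subcodes <- c("C77.0", "C77.2", "C77.9")

  inc_ev <- events[!events$prevalent_flag, ]
  covered <- dplyr::inner_join(
    inc_ev[, c("person_id", "diagnosis_date")], spells,
    by = "person_id", relationship = "many-to-many"
  )
  covered <- unique(covered$person_id[
    covered$start_date <= covered$diagnosis_date &
      covered$diagnosis_date <= covered$end_date
  ])
  uncoded <- inc_ev[!inc_ev$person_id %in% covered, ]
  ev <- inc_ev[inc_ev$person_id %in% covered, ]
  ne <- nrow(ev)

  if (ne > 0) {
    entry_qi <- q_index(ev$diagnosis_year, quarter_of_date(ev$diagnosis_date))
    icd0 <- sample(crc_subcodes, ne, replace = TRUE, prob = crc_probs)
    inpat0 <- stats::runif(ne) < config$p_initial_inpatient

    inp_list$initial <- tibble::tibble(
      person_id = ev$person_id[inpat0], date = ev$diagnosis_date[inpat0],
      icd_code = icd0[inpat0], position = "main")
    out_list$initial <- tibble::tibble(
      person_id = ev$person_id[!inpat0], year = ev$diagnosis_year[!inpat0],
      quarter = quarter_of_date(ev$diagnosis_date[!inpat0]),
      icd_code = icd0[!inpat0], certainty = "confirmed")

    adm <- stats::runif(ne) < config$p_admission_code
    inp_list$admission <- tibble::tibble(
      person_id = ev$person_id[adm], date = ev$diagnosis_date[adm],
      icd_code = icd0[adm], position = "admission")

    conf <- stats::runif(ne) < config$p_confirmation_code
    conf_lag <- sample(0:2, ne, replace = TRUE,
                       prob = config$confirmation_lag_probs)
    conf_qi <- entry_qi + conf_lag
    conf_icd <- sample(crc_subcodes, ne, replace = TRUE, prob = crc_probs)
    conf_inpat <- stats::runif(ne) < 0.3
    ci <- conf & conf_inpat
    co <- conf & !conf_inpat
    inp_list$confirm <- tibble::tibble(
      person_id = ev$person_id[ci],
      date = inpatient_date_in_quarter(conf_qi[ci], ev$diagnosis_date[ci]),
      icd_code = conf_icd[ci],
      position = sample(c("main", "secondary"), sum(ci), replace = TRUE))
    out_list$confirm <- tibble::tibble(
      person_id = ev$person_id[co], year = q_index_year(conf_qi[co]),
      quarter = q_index_quarter(conf_qi[co]), icd_code = conf_icd[co],
      certainty = "confirmed")

    # lymph-node involvement codes: true III always eligible, true IV with
    # its own (lower) probability
    p77 <- ifelse(ev$true_stage == "III", config$p_c77_given_III,
                  ifelse(ev$true_stage == "IV", config$p_c77_given_IV, 0))
    e77 <- stats::runif(ne) < p77
    lag77 <- sample(0:2, ne, replace = TRUE, prob = config$stage_code_lag_probs)
    qi77 <- entry_qi + lag77
    icd77 <- sample(lymph_subcodes, ne, replace = TRUE)
    in77 <- stats::runif(ne) < 0.5
    s1 <- e77 & in77
    s2 <- e77 & !in77
    inp_list$c77 <- tibble::tibble(
      person_id = ev$person_id[s1],
      date = inpatient_date_in_quarter(qi77[s1], ev$diagnosis_date[s1]),
      icd_code = icd77[s1],
      position = sample(c("main", "secondary"), sum(s1), replace = TRUE))
    out_list$c77 <- tibble::tibble(
      person_id = ev$person_id[s2], year = q_index_year(qi77[s2]),
      quarter = q_index_quarter(qi77[s2]), icd_code = icd77[s2],
      certainty = "confirmed")

    # distant-metastasis codes for true IV
    is_iv <- ev$true_stage == "IV"
    e78 <- is_iv & stats::runif(ne) < config$p_c78_given_IV
    lag78 <- sample(0:2, ne, replace = TRUE, prob = config$stage_code_lag_probs)
    qi78 <- entry_qi + lag78
    icd78 <- sample(met_subcodes, ne, replace = TRUE)
    in78 <- stats::runif(ne) < config$p_inpatient_metastasis_code
    m1 <- e78 & in78
    m2 <- e78 & !in78
    inp_list$c78 <- tibble::tibble(
      person_id = ev$person_id[m1],
      date = inpatient_date_in_quarter(qi78[m1], ev$diagnosis_date[m1]),
      icd_code = icd78[m1],
      position = sample(c("main", "secondary"), sum(m1), replace = TRUE))
    out_list$c78 <- tibble::tibble(
      person_id = ev$person_id[m2], year = q_index_year(qi78[m2]),
      quarter = q_index_quarter(qi78[m2]), icd_code = icd78[m2],
      certainty = "confirmed")
    dup <- m2 & stats::runif(ne) < config$p_second_outpatient_metastasis_code
    qi_dup <- qi78 + sample(0:1, ne, replace = TRUE)
    out_list$c78_dup <- tibble::tibble(
      person_id = ev$person_id[dup], year = q_index_year(qi_dup[dup]),
      quarter = q_index_quarter(qi_dup[dup]), icd_code = icd78[dup],
      certainty = "confirmed")

    # advanced-CRC systemic therapy for true IV
    rx <- is_iv & stats::runif(ne) < config$p_advanced_therapy
    disp_list$therapy <- tibble::tibble(
      person_id = ev$person_id[rx],
      date = ev$diagnosis_date[rx] +
        floor(stats::runif(sum(rx)) * config$therapy_window_days),
      agent_code = sample(c("L01XC07", "L01XC06", "L01XC08"), sum(rx),
                          replace = TRUE, prob = c(0.6, 0.3, 0.1)))
  }

  # prevalent cancers: recurring "status post" outpatient codes
  prev_ev <- events[events$prevalent_flag, ]
  if (nrow(prev_ev) > 0) {
    pg <- tidyr::expand_grid(idx = seq_len(nrow(prev_ev)), year = years)
    keep <- stats::runif(nrow(pg)) < config$p_prevalent_recode
    pg <- pg[keep, ]
    out_list$prevalent <- tibble::tibble(
      person_id = prev_ev$person_id[pg$idx], year = pg$year,
      quarter = sample(1:4, nrow(pg), replace = TRUE),
      icd_code = sample(crc_subcodes, nrow(pg), replace = TRUE,
                        prob = crc_probs),
      certainty = "status_post")
  }

  # diagnostic work-ups: suspected / excluded CRC codes that must never
  # create a case
  n_susp <- stats::rpois(1, n_py * config$suspected_crc_per_person_year)
  if (n_susp > 0) {
    out_list$suspected <- tibble::tibble(
      person_id = sample.int(config$n_persons, n_susp, replace = TRUE),
      year = sample(years, n_susp, replace = TRUE),
      quarter = sample(1:4, n_susp, replace = TRUE),
      icd_code = sample(crc_subcodes, n_susp, replace = TRUE, prob = crc_probs),
      certainty = sample(c("suspected", "excluded"), n_susp, replace = TRUE,
                         prob = c(0.8, 0.2)))
  }

  # non-cancer outpatient noise
  n_noise <- stats::rpois(1, n_py * config$noise_dx_per_person_year)
  if (n_noise > 0) {
    out_list$noise <- tibble::tibble(
      person_id = sample.int(config$n_persons, n_noise, replace = TRUE),
      year = sample(years, n_noise, replace = TRUE),
      quarter = sample(1:4, n_noise, replace = TRUE),
      icd_code = sample(c("I10.00", "E11.9", "K52.9", "M54.5", "J06.9"),
                        n_noise, replace = TRUE),
      certainty = sample(c("confirmed", "suspected"), n_noise, replace = TRUE,
                         prob = c(0.9, 0.1)))
  }

  # non-oncological dispensation noise
  n_dn <- stats::rpois(1, n_py * 0.05)
  if (n_dn > 0) {
    range_start <- as.Date(sprintf("%d-01-01", yr[1]))
    span <- as.integer(as.Date(sprintf("%d-12-31", yr[2])) - range_start) + 1L
    disp_list$noise <- tibble::tibble(
      person_id = sample.int(config$n_persons, n_dn, replace = TRUE),
      date = range_start + floor(stats::runif(n_dn) * span),
      agent_code = sample(c("A10BA02", "C07AB07", "M01AE01"), n_dn,
                          replace = TRUE))
  }

  outpatient <- dplyr::arrange(dplyr::bind_rows(out_list), .data$person_id,
                               .data$year, .data$quarter, .data$icd_code)
  inpatient <- dplyr::arrange(dplyr::bind_rows(inp_list), .data$person_id,
                              .data$date, .data$icd_code)
  dispensations <- dplyr::arrange(dplyr::bind_rows(disp_list),
                                  .data$person_id, .data$date)

  bundle <- claimsBundle(persons, spells, outpatient, inpatient, dispensations)
  attr(bundle, "uncoded_events") <- uncoded
  bundle
}

#' Emit registry records for simulated cancers
#'
#' Produces one TNM registry record per reported cancer. The faithful record
#' carries (N0, M0) for non-advanced, (N_plus, M0) for stage III and
#' (N_plus, M1) for stage IV disease; the configured reporting mechanisms
#' then distort it: pathologist-only notification sets both statuses
#' missing, premature M0 records a true stage-IV cancer as M0 (N kept), and
#' independent N/M missingness is applied afterwards. Missingness is always
#' explicit -- never encoded as M0.
#'
#' @param events From [simulateEvents()].
#' @param config The [simConfig()] object.
#' @return Tibble of records: `record_id`, `person_id`, `sex`,
#'   `age_at_diagnosis`, `diagnosis_year`, `n_status`, `m_status`.
#' @export
emitRegistry <- function(events, config) {
  validateSimConfig(config)
  set.seed(op_seed(config, 4L))
  rep_ok <- stats::runif(nrow(events)) < config$reporting_completeness
  ev <- events[rep_ok, ]
  n <- nrow(ev)

  n_status <- ifelse(ev$true_stage == "non_advanced", "N0", "N_plus")
  m_status <- ifelse(ev$true_stage == "IV", "M1", "M0")

  path_only <- stats::runif(n) < config$p_pathologist_only
  premature <- !path_only & ev$true_stage == "IV" &
    stats::runif(n) < config$p_premature_M0
  n_status[path_only] <- "missing"
  m_status[path_only] <- "missing"
  m_status[premature] <- "M0"

  n_status[stats::runif(n) < config$p_N_missing] <- "missing"
  m_status[stats::runif(n) < config$p_M_missing] <- "missing"

  tibble::tibble(
    record_id = sprintf("R%07d", seq_len(n)),
    person_id = ev$person_id,
    sex = ev$sex,
    age_at_diagnosis = pmax(attainedAge(ev$diagnosis_year, ev$birth_year), 0L),
    diagnosis_year = ev$diagnosis_year,
    n_status = n_status,
    m_status = m_status
  )
}

#' Run the full synthetic generator
#'
#' Convenience wrapper: population, ground-truth events, claims and registry
#' in one call, all deterministic given the configured seed.
#'
#' @param config A [simConfig()] object.
#' @return Object of class `advcrc_sim`: a list with `config`, `bundle` (the
#'   [claimsBundle()]), `truth` (the event table) and `registry`.
#' @examples
#' sim <- simulateClaimsRegistry(simConfig(n_persons = 500, rng_seed = 1))
#' sim$bundle
#' @export
simulateClaimsRegistry <- function(config) {
  pop <- simulatePopulation(config)
  truth <- simulateEvents(pop$persons, config)
  bundle <- emitClaims(pop$persons, pop$spells, truth, config)
  registry <- emitRegistry(truth, config)
  structure(list(config = config, bundle = bundle, truth = truth,
                 registry = registry),
            class = "advcrc_sim")
}

#' @export
print.advcrc_sim <- function(x, ...) {
  cat("Synthetic claims + registry data\n")
  cat("  persons:", nrow(x$bundle$persons),
      " years:", x$config$year_range[1], "-", x$config$year_range[2], "\n")
  cat("  true cancers:", nrow(x$truth),
      sprintf(" (%d prevalent)", sum(x$truth$prevalent_flag)), "\n")
  cat("  registry records:", nrow(x$registry), "\n")
  invisible(x)
}
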