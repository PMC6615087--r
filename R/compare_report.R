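#' Percent decline between two rates
#'
#' `100 * (1 - rate_last / rate_first)`, rounded half away from zero to an
#' integer percent. Positive values are declines, negative values increases.
#'
#' @param rate_first Rate in the first year; must be positive.
#' @param rate_last Rate in the last year.
#' @return Integer percent decline.
#' @examples
#' percentChange(15.2, 12.9)  # 15
#' percentChange(10.4, 8.5)   # 18
#' @export
percentChange <- function(rate_first, rate_last) {
  if (any(rate_first <= 0)) {
    stop("`rate_first` must be positive", call. = FALSE)
  }
  as.integer(round_half_away(100 * (1 - rate_last / rate_first), 0))
}

#' First-to-last-year trend summary per sex and stage
#'
#' @param rates A [rateTable()] output.
#' @return Tibble `sex`, `stage`, `first_year`, `last_year`, `asir_first`,
#'   `asir_last`, `percent_decline` (integer percent, half away from zero).
#' @export
trendSummary <- function(rates) {
  dplyr::reframe(
    dplyr::group_by(dplyr::arrange(rates, .data$year), .data$sex, .data$stage),
    first_year = dplyr::first(.data$year),
    last_year = dplyr::last(.data$year),
    asir_first = dplyr::first(.data$asir),
    asir_last = dplyr::last(.data$asir),
    percent_decline = if (dplyr::first(.data$asir) > 0) {
      percentChange(dplyr::first(.data$asir), dplyr::last(.data$asir))
    } else NA_integer_
  )
}

#' Claims vs registry rate comparison
#'
#' Joins two rate tables on year x sex x stage and computes the absolute
#' (claims minus registry) and relative differences of the ASIRs. Strata
#' present in only one table are kept with `NA` differences and reported via
#' a message; a relative difference is `NA` when the registry rate is zero.
#'
#' @param claims_rates,registry_rates [rateTable()] outputs.
#' @return Tibble `year`, `sex`, `stage`, `asir_claims`, `asir_registry`,
#'   `abs_difference`, `relative_difference` (percent).
#' @export
buildComparison <- function(claims_rates, registry_rates) {
  cl <- claims_rates[, c("year", "sex", "stage", "asir")]
  rg <- registry_rates[, c("year", "sex", "stage", "asir")]
  names(cl)[4] <- "asir_claims"
  names(rg)[4] <- "asir_registry"
  out <- dplyr::full_join(cl, rg, by = c("year", "sex", "stage"))
  unmatched <- sum(is.na(out$asir_claims) | is.na(out$asir_registry))
  if (unmatched > 0) {
    message(unmatched, " stratum/strata present in only one rate table; ",
            "differences reported as NA")
  }
  out$abs_difference <- out$asir_claims - out$asir_registry
  out$relative_difference <- ifelse(
    !is.na(out$asir_registry) & out$asir_registry > 0,
    100 * (out$asir_claims - out$asir_registry) / out$asir_registry,
    NA_real_
  )
  dplyr::arrange(out, .data$year, .data$sex, .data$stage)
}

#' Staging-window sensitivity analysis
#'
#' Re-stages the ascertained cases with each staging window in `windows`
#' (entry quarter plus 0, 1 or 2 following quarters) and tabulates the
#' stage-IV rates per window. The set of cases staged IV can only grow with
#' the window, so IV counts are checked to be non-decreasing; a violation is
#' an error.
#'
#' @param bundle A [claimsBundle()].
#' @param years Calendar years to analyse.
#' @param code_lists A [codeLists()] object.
#' @param windows Integer subset of `c(0, 1, 2)`.
#' @param weights Standardization weights, default [espWeights()].
#' @param ... Passed to [claimsPipeline()].
#' @return Tibble `window`, `year`, `sex`, `stage` (= "IV"), `case_count`,
#'   `person_denominator`, `crude_rate`, `asir`.
#' @export
windowSensitivity <- function(bundle, years, code_lists = codeLists(),
                              windows = 0:2, weights = espWeights(), ...) {
  stopifnot(all(windows %in% 0:2))
  windows <- sort(unique(as.integer(windows)))
  base <- claimsPipeline(bundle, years, code_lists,
                         n_following_quarters = 0, ...)
  denoms <- base$denominators
  cases0 <- base$staged_cases[, setdiff(names(base$staged_cases),
                                        c("stage", "staging_window_quarters"))]
  out <- list()
  prev_iv <- NULL
  for (w in windows) {
    staged <- stageCases(cases0, bundle, code_lists, n_following_quarters = w)
    iv_ids <- staged$person_id[staged$stage == "IV"]
    if (!is.null(prev_iv) && !all(prev_iv %in% iv_ids)) {
      stop("stage-IV case set shrank when the staging window grew",
           call. = FALSE)
    }
    prev_iv <- iv_ids
    strata <- caseStrata(staged, add_advanced = FALSE)
    strata <- strata[strata$stage == "IV", ]
    if (nrow(strata) == 0) next
    rt <- rateTable(strata, denoms, weights)
    rt$window <- w
    out[[as.character(w)]] <- rt
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) > 0) {
    res <- res[, c("window", setdiff(names(res), "window"))]
  }
  res
}

#' Run the full pipeline end to end
#'
#' Simulates a claims + registry dataset, runs the claims ascertainment and
#' staging pipeline and the registry classification under all four
#' missing-data scenarios, computes crude and age-standardized rates for
#' both sources, and derives the comparison and trend summaries. All outputs
#' are optionally written as CSV files together with a JSON manifest of the
#' configuration. Deterministic given the seed.
#'
#' @param config A [simConfig()] object.
#' @param seed Optional integer overriding `config$rng_seed`.
#' @param out_dir Optional output directory for CSVs and the manifest.
#' @param n_following_quarters Staging window of the main analysis
#'   (default 1).
#' @param run_window_sensitivity Also run [windowSensitivity()] over windows
#'   0--2.
#' @return List with elements `sim`, `staged_cases`, `denominators`,
#'   `claims_rates`, `registry_classified`, `registry_rates` (one rate table
#'   per scenario), `comparison`, `trend_claims`, `trend_registry` and
#'   (optionally) `window_sensitivity`.
#' @export
runAll <- function(config, seed = NULL, out_dir = NULL,
                   n_following_quarters = 1,
                   run_window_sensitivity = FALSE) {
  if (!is.null(seed)) {
    config$rng_seed <- as.integer(seed)
    validateSimConfig(config)
  }
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  yr <- config$year_range
  years <- (yr[1] + 4L):yr[2]
  if (length(years) == 0 || years[1] > yr[2]) {
    stop("year_range too short: need at least 4 look-back years plus one ",
         "analysis year", call. = FALSE)
  }
  cl <- codeLists()

  sim <- step("simulate", simulateClaimsRegistry(config))
  claims <- step("claims-cohort",
                 claimsPipeline(sim$bundle, years, cl,
                                n_following_quarters = n_following_quarters))
  claims_rates <- step("rates", rateTable(caseStrata(claims$staged_cases),
                                          claims$denominators))

  registry <- step("registry-classify", {
    reg <- sim$registry[sim$registry$diagnosis_year %in% years, ]
    classifyTnm(reg)
  })
  pop_denoms <- step("rates", populationDenominators(sim$bundle$persons, years))
  scenarios <- c("as_observed", "drop_nonclassifiable",
                 "nonclassifiable_as_nonadvanced", "unstratifiable_as_IV")
  registry_rates <- lapply(scenarios, function(sc) {
    step("rates", {
      strata <- registryStrata(applyScenario(registry, sc))
      rateTable(strata, pop_denoms)
    })
  })
  names(registry_rates) <- scenarios

  comparison <- step("compare", {
    rg <- registry_rates$as_observed
    buildComparison(
      claims_rates[claims_rates$stage %in% c("non_advanced", "III", "IV",
                                             "advanced"), ],
      rg[rg$stage %in% c("non_advanced", "III", "IV", "advanced"), ]
    )
  })
  trend_claims <- step("compare", trendSummary(claims_rates))
  trend_registry <- step("compare", trendSummary(registry_rates$as_observed))

  result <- list(sim = sim, staged_cases = claims$staged_cases,
                 denominators = claims$denominators,
                 claims_rates = claims_rates,
                 registry_classified = registry,
                 registry_rates = registry_rates,
                 comparison = comparison,
                 trend_claims = trend_claims,
                 trend_registry = trend_registry)

  if (run_window_sensitivity) {
    result$window_sensitivity <-
      step("window-sensitivity", windowSensitivity(sim$bundle, years, cl))
  }

  if (!is.null(out_dir)) {
    step("write-report", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      wr <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                             row.names = FALSE)
      wr(result$staged_cases, "staged_cases.csv")
      wr(result$denominators, "denominators.csv")
      wr(result$claims_rates, "claims_rates.csv")
      for (sc in scenarios) {
        wr(result$registry_rates[[sc]],
           paste0("registry_rates_", sc, ".csv"))
      }
      wr(result$comparison, "comparison.csv")
      wr(result$trend_claims, "trend_claims.csv")
      wr(result$trend_registry, "trend_registry.csv")
      if (!is.null(result$window_sensitivity)) {
        wr(result$window_sensitivity, "window_sensitivity.csv")
      }
      cfg <- config
      cfg$incidence <- as.data.frame(cfg$incidence)
      jsonlite::write_json(
        list(config = unclass(cfg), analysis_years = years,
             n_following_quarters = n_following_quarters),
        file.path(out_dir, "manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
    })
  }
  result
}
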