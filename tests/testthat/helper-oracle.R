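# Naive per-person reference interpreter of the claims rules, written
# independently of the package's vectorized pipeline: explicit loops, a
# literal day-by-day coverage scan, and direct re-reading of each rule. Used
# to cross-check identifyIncidentCases() + stageCases() on small bundles.

oracle_is_prefix <- function(code, prefixes) {
  for (p in prefixes) if (startsWith(code, p)) return(TRUE)
  FALSE
}

oracle_q_start <- function(y, q) as.Date(sprintf("%d-%02d-01", y, (q - 1) * 3 + 1))

oracle_q_end <- function(y, q) {
  if (q == 4) as.Date(sprintf("%d-12-31", y)) else oracle_q_start(y, q + 1) - 1
}

oracle_qidx <- function(y, q) 4 * y + q - 1

# staged cases for one year, one person at a time
oracle_cases <- function(bundle, year, code_lists = codeLists(),
                         lookback_years = 4, confirm_quarters = 2,
                         max_gap_days = 15, min_age = 5,
                         n_following_quarters = 1) {
  lb <- as.integer(round(lookback_years * 365.25))
  ref <- as.Date(sprintf("%d-12-31", year))
  rows <- list()

  for (k in seq_len(nrow(bundle$persons))) {
    pid <- bundle$persons$person_id[k]
    birth_year <- bundle$persons$birth_year[k]
    out <- bundle$outpatient[bundle$outpatient$person_id == pid, , drop = FALSE]
    inp <- bundle$inpatient[bundle$inpatient$person_id == pid, , drop = FALSE]
    sp <- bundle$spells[bundle$spells$person_id == pid, , drop = FALSE]

    # qualifying CRC records (any year)
    recs <- data.frame(qi = integer(), eff = as.Date(character()),
                       exact = as.Date(character()), prio = integer(),
                       code = character())
    if (nrow(out) > 0) for (i in seq_len(nrow(out))) {
      if (out$certainty[i] == "confirmed" &&
          oracle_is_prefix(out$icd_code[i], code_lists$crc_codes)) {
        recs <- rbind(recs, data.frame(
          qi = oracle_qidx(out$year[i], out$quarter[i]),
          eff = oracle_q_start(out$year[i], out$quarter[i]),
          exact = as.Date(NA), prio = 2L, code = out$icd_code[i]))
      }
    }
    if (nrow(inp) > 0) for (i in seq_len(nrow(inp))) {
      if (inp$position[i] %in% c("main", "secondary") &&
          oracle_is_prefix(inp$icd_code[i], code_lists$crc_codes)) {
        d <- inp$date[i]
        y <- as.integer(format(d, "%Y"))
        q <- (as.integer(format(d, "%m")) - 1) %/% 3 + 1
        recs <- rbind(recs, data.frame(
          qi = oracle_qidx(y, q), eff = d, exact = d,
          prio = if (inp$position[i] == "main") 0L else 1L,
          code = inp$icd_code[i]))
      }
    }
    in_year <- recs[format(recs$eff, "%Y") == as.character(year), , drop = FALSE]
    if (nrow(in_year) == 0) next

    # cohort entry: first record in the year, ties by setting then code
    in_year <- in_year[order(in_year$eff, in_year$prio, in_year$code), ,
                       drop = FALSE]
    entry_q <- in_year$qi[1]
    exact_in_q <- recs$exact[!is.na(recs$exact) & recs$qi == entry_q]
    entry_date <- if (length(exact_in_q) > 0) min(exact_in_q) else
      oracle_q_start(entry_q %/% 4, entry_q %% 4 + 1)

    # confirmation: a second qualifying record in the window
    n_window <- sum(recs$qi >= entry_q & recs$qi <= entry_q + confirm_quarters)
    if (n_window < 2) next

    # washout scan
    washed <- FALSE
    if (nrow(out) > 0) for (i in seq_len(nrow(out))) {
      if (oracle_is_prefix(out$icd_code[i], code_lists$crc_codes) &&
          out$certainty[i] %in% c("confirmed", "status_post")) {
        qi <- oracle_qidx(out$year[i], out$quarter[i])
        if (qi < entry_q &&
            oracle_q_end(out$year[i], out$quarter[i]) >= entry_date - lb) {
          washed <- TRUE
        }
      }
    }
    if (nrow(inp) > 0) for (i in seq_len(nrow(inp))) {
      if (inp$position[i] %in% c("main", "secondary") &&
          oracle_is_prefix(inp$icd_code[i], code_lists$crc_codes) &&
          inp$date[i] >= entry_date - lb && inp$date[i] <= entry_date - 1) {
        washed <- TRUE
      }
    }
    if (washed) next

    # continuity: literal day-by-day coverage of [entry - lb, Dec 31]
    days <- seq(entry_date - lb, ref, by = "day")
    covered <- rep(FALSE, length(days))
    if (nrow(sp) > 0) for (i in seq_len(nrow(sp))) {
      covered <- covered | (days >= sp$start_date[i] & days <= sp$end_date[i])
    }
    runs <- rle(covered)
    if (any(!runs$values & runs$lengths > max_gap_days)) next

    age <- year - birth_year
    if (age < min_age) next

    # staging scan
    has_distant <- FALSE
    has_lymph <- FALSE
    stage_codes <- c(code_lists$lymph_only_codes, code_lists$distant_codes)
    scan <- function(code, qi) {
      if (qi >= entry_q && qi <= entry_q + n_following_quarters) {
        if (oracle_is_prefix(code, code_lists$distant_codes)) {
          has_distant <<- TRUE
        } else if (oracle_is_prefix(code, code_lists$lymph_only_codes)) {
          has_lymph <<- TRUE
        }
      }
    }
    if (nrow(out) > 0) for (i in seq_len(nrow(out))) {
      if (out$certainty[i] == "confirmed" &&
          oracle_is_prefix(out$icd_code[i], stage_codes)) {
        scan(out$icd_code[i], oracle_qidx(out$year[i], out$quarter[i]))
      }
    }
    if (nrow(inp) > 0) for (i in seq_len(nrow(inp))) {
      if (inp$position[i] %in% c("main", "secondary") &&
          oracle_is_prefix(inp$icd_code[i], stage_codes)) {
        d <- inp$date[i]
        y <- as.integer(format(d, "%Y"))
        q <- (as.integer(format(d, "%m")) - 1) %/% 3 + 1
        scan(inp$icd_code[i], oracle_qidx(y, q))
      }
    }
    stage <- if (has_distant) "IV" else if (has_lymph) "III" else "non_advanced"

    rows[[length(rows) + 1]] <- data.frame(
      person_id = pid, cohort_entry_date = entry_date,
      entry_quarter = entry_q %% 4 + 1, age_at_entry = age,
      stage = stage, calendar_year = year)
  }
  if (length(rows) == 0) {
    return(data.frame(person_id = integer(),
                      cohort_entry_date = as.Date(character()),
                      entry_quarter = integer(), age_at_entry = integer(),
                      stage = character(), calendar_year = integer()))
  }
  do.call(rbind, rows)
}

# package pipeline restricted to the columns the oracle produces
pipeline_cases_for_oracle <- function(bundle, year, ...,
                                      n_following_quarters = 1) {
  cases <- identifyIncidentCases(bundle, year, ...)
  staged <- stageCases(cases, bundle, n_following_quarters = n_following_quarters)
  out <- staged[, c("person_id", "cohort_entry_date", "entry_quarter",
                    "age_at_entry", "stage", "calendar_year")]
  out[order(out$person_id), ]
}
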