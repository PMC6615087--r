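# Internal helpers: calendar quarters, ages, rounding.
#
# German outpatient claims carry diagnoses at (year, quarter) granularity only;
# a linear quarter index makes window arithmetic across year boundaries trivial.

q_index <- function(year, quarter) 4L * as.integer(year) + as.integer(quarter) - 1L

q_index_year <- function(qi) qi %/% 4L

q_index_quarter <- function(qi) qi %% 4L + 1L

quarter_of_date <- function(date) {
  (as.integer(format(date, "%m")) - 1L) %/% 3L + 1L
}

quarter_start <- function(year, quarter) {
  as.Date(sprintf("%04d-%02d-01", as.integer(year), 3L * (as.integer(quarter) - 1L) + 1L))
}

quarter_end <- function(year, quarter) {
  qi <- q_index(year, quarter) + 1L
  quarter_start(q_index_year(qi), q_index_quarter(qi)) - 1L
}

q_index_start <- function(qi) quarter_start(q_index_year(qi), q_index_quarter(qi))

q_index_end <- function(qi) quarter_end(q_index_year(qi), q_index_quarter(qi))

#' Attained age in a calendar year
#'
#' Claims and registry data carry the year of birth only, so ages are computed
#' with the attained-age (mid-year birthday) convention: the age reached in
#' calendar year `y` is `y - birth_year`. The same convention is applied to
#' numerator and denominator so that every ascertained case falls in the age
#' band in which its person is counted.
#'
#' @param year Calendar year (integer).
#' @param birth_year Year of birth (integer).
#' @return Integer age in years.
#' @export
attainedAge <- function(year, birth_year) as.integer(year) - as.integer(birth_year)

# Round half away from zero (the convention used for all displayed rates and
# percentages); base round() rounds half to even.
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# days in the look-back / preobservation window ("4 years" measured as
# 4 x 365.25 days)
lookback_days <- function(lookback_years) as.integer(round(lookback_years * 365.25))

# TRUE where `codes` starts with any of the ICD/ATC prefixes
matches_prefix <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
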