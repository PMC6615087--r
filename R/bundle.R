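#' Claims bundle: the five claims tables of one population
#'
#' Validates and containers the five tables a German-claims analysis
#' consumes:
#'
#' * `persons`: `person_id`, `sex` ("male"/"female"), `birth_year`;
#' * `spells`: insurance periods `person_id`, `start_date`, `end_date`
#'   (sorted, non-overlapping within person);
#' * `outpatient`: quarter-granular diagnoses `person_id`, `year`, `quarter`
#'   (1--4), `icd_code`, `certainty` ("confirmed", "suspected",
#'   "status_post", "excluded");
#' * `inpatient`: dated discharge diagnoses `person_id`, `date`, `icd_code`,
#'   `position` ("main", "secondary", "admission");
#' * `dispensations`: `person_id`, `date`, `agent_code`.
#'
#' @param persons,spells,outpatient,inpatient,dispensations The five tables.
#' @return Object of class `claims_bundle`.
#' @export
claimsBundle <- function(persons, spells, outpatient, inpatient,
                         dispensations) {
  check_cols <- function(df, nm, cols) {
    if (!is.data.frame(df) || !all(cols %in% names(df))) {
      stop("`", nm, "` must have columns ", paste(cols, collapse = ", "),
           call. = FALSE)
    }
  }
  check_cols(persons, "persons", c("person_id", "sex", "birth_year"))
  check_cols(spells, "spells", c("person_id", "start_date", "end_date"))
  check_cols(outpatient, "outpatient",
             c("person_id", "year", "quarter", "icd_code", "certainty"))
  check_cols(inpatient, "inpatient",
             c("person_id", "date", "icd_code", "position"))
  check_cols(dispensations, "dispensations",
             c("person_id", "date", "agent_code"))

  if (anyDuplicated(persons$person_id)) {
    stop("`persons$person_id` must be unique", call. = FALSE)
  }
  if (!all(persons$sex %in% c("male", "female"))) {
    stop("`persons$sex` must be 'male' or 'female'", call. = FALSE)
  }
  if (nrow(outpatient) > 0 && !all(outpatient$quarter %in% 1:4)) {
    stop("`outpatient$quarter` must be in 1..4", call. = FALSE)
  }
  if (nrow(outpatient) > 0 &&
      !all(outpatient$certainty %in%
           c("confirmed", "suspected", "status_post", "excluded"))) {
    stop("invalid `outpatient$certainty` value", call. = FALSE)
  }
  if (nrow(inpatient) > 0 &&
      !all(inpatient$position %in% c("main", "secondary", "admission"))) {
    stop("invalid `inpatient$position` value", call. = FALSE)
  }
  validateSpells(spells)

  structure(list(persons = tibble::as_tibble(persons),
                 spells = tibble::as_tibble(spells),
                 outpatient = tibble::as_tibble(outpatient),
                 inpatient = tibble::as_tibble(inpatient),
                 dispensations = tibble::as_tibble(dispensations)),
            class = "claims_bundle")
}

# spells must be non-overlapping and sorted within person
validateSpells <- function(spells) {
  if (nrow(spells) == 0) return(invisible(spells))
  if (any(spells$start_date > spells$end_date)) {
    stop("spell with start_date after end_date", call. = FALSE)
  }
  s <- dplyr::arrange(spells, .data$person_id, .data$start_date)
  same <- s$person_id == dplyr::lag(s$person_id, default = -1L)
  overlap <- same & s$start_date <= dplyr::lag(s$end_date,
                                               default = as.Date("1800-01-01"))
  if (any(overlap, na.rm = TRUE)) {
    stop("overlapping insurance spells for person ",
         s$person_id[which(overlap)[1]], call. = FALSE)
  }
  invisible(spells)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("Claims bundle\n")
  cat(sprintf("  persons: %d   spells: %d\n", nrow(x$persons), nrow(x$spells)))
  cat(sprintf("  outpatient dx: %d   inpatient dx: %d   dispensations: %d\n",
              nrow(x$outpatient), nrow(x$inpatient), nrow(x$dispensations)))
  invisible(x)
}

#' Write a simulated dataset (or bare bundle) to CSV
#'
#' Writes the five claims tables (plus, for a full simulation, the registry
#' and ground-truth tables) as one-header-row CSV files with ISO-8601 dates,
#' and a `manifest.json` recording the generator configuration and seed.
#'
#' @param x A `claims_bundle` or `advcrc_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "advcrc_sim")) {
    bundle <- x$bundle
    utils::write.csv(x$registry, file.path(dir, "registry.csv"),
                     row.names = FALSE)
    utils::write.csv(x$truth, file.path(dir, "truth.csv"), row.names = FALSE)
    cfg <- x$config
    cfg$incidence <- as.data.frame(cfg$incidence)
    jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    bundle <- x
  }
  stopifnot(inherits(bundle, "claims_bundle"))
  for (nm in names(bundle)) {
    utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a claims bundle (and companions) from CSV
#'
#' Counterpart of [writeBundle()]. Returns a validated [claimsBundle()];
#' registry and truth tables, when present in the directory, are attached as
#' attributes `registry` and `truth`.
#'
#' @param dir Directory holding the CSV files.
#' @return A `claims_bundle`.
#' @export
readBundle <- function(dir) {
  rd <- function(f) tibble::as_tibble(utils::read.csv(file.path(dir, f),
                                                      stringsAsFactors = FALSE))
  persons <- rd("persons.csv")
  spells <- rd("spells.csv")
  spells$start_date <- as.Date(spells$start_date)
  spells$end_date <- as.Date(spells$end_date)
  outpatient <- rd("outpatient.csv")
  inpatient <- rd("inpatient.csv")
  inpatient$date <- as.Date(inpatient$date)
  dispensations <- rd("dispensations.csv")
  if (nrow(dispensations) > 0) dispensations$date <- as.Date(dispensations$date)
  b <- claimsBundle(persons, spells, outpatient, inpatient, dispensations)
  if (file.exists(file.path(dir, "registry.csv"))) {
    attr(b, "registry") <- rd("registry.csv")
  }
  if (file.exists(file.path(dir, "truth.csv"))) {
    tr <- rd("truth.csv")
    tr$diagnosis_date <- as.Date(tr$diagnosis_date)
    attr(b, "truth") <- tr
  }
  b
}
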