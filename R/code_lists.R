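#' Diagnosis and therapy code lists for the claims algorithm
#'
#' Bundles the ICD-10-GM prefixes and drug (ATC-style) codes used by the
#' claims-based ascertainment and staging algorithm:
#'
#' * `crc_codes`: primary colorectal cancer (default C18--C20),
#' * `lymph_only_codes`: secondary neoplasm of lymph nodes (default C77),
#'   interpreted as regional involvement, i.e. UICC stage III,
#' * `distant_codes`: secondary neoplasm of other/distant sites (default
#'   C78--C79), interpreted as distant metastases, i.e. UICC stage IV,
#' * `advanced_therapy_codes`: agents essentially only given in advanced
#'   CRC (default: bevacizumab-class antibodies and related targeted agents),
#'   used by the medication cross-check.
#'
#' Codes are matched by prefix, so "C18" covers "C18.0" ... "C18.9". The three
#' diagnosis sets must be pairwise disjoint.
#'
#' @param crc_codes Character vector of ICD-10 prefixes for primary CRC.
#' @param lymph_only_codes Prefixes for lymph-node-only metastasis codes.
#' @param distant_codes Prefixes for distant-metastasis codes.
#' @param advanced_therapy_codes Agent code prefixes for the medication
#'   cross-check.
#' @return An object of class `code_lists`.
#' @examples
#' cl <- codeLists()
#' cl$crc_codes
#' @export
codeLists <- function(crc_codes = c("C18", "C19", "C20"),
                      lymph_only_codes = "C77",
                      distant_codes = c("C78", "C79"),
                      advanced_therapy_codes = c("L01XC06", "L01XC07", "L01XC08")) {
  for (nm in c("crc_codes", "lymph_only_codes", "distant_codes",
               "advanced_therapy_codes")) {
    v <- get(nm)
    if (!is.character(v) || length(v) < 1 || anyNA(v)) {
      stop("`", nm, "` must be a non-empty character vector", call. = FALSE)
    }
  }
  sets <- list(crc_codes, lymph_only_codes, distant_codes)
  for (i in 1:2) for (j in (i + 1):3) {
    if (length(intersect(sets[[i]], sets[[j]])) > 0) {
      stop("diagnosis code sets must be pairwise disjoint", call. = FALSE)
    }
  }
  structure(
    list(crc_codes = crc_codes,
         lymph_only_codes = lymph_only_codes,
         distant_codes = distant_codes,
         advanced_therapy_codes = advanced_therapy_codes),
    class = "code_lists"
  )
}

#' @export
print.code_lists <- function(x, ...) {
  cat("Code lists for claims-based CRC staging\n")
  cat("  primary CRC:        ", paste(x$crc_codes, collapse = ", "), "\n")
  cat("  lymph nodes (III):  ", paste(x$lymph_only_codes, collapse = ", "), "\n")
  cat("  distant mets (IV):  ", paste(x$distant_codes, collapse = ", "), "\n")
  cat("  advanced therapy:   ", paste(x$advanced_therapy_codes, collapse = ", "), "\n")
  invisible(x)
}
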