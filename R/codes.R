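#' Normalize a diagnosis code
#'
#' EHR extracts record ICD codes in dotted ("J44.9") or undotted ("J449")
#' dialects, sometimes lowercased. All code comparison in this package runs
#' on the normalized form: uppercased, with every dot removed.
#'
#' @param raw character vector of codes as recorded.
#' @param system code system, `"ICD9CM"` or `"ICD10CM"` (recycled).
#' @return a data.frame with columns `raw`, `system`, `normalized`.
#' @examples
#' normalize_code("j44.9", "ICD10CM")
#' @export
normalize_code <- function(raw, system) {
  system <- match.arg(system, c("ICD9CM", "ICD10CM"), several.ok = TRUE)
  if (length(system) == 1L) system <- rep(system, length(raw))
  if (length(system) != length(raw)) {
    stop_user("`raw` and `system` lengths differ")
  }
  raw <- as.character(raw)
  trimmed <- trimws(raw)
  if (any(is.na(trimmed)) || any(!nzchar(trimmed))) {
    stop_user("invalid code: empty or missing after trimming")
  }
  normalized <- toupper(gsub(".", "", trimmed, fixed = TRUE))
  data.frame(raw = raw, system = system, normalized = normalized,
             stringsAsFactors = FALSE)
}

#' Diagnosis code sets
#'
#' A code set names the structured-data definition of a condition: the exact
#' ICD-9-CM and ICD-10-CM codes whose presence on an encounter marks it as
#' condition-coded. Matching is exact set membership after normalization —
#' deliberately no prefix or child-code expansion, because the default COPD
#' definition is a closed enumeration and silent widening would change the
#' cohort. Supply a custom set (or [read_codeset()]) for broader lists.
#'
#' @param name label for the set.
#' @param icd9,icd10 character vectors of codes, dotted or undotted.
#' @return an object of class `notesieve_codeset`.
#' @export
code_set <- function(name, icd9 = character(), icd10 = character()) {
  stopifnot(is_scalar_character(name))
  norm <- function(x, sys) {
    if (length(x) == 0L) return(character())
    unique(normalize_code(x, sys)$normalized)
  }
  structure(list(name = name,
                 icd9 = norm(icd9, "ICD9CM"),
                 icd10 = norm(icd10, "ICD10CM")),
            class = "notesieve_codeset")
}

#' @export
print.notesieve_codeset <- function(x, ...) {
  cat(sprintf("<codeset '%s': %d ICD-9-CM, %d ICD-10-CM codes>\n",
              x$name, length(x$icd9), length(x$icd10)))
  invisible(x)
}

#' Default COPD code set
#'
#' The 11 ICD-9-CM and 11 ICD-10-CM codes of the standard administrative
#' COPD definition (chronic bronchitis, emphysema, chronic obstructive
#' asthma, and unspecified chronic airway obstruction).
#'
#' @return a `notesieve_codeset`.
#' @export
copd_codeset <- function() {
  code_set(
    "COPD-default",
    icd9 = c("491", "491.1", "491.2", "491.21", "491.22", "491.8",
             "491.9", "492", "492.8", "493.92", "496"),
    icd10 = c("J41.0", "J41.1", "J41.8", "J42", "J43.1", "J43.2",
              "J43.8", "J43.9", "J44.0", "J44.1", "J44.9")
  )
}

#' Test codes for membership in a code set
#'
#' @param code a data.frame as returned by [normalize_code()] (columns
#'   `system`, `normalized`), or a character vector of raw codes combined
#'   with `system`.
#' @param codeset a `notesieve_codeset`.
#' @param system code system, used when `code` is a character vector.
#' @return logical vector.
#' @examples
#' is_target_code("J44.9", copd_codeset(), system = "ICD10CM")
#' @export
is_target_code <- function(code, codeset, system = NULL) {
  stopifnot(inherits(codeset, "notesieve_codeset"))
  if (is.character(code)) {
    if (is.null(system)) stop_user("`system` required for character codes")
    code <- normalize_code(code, system)
  }
  ifelse(code$system == "ICD9CM",
         code$normalized %in% codeset$icd9,
         code$normalized %in% codeset$icd10)
}

#' Read a code set from a JSON file
#'
#' Expected keys: `name`, `icd9` (list), `icd10` (list); codes may be dotted
#' or undotted.
#'
#' @param path file path.
#' @return a `notesieve_codeset`.
#' @export
read_codeset <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$name)) stop_user("codeset file lacks a 'name' key")
  code_set(x$name, icd9 = x$icd9 %||% character(),
           icd10 = x$icd10 %||% character())
}

#' Write a code set to a JSON file
#' @param codeset a `notesieve_codeset`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_codeset <- function(codeset, path) {
  stopifnot(inherits(codeset, "notesieve_codeset"))
  jsonlite::write_json(list(name = codeset$name, icd9 = codeset$icd9,
                            icd10 = codeset$icd10),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
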