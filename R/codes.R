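#' Coding systems recognized in claims tables
#' @export
CODE_SYSTEMS <- c("ICD-9", "ICD-10-CM", "CPT", "HCPCS", "NDC")

# Systems whose codes carry a decimal point that billing extracts drop
# inconsistently; comparison is therefore dot-insensitive.
icd_system <- function(system) system %in% c("ICD-9", "ICD-10-CM")

#' Normalize a billing code for comparison
#'
#' Codes are uppercased and, for ICD systems, stripped of the decimal
#' point, so that `"e05.00"` and `"E0500"` compare equal. CPT/HCPCS/NDC
#' codes are passed through uppercased. A trailing `*` (wildcard marker
#' used in code lists) is preserved.
#'
#' @param code character vector of raw codes.
#' @param system character vector (recycled) naming the coding system.
#' @return normalized character vector.
#' @export
normalize_code <- function(code, system) {
  if (length(code) == 0L) return(character(0))
  code <- toupper(trimws(as.character(code)))
  if (any(is.na(code) | code == "" | code == "*")) {
    stop_input("empty code string at position %d",
               which(is.na(code) | code == "" | code == "*")[1])
  }
  icd <- rep_len(icd_system(system), length(code))
  code[icd] <- gsub(".", "", code[icd], fixed = TRUE)
  code
}

code_key <- function(system, code) paste(system, code, sep = ":")

#' Read named code lists from a JSON file
#'
#' The file maps set names (e.g. "hyperthyroidism", "exophthalmos") to
#' arrays of `{system, code}` entries; a trailing `*` in a code marks a
#' prefix wildcard. Matching is otherwise exact after normalization.
#'
#' @param path JSON file path.
#' @return named list of data.frames with columns `system`, `code`,
#'   `wildcard`, of class `ted_codelists`.
#' @export
read_code_lists <- function(path) {
  if (!file.exists(path)) stop_input("code-list file '%s' not found", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(raw)) stop_input("code-list file '%s' is empty", path)
  out <- lapply(names(raw), function(nm) {
    df <- as.data.frame(raw[[nm]], stringsAsFactors = FALSE)
    if (!all(c("system", "code") %in% names(df)) || nrow(df) == 0L) {
      stop_input("code set '%s' is empty or malformed", nm)
    }
    bad <- !df$system %in% CODE_SYSTEMS
    if (any(bad)) stop_input("code set '%s': unknown system '%s'", nm, df$system[bad][1])
    wild <- endsWith(df$code, "*")
    code <- normalize_code(sub("\\*$", "", df$code), df$system)
    data.frame(system = df$system, code = ifelse(wild, paste0(code, "*"), code),
               wildcard = wild, stringsAsFactors = FALSE)
  })
  names(out) <- names(raw)
  structure(out, class = "ted_codelists")
}

#' Default TED code lists
#'
#' The appendix code lists behind the six identification algorithms are
#' not reproduced verbatim anywhere public, so the package ships an
#' editable default mapping of each symptom/sign concept to ICD-10-CM and
#' ICD-9 families (hyperthyroidism = E05.x / 242.x, exophthalmos =
#' H05.2x, diplopia = H53.2, lid retraction = H02.53x, ...). Lists are
#' data, not code: every consumer takes a `ted_codelists` argument so a
#' revised list file drops in without touching the engine.
#'
#' @return a `ted_codelists` object.
#' @export
default_code_lists <- function() {
  read_code_lists(system.file("extdata", "ted_codelists.json",
                              package = "tedclaims", mustWork = TRUE))
}

# Logical match of (system, normalized code) vectors against one code set.
codes_match <- function(system, code, codeset) {
  hit <- rep(FALSE, length(code))
  exact <- codeset[!codeset$wildcard, , drop = FALSE]
  if (nrow(exact)) hit <- code_key(system, code) %in% code_key(exact$system, exact$code)
  wild <- codeset[codeset$wildcard, , drop = FALSE]
  for (i in seq_len(nrow(wild))) {
    pre <- sub("\\*$", "", wild$code[i])
    hit <- hit | (system == wild$system[i] & startsWith(code, pre))
  }
  hit
}
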