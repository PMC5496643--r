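#' Load the packaged drug catalog
#'
#' The catalog maps raw hospital drug codes to 4-character stems, generic
#' names and the ATC class relevant to NSAID / gastro-protection auditing:
#' antacids (`A02A`), peptic-ulcer and GORD drugs (`A02B`), conventional
#' NSAIDs (`M01A_conventional`) and COX-2 inhibitors (`M01A_cox2`). One stem
#' (`MOBC`) has no published catalog row and is carried as a synthetic
#' M01A-conventional entry so demonstration fixtures can include it.
#'
#' @param path optional path to a catalog CSV with columns
#'   `raw_code,stem,generic_name,atc_class`; defaults to the packaged file.
#' @return a data frame with columns `raw_code`, `stem`, `generic_name`,
#'   `atc_class`.
#' @examples
#' cat <- load_catalog()
#' head(cat)
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_catalog.csv", package = "rxminer")
  }
  if (!nzchar(path) || !file.exists(path)) {
    rx_stop(sprintf("catalog file not found: '%s'", path), "rx_io_error")
  }
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("raw_code", "stem", "generic_name", "atc_class")
  if (!all(need %in% names(cat))) {
    rx_stop("catalog must have columns raw_code, stem, generic_name, atc_class",
            "rx_schema_error")
  }
  bad <- cat$stem != substr(cat$raw_code, 1, 4)
  if (any(bad)) {
    rx_stop(sprintf("catalog stem mismatch for raw code(s): %s",
                    paste(cat$raw_code[bad], collapse = ", ")),
            "rx_schema_error")
  }
  cat
}

#' Normalize a raw drug code to its 4-character stem
#'
#' Hospital drug codes encode strength and dosage form in the trailing
#' characters; the leading 4 characters identify the compound (e.g.
#' `IBUP1T-`, `IBUP2T-` and `IBUP-S-` all collapse to `IBUP`). Mining and
#' auditing operate on stems so that different strengths of the same drug
#' count as one item.
#'
#' @param raw_code character vector of raw drug codes, each at least 4
#'   characters.
#' @return character vector of 4-character stems.
#' @examples
#' normalize_drug_code(c("IBUP1T-", "OMPZ-C-"))
#' @export
normalize_drug_code <- function(raw_code) {
  if (length(raw_code) == 0) return(character(0))
  short <- is.na(raw_code) | nchar(raw_code) < 4
  if (any(short)) {
    rx_stop(sprintf("invalid drug code(s), shorter than 4 characters: %s",
                    paste(unique(raw_code[short]), collapse = ", ")),
            "rx_invalid_code")
  }
  substr(raw_code, 1, 4)
}

#' Classify a drug stem into its ATC class
#'
#' Looks the stem up in the catalog; stems not in the catalog classify as
#' `"other"` (never an error — unknown co-prescribed drugs are simply outside
#' the audit scope).
#'
#' @param stem character vector of 4-character stems.
#' @param catalog catalog data frame from [load_catalog()].
#' @return character vector of classes: `"A02A"`, `"A02B"`,
#'   `"M01A_conventional"`, `"M01A_cox2"` or `"other"`.
#' @examples
#' classify_atc(c("ARCX", "XAND", "ZZZZ"), load_catalog())
#' @export
classify_atc <- function(stem, catalog = load_catalog()) {
  idx <- match(stem, catalog$stem)
  out <- catalog$atc_class[idx]
  out[is.na(out)] <- "other"
  out
}

# Stem groups used by the guideline audit. H2RA/PPI/COX-2/aspirin membership
# follows the catalog's generic names.
#' Drug-class stem sets used by the audit
#'
#' @return a named list of character vectors: `h2ra`, `ppi`, `cox2`,
#'   `aspirin`.
#' @examples
#' audit_stems()$ppi
#' @export
audit_stems <- function() {
  list(
    h2ra    = "XAND",
    ppi     = c("COTL", "DEXI", "LOSC", "NEXM", "OMPZ", "PARI", "PRVF"),
    cox2    = c("ARCX", "CELB"),
    aspirin = c("ASPT", "ASA.", "CAPN")
  )
}
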