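#' ICD-10 ranges for gastrointestinal complications
#'
#' The GI-complication screen uses three inclusive ICD-10 ranges:
#' K20-K29.9 (oesophagus/stomach/duodenum), K30-K38.9 (dyspepsia, appendix)
#' and K90-K93.8 (other digestive). Codes are handled dot-stripped
#' ("K29.7" as "K297"), matching how diagnosis tables store them.
#'
#' @return a data frame with columns `low`, `high` (dot-stripped bounds).
#' @export
gi_ranges <- function() {
  data.frame(low = c("K20", "K30", "K90"),
             high = c("K299", "K389", "K938"),
             stringsAsFactors = FALSE)
}

# internal: dot-stripped ICD-10 code -> list(letter, value) where value is
# the numeric category.subcategory reading, e.g. "K297" -> 29.7, "K30" -> 30
icd_value <- function(code) {
  code <- toupper(gsub(".", "", code, fixed = TRUE))
  ok <- grepl("^[A-Z][0-9]{2}[0-9]*$", code)
  if (any(!ok)) {
    rx_stop(sprintf("malformed ICD-10 code(s): %s",
                    paste(unique(code[!ok]), collapse = ", ")),
            "rx_icd_error")
  }
  digits <- substring(code, 2)
  val <- as.numeric(paste0(substr(digits, 1, 2), ".",
                           ifelse(nchar(digits) > 2, substring(digits, 3), "0")))
  list(letter = substr(code, 1, 1), value = val)
}

#' Test ICD-10 codes against inclusive code ranges
#'
#' A code lies in a range if its letter matches and its numeric part, read
#' as `category.subcategory` (so "K297" is 29.7), falls inside the inclusive
#' bounds. A 3-character code such as "K30" reads as 30.0 and therefore sits
#' inside a range whose lower bound is "K30". "K939" (93.9) is outside the
#' K90-K93.8 range because 93.9 exceeds the 93.8 upper bound.
#'
#' @param code character vector of dot-stripped ICD-10 codes.
#' @param ranges data frame with `low`, `high` columns (dot-stripped
#'   inclusive bounds); defaults to the GI-complication ranges.
#' @return logical vector, `TRUE` where the code lies in any range.
#' @examples
#' icd_in_ranges(c("K297", "K40", "K939"))  # TRUE FALSE FALSE
#' @export
icd_in_ranges <- function(code, ranges = gi_ranges()) {
  if (length(code) == 0) return(logical(0))
  cv <- icd_value(code)
  lo <- icd_value(ranges$low)
  hi <- icd_value(ranges$high)
  out <- rep(FALSE, length(code))
  for (r in seq_len(nrow(ranges))) {
    out <- out | (cv$letter == lo$letter[r] &
                    cv$value >= lo$value[r] & cv$value <= hi$value[r])
  }
  out
}
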