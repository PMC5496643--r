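#' Parse a dose/frequency code
#'
#' Hospital dose codes follow the grammar `<quantity><unit><schedule><residue>`
#' with unit `CAP` (capsule) or `TAB` (tablet) and schedule `AM` (morning),
#' `PM` (evening) or `BID` (twice a day, morning and evening). Any trailing
#' residue (e.g. `SD`) is not defined by the source system's documentation and
#' is carried verbatim in `modifier`. Unparseable codes are not fatal: they
#' yield an empty meal set with the whole code in `modifier`, so an audit can
#' continue on partial data.
#'
#' @param code character vector of dose/frequency codes (e.g. `"1CAPAM"`).
#' @return a data frame with one row per code: `quantity`, `unit`
#'   (`"CAP"`, `"TAB"` or `"other"`), `morning`, `evening` (logicals),
#'   `modifier`, `parsed` (logical).
#' @examples
#' parse_dose_freq(c("1CAPAM", "1TABBID", "2TABPMSD"))
#' @export
parse_dose_freq <- function(code) {
  code <- as.character(code)
  m <- regexec("^([0-9]+)(CAP|TAB)(AM|PM|BID)(.*)$", code)
  parts <- regmatches(code, m)
  ok <- lengths(parts) == 5
  quantity <- rep(NA_real_, length(code))
  unit <- rep("other", length(code))
  morning <- evening <- rep(FALSE, length(code))
  modifier <- ifelse(is.na(code), "", code)

  if (any(ok)) {
    pm <- do.call(rbind, parts[ok])
    quantity[ok] <- as.numeric(pm[, 2])
    unit[ok] <- pm[, 3]
    sched <- pm[, 4]
    morning[ok] <- sched %in% c("AM", "BID")
    evening[ok] <- sched %in% c("PM", "BID")
    modifier[ok] <- pm[, 5]
  }
  data.frame(code = code, quantity = quantity, unit = unit,
             morning = morning, evening = evening,
             modifier = modifier, parsed = ok,
             stringsAsFactors = FALSE)
}

#' Do two dose schedules share a meal slot?
#'
#' Two drugs are taken "at the same meals" if their parsed schedules share
#' at least one slot (morning or evening). Used to flag same-meal
#' co-administration of two gastro-protective agents.
#'
#' @param a,b single rows (or one-row data frames) from [parse_dose_freq()].
#' @return `TRUE` if the meal sets intersect.
#' @examples
#' s <- parse_dose_freq(c("1CAPAM", "1TABBID", "2TABPM"))
#' schedules_overlap(s[1, ], s[2, ])  # TRUE: shared morning slot
#' schedules_overlap(s[1, ], s[3, ])  # FALSE
#' @export
schedules_overlap <- function(a, b) {
  isTRUE((a$morning && b$morning) || (a$evening && b$evening))
}
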