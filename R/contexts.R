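#' Build per-visit audit contexts
#'
#' Joins prescriptions, diagnoses and demographics into the per-visit facts
#' the guideline audit needs: age in completed years at the visit date, sex,
#' the set of dot-stripped diagnosis codes, an aspirin-exposure flag, and
#' each prescribed stem's parsed dose schedule and clinic.
#'
#' Aspirin exposure is same-day by default: a visit counts as
#' aspirin-exposed if an aspirin stem (ASPT, ASA., CAPN) was prescribed to
#' the patient within `aspirin_window_days` days of the visit date. The
#' source study does not state a look-back window, hence the configurable
#' default of 0 (same day).
#'
#' @param prescriptions data frame: `patient_id`, `date`, `drug_code`, and
#'   optionally `dose_freq`, `clinic`.
#' @param diagnoses data frame: `patient_id`, `date`, `icd10`
#'   (dots allowed; stored dot-stripped).
#' @param patients data frame: `patient_id`, `birth_date`, `sex`
#'   (`"male"`/`"female"`).
#' @param catalog catalog data frame from [load_catalog()].
#' @param aspirin_window_days days around the visit date within which an
#'   aspirin prescription counts as co-therapy.
#' @return a `visit_contexts` object: a list with data frames `visits`
#'   (`visit_key`, `age_years`, `sex`, `aspirin`, `dx` semicolon-joined) and
#'   `drugs` (`visit_key`, `stem`, parsed schedule columns, `clinic`).
#' @export
build_contexts <- function(prescriptions, diagnoses = NULL, patients = NULL,
                           catalog = load_catalog(),
                           aspirin_window_days = 0) {
  need <- c("patient_id", "date", "drug_code")
  if (!all(need %in% names(prescriptions))) {
    rx_stop("prescriptions need columns patient_id, date, drug_code",
            "rx_schema_error")
  }
  pr <- prescriptions
  pr$stem <- normalize_drug_code(pr$drug_code)
  pr$visit_key <- paste(pr$patient_id, pr$date, sep = "|")
  if (is.null(pr$dose_freq)) pr$dose_freq <- rep(NA_character_, nrow(pr))
  if (is.null(pr$clinic)) pr$clinic <- rep(NA_character_, nrow(pr))

  sched <- parse_dose_freq(pr$dose_freq)
  drugs <- data.frame(visit_key = pr$visit_key, stem = pr$stem,
                      quantity = sched$quantity, unit = sched$unit,
                      morning = sched$morning, evening = sched$evening,
                      modifier = sched$modifier, parsed = sched$parsed,
                      clinic = pr$clinic, stringsAsFactors = FALSE)
  drugs <- drugs[!duplicated(paste(drugs$visit_key, drugs$stem, sep = "\x1f")), ]

  keys <- sort(unique(pr$visit_key))
  visits <- data.frame(visit_key = keys, stringsAsFactors = FALSE)
  split_key <- strsplit(keys, "|", fixed = TRUE)
  visits$patient_id <- vapply(split_key, `[`, character(1), 1)
  visits$date <- vapply(split_key, `[`, character(1), 2)

  # demographics: completed years at the visit date
  if (!is.null(patients)) {
    idx <- match(visits$patient_id, patients$patient_id)
    bd <- as.Date(patients$birth_date[idx])
    vd <- as.Date(visits$date)
    visits$age_years <- age_completed_years(bd, vd)
    visits$sex <- as.character(patients$sex[idx])
  } else {
    visits$age_years <- NA_integer_
    visits$sex <- NA_character_
  }

  # diagnoses: dot-stripped set per visit
  if (!is.null(diagnoses) && nrow(diagnoses) > 0) {
    dx <- diagnoses
    dx$visit_key <- paste(dx$patient_id, dx$date, sep = "|")
    dx$code <- toupper(gsub(".", "", dx$icd10, fixed = TRUE))
    dx_by_visit <- split(dx$code, dx$visit_key)
    dx_join <- vapply(dx_by_visit, function(x) paste(sort(unique(x)), collapse = ";"),
                      character(1))
    visits$dx <- unname(dx_join[visits$visit_key])
    visits$dx[is.na(visits$dx)] <- ""
  } else {
    visits$dx <- ""
  }

  # aspirin exposure within the window, per patient
  asp_stems <- audit_stems()$aspirin
  asp_rows <- pr[pr$stem %in% asp_stems, c("patient_id", "date")]
  visits$aspirin <- aspirin_exposed(visits$patient_id, visits$date,
                                    asp_rows, aspirin_window_days)

  structure(list(visits = visits, drugs = drugs), class = "visit_contexts")
}

# internal: floor of the exact year difference between birth and visit dates
age_completed_years <- function(birth, visit) {
  out <- rep(NA_integer_, length(visit))
  ok <- !is.na(birth) & !is.na(visit)
  if (!any(ok)) return(out)
  b <- as.POSIXlt(birth[ok]); v <- as.POSIXlt(visit[ok])
  yrs <- v$year - b$year
  before_bday <- (v$mon < b$mon) | (v$mon == b$mon & v$mday < b$mday)
  out[ok] <- as.integer(yrs - before_bday)
  out
}

# internal: TRUE where an aspirin prescription exists for the patient within
# +/- window days of the visit date
aspirin_exposed <- function(patient_id, date, asp_rows, window_days) {
  if (nrow(asp_rows) == 0) return(rep(FALSE, length(patient_id)))
  if (window_days == 0) {
    key <- paste(patient_id, date, sep = "|")
    akey <- paste(asp_rows$patient_id, asp_rows$date, sep = "|")
    return(key %in% akey)
  }
  vd <- as.Date(date)
  asp_by_pat <- split(as.Date(asp_rows$date), asp_rows$patient_id)
  vapply(seq_along(patient_id), function(i) {
    ad <- asp_by_pat[[patient_id[i]]]
    !is.null(ad) && any(abs(as.numeric(ad - vd[i])) <= window_days)
  }, logical(1))
}

#' Construct visit contexts directly
#'
#' Low-level constructor used by fixture builders and callers that already
#' have per-visit facts (age, diagnosis set, aspirin flag) rather than raw
#' tables.
#'
#' @param visits data frame with `visit_key`, `age_years`, `sex`, `dx`
#'   (semicolon-joined dot-stripped codes, `""` for none), `aspirin`.
#' @param drugs optional data frame with `visit_key`, `stem`, `morning`,
#'   `evening`, `clinic` (missing columns are filled with `NA`).
#' @return a `visit_contexts` object.
#' @export
visit_contexts <- function(visits, drugs = NULL) {
  need <- c("visit_key", "age_years", "dx", "aspirin")
  if (!all(need %in% names(visits))) {
    rx_stop("visits need columns visit_key, age_years, dx, aspirin",
            "rx_schema_error")
  }
  if (is.null(visits$sex)) visits$sex <- rep(NA_character_, nrow(visits))
  if (is.null(drugs)) {
    drugs <- data.frame(visit_key = character(0), stem = character(0),
                        morning = logical(0), evening = logical(0),
                        clinic = character(0), stringsAsFactors = FALSE)
  }
  for (col in c("morning", "evening")) {
    if (is.null(drugs[[col]])) drugs[[col]] <- rep(NA, nrow(drugs))
  }
  if (is.null(drugs$clinic)) drugs$clinic <- rep(NA_character_, nrow(drugs))
  structure(list(visits = visits, drugs = drugs), class = "visit_contexts")
}
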