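#' @name guideline_audit
#' @title Guideline audit of flagged co-prescription patterns
#'
#' @description
#' Two co-prescription patterns flagged by rule mining are audited against
#' explicit guideline criteria:
#'
#' * **H2RA + PPI** (e.g. ranitidine with omeprazole): concomitant use is
#'   recommended only for gastro-oesophageal reflux disease, so a visit is
#'   concordant iff a GORD diagnosis (ICD-10 prefix K21) is coded.
#' * **COX-2 inhibitor + PPI** (etoricoxib/celecoxib with a PPI):
#'   recommended only for patients at high GI risk — aged 60 or over, with a
#'   GI complication (K20-K29.9, K30-K38.9, K90-K93.8), or on aspirin. A
#'   visit is discordant iff none of the three applies.
#'
#' Findings carry the per-visit criteria so summaries can reproduce
#' category/frequency tables.
NULL

# internal: one row per flagged visit with audit criteria filled in
audit_findings <- function(txns, contexts, pattern, group_a, group_b) {
  stopifnot(inherits(txns, "transaction_set"),
            inherits(contexts, "visit_contexts"))
  has_a <- vapply(txns$items, function(it) any(group_a %in% it), logical(1))
  has_b <- vapply(txns$items, function(it) any(group_b %in% it), logical(1))
  flagged <- which(has_a & has_b)
  if (length(flagged) == 0) {
    return(empty_findings())
  }
  v <- contexts$visits
  idx <- match(txns$visit_key[flagged], v$visit_key)
  known <- !is.na(idx)
  if (any(!known)) {
    warning(sprintf("%d flagged visit(s) have no audit context: %s",
                    sum(!known),
                    paste(utils::head(txns$visit_key[flagged][!known], 5),
                          collapse = ", ")))
  }

  dx <- ifelse(known, v$dx[idx], NA_character_)
  dx_sets <- strsplit(ifelse(is.na(dx), "", dx), ";", fixed = TRUE)
  gord <- vapply(dx_sets, function(d) any(startsWith(d, "K21")), logical(1))
  gi <- vapply(dx_sets, function(d) length(d) > 0 && any(icd_in_ranges(d)),
               logical(1))
  age <- ifelse(known, v$age_years[idx], NA_integer_)
  asp <- ifelse(known, v$aspirin[idx], NA)
  gord[!known] <- NA
  gi[!known] <- NA

  meal_clinic <- t(vapply(flagged, function(i) {
    same_meal_clinic(txns$visit_key[i], txns$items[[i]], contexts,
                     group_a, group_b)
  }, logical(2)))

  out <- data.frame(
    visit_key = txns$visit_key[flagged],
    pattern = pattern,
    drugs = vapply(txns$items[flagged], paste, character(1), collapse = "+"),
    dx = ifelse(is.na(dx), "", dx),
    gord_dx = gord,
    age_years = as.integer(age),
    age_ge_60 = !is.na(age) & age >= 60,
    gi_complication = gi,
    aspirin = as.logical(asp),
    same_meal = meal_clinic[, 1],
    same_clinic = meal_clinic[, 2],
    context_known = known,
    stringsAsFactors = FALSE
  )
  out$age_ge_60[is.na(age)] <- NA

  if (pattern == "H2RA_PPI") {
    out$verdict <- ifelse(!known, "discordant",
                          ifelse(out$gord_dx, "concordant", "discordant"))
  } else {
    complete <- known & !is.na(out$age_ge_60)
    disc <- !out$age_ge_60 & !out$gi_complication & !out$aspirin
    out$verdict <- ifelse(!known, "discordant",
                          ifelse(!complete, NA_character_,
                                 ifelse(disc, "discordant", "concordant")))
  }
  rownames(out) <- NULL
  out
}

empty_findings <- function() {
  data.frame(visit_key = character(0), pattern = character(0),
             drugs = character(0), dx = character(0), gord_dx = logical(0),
             age_years = integer(0), age_ge_60 = logical(0),
             gi_complication = logical(0), aspirin = logical(0),
             same_meal = logical(0), same_clinic = logical(0),
             context_known = logical(0), verdict = character(0),
             stringsAsFactors = FALSE)
}

# internal: do any cross-class drug pairs at this visit share a meal slot /
# a clinic? NA when schedule or clinic data are unavailable.
same_meal_clinic <- function(key, items, contexts, group_a, group_b) {
  d <- contexts$drugs[contexts$drugs$visit_key == key, , drop = FALSE]
  a <- d[d$stem %in% intersect(items, group_a), , drop = FALSE]
  b <- d[d$stem %in% intersect(items, group_b), , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) return(c(NA, NA))
  meal <- FALSE; clinic <- FALSE
  meal_known <- clinic_known <- FALSE
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (!is.na(a$morning[i]) && !is.na(b$morning[j])) {
        meal_known <- TRUE
        if ((a$morning[i] && b$morning[j]) || (a$evening[i] && b$evening[j])) {
          meal <- TRUE
        }
      }
      if (!is.na(a$clinic[i]) && !is.na(b$clinic[j])) {
        clinic_known <- TRUE
        if (a$clinic[i] == b$clinic[j]) clinic <- TRUE
      }
    }
  }
  c(if (meal_known) meal else NA, if (clinic_known) clinic else NA)
}

#' Find H2RA + PPI co-prescription visits
#'
#' @param txns a [transaction_set()].
#' @param contexts a `visit_contexts` object covering the flagged visits.
#' @return a findings data frame (one row per flagged visit) with criteria
#'   columns and a `verdict` (`"concordant"` iff a GORD diagnosis is coded).
#'   Visits lacking context are flagged `context_known = FALSE`, default to
#'   discordant, and are excluded from summary denominators.
#' @export
find_h2ra_ppi_visits <- function(txns, contexts) {
  st <- audit_stems()
  audit_findings(txns, contexts, "H2RA_PPI", st$h2ra, st$ppi)
}

#' Find COX-2 inhibitor + PPI co-prescription visits
#'
#' @inheritParams find_h2ra_ppi_visits
#' @return a findings data frame; `verdict` is `"discordant"` iff the
#'   patient is under 60 with no GI-complication diagnosis and no aspirin
#'   exposure. Visits with missing age have `verdict = NA` and are excluded
#'   from summary denominators.
#' @export
find_cox2_ppi_visits <- function(txns, contexts) {
  st <- audit_stems()
  audit_findings(txns, contexts, "COX2_PPI", st$cox2, st$ppi)
}

# internal: category/count/percent block; percents by exact integer rounding
category_block <- function(labels, counts, total) {
  data.frame(category = labels, count = as.integer(counts),
             percent = if (total > 0) round_ratio(100 * counts, total, 1)
                       else rep(NA_real_, length(counts)),
             stringsAsFactors = FALSE)
}

#' Summarize audit findings into category tables
#'
#' For the COX-2 + PPI pattern: age bands (>= 60, 50-59, < 50),
#' GI complication yes/no, aspirin yes/no, and the joint
#' guideline-discordance category (age < 60 with no GI complication and no
#' aspirin). For the H2RA + PPI pattern: GORD vs non-GORD and a
#' diagnosis-code frequency table (each visit represented by its GORD code
#' if any, else its first GI-range code, else "none"). Percentages are
#' computed on visits with complete context; incomplete visits are counted
#' separately in `excluded`.
#'
#' @param findings output of [find_h2ra_ppi_visits()] or
#'   [find_cox2_ppi_visits()].
#' @param pattern `"H2RA_PPI"` or `"COX2_PPI"`; defaults to the findings'
#'   pattern.
#' @return an `audit_summary` list: `pattern`, `total` (complete-context
#'   visits), `excluded`, and `tables` (named list of
#'   category/count/percent data frames).
#' @export
summarize_audit <- function(findings, pattern = NULL) {
  if (is.null(pattern)) {
    pattern <- if (nrow(findings) > 0) findings$pattern[1] else "H2RA_PPI"
  }
  if (nrow(findings) > 0 && any(findings$pattern != pattern)) {
    rx_stop("findings mix audit patterns", "rx_schema_error")
  }
  if (pattern == "COX2_PPI") {
    ok <- findings$context_known & !is.na(findings$age_ge_60)
  } else {
    ok <- findings$context_known
  }
  f <- findings[ok, , drop = FALSE]
  total <- nrow(f)
  tables <- list()

  if (pattern == "H2RA_PPI") {
    n_gord <- sum(f$gord_dx)
    tables$gord <- category_block(c("GORD", "non-GORD"),
                                  c(n_gord, total - n_gord), total)
    rep_code <- vapply(strsplit(f$dx, ";", fixed = TRUE), function(d) {
      d <- d[nzchar(d)]
      k21 <- d[startsWith(d, "K21")]
      if (length(k21) > 0) return(sort(k21)[1])
      gi <- d[icd_in_ranges(d)]
      if (length(gi) > 0) return(sort(gi)[1])
      "none"
    }, character(1))
    tab <- sort(table(rep_code), decreasing = TRUE)
    tables$diagnosis <- category_block(names(tab), as.integer(tab), total)
  } else {
    band <- ifelse(f$age_ge_60, ">=60",
                   ifelse(f$age_years >= 50, "50-59", "<50"))
    bands <- c(">=60", "50-59", "<50")
    tables$age <- category_block(bands,
                                 vapply(bands, function(b) sum(band == b),
                                        numeric(1)), total)
    tables$gi_complication <- category_block(
      c("yes", "no"), c(sum(f$gi_complication), sum(!f$gi_complication)), total)
    tables$aspirin <- category_block(
      c("yes", "no"), c(sum(f$aspirin), sum(!f$aspirin)), total)
    disc <- f$verdict == "discordant"
    tables$discordant <- category_block(
      c("yes", "no"), c(sum(disc), sum(!disc)), total)
  }

  structure(list(pattern = pattern, total = total,
                 excluded = sum(!ok), tables = tables),
            class = "audit_summary")
}

#' @export
print.audit_summary <- function(x, ...) {
  cat(sprintf("audit_summary: pattern %s, %d visits (%d excluded)\n",
              x$pattern, x$total, x$excluded))
  for (nm in names(x$tables)) {
    cat("--", nm, "--\n")
    print(x$tables[[nm]], row.names = FALSE)
  }
  invisible(x)
}
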