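#' Pipeline configuration
#'
#' Collects input paths and analysis settings for [run_pipeline()].
#'
#' @param prescriptions,diagnoses,patients paths to the input CSV files
#'   (headers `patient_id,date,drug_code,dose_freq,clinic`;
#'   `patient_id,date,icd10`; `patient_id,birth_date,sex`). `diagnoses` and
#'   `patients` may be `NULL` to skip the audit stage.
#' @param out_dir output directory (created if absent).
#' @param catalog optional path to a drug catalog CSV; defaults to the
#'   packaged catalog.
#' @param min_support,min_confidence,max_rule_items mining thresholds, see
#'   [mining_config()].
#' @param aspirin_window_days aspirin co-therapy look-back window, see
#'   [build_contexts()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(prescriptions, out_dir,
                            diagnoses = NULL, patients = NULL,
                            catalog = NULL,
                            min_support = 0.01, min_confidence = 0.5,
                            max_rule_items = 2L,
                            aspirin_window_days = 0) {
  for (p in c(prescriptions, diagnoses, patients, catalog)) {
    if (!file.exists(p)) {
      rx_stop(sprintf("input file not found: '%s'", p), "rx_config_error")
    }
  }
  mining_config(min_support, min_confidence, max_rule_items)  # validates
  structure(list(prescriptions = prescriptions, diagnoses = diagnoses,
                 patients = patients, catalog = catalog, out_dir = out_dir,
                 min_support = min_support, min_confidence = min_confidence,
                 max_rule_items = as.integer(max_rule_items),
                 aspirin_window_days = aspirin_window_days),
            class = "pipeline_config")
}

#' Run the full co-prescription analysis pipeline
#'
#' Executes ETL (prescription rows to per-visit transactions), association
#' rule mining, and — when diagnosis and demographic tables are supplied —
#' the guideline audit of both flagged patterns. Writes
#' `transactions.jsonl`, `rules.csv`, `findings.csv`, `summary.csv` and a
#' `manifest.json` (configuration echo, input checksums, stage counts,
#' output checksums) to the output directory. Re-running with identical
#' inputs and configuration yields byte-identical outputs. Any stage failure
#' removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage-count messages.
#' @return invisibly, a list with `txns`, `omitted`, `rules`, `findings`,
#'   `summaries`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(config$out_dir,
                       c("transactions.jsonl", "rules.csv", "findings.csv",
                         "summary.csv", "manifest.json"))
  names(outputs) <- c("transactions", "rules", "findings", "summary",
                      "manifest")
  say <- function(...) if (!quiet) message(sprintf(...))

  res <- tryCatch({
    catalog <- load_catalog(config$catalog)
    rx <- utils::read.csv(config$prescriptions, stringsAsFactors = FALSE,
                          colClasses = "character")
    say("etl: %d prescription rows in", nrow(rx))
    bt <- build_transactions(rx, catalog)
    say("etl: %d patient-days; %d omitted (single-item or out of scope); %d retained",
        bt$txns$n + bt$omitted, bt$omitted, bt$txns$n)
    write_transactions_jsonl(bt$txns, outputs["transactions"])

    rules <- mine_rules(bt$txns, config$min_support, config$min_confidence,
                        config$max_rule_items)
    say("mine: %d rules at support >= %g, confidence >= %g",
        nrow(rules), config$min_support, config$min_confidence)
    utils::write.csv(format_rules(rules), outputs["rules"], row.names = FALSE)

    findings <- empty_findings()
    summaries <- list()
    if (!is.null(config$diagnoses) && !is.null(config$patients)) {
      dx <- utils::read.csv(config$diagnoses, stringsAsFactors = FALSE,
                            colClasses = "character")
      pat <- utils::read.csv(config$patients, stringsAsFactors = FALSE,
                             colClasses = "character")
      contexts <- build_contexts(rx, dx, pat, catalog,
                                 config$aspirin_window_days)
      findings <- rbind(find_h2ra_ppi_visits(bt$txns, contexts),
                        find_cox2_ppi_visits(bt$txns, contexts))
      say("audit: %d flagged visits (%d H2RA+PPI, %d COX2+PPI)",
          nrow(findings), sum(findings$pattern == "H2RA_PPI"),
          sum(findings$pattern == "COX2_PPI"))
      for (p in c("H2RA_PPI", "COX2_PPI")) {
        f <- findings[findings$pattern == p, , drop = FALSE]
        if (nrow(f) > 0) summaries[[p]] <- summarize_audit(f, p)
      }
    }
    utils::write.csv(findings, outputs["findings"], row.names = FALSE)
    utils::write.csv(summary_frame(summaries), outputs["summary"],
                     row.names = FALSE)

    manifest <- list(
      config = unclass(config),
      inputs = checksum_list(c(config$prescriptions, config$diagnoses,
                               config$patients, config$catalog)),
      counts = list(prescription_rows = nrow(rx),
                    patient_days = bt$txns$n + bt$omitted,
                    omitted = bt$omitted, transactions = bt$txns$n,
                    rules = nrow(rules), findings = nrow(findings))
    )
    manifest$outputs <- checksum_list(outputs[names(outputs) != "manifest"])
    jsonlite::write_json(manifest, outputs["manifest"], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
    list(txns = bt$txns, omitted = bt$omitted, rules = rules,
         findings = findings, summaries = summaries, manifest = manifest)
  }, error = function(e) {
    unlink(outputs)
    stop(e)
  })
  invisible(res)
}

# internal: md5 checksums keyed by file name
checksum_list <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  paths <- unlist(paths)
  as.list(stats::setNames(unname(tools::md5sum(paths)), basename(paths)))
}

# internal: flatten audit summaries to a single category table
summary_frame <- function(summaries) {
  rows <- list()
  for (p in names(summaries)) {
    s <- summaries[[p]]
    for (nm in names(s$tables)) {
      t <- s$tables[[nm]]
      t$pattern <- p
      t$table <- nm
      rows[[length(rows) + 1]] <- t[, c("pattern", "table", "category",
                                        "count", "percent")]
    }
  }
  if (length(rows) == 0) {
    return(data.frame(pattern = character(0), table = character(0),
                      category = character(0), count = integer(0),
                      percent = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Format mined rules for reporting
#'
#' Adds a rule number and renders support, confidence and lift at 4
#' decimals (half-away-from-zero on the exact integer counts); counts stay
#' exact.
#'
#' @param rules an `association_rules` data frame from [mine_rules()].
#' @param digits decimals for the displayed statistics.
#' @return a data frame with columns `rule_no`, `lhs`, `rhs`, `support`,
#'   `confidence`, `lift` (formatted character), `support_count`.
#' @export
format_rules <- function(rules, digits = 4L) {
  fmt <- function(x) formatC(x, format = "f", digits = digits)
  data.frame(
    rule_no = seq_len(nrow(rules)),
    lhs = rules$lhs, rhs = rules$rhs,
    support = fmt(round_ratio(rules$support_count, rules$n, digits)),
    confidence = fmt(round_ratio(rules$support_count, rules$count_lhs, digits)),
    lift = fmt(round_ratio(rules$support_count * rules$n,
                           rules$count_lhs * rules$count_rhs, digits)),
    support_count = rules$support_count,
    stringsAsFactors = FALSE
  )
}

#' Render a text report of rules and audit summaries
#'
#' @param rules an `association_rules` data frame.
#' @param summaries named list of `audit_summary` objects (may be empty).
#' @return a character vector of report lines (also printable with
#'   `writeLines()`).
#' @export
render_report <- function(rules, summaries = list()) {
  lines <- c("== Association rules ==")
  ft <- format_rules(rules)
  lines <- c(lines, utils::capture.output(print(ft, row.names = FALSE)))
  for (p in names(summaries)) {
    s <- summaries[[p]]
    lines <- c(lines, "", sprintf("== Audit: %s (n = %d, excluded = %d) ==",
                                  p, s$total, s$excluded))
    for (nm in names(s$tables)) {
      t <- s$tables[[nm]]
      t$percent <- formatC(t$percent, format = "f", digits = 1)
      lines <- c(lines, sprintf("-- %s --", nm),
                 utils::capture.output(print(t, row.names = FALSE)))
    }
  }
  lines
}
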