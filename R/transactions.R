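#' Construct a transaction set
#'
#' A transaction is the set of drug stems prescribed to one patient on one
#' day; the transaction set is the unit the association-rule engine mines.
#' Items within a transaction are deduplicated and sorted; transactions are
#' sorted by visit key so construction is deterministic.
#'
#' @param items list of character vectors (one per transaction).
#' @param visit_key character vector of visit keys (`"HN|YYYY-MM-DD"`);
#'   generated keys `txn000001, ...` are used if omitted.
#' @return an object of class `transaction_set` with elements `visit_key`,
#'   `items` (list of sorted unique stems) and `n`.
#' @examples
#' txns <- transaction_set(list(c("OMPZ", "XAND"), c("NAPX", "OMPZ")))
#' txns$n
#' @export
transaction_set <- function(items, visit_key = NULL) {
  stopifnot(is.list(items))
  if (is.null(visit_key)) {
    visit_key <- sprintf("txn%06d", seq_along(items))
  }
  if (length(visit_key) != length(items)) {
    rx_stop("visit_key and items lengths differ", "rx_schema_error")
  }
  if (anyDuplicated(visit_key)) {
    rx_stop("duplicate visit keys in transaction set", "rx_schema_error")
  }
  items <- lapply(items, function(x) sort(unique(as.character(x))))
  ord <- order(visit_key)
  structure(
    list(visit_key = visit_key[ord], items = items[ord],
         n = length(items)),
    class = "transaction_set"
  )
}

#' @export
print.transaction_set <- function(x, ...) {
  cat(sprintf("transaction_set: %d transactions, %d distinct items\n",
              x$n, length(unique(unlist(x$items)))))
  invisible(x)
}

#' Build per-visit transactions from prescription rows
#'
#' Normalizes raw drug codes to stems, keeps only stems in the audit's drug
#' classes (antacids, peptic-ulcer/GORD drugs, NSAIDs including COX-2
#' inhibitors), groups rows into patient-day visits, deduplicates stems
#' within a visit, and drops visits with fewer than two distinct stems —
#' single-drug visits carry no co-prescription information.
#'
#' @param rows data frame with columns `patient_id`, `date`, `drug_code`
#'   (columns `dose_freq` and `clinic` may be present and are ignored here).
#' @param catalog catalog data frame from [load_catalog()].
#' @return a list with `txns` (a [transaction_set()] of the retained
#'   multi-item visits) and `omitted` (the number of distinct patient-days in
#'   the input that were dropped, including days whose drugs all fall outside
#'   the audit classes). Retained plus omitted always equals the number of
#'   distinct patient-days in the input.
#' @examples
#' cat <- load_catalog()
#' rows <- data.frame(
#'   patient_id = c("p1", "p1", "p2"),
#'   date = c("2014-01-05", "2014-01-05", "2014-01-05"),
#'   drug_code = c("OMPZ-C-", "XAND-T-", "IBUP1T-")
#' )
#' build_transactions(rows, cat)  # p1 kept (2 stems), p2 omitted
#' @export
build_transactions <- function(rows, catalog = load_catalog()) {
  need <- c("patient_id", "date", "drug_code")
  if (!all(need %in% names(rows))) {
    rx_stop("prescription rows need columns patient_id, date, drug_code",
            "rx_schema_error")
  }
  if (nrow(rows) == 0) {
    return(list(txns = transaction_set(list(), character(0)), omitted = 0L))
  }
  key_all <- paste(rows$patient_id, rows$date, sep = "|")
  n_days <- length(unique(key_all))

  stem <- normalize_drug_code(rows$drug_code)
  keep <- classify_atc(stem, catalog) != "other"
  key <- key_all[keep]
  stem <- stem[keep]

  if (length(key) == 0) {
    return(list(txns = transaction_set(list(), character(0)),
                omitted = n_days))
  }
  # deduplicate (visit, stem) pairs, then count stems per visit
  dup <- duplicated(paste(key, stem, sep = "\x1f"))
  key <- key[!dup]
  stem <- stem[!dup]
  per_visit <- split(stem, key)
  multi <- per_visit[lengths(per_visit) >= 2]

  txns <- transaction_set(unname(multi), names(multi))
  list(txns = txns, omitted = n_days - txns$n)
}

#' Write / read transactions as JSON lines
#'
#' One JSON object per line: `{"visit_key": ..., "items": [...]}`.
#'
#' @param txns a [transaction_set()].
#' @param path output file path.
#' @return `write_transactions_jsonl()` returns `path` invisibly;
#'   `read_transactions_jsonl()` returns a [transaction_set()].
#' @export
write_transactions_jsonl <- function(txns, path) {
  stopifnot(inherits(txns, "transaction_set"))
  lines <- vapply(seq_len(txns$n), function(i) {
    jsonlite::toJSON(list(visit_key = jsonlite::unbox(txns$visit_key[i]),
                          items = txns$items[[i]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transactions_jsonl
#' @export
read_transactions_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  objs <- lapply(lines, jsonlite::fromJSON)
  transaction_set(
    items = lapply(objs, function(o) as.character(o$items)),
    visit_key = vapply(objs, function(o) as.character(o$visit_key), character(1))
  )
}
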