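# shared test helpers: tiny transaction builders and random instances

# transaction set from compact strings: tx("AB", "AC") = {A,B}, {A,C}
tx <- function(...) {
  transaction_set(lapply(list(...), function(s) strsplit(s, "")[[1]]))
}

# random transaction set with <= n_items distinct single-letter items
random_txns <- function(n_txn, n_items, min_len = 1, max_len = NULL) {
  univ <- LETTERS[seq_len(n_items)]
  if (is.null(max_len)) max_len <- n_items
  transaction_set(lapply(seq_len(n_txn), function(i) {
    k <- sample(min_len:max_len, 1)
    sample(univ, k)
  }))
}

# canonical rule keys for set comparison
rule_keys <- function(rules) sort(paste(rules$lhs, rules$rhs, sep = "=>"))

# joint/marginal counts of a pair over a cohort's full visit set
pair_counts_from_cohort <- function(cohort, x, y) {
  pr <- cohort$prescriptions
  key <- paste(pr$patient_id, pr$date, sep = "|")
  stem <- substr(pr$drug_code, 1, 4)
  kx <- unique(key[stem == x])
  ky <- unique(key[stem == y])
  list(n = nrow(cohort$visits), nx = length(kx), ny = length(ky),
       nxy = length(intersect(kx, ky)))
}
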