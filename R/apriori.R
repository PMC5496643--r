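#' Mining configuration
#'
#' @param min_support minimum support proportion, in (0, 1].
#' @param min_confidence minimum confidence proportion, in (0, 1].
#' @param max_rule_items maximum number of items in a rule (antecedent plus
#'   consequent). The default 2 restricts reporting to single-item
#'   antecedent and consequent pairs, the shape used for co-prescription
#'   screening; larger itemsets are still mined when this is raised.
#' @param rounding_decimals decimals for displayed statistics.
#' @return a `mining_config` list.
#' @examples
#' mining_config(0.01, 0.5)
#' @export
mining_config <- function(min_support = 0.01, min_confidence = 0.5,
                          max_rule_items = 2L, rounding_decimals = 4L) {
  if (!(min_support > 0 && min_support <= 1)) {
    rx_stop("min_support must be in (0, 1]", "rx_config_error")
  }
  if (!(min_confidence > 0 && min_confidence <= 1)) {
    rx_stop("min_confidence must be in (0, 1]", "rx_config_error")
  }
  if (max_rule_items < 2) rx_stop("max_rule_items must be >= 2", "rx_config_error")
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 max_rule_items = as.integer(max_rule_items),
                 rounding_decimals = as.integer(rounding_decimals)),
            class = "mining_config")
}

# internal: item -> sorted vector of transaction indices (tid-lists)
tid_lists <- function(txns) {
  len <- lengths(txns$items)
  item <- unlist(txns$items, use.names = FALSE)
  tid <- rep.int(seq_len(txns$n), len)
  split(tid, item)
}

# internal canonical key for an itemset (items assumed sorted)
iset_key <- function(items) paste(items, collapse = "\x1f")

#' Support of an itemset
#'
#' The number and proportion of transactions containing every item of the
#' set. The proportion is the raw ratio `count / n`; rounding happens only
#' at report time.
#'
#' @param items character vector of stems.
#' @param txns a [transaction_set()].
#' @return a list with `count` and `proportion`.
#' @examples
#' txns <- transaction_set(list(c("A", "B"), c("A", "B"), c("A", "C")))
#' itemset_support(c("A", "B"), txns)
#' @export
itemset_support <- function(items, txns) {
  stopifnot(inherits(txns, "transaction_set"))
  if (txns$n == 0) {
    rx_stop("support proportion undefined on an empty transaction set",
            "rx_empty_transactions")
  }
  items <- unique(as.character(items))
  count <- sum(vapply(txns$items, function(t) all(items %in% t), logical(1)))
  list(count = count, proportion = count / txns$n)
}

#' Level-wise Apriori frequent-itemset mining
#'
#' Classical Apriori: frequent 1-itemsets first, then candidate k-itemsets
#' joined from frequent (k-1)-itemsets sharing their first k-2 items, pruned
#' by the anti-monotonicity of support (every subset of a frequent itemset
#' is frequent), with support counted on transaction-id lists. Output is
#' sorted by itemset size then lexicographically, so results are
#' deterministic.
#'
#' @param txns a [transaction_set()].
#' @param config a [mining_config()].
#' @param max_size largest itemset size to mine; defaults to
#'   `config$max_rule_items`. Use `Inf` for all sizes.
#' @return a data frame with columns `items` (list column of sorted stems),
#'   `size`, `count`, `support`.
#' @examples
#' txns <- transaction_set(list(c("A","B"), c("A","B"), c("A","C"),
#'                              c("B","C"), "A"))
#' frequent_itemsets(txns, mining_config(0.4, 0.5))
#' @export
frequent_itemsets <- function(txns, config = mining_config(),
                              max_size = config$max_rule_items) {
  stopifnot(inherits(txns, "transaction_set"))
  empty <- data.frame(size = integer(0), count = integer(0),
                      support = numeric(0))
  empty$items <- list()
  if (txns$n == 0) return(empty[, c("items", "size", "count", "support")])

  # count >= min_support * n, on integers (ceiling; exact boundary included)
  min_count <- as.integer(ceiling(config$min_support * txns$n - 1e-9))
  min_count <- max(min_count, 1L)

  tids <- tid_lists(txns)
  counts1 <- lengths(tids)
  freq_items <- sort(names(counts1)[counts1 >= min_count])
  if (length(freq_items) == 0) return(empty[, c("items", "size", "count", "support")])

  levels <- list()
  levels[[1]] <- list(items = as.list(freq_items),
                      tids = tids[freq_items],
                      count = unname(counts1[freq_items]))

  k <- 1L
  while (k < max_size && length(levels[[k]]$items) >= 2) {
    prev <- levels[[k]]
    prev_keys <- vapply(prev$items, iset_key, character(1))
    cand_items <- list(); cand_tids <- list(); cand_count <- integer(0)
    m <- length(prev$items)
    # join step: pairs sharing the first k-1 items (items kept sorted)
    prefix <- vapply(prev$items, function(x) iset_key(x[-length(x)]), character(1))
    groups <- split(seq_len(m), prefix)
    for (g in groups) {
      if (length(g) < 2) next
      for (a in seq_len(length(g) - 1)) {
        for (b in (a + 1):length(g)) {
          i <- g[a]; j <- g[b]
          cand <- sort(union(prev$items[[i]], prev$items[[j]]))
          if (length(cand) != k + 1) next
          # prune: all k-subsets must be frequent
          subs_ok <- all(vapply(seq_along(cand), function(d) {
            iset_key(cand[-d]) %in% prev_keys
          }, logical(1)))
          if (!subs_ok) next
          tid <- intersect(prev$tids[[i]], prev$tids[[j]])
          if (length(tid) >= min_count) {
            cand_items[[length(cand_items) + 1]] <- cand
            cand_tids[[length(cand_tids) + 1]] <- tid
            cand_count <- c(cand_count, length(tid))
          }
        }
      }
    }
    if (length(cand_items) == 0) break
    # joins from different prefix groups cannot duplicate; joins within a
    # group are unique pairs, so candidates are already distinct
    ord <- order(vapply(cand_items, iset_key, character(1)))
    levels[[k + 1]] <- list(items = cand_items[ord], tids = cand_tids[ord],
                            count = cand_count[ord])
    k <- k + 1L
  }

  items <- do.call(c, lapply(levels, `[[`, "items"))
  count <- unlist(lapply(levels, `[[`, "count"))
  out <- data.frame(size = lengths(items), count = as.integer(count),
                    support = count / txns$n)
  out$items <- items
  out <- out[order(out$size, vapply(items, iset_key, character(1))), ]
  rownames(out) <- NULL
  out[, c("items", "size", "count", "support")]
}

# internal: all ordered (lhs, rhs) bipartitions of a sorted itemset
rule_partitions <- function(items) {
  k <- length(items)
  out <- list()
  for (mask in 1:(2^k - 2)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(k - 1))))
    out[[length(out) + 1]] <- list(lhs = items[sel], rhs = items[!sel])
  }
  out
}

# internal: assemble the rules data frame from count vectors
make_rules_df <- function(lhs, rhs, count_xy, count_lhs, count_rhs, n) {
  df <- data.frame(
    lhs = vapply(lhs, paste, character(1), collapse = "+"),
    rhs = vapply(rhs, paste, character(1), collapse = "+"),
    support_count = as.integer(count_xy),
    count_lhs = as.integer(count_lhs),
    count_rhs = as.integer(count_rhs),
    n = rep(as.integer(n), length(count_xy)),
    stringsAsFactors = FALSE
  )
  df$support <- df$support_count / n
  df$confidence <- df$support_count / df$count_lhs
  df$lift <- (df$support_count * n) / (df$count_lhs * df$count_rhs)
  # order: descending lift, then descending support, then lexicographic lhs
  df <- df[order(-df$lift, -df$support, df$lhs, df$rhs), ]
  rownames(df) <- NULL
  class(df) <- c("association_rules", "data.frame")
  df
}

#' Derive association rules from frequent itemsets
#'
#' For every frequent itemset of two or more items (up to
#' `config$max_rule_items`), emits each ordered antecedent/consequent
#' bipartition and keeps rules whose confidence meets the threshold. With
#' the default `max_rule_items = 2` this yields single-item to single-item
#' rules; both directions of a pair are distinct rules. Support, confidence
#' and lift are computed from exact integer counts:
#' support = P(X and Y), confidence = P(Y | X),
#' lift = P(X,Y) / (P(X) P(Y)) — lift below/above/at 1 indicates
#' negative/positive/no association.
#'
#' @param frequents output of [frequent_itemsets()] computed at
#'   `config$min_support`.
#' @param txns the [transaction_set()] the itemsets were mined from.
#' @param config a [mining_config()].
#' @return an `association_rules` data frame with columns `lhs`, `rhs`,
#'   `support_count`, `count_lhs`, `count_rhs`, `n`, `support`,
#'   `confidence`, `lift`, ordered by descending lift then support then
#'   antecedent.
#' @export
derive_rules <- function(frequents, txns, config = mining_config()) {
  stopifnot(inherits(txns, "transaction_set"))
  counts <- stats::setNames(frequents$count,
                            vapply(frequents$items, iset_key, character(1)))
  lhs_l <- list(); rhs_l <- list()
  cxy <- cx <- cy <- integer(0)
  big <- frequents[frequents$size >= 2 & frequents$size <= config$max_rule_items, ]
  for (i in seq_len(nrow(big))) {
    items <- big$items[[i]]
    for (p in rule_partitions(items)) {
      kx <- iset_key(sort(p$lhs)); ky <- iset_key(sort(p$rhs))
      # subsets of a frequent itemset are frequent, so counts are present
      conf <- big$count[i] / counts[[kx]]
      if (conf >= config$min_confidence - 1e-12) {
        lhs_l[[length(lhs_l) + 1]] <- sort(p$lhs)
        rhs_l[[length(rhs_l) + 1]] <- sort(p$rhs)
        cxy <- c(cxy, big$count[i])
        cx <- c(cx, counts[[kx]])
        cy <- c(cy, counts[[ky]])
      }
    }
  }
  make_rules_df(lhs_l, rhs_l, cxy, cx, cy, txns$n)
}

#' Mine association rules (Apriori)
#'
#' Convenience wrapper: [frequent_itemsets()] followed by [derive_rules()].
#'
#' @param txns a [transaction_set()].
#' @param min_support,min_confidence,max_rule_items see [mining_config()].
#' @return an `association_rules` data frame (see [derive_rules()]).
#' @examples
#' txns <- transaction_set(list(c("OMPZ","XAND"), c("OMPZ","XAND"), "OMPZ"))
#' mine_rules(txns, min_support = 0.5, min_confidence = 0.5)
#' @export
mine_rules <- function(txns, min_support = 0.01, min_confidence = 0.5,
                       max_rule_items = 2L) {
  config <- mining_config(min_support, min_confidence, max_rule_items)
  derive_rules(frequent_itemsets(txns, config), txns, config)
}

#' Lift of an association rule
#'
#' `P(X,Y) / (P(X) P(Y))` from exact counts.
#'
#' @param count_xy joint count of antecedent and consequent.
#' @param count_x,count_y marginal counts (must be positive).
#' @param n number of transactions.
#' @return the lift value.
#' @examples
#' rule_lift(1, 2, 2, 4)  # independence: 1
#' @export
rule_lift <- function(count_xy, count_x, count_y, n) {
  if (any(count_x <= 0) || any(count_y <= 0)) {
    rx_stop("lift undefined: zero marginal count", "rx_zero_marginal")
  }
  (count_xy * n) / (count_x * count_y)
}

#' Brute-force rule mining oracle
#'
#' Enumerates every non-empty itemset by exhaustive subset scan and every
#' ordered rule bipartition, applying the same thresholds as
#' [derive_rules()]. Exponential in the number of distinct items, so it
#' refuses more than 12; intended as an independent correctness oracle for
#' the Apriori path, not for analysis use.
#'
#' @param txns a [transaction_set()] with at most 12 distinct items.
#' @param config a [mining_config()].
#' @return an `association_rules` data frame (same shape as
#'   [derive_rules()]).
#' @export
brute_force_rules <- function(txns, config = mining_config()) {
  stopifnot(inherits(txns, "transaction_set"))
  univ <- sort(unique(unlist(txns$items)))
  if (length(univ) > 12) {
    rx_stop("brute-force oracle refuses more than 12 distinct items",
            "rx_guard_error")
  }
  if (txns$n == 0 || length(univ) == 0) {
    return(make_rules_df(list(), list(), integer(0), integer(0), integer(0),
                         max(txns$n, 1L))[0, ])
  }
  min_count <- max(1L, as.integer(ceiling(config$min_support * txns$n - 1e-9)))
  p <- length(univ)
  masks <- 1:(2^p - 1)
  sets <- lapply(masks, function(m) univ[as.logical(bitwAnd(m, 2^(0:(p - 1))))])
  cnt <- vapply(sets, function(s) {
    sum(vapply(txns$items, function(t) all(s %in% t), logical(1)))
  }, numeric(1))
  names(cnt) <- vapply(sets, iset_key, character(1))

  lhs_l <- list(); rhs_l <- list()
  cxy <- cx <- cy <- integer(0)
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (length(s) < 2 || length(s) > config$max_rule_items) next
    if (cnt[i] < min_count) next
    for (pp in rule_partitions(s)) {
      kx <- iset_key(sort(pp$lhs)); ky <- iset_key(sort(pp$rhs))
      conf <- cnt[i] / cnt[[kx]]
      if (conf >= config$min_confidence - 1e-12) {
        lhs_l[[length(lhs_l) + 1]] <- sort(pp$lhs)
        rhs_l[[length(rhs_l) + 1]] <- sort(pp$rhs)
        cxy <- c(cxy, cnt[i]); cx <- c(cx, cnt[[kx]]); cy <- c(cy, cnt[[ky]])
      }
    }
  }
  make_rules_df(lhs_l, rhs_l, cxy, cx, cy, txns$n)
}
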