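test_that("itemset support counts containing transactions exactly", {
  txns <- tx("AB", "AB", "AC", "BC", "A")
  expect_equal(itemset_support("A", txns), list(count = 4L, proportion = 0.8))
  expect_equal(itemset_support(c("A", "B"), txns)$count, 2L)
  expect_equal(itemset_support(c("A", "B", "C"), txns)$count, 0L)
  # an itemset present everywhere has proportion 1
  everywhere <- tx("AB", "ABC", "ABD")
  expect_equal(itemset_support(c("A", "B"), everywhere)$proportion, 1)
  expect_error(itemset_support("A", transaction_set(list())),
               class = "rx_empty_transactions")
})

test_that("frequent itemsets match hand enumeration on the 5-transaction toy", {
  txns <- tx("AB", "AB", "AC", "BC", "A")
  fi <- frequent_itemsets(txns, mining_config(0.4, 0.5))
  got <- stats::setNames(fi$count,
                         vapply(fi$items, paste, character(1), collapse = ""))
  # brute-force enumeration of all subsets: A:4 B:3 C:2 AB:2 (AC, BC: 1 each)
  expect_equal(got, c(A = 4L, B = 3L, C = 2L, AB = 2L))
})

test_that("min_support 1 keeps only itemsets present in every transaction", {
  txns <- tx("ABC", "ABD")
  fi <- frequent_itemsets(txns, mining_config(1, 0.5), max_size = Inf)
  keys <- vapply(fi$items, paste, character(1), collapse = "")
  expect_setequal(keys, c("A", "B", "AB"))
})

test_that("rule statistics come from exact counts and both directions are emitted", {
  # 2 of 4 transactions contain both A and B; A in 3, B in 3
  txns <- tx("AB", "AB", "AC", "BC")
  rules <- mine_rules(txns, min_support = 0.25, min_confidence = 0.5)
  ab <- rules[rules$lhs == "A" & rules$rhs == "B", ]
  ba <- rules[rules$lhs == "B" & rules$rhs == "A", ]
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$support, 0.5)
  expect_equal(ab$confidence, 2 / 3)
  expect_equal(ab$lift, (2 / 4) / ((3 / 4) * (3 / 4)))
  # directed pair: same support and lift, own confidence
  expect_equal(ba$support, ab$support)
  expect_equal(ba$lift, ab$lift)
  # a pair present everywhere has confidence 1 in both directions
  all2 <- mine_rules(tx("AB", "AB"), 0.5, 0.5)
  expect_equal(sort(all2$confidence), c(1, 1))
})

test_that("lift is joint over product of marginals, with independence at 1", {
  # 4 transactions {AB, A, B, C}: P(A,B)=1/4 = P(A)P(B) -> lift 1
  expect_equal(rule_lift(1, 2, 2, 4), 1)
  expect_equal(rule_lift(2, 2, 2, 4), 2)
  expect_error(rule_lift(0, 0, 2, 4), class = "rx_zero_marginal")
  txns <- tx("AB", "A", "B", "C")
  rules <- mine_rules(txns, min_support = 0.2, min_confidence = 0.4)
  expect_equal(rules$lift[rules$lhs == "A" & rules$rhs == "B"], 1)
})

test_that("Apriori equals the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:20) {
    n_items <- sample(3:7, 1)
    txns <- random_txns(n_txn = sample(10:80, 1), n_items = n_items,
                        max_len = min(n_items, 4))
    cfg <- mining_config(min_support = sample(c(0.05, 0.1, 0.2), 1),
                         min_confidence = sample(c(0.3, 0.5, 0.7), 1),
                         max_rule_items = sample(2:3, 1))
    a <- derive_rules(frequent_itemsets(txns, cfg), txns, cfg)
    b <- brute_force_rules(txns, cfg)
    expect_identical(rule_keys(a), rule_keys(b))
    ord <- function(r) r[order(r$lhs, r$rhs), c("lhs", "rhs", "support_count",
                                                "count_lhs", "count_rhs")]
    expect_equal(ord(a), ord(b), ignore_attr = TRUE)
  }
  # one instance at the 12-item oracle guard
  txns <- random_txns(100, 12, max_len = 5)
  cfg <- mining_config(0.05, 0.5)
  expect_identical(rule_keys(derive_rules(frequent_itemsets(txns, cfg), txns, cfg)),
                   rule_keys(brute_force_rules(txns, cfg)))
  expect_error(brute_force_rules(random_txns(5, 13), cfg),
               class = "rx_guard_error")
})

test_that("every subset of a frequent itemset is frequent (anti-monotonicity)", {
  set.seed(7)
  for (rep in 1:5) {
    txns <- random_txns(60, 6, max_len = 5)
    fi <- frequent_itemsets(txns, mining_config(0.1, 0.5), max_size = Inf)
    keys <- vapply(fi$items, paste, character(1), collapse = "\x1f")
    for (i in which(fi$size >= 2)) {
      items <- fi$items[[i]]
      subs <- vapply(seq_along(items), function(d) {
        paste(items[-d], collapse = "\x1f")
      }, character(1))
      expect_true(all(subs %in% keys))
      # and each subset's count is at least the superset's
      expect_true(all(fi$count[match(subs, keys)] >= fi$count[i]))
    }
  }
})

test_that("support and lift are symmetric across rule direction; bounds hold", {
  set.seed(11)
  for (rep in 1:5) {
    txns <- random_txns(80, 6, max_len = 4)
    rules <- mine_rules(txns, min_support = 0.05, min_confidence = 0.01)
    key <- paste(rules$lhs, rules$rhs, sep = "=>")
    rev_idx <- match(paste(rules$rhs, rules$lhs, sep = "=>"), key)
    expect_false(anyNA(rev_idx))  # confidence floor low enough to keep both
    expect_equal(rules$support, rules$support[rev_idx])
    expect_equal(rules$lift, rules$lift[rev_idx])
    expect_true(all(rules$support <= rules$confidence + 1e-12))
    expect_true(all(rules$confidence <= 1 + 1e-12))
    # lift * P(rhs) = confidence
    expect_equal(rules$lift * rules$count_rhs / rules$n, rules$confidence)
  }
})

test_that("raising thresholds never adds a rule", {
  set.seed(23)
  txns <- random_txns(100, 6, max_len = 4)
  base <- rule_keys(mine_rules(txns, 0.05, 0.2))
  for (s in c(0.1, 0.2)) {
    for (co in c(0.4, 0.6)) {
      expect_true(all(rule_keys(mine_rules(txns, s, co)) %in% base))
    }
  }
})

test_that("degenerate inputs are handled", {
  expect_equal(nrow(mine_rules(transaction_set(list()))), 0L)
  expect_equal(nrow(brute_force_rules(transaction_set(list()))), 0L)
  expect_equal(nrow(mine_rules(tx("A", "A", "B"))), 0L)  # no 2-itemsets
  expect_error(mining_config(0, 0.5), class = "rx_config_error")
  expect_error(mining_config(0.5, 1.2), class = "rx_config_error")
})
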