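# compact builder for audit inputs
audit_input <- function(items, age, dx, aspirin) {
  n <- length(items)
  keys <- sprintf("v%03d|2014-06-01", seq_len(n))
  txns <- transaction_set(items, keys)
  ctx <- visit_contexts(data.frame(
    visit_key = keys, age_years = age, sex = "female",
    dx = dx, aspirin = aspirin, stringsAsFactors = FALSE))
  list(txns = txns, ctx = ctx)
}

test_that("H2RA+PPI visits are concordant iff a GORD (K21x) diagnosis is coded", {
  ai <- audit_input(
    items = list(c("OMPZ", "XAND"), c("OMPZ", "XAND"), c("XAND", "COTL"),
                 c("NAPX", "OMPZ"), c("OMPZ", "XAND")),
    age = c(70L, 30L, 55L, 60L, 45L),
    dx = c("K219", "K30", "", "K219", "K210;I10"),
    aspirin = FALSE
  )
  f <- find_h2ra_ppi_visits(ai$txns, ai$ctx)
  # the NAPX+OMPZ visit has no H2RA: not flagged
  expect_equal(nrow(f), 4L)
  expect_equal(f$verdict[f$dx == "K219"], "concordant")
  expect_equal(f$verdict[f$dx == "K30"], "discordant")
  expect_equal(f$verdict[f$dx == ""], "discordant")
  expect_equal(f$verdict[f$dx == "K210;I10"], "concordant")
})

test_that("COX2+PPI discordance requires under-60, no GI complication, no aspirin", {
  ai <- audit_input(
    items = list(c("CELB", "OMPZ"), c("ARCX", "OMPZ"), c("CELB", "NEXM"),
                 c("ARCX", "LOSC"), c("CELB", "OMPZ")),
    age = c(55L, 72L, 45L, 59L, 59L),
    dx = c("", "", "K254", "", "M179"),
    aspirin = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  f <- find_cox2_ppi_visits(ai$txns, ai$ctx)
  expect_equal(f$verdict,
               c("discordant",  # 55, nothing
                 "concordant",  # 72: age criterion
                 "concordant",  # K254 inside K20-K29.9
                 "concordant",  # aspirin co-therapy
                 "discordant")) # arthritis code is not a GI complication
})

test_that("flipping any high-risk criterion to true never makes a visit discordant", {
  base <- expand.grid(age = c(45L, 65L), gi = c(FALSE, TRUE),
                      asp = c(FALSE, TRUE))
  verdict_of <- function(age, gi, asp) {
    ai <- audit_input(list(c("CELB", "OMPZ")), age,
                      ifelse(gi, "K297", ""), asp)
    find_cox2_ppi_visits(ai$txns, ai$ctx)$verdict
  }
  for (i in seq_len(nrow(base))) {
    v0 <- verdict_of(base$age[i], base$gi[i], base$asp[i])
    # raise each criterion in turn
    for (v1 in c(verdict_of(65L, base$gi[i], base$asp[i]),
                 verdict_of(base$age[i], TRUE, base$asp[i]),
                 verdict_of(base$age[i], base$gi[i], TRUE))) {
      expect_false(v0 == "concordant" && v1 == "discordant")
    }
  }
})

test_that("verdicts and summaries are invariant to input order", {
  spec <- demo_cox2_audit_spec()
  fx <- make_audit_fixture(spec)
  f1 <- find_cox2_ppi_visits(fx$txns, fx$contexts)
  # permute context rows; transactions are canonically sorted already
  perm <- fx$contexts
  set.seed(5)
  perm$visits <- perm$visits[sample(nrow(perm$visits)), ]
  f2 <- find_cox2_ppi_visits(fx$txns, perm)
  expect_equal(f1[order(f1$visit_key), ], f2[order(f2$visit_key), ],
               ignore_attr = TRUE)
  s1 <- summarize_audit(f1)
  s2 <- summarize_audit(f2[sample(nrow(f2)), ])
  expect_equal(s1$tables, s2$tables)
})

test_that("summary partitions conserve counts and percents sum to ~100", {
  fx <- make_audit_fixture(rbind(demo_h2ra_audit_spec()))
  s <- summarize_audit(find_h2ra_ppi_visits(fx$txns, fx$contexts))
  for (t in s$tables) {
    expect_equal(sum(t$count), s$total)
    expect_lt(abs(sum(t$percent) - 100), 0.2)
  }
  fx2 <- make_audit_fixture(demo_cox2_audit_spec())
  s2 <- summarize_audit(find_cox2_ppi_visits(fx2$txns, fx2$contexts))
  for (t in s2$tables) {
    expect_equal(sum(t$count), s2$total)
    expect_lt(abs(sum(t$percent) - 100), 0.2)
  }
})

test_that("single finding summarizes to 100 percent; empty findings to total 0", {
  ai <- audit_input(list(c("OMPZ", "XAND")), 50L, "K219", FALSE)
  s <- summarize_audit(find_h2ra_ppi_visits(ai$txns, ai$ctx))
  expect_equal(s$total, 1L)
  expect_equal(s$tables$gord$percent[s$tables$gord$category == "GORD"], 100.0)
  s0 <- summarize_audit(find_h2ra_ppi_visits(tx("AB"), ai$ctx), "H2RA_PPI")
  expect_equal(s0$total, 0L)
})

test_that("visits without context default to discordant and leave denominators", {
  txns <- transaction_set(list(c("OMPZ", "XAND"), c("OMPZ", "XAND")),
                          c("known|2014-06-01", "unknown|2014-06-01"))
  ctx <- visit_contexts(data.frame(
    visit_key = "known|2014-06-01", age_years = 50L, sex = "female",
    dx = "K219", aspirin = FALSE, stringsAsFactors = FALSE))
  expect_warning(f <- find_h2ra_ppi_visits(txns, ctx), "no audit context")
  expect_equal(f$verdict[!f$context_known], "discordant")
  s <- summarize_audit(f)
  expect_equal(s$total, 1L)
  expect_equal(s$excluded, 1L)
})

test_that("same-meal and same-clinic flags come from per-drug schedules", {
  keys <- sprintf("v%03d|2014-06-01", 1:3)
  txns <- transaction_set(rep(list(c("OMPZ", "XAND")), 3), keys)
  sched <- parse_dose_freq(c("1CAPAM", "1TABBID",   # overlap: morning
                             "1CAPAM", "2TABPM",    # disjoint meals
                             "1CAPBID", "1TABBID")) # overlap both
  drugs <- data.frame(
    visit_key = rep(keys, each = 2),
    stem = rep(c("OMPZ", "XAND"), 3),
    morning = sched$morning, evening = sched$evening,
    clinic = c("PMD02", "PMD02", "ORP11", "OFM18", "OPS01", "OPS01"),
    stringsAsFactors = FALSE
  )
  ctx <- visit_contexts(data.frame(
    visit_key = keys, age_years = 50L, sex = "female", dx = "K219",
    aspirin = FALSE, stringsAsFactors = FALSE), drugs)
  f <- find_h2ra_ppi_visits(txns, ctx)
  expect_equal(f$same_meal, c(TRUE, FALSE, TRUE))
  expect_equal(f$same_clinic, c(TRUE, FALSE, TRUE))
})

test_that("ages derive as completed years and aspirin windows widen exposure", {
  pr <- data.frame(
    patient_id = c("p1", "p1", "p2", "p2", "p2"),
    date = c("2014-06-01", "2014-06-01", "2014-06-01", "2014-06-01",
             "2014-06-03"),
    drug_code = c("CELB-C-", "OMPZ-C-", "CELB-C-", "OMPZ-C-", "ASPT-T-"),
    stringsAsFactors = FALSE
  )
  pat <- data.frame(patient_id = c("p1", "p2"),
                    birth_date = c("1954-06-02", "1954-05-31"),
                    sex = "female", stringsAsFactors = FALSE)
  ctx0 <- build_contexts(pr, NULL, pat)
  v <- ctx0$visits[ctx0$visits$patient_id %in% c("p1", "p2") &
                     ctx0$visits$date == "2014-06-01", ]
  # p1 turns 60 the day after the visit; p2 already 60
  expect_equal(v$age_years[v$patient_id == "p1"], 59L)
  expect_equal(v$age_years[v$patient_id == "p2"], 60L)
  expect_false(any(ctx0$visits$aspirin[ctx0$visits$date == "2014-06-01"]))
  ctx3 <- build_contexts(pr, NULL, pat, aspirin_window_days = 3)
  expect_true(ctx3$visits$aspirin[ctx3$visits$patient_id == "p2" &
                                    ctx3$visits$date == "2014-06-01"])
  expect_false(ctx3$visits$aspirin[ctx3$visits$patient_id == "p1" &
                                     ctx3$visits$date == "2014-06-01"])
})
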