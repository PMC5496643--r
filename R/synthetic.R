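#' Parameters for the synthetic outpatient cohort
#'
#' Defaults reproduce the descriptive statistics of the outpatient
#' population the analysis targets: mean age 48.4 (SD 21.4) years, 34% male,
#' 4.7 (SD 4.4) visits per person per year, background GI-complication
#' coding rate 1.80% and arthritis coding rate 0.74%. Per-visit drug sets
#' are Bernoulli draws from `drug_prevalence` with optional pairwise
#' association boosts: a boosted pair's joint probability is
#' `boost * p_x * p_y`, achieved by drawing the second item conditionally on
#' the first, so the mined lift of a boosted pair estimates the boost
#' itself.
#'
#' @param n_patients number of patients.
#' @param mean_visits_per_year,visit_rate_sd visit-rate mean and SD per
#'   person-year (matched by a negative binomial).
#' @param male_fraction proportion male.
#' @param age_mean,age_sd age distribution in years (normal truncated at 0).
#' @param drug_prevalence named numeric vector: per-visit inclusion
#'   probability per stem.
#' @param pair_boost data frame with columns `x`, `y`, `boost`; pairs must
#'   not share stems.
#' @param gi_dx_prob_given_ppi probability a visit with a gastro-protective
#'   drug (A02A/A02B) carries a GI diagnosis code.
#' @param background_gi_dx_prob GI diagnosis probability at other visits.
#' @param arthritis_dx_prob arthritis diagnosis probability per visit.
#' @param seed integer RNG seed; identical parameters and seed give
#'   identical output.
#' @return a `cohort_params` list, validated.
#' @export
cohort_params <- function(n_patients = 2000,
                          mean_visits_per_year = 4.7,
                          visit_rate_sd = 4.4,
                          male_fraction = 0.34,
                          age_mean = 48.4,
                          age_sd = 21.4,
                          drug_prevalence = default_drug_prevalence(),
                          pair_boost = NULL,
                          gi_dx_prob_given_ppi = 0.25,
                          background_gi_dx_prob = 0.018,
                          arthritis_dx_prob = 0.0074,
                          seed = 1L) {
  probs <- c(male_fraction, gi_dx_prob_given_ppi, background_gi_dx_prob,
             arthritis_dx_prob, drug_prevalence)
  if (any(probs < 0 | probs > 1)) {
    rx_stop("all probabilities must lie in [0, 1]", "rx_param_error")
  }
  if (is.null(names(drug_prevalence)) || any(!nzchar(names(drug_prevalence)))) {
    rx_stop("drug_prevalence must be a named vector of stems", "rx_param_error")
  }
  if (!is.null(pair_boost)) {
    if (!all(c("x", "y", "boost") %in% names(pair_boost))) {
      rx_stop("pair_boost needs columns x, y, boost", "rx_param_error")
    }
    stems <- c(pair_boost$x, pair_boost$y)
    if (anyDuplicated(stems)) {
      rx_stop("boosted pairs must not share stems", "rx_param_error")
    }
    if (!all(stems %in% names(drug_prevalence))) {
      rx_stop("boosted stems must appear in drug_prevalence", "rx_param_error")
    }
    px <- drug_prevalence[pair_boost$x]
    py <- drug_prevalence[pair_boost$y]
    pxy <- pair_boost$boost * px * py
    bad <- pxy > pmin(px, py) + 1e-12 |
      (py - pxy) > (1 - px) + 1e-12 | pxy < 0
    if (any(bad)) {
      rx_stop(sprintf("invalid joint probability for boosted pair(s): %s",
                      paste(pair_boost$x[bad], pair_boost$y[bad],
                            collapse = ", ")),
              "rx_param_error")
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 mean_visits_per_year = mean_visits_per_year,
                 visit_rate_sd = visit_rate_sd,
                 male_fraction = male_fraction,
                 age_mean = age_mean, age_sd = age_sd,
                 drug_prevalence = drug_prevalence,
                 pair_boost = pair_boost,
                 gi_dx_prob_given_ppi = gi_dx_prob_given_ppi,
                 background_gi_dx_prob = background_gi_dx_prob,
                 arthritis_dx_prob = arthritis_dx_prob,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Default per-visit drug prevalences for the synthetic cohort
#'
#' A plausible outpatient mix over the audited drug classes: omeprazole
#' dominant among PPIs, ranitidine as the H2RA, common conventional NSAIDs,
#' low-dose aspirin, and the two COX-2 inhibitors.
#'
#' @return named numeric vector of per-visit inclusion probabilities.
#' @export
default_drug_prevalence <- function() {
  c(OMPZ = 0.060, XAND = 0.040, NAPX = 0.020, IBUP = 0.020, DICF = 0.012,
    MELO = 0.010, ASPT = 0.008, `ASA.` = 0.030, CELB = 0.010, ARCX = 0.012,
    ANTC = 0.020, ALHY = 0.010)
}

#' Generate a synthetic outpatient cohort
#'
#' Produces the three raw tables the ETL consumes: prescriptions
#' (`patient_id, date, drug_code, dose_freq, clinic`), diagnoses
#' (`patient_id, date, icd10`) and patients
#' (`patient_id, birth_date, sex`). Fully reproducible for a given
#' parameter set and seed. GI diagnosis codes are attached with elevated
#' probability at visits carrying a gastro-protective drug, emulating
#' confounding by indication.
#'
#' @param params a [cohort_params()] object.
#' @param out_dir optional directory; when given, the three tables are also
#'   written as `prescriptions.csv`, `diagnoses.csv`, `patients.csv`.
#' @return a list with data frames `prescriptions`, `diagnoses`, `patients`
#'   and `visits` (every generated visit, including drug-free ones — the
#'   correct denominator for per-visit probabilities). The returned
#'   `patients` carries an extra `age_ref` column: the exact sampled age at
#'   the cohort reference date, not written to CSV.
#' @export
generate_cohort <- function(params = cohort_params(), out_dir = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  np <- params$n_patients
  start <- as.Date("2013-10-01")
  ref <- as.Date("2014-10-01")
  n_days <- 731L  # two fiscal years

  # patients: truncated-normal ages, birth date back-computed from the
  # reference date
  age <- stats::rnorm(np, params$age_mean, params$age_sd)
  while (any(age < 0)) {
    k <- age < 0
    age[k] <- stats::rnorm(sum(k), params$age_mean, params$age_sd)
  }
  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(np)),
    birth_date = format(ref - round(age * 365.2425)),
    sex = ifelse(stats::runif(np) < params$male_fraction, "male", "female"),
    age_ref = age,
    stringsAsFactors = FALSE
  )

  # visits: negative binomial rate per person-year, two years
  mu <- params$mean_visits_per_year
  v <- params$visit_rate_sd^2
  nvis <- if (v > mu) {
    size <- mu^2 / (v - mu)
    stats::rnbinom(np, size = size, mu = mu) + stats::rnbinom(np, size = size, mu = mu)
  } else {
    stats::rpois(np, 2 * mu)
  }
  nvis <- pmin(nvis, n_days)
  pat_idx <- rep.int(seq_len(np), nvis)
  offs <- unlist(lapply(nvis[nvis > 0], function(k) sample.int(n_days, k) - 1L))
  visit_pat <- patients$patient_id[pat_idx]
  visit_date <- format(start + offs)
  nv <- length(visit_pat)

  # per-visit drug sets: independent Bernoulli, then boosted pairs redrawn
  # conditionally so the joint probability equals boost * p_x * p_y
  prev <- params$drug_prevalence
  stems <- names(prev)
  sel <- matrix(stats::runif(nv * length(stems)), nv) <
    matrix(prev, nv, length(stems), byrow = TRUE)
  colnames(sel) <- stems
  pb <- params$pair_boost
  if (!is.null(pb)) {
    for (i in seq_len(nrow(pb))) {
      x <- pb$x[i]; y <- pb$y[i]
      pxy <- pb$boost[i] * prev[[x]] * prev[[y]]
      u <- stats::runif(nv)
      sel[, y] <- ifelse(sel[, x],
                         u < pxy / prev[[x]],
                         u < (prev[[y]] - pxy) / (1 - prev[[x]]))
    }
  }

  # prescription rows
  catalog <- load_catalog()
  raw_of <- catalog$raw_code[match(stems, catalog$stem)]
  raw_of[is.na(raw_of)] <- paste0(stems[is.na(raw_of)], "-T-")
  dose_pool <- c("1CAPAM", "1CAPBID", "1TABAM", "1TABBID", "2TABPM",
                 "1CAPAMSD", "1TABBIDSD", "2TABPMSD")
  clinic_pool <- c("ORP11", "PMD02", "OGY111", "OPS01", "OET11", "OEX01",
                   "OSU05", "PRP03", "PET01", "OFM18")
  hit <- which(sel, arr.ind = TRUE)
  prescriptions <- data.frame(
    patient_id = visit_pat[hit[, 1]],
    date = visit_date[hit[, 1]],
    drug_code = raw_of[hit[, 2]],
    dose_freq = sample(dose_pool, nrow(hit), replace = TRUE),
    clinic = sample(clinic_pool, nrow(hit), replace = TRUE),
    stringsAsFactors = FALSE
  )
  ord <- order(prescriptions$patient_id, prescriptions$date,
               prescriptions$drug_code)
  prescriptions <- prescriptions[ord, ]
  rownames(prescriptions) <- NULL

  # diagnoses: GI codes enriched at gastro-protective visits
  gastro_stems <- catalog$stem[catalog$atc_class %in% c("A02A", "A02B")]
  has_gastro <- rowSums(sel[, intersect(stems, gastro_stems), drop = FALSE]) > 0
  p_gi <- ifelse(has_gastro, params$gi_dx_prob_given_ppi,
                 params$background_gi_dx_prob)
  gi_codes <- c("K219", "K30", "K297", "K279", "K259", "K921")
  gi_w <- c(0.45, 0.25, 0.12, 0.08, 0.06, 0.04)
  draw_gi <- stats::runif(nv) < p_gi
  draw_arth <- stats::runif(nv) < params$arthritis_dx_prob
  draw_oth <- stats::runif(nv) < 0.2
  dx_rows <- rbind(
    data.frame(patient_id = visit_pat[draw_gi], date = visit_date[draw_gi],
               icd10 = sample(gi_codes, sum(draw_gi), replace = TRUE,
                              prob = gi_w), stringsAsFactors = FALSE),
    data.frame(patient_id = visit_pat[draw_arth], date = visit_date[draw_arth],
               icd10 = "M179", stringsAsFactors = FALSE),
    data.frame(patient_id = visit_pat[draw_oth], date = visit_date[draw_oth],
               icd10 = sample(c("I10", "E119", "J069"), sum(draw_oth),
                              replace = TRUE), stringsAsFactors = FALSE)
  )
  dx_rows <- dx_rows[order(dx_rows$patient_id, dx_rows$date, dx_rows$icd10), ]
  rownames(dx_rows) <- NULL

  out <- list(prescriptions = prescriptions, diagnoses = dx_rows,
              patients = patients,
              visits = data.frame(patient_id = visit_pat, date = visit_date,
                                  stringsAsFactors = FALSE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(prescriptions, file.path(out_dir, "prescriptions.csv"),
                     row.names = FALSE)
    utils::write.csv(dx_rows, file.path(out_dir, "diagnoses.csv"),
                     row.names = FALSE)
    utils::write.csv(patients[c("patient_id", "birth_date", "sex")],
                     file.path(out_dir, "patients.csv"), row.names = FALSE)
  }
  out
}

#' Recover integer counts behind rounded rule statistics
#'
#' Published rule tables print support, confidence and lift rounded to 4
#' decimals. Given the transaction total `n`, this oracle searches
#' exhaustively for the integer counts (joint count, antecedent count,
#' consequent count) whose exact ratios round — half-away-from-zero — to the
#' printed values. It reports every exact solution, or the nearest misses
#' when a printed value admits no integer solution at this `n` (which
#' documents irreproducible table entries rather than hiding them).
#'
#' @param n transaction count (support denominator).
#' @param support printed support, 4 decimals.
#' @param confidence optional printed confidence, 4 decimals.
#' @param lift optional printed lift, 4 decimals.
#' @return a list: `solutions` (data frame `count_xy`, `count_x`, `count_y`;
#'   columns are `NA` for statistics not supplied), logical flags
#'   `support_exact`, `confidence_exact`, `lift_exact`, and `nearest` (one
#'   row of best-achievable counts with the statistics they actually round
#'   to).
#' @examples
#' invert_printed_rule(6168, support = 0.1085, confidence = 0.9738)
#' invert_printed_rule(6168, support = 0.0552)  # no exact solution: nearest 340
#' @export
invert_printed_rule <- function(n, support, confidence = NULL, lift = NULL) {
  stopifnot(n >= 1)
  counts <- 0:n
  cxy_cand <- counts[round_ratio(counts, n, 4) == support]
  support_exact <- length(cxy_cand) > 0
  if (!support_exact) {
    cxy_cand <- counts[which.min(abs(counts / n - support))]
  }

  confidence_exact <- TRUE
  lift_exact <- TRUE
  rows <- list()
  for (cxy in cxy_cand) {
    x_cand <- NA_integer_
    if (!is.null(confidence)) {
      if (cxy == 0) next
      xs <- cxy:n
      x_cand <- xs[round_ratio(cxy, xs, 4) == confidence]
      if (length(x_cand) == 0) {
        confidence_exact <- FALSE
        x_cand <- xs[which.min(abs(cxy / xs - confidence))]
      }
    }
    for (x in x_cand) {
      y_cand <- NA_integer_
      if (!is.null(lift)) {
        xx <- if (is.na(x)) cxy else x
        ys <- cxy:n
        y_cand <- ys[round_ratio(cxy * n, xx * ys, 4) == lift]
        if (length(y_cand) == 0) {
          lift_exact <- FALSE
          y_cand <- ys[which.min(abs((cxy * n) / (xx * ys) - lift))]
        }
      }
      for (y in y_cand) {
        rows[[length(rows) + 1]] <- data.frame(count_xy = cxy, count_x = x,
                                               count_y = y)
      }
    }
  }
  if (length(rows) == 0) {
    rx_stop("no feasible counts (printed confidence requires a nonzero joint count)",
            "rx_inversion_error")
  }
  all_rows <- do.call(rbind, rows)
  exact_all <- support_exact &&
    (is.null(confidence) || confidence_exact) &&
    (is.null(lift) || lift_exact)
  nearest <- all_rows[1, , drop = FALSE]
  nearest$achieved_support <- round_ratio(nearest$count_xy, n, 4)
  nearest$achieved_confidence <- if (is.null(confidence)) NA_real_ else
    round_ratio(nearest$count_xy, nearest$count_x, 4)
  nearest$achieved_lift <- if (is.null(lift)) NA_real_ else
    round_ratio(nearest$count_xy * n,
                (if (is.null(confidence)) nearest$count_xy else nearest$count_x) *
                  nearest$count_y, 4)
  list(
    solutions = if (exact_all) all_rows else all_rows[0, , drop = FALSE],
    support_exact = support_exact,
    confidence_exact = if (is.null(confidence)) NA else confidence_exact,
    lift_exact = if (is.null(lift)) NA else lift_exact,
    nearest = nearest,
    n = n
  )
}

# internal: spread `total` transactions over filler items, each filler item
# used at most `cap` times, pairing fillers with `with` (or with a second
# filler when `with` is NULL)
filler_blocks <- function(total, cap, prefix, with = NULL) {
  if (total == 0) return(list())
  n_chunks <- ceiling(total / cap)
  sizes <- rep(cap, n_chunks)
  sizes[n_chunks] <- total - cap * (n_chunks - 1)
  out <- list()
  for (k in seq_len(n_chunks)) {
    a <- sprintf("%sA%03d", prefix, k)
    b <- if (is.null(with)) sprintf("%sB%03d", prefix, k) else with
    out <- c(out, rep(list(c(b, a)), sizes[k]))
  }
  out
}

#' Build a two-item pair fixture with exact counts
#'
#' Constructs a deterministic transaction set of exactly `n` transactions in
#' which items `x` and `y` co-occur `count_xy` times and have marginal
#' counts `count_x`, `count_y`. Excess marginal occurrences and padding
#' transactions use filler items whose totals stay strictly below the
#' frequency threshold, so no filler ever appears in a rule surviving
#' `min_support`; every transaction has two items.
#'
#' @param n transaction total.
#' @param count_x,count_y,count_xy marginal and joint counts
#'   (`count_xy <= min(count_x, count_y)`;
#'   `count_x + count_y - count_xy <= n`). `NA` marginals default to
#'   `count_xy`.
#' @param x,y item names.
#' @param min_support the mining threshold the filler items must stay
#'   under.
#' @return a [transaction_set()].
#' @examples
#' fx <- make_pair_fixture(6168, 687, 4182, 669, "NAPX", "OMPZ")
#' mine_rules(fx)  # one surviving rule: NAPX -> OMPZ
#' @export
make_pair_fixture <- function(n, count_x, count_y, count_xy, x = "ITMX",
                              y = "ITMY", min_support = 0.01) {
  if (is.na(count_x)) count_x <- count_xy
  if (is.na(count_y)) count_y <- count_xy
  if (count_xy > min(count_x, count_y) ||
      count_x + count_y - count_xy > n || count_xy < 0) {
    rx_stop("infeasible pair counts", "rx_fixture_error")
  }
  cap <- as.integer(ceiling(min_support * n - 1e-9)) - 1L
  if (cap < 1) rx_stop("min_support too low for filler allocation",
                       "rx_fixture_error")
  ex <- count_x - count_xy
  ey <- count_y - count_xy
  rest <- n - count_xy - ex - ey
  items <- c(rep(list(c(x, y)), count_xy),
             filler_blocks(ex, cap, "FX", with = x),
             filler_blocks(ey, cap, "FY", with = y),
             filler_blocks(rest, cap, "ZZ"))
  transaction_set(items)
}

#' Deterministic 12-rule demonstration fixture
#'
#' A block-design transaction set of 6,168 two-item transactions over the
#' audited drug stems, constructed so that mining at support >= 1% and
#' confidence >= 50% yields exactly 12 single-item rules: omeprazole and
#' ranitidine in both directions, plus ten NSAID/antacid antecedents each
#' implying omeprazole. Blocks: 2,600 of \{OMPZ, XAND\}; per antecedent stem
#' 70 of \{stem, OMPZ\} and 50 of \{stem, filler\}; 2,000 of
#' \{XAND, filler\} and 368 filler pairs, every filler item kept below the
#' 1% frequency threshold.
#'
#' @return a [transaction_set()] with 6,168 transactions.
#' @examples
#' txns <- make_demo_fixture()
#' nrow(mine_rules(txns, 0.01, 0.5))  # 12
#' @export
make_demo_fixture <- function() {
  antecedents <- c("NAPX", "MELO", "IBUP", "DICF", "ASPT", "ASA.",
                   "CELB", "MOBC", "ARCX", "ANTC")
  cap <- 61L  # < 1% of 6168
  items <- rep(list(c("OMPZ", "XAND")), 2600)
  for (k in seq_along(antecedents)) {
    s <- antecedents[k]
    items <- c(items, rep(list(c(s, "OMPZ")), 70),
               rep(list(c(s, sprintf("QA%03d", k))), 50))
  }
  items <- c(items,
             filler_blocks(2000, cap, "QX", with = "XAND"),
             filler_blocks(368, cap, "QZ"))
  transaction_set(items)
}

#' Build a deterministic audit fixture from category counts
#'
#' Expands a specification of joint attribute cells (pattern, age, diagnosis
#' codes, aspirin flag, count) into a transaction set plus matching visit
#' contexts, for reconstructing audit category tables exactly. H2RA+PPI
#' cells get items \{OMPZ, XAND\}; COX-2+PPI cells get \{CELB, OMPZ\}.
#'
#' @param spec data frame with columns `pattern` (`"H2RA_PPI"` or
#'   `"COX2_PPI"`), `n` (cell count), `age` (years), `dx` (semicolon-joined
#'   dot-stripped ICD-10 codes, `""` for none), `aspirin` (logical).
#' @return a list with `txns` (a [transaction_set()]) and `contexts` (a
#'   `visit_contexts`).
#' @export
make_audit_fixture <- function(spec) {
  need <- c("pattern", "n", "age", "dx", "aspirin")
  if (!all(need %in% names(spec))) {
    rx_stop("audit fixture spec needs columns pattern, n, age, dx, aspirin",
            "rx_fixture_error")
  }
  if (any(spec$n < 0) || any(spec$n != trunc(spec$n))) {
    rx_stop("cell counts must be non-negative integers", "rx_fixture_error")
  }
  idx <- rep.int(seq_len(nrow(spec)), spec$n)
  total <- length(idx)
  if (total == 0) {
    return(list(txns = transaction_set(list(), character(0)),
                contexts = visit_contexts(
                  data.frame(visit_key = character(0), age_years = integer(0),
                             dx = character(0), aspirin = logical(0),
                             stringsAsFactors = FALSE))))
  }
  keys <- sprintf("AUD%05d|2014-06-01", seq_len(total))
  items <- lapply(seq_len(total), function(i) {
    if (spec$pattern[idx[i]] == "H2RA_PPI") c("OMPZ", "XAND")
    else c("CELB", "OMPZ")
  })
  txns <- transaction_set(items, keys)
  visits <- data.frame(
    visit_key = keys,
    age_years = as.integer(spec$age[idx]),
    sex = "female",
    dx = as.character(spec$dx[idx]),
    aspirin = as.logical(spec$aspirin[idx]),
    stringsAsFactors = FALSE
  )
  list(txns = txns, contexts = visit_contexts(visits))
}

#' Worked-example audit specifications
#'
#' `demo_h2ra_audit_spec()` gives the 340-visit H2RA + PPI diagnosis
#' distribution used in the package's worked example: 222 GORD visits (221
#' K219 + 1 K210) and 118 non-GORD visits (ten listed GI codes plus 59
#' visits without a GI diagnosis). `demo_cox2_audit_spec()` gives the
#' 828-visit COX-2 + PPI joint distribution: 498 aged >= 60 (106 with a GI
#' diagnosis, 11 on aspirin), 233 aged 50-59 and 97 under 50 (295 of the 330
#' under-60 visits with no GI diagnosis and no aspirin; the other 35 carry a
#' GI diagnosis), giving 141 GI-complication visits, 11 aspirin visits and
#' 295 guideline-discordant visits overall.
#'
#' @return a data frame accepted by [make_audit_fixture()].
#' @export
demo_h2ra_audit_spec <- function() {
  data.frame(
    pattern = "H2RA_PPI",
    n = c(221L, 1L, 38L, 9L, 5L, 2L, 1L, 1L, 1L, 1L, 1L, 59L),
    age = 55L,
    dx = c("K219", "K210", "K30", "K279", "K297", "K922", "K921", "K319",
           "K254", "K259", "K20", ""),
    aspirin = FALSE,
    stringsAsFactors = FALSE
  )
}

#' @rdname demo_h2ra_audit_spec
#' @export
demo_cox2_audit_spec <- function() {
  data.frame(
    pattern = "COX2_PPI",
    n = c(381L, 106L, 11L, 208L, 25L, 87L, 10L),
    age = c(65L, 70L, 68L, 55L, 52L, 45L, 40L),
    dx = c("", "K297", "", "", "K30", "", "K219"),
    aspirin = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}
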