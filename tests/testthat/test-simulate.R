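test_that("default parameters encode the study conditions", {
  p <- cohort_params()
  expect_equal(p$n_hgsoc, 171L)
  expect_equal(p$n_ec, 80L)
  expect_equal(unname(p$mutation_prevalence), c(169 / 171, 7 / 80))
  expect_equal(unname(p$class_mix$HGSOC), c(112, 57) / 169)
  expect_equal(unname(p$class_mix$EC), c(5, 2) / 7)
  # method-1 conditionals are the contingency-table column proportions
  m1 <- p$staining_conditional[["1"]]
  expect_equal(unname(m1$nonsynonymous["OE"]), 1)
  expect_equal(unname(m1$NDM["WT"]), 1)
  expect_equal(unname(m1$stopgain["CA"]), 13 / 17)
  expect_equal(unname(m1$indel["CY"]), 2 / 24)
  # all probability rows sum to 1
  for (method in p$staining_conditional) {
    for (cond in method) expect_equal(sum(cond), 1, tolerance = 1e-9)
  }
})

test_that("invalid parameters are rejected", {
  p <- cohort_params()
  p$staining_conditional[["1"]]$NDM <- c(OE = 0.5, CA = 0.2, CY = 0, WT = 0.2)
  expect_error(validate_params(p), class = "p53ihc_validation_error")
  p2 <- cohort_params()
  p2$mutation_prevalence["EC"] <- 1.5
  expect_error(validate_params(p2), class = "p53ihc_validation_error")
})

test_that("generation is deterministic given the seed", {
  a <- simulate_cohort(cohort_params(seed = 99))
  b <- simulate_cohort(cohort_params(seed = 99))
  expect_identical(a, b)
  c <- simulate_cohort(cohort_params(seed = 100))
  expect_false(identical(a$variant, c$variant))
})

test_that("degenerate prevalence makes every case mutated", {
  p <- cohort_params(n_hgsoc = 50, n_ec = 20, seed = 5)
  p$mutation_prevalence[] <- 1
  cohort <- simulate_cohort(p)
  expect_true(all(cohort$deleterious))
})

test_that("every generated variant notation round-trips through the parsers", {
  cohort <- simulate_cohort(cohort_params(seed = 21))
  for (notation in cohort$variant) {
    v <- select_primary_variant(parse_variant(notation))
    expect_true(v$kind %in% c("substitution", "stopgain", "deletion_inframe",
                              "frameshift", "splicing", "none"))
    for (cd in c(v$codon_start, v$codon_end)) {
      if (!is.na(cd)) expect_true(cd >= 1 && cd <= 393)
    }
  }
})

test_that("empirical staining frequencies converge to the generating conditionals", {
  # scale the cohort tenfold and compare, per mutation type, the observed
  # method-1 pattern frequencies with the generating probabilities, within
  # 2 binomial standard errors (plus a floor for near-degenerate cells)
  p <- cohort_params(n_hgsoc = 1710, n_ec = 800, seed = 17)
  cohort <- simulate_cohort(p)
  cond <- p$staining_conditional[["1"]]
  scored <- cohort[cohort$pattern_m1 != "unscored", ]
  type_key <- ifelse(scored$mutation_type == "none", "NDM",
                     scored$mutation_type)
  for (type in c("nonsynonymous", "indel", "stopgain", "splicing", "NDM")) {
    sub <- scored$pattern_m1[type_key == type]
    n <- length(sub)
    expect_gt(n, 30)
    for (pattern in names(cond[[type]])) {
      prob <- cond[[type]][[pattern]]
      emp <- mean(sub == pattern)
      se <- sqrt(prob * (1 - prob) / n)
      expect_lt(abs(emp - prob), 2 * se + 3 / n,
                label = sprintf("|%.3f - %.3f| for P(%s | %s)",
                                emp, prob, pattern, type))
    }
  }
})

test_that("engine metrics on a large cohort match the analytic values", {
  # independent analytic oracle: binary sensitivity implied by the
  # generating mixture, sum over types of P(type | deleterious) *
  # P(abnormal staining | type)
  p <- cohort_params(n_hgsoc = 1710, n_ec = 800, seed = 29)
  cohort <- simulate_cohort(p)

  w_h <- c(HGSOC = p$n_hgsoc * p$mutation_prevalence[["HGSOC"]],
           EC = p$n_ec * p$mutation_prevalence[["EC"]])
  w_h <- w_h / sum(w_h)
  type_given_del <- function(h) {
    mix <- p$class_mix[[h]]
    c(nonsynonymous = unname(mix["GOF"]),
      unname(mix["LOF"]) * p$lof_type_weights)
  }
  tg <- w_h[["HGSOC"]] * type_given_del("HGSOC") +
    w_h[["EC"]] * type_given_del("EC")
  names(tg) <- c("nonsynonymous", "indel", "stopgain", "splicing")
  cond <- p$staining_conditional[["1"]]
  p_abnormal <- vapply(names(tg), function(t)
    sum(cond[[t]][c("OE", "CA", "CY")]), numeric(1))
  expected_sens <- sum(tg * p_abnormal)

  m <- binary_metrics(build_confusion(cohort, "binary", 1))
  n_del <- sum(cohort$deleterious & cohort$pattern_m1 != "unscored")
  se <- sqrt(expected_sens * (1 - expected_sens) / n_del)
  expect_lt(abs(m$sensitivity - expected_sens), 2 * se)
  # specificity is 1 by construction for method 1 (NDM always stains WT)
  expect_equal(m$specificity, 1)
})

test_that("weaker-staining methods shift wild-type calls toward complete absence", {
  p <- cohort_params(n_hgsoc = 1710, n_ec = 800, seed = 31)
  cohort <- simulate_cohort(p)
  ndm <- cohort[cohort$functional_class == "NDM", ]
  ca_rate <- vapply(1:4, function(m) {
    pat <- ndm[[paste0("pattern_m", m)]]
    mean(pat[pat != "unscored"] == "CA")
  }, numeric(1))
  expect_equal(ca_rate[1], 0)
  expect_true(all(diff(ca_rate) > 0))  # methods 2-4 progressively worse
})

test_that("rater-pair simulation spans the kappa range", {
  cohort <- simulate_cohort(cohort_params(seed = 8))
  perfect <- simulate_rater_pair(cohort, 0, seed = 1)
  expect_equal(cohens_kappa(perfect$rater_a, perfect$rater_b)$kappa, 1)

  full <- simulate_rater_pair(cohort, 1, seed = 1)
  expect_true(all(full$rater_a != full$rater_b))
  expect_lt(cohens_kappa(full$rater_a, full$rater_b)$kappa, 1)

  # at a 6% disagreement rate over 148 cases the agreement is "very good"
  kappas <- vapply(1:30, function(s) {
    sub <- cohort[1:160, ]
    pair <- simulate_rater_pair(sub, 0.06, seed = s)
    k <- cohens_kappa(pair$rater_a[1:148], pair$rater_b[1:148])
    k$kappa
  }, numeric(1))
  expect_gt(mean(kappas), 0.8)
  expect_lt(mean(kappas), 0.95)
})
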