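test_that("the packaged cohort reproduces the published contingency table", {
  cohort <- fixture_cohort()

  cm <- build_confusion(cohort, "binary", 1)
  expect_equal(cm$table["abnormal", "deleterious"], 166L)
  expect_equal(cm$table["abnormal", "NDM"], 0L)
  expect_equal(cm$table["normal", "deleterious"], 7L)
  expect_equal(cm$table["normal", "NDM"], 76L)
  expect_equal(cm$n_included, 249L)
  expect_equal(unname(cm$excluded["unscored"]), 2L)

  ct <- build_confusion(cohort, "ternary", 1)
  expect_equal(ct$n_included, 245L)
  expect_equal(unname(ct$excluded["cytoplasmic"]), 4L)
  expect_equal(ct$table["GOF", "GOF"], 115L)
  expect_equal(ct$table["LOF", "LOF"], 41L)
  expect_equal(ct$table["NDM", "NDM"], 76L)
  expect_equal(ct$table["NDM", "LOF"], 7L)
  expect_equal(ct$table["GOF", "LOF"], 6L)

  # cells plus exclusions always account for every case
  expect_equal(sum(cm$table) + sum(cm$excluded), nrow(cohort))
  expect_equal(sum(ct$table) + sum(ct$excluded), nrow(cohort))
})

test_that("degenerate cohorts give zero matrices and NA (not zero) metrics", {
  empty <- classify_cohort(tibble::tibble(
    case_id = character(), histotype = character(), variant = character(),
    pattern_m1 = character()))
  cm <- build_confusion(empty, "binary", 1)
  expect_true(all(cm$table == 0L))
  expect_equal(cm$n_included, 0L)

  # no NDM cases: specificity undefined
  all_mut <- classify_cohort(tibble::tibble(
    case_id = c("a", "b"), histotype = "HGSOC",
    variant = c("p.R175H", "p.R196X"), pattern_m1 = c("OE", "CA")))
  expect_warning(m <- binary_metrics(build_confusion(all_mut, "binary", 1)),
                 "specificity")
  expect_true(is.na(m$specificity))
  expect_equal(m$sensitivity, 1)

  # unknown pattern token is rejected with the offending case named
  bad <- all_mut
  bad$pattern_m1[1] <- "OD"
  expect_error(build_confusion(bad, "binary", 1),
               class = "p53ihc_validation_error", regexp = "OD")
})

test_that("metrics equal a naive per-case oracle on random cohorts", {
  set.seed(42)
  for (i in 1:50) {
    cohort <- random_cohort(n = 60)
    cm <- build_confusion(cohort, "binary", 1)
    m <- suppressWarnings(binary_metrics(cm))
    o <- oracle_binary(cohort)
    expect_equal(m$sensitivity, o$sensitivity)
    expect_equal(m$specificity, o$specificity)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$n_included, o$n_included)

    tm <- suppressWarnings(ternary_metrics(build_confusion(cohort, "ternary", 1)))
    ot <- oracle_ternary(cohort)
    for (k in c("GOF", "LOF", "NDM")) {
      row <- tm$per_class[tm$per_class$class == k, ]
      expect_equal(row$sensitivity, unname(ot$per_class[[k]]["sensitivity"]))
      expect_equal(row$specificity, unname(ot$per_class[[k]]["specificity"]))
    }
    expect_equal(tm$accuracy, ot$accuracy)
  }
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  set.seed(7)
  for (i in 1:20) {
    cohort <- random_cohort(n = 80)
    m <- suppressWarnings(binary_metrics(build_confusion(cohort, "binary", 1)))
    expect_equal(m$balanced_accuracy, mean(c(m$sensitivity, m$specificity)))
    tm <- suppressWarnings(ternary_metrics(build_confusion(cohort, "ternary", 1)))
    expect_equal(tm$per_class$balanced_accuracy,
                 (tm$per_class$sensitivity + tm$per_class$specificity) / 2)
  }
})

test_that("binary metrics agree with the caret reference implementation", {
  skip_if_not_installed("caret")
  cohort <- simulate_cohort(cohort_params(seed = 11))
  pat <- cohort$pattern_m1
  keep <- pat != "unscored"
  predicted <- factor(ifelse(pat[keep] %in% c("OE", "CA", "CY"),
                             "abnormal", "normal"),
                      levels = c("abnormal", "normal"))
  truth <- factor(ifelse(cohort$functional_class[keep] == "NDM",
                         "normal", "abnormal"),
                  levels = c("abnormal", "normal"))
  ref <- caret::confusionMatrix(predicted, truth, positive = "abnormal")
  m <- binary_metrics(build_confusion(cohort, "binary", 1))
  expect_equal(m$sensitivity, unname(ref$byClass["Sensitivity"]))
  expect_equal(m$specificity, unname(ref$byClass["Specificity"]))
  expect_equal(m$accuracy, unname(ref$overall["Accuracy"]))
  expect_equal(m$ci_low, unname(ref$overall["AccuracyLower"]))
  expect_equal(m$ci_high, unname(ref$overall["AccuracyUpper"]))
})

test_that("the accuracy interval matches the exact binomial closed form", {
  m <- binary_metrics(build_confusion(fixture_cohort(), "binary", 1))
  x <- 242; n <- 249
  expect_equal(m$ci_low, qbeta(0.025, x, n - x + 1))
  expect_equal(m$ci_high, qbeta(0.975, x + 1, n - x))
})

test_that("kappa honours its closed forms and the e1071 reference", {
  # perfect agreement
  expect_equal(cohens_kappa(c("OE", "WT", "CA", "CY"),
                            c("OE", "WT", "CA", "CY"))$kappa, 1)
  # two labels split 50/50 with maximal disagreement
  expect_equal(cohens_kappa(c("OE", "OE", "WT", "WT"),
                            c("WT", "WT", "OE", "OE"))$kappa, -1)
  # kappa identity (po - pe) / (1 - pe)
  set.seed(3)
  a <- sample(c("OE", "CA", "WT", "CY"), 200, replace = TRUE)
  b <- sample(c("OE", "CA", "WT", "CY"), 200, replace = TRUE)
  k <- cohens_kappa(a, b)
  expect_equal(k$kappa,
               (k$observed_agreement - k$expected_agreement) /
                 (1 - k$expected_agreement))
  expect_equal(k$kappa, oracle_kappa(a, b))

  skip_if_not_installed("e1071")
  tab <- table(factor(a, levels = c("OE", "CA", "WT", "CY")),
               factor(b, levels = c("OE", "CA", "WT", "CY")))
  expect_equal(k$kappa, e1071::classAgreement(tab)$kappa)
})

test_that("independently drawn raters have kappa near zero", {
  set.seed(123)
  a <- sample(c("OE", "CA", "WT", "CY"), 20000, replace = TRUE,
              prob = c(0.45, 0.2, 0.3, 0.05))
  b <- sample(c("OE", "CA", "WT", "CY"), 20000, replace = TRUE,
              prob = c(0.45, 0.2, 0.3, 0.05))
  expect_lt(abs(cohens_kappa(a, b)$kappa), 0.03)
})

test_that("kappa validates its inputs", {
  expect_error(cohens_kappa(c("OE", "WT"), c("OE")),
               class = "p53ihc_validation_error")
  expect_error(cohens_kappa(c("OE", "unscored"), c("OE", "WT")),
               class = "p53ihc_validation_error")
})
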