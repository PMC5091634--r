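# Shared fixtures and independent per-case oracles used by the property
# tests. The oracles deliberately avoid the package's tabulation path:
# they loop over cases one at a time and count.

fixture_cohort <- function() {
  classify_cohort(table4_cohort())
}

# a random case-level cohort drawn directly on the classifier's input
# domain (class labels and pattern tokens), independent of the variant
# parser and of the study's structure
random_cohort <- function(n = 60) {
  tibble::tibble(
    case_id = sprintf("r%04d", seq_len(n)),
    histotype = sample(c("HGSOC", "EC"), n, replace = TRUE),
    variant = NA_character_,
    pattern_m1 = sample(c("OE", "CA", "WT", "CY", "unscored"), n,
                        replace = TRUE, prob = c(0.4, 0.2, 0.3, 0.05, 0.05)),
    mutation_type = NA_character_,
    functional_class = sample(c("GOF", "LOF", "NDM"), n, replace = TRUE),
    deleterious = NA
  )
}

# binary metrics by explicit per-case counting
oracle_binary <- function(cohort, method_id = 1) {
  tp <- fp <- fn <- tn <- 0L
  pat <- cohort[[paste0("pattern_m", method_id)]]
  for (i in seq_len(nrow(cohort))) {
    p <- pat[i]
    if (is.na(p) || p == "unscored") next
    abnormal <- p %in% c("OE", "CA", "CY")
    del <- cohort$functional_class[i] != "NDM"
    if (abnormal && del) tp <- tp + 1L
    else if (abnormal && !del) fp <- fp + 1L
    else if (!abnormal && del) fn <- fn + 1L
    else tn <- tn + 1L
  }
  n <- tp + fp + fn + tn
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = if (n > 0) (tp + tn) / n else NA_real_,
    n_included = n
  )
}

# ternary one-vs-rest metrics by explicit per-case counting
oracle_ternary <- function(cohort, method_id = 1) {
  implied <- c(OE = "GOF", CA = "LOF", WT = "NDM")
  pat <- cohort[[paste0("pattern_m", method_id)]]
  pred <- truth <- character(0)
  for (i in seq_len(nrow(cohort))) {
    p <- pat[i]
    if (is.na(p) || p %in% c("unscored", "CY")) next
    pred <- c(pred, implied[[p]])
    truth <- c(truth, cohort$functional_class[i])
  }
  per <- lapply(c("GOF", "LOF", "NDM"), function(k) {
    tp <- sum(pred == k & truth == k)
    fn <- sum(pred != k & truth == k)
    fp <- sum(pred == k & truth != k)
    tn <- sum(pred != k & truth != k)
    c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
  names(per) <- c("GOF", "LOF", "NDM")
  list(per_class = per,
       accuracy = if (length(pred)) mean(pred == truth) else NA_real_,
       n_included = length(pred))
}

# kappa by explicit counting over the pair list
oracle_kappa <- function(a, b, levels = c("OE", "CA", "WT", "CY")) {
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (l1 in levels) {
    pe <- pe + (sum(a == l1) / n) * (sum(b == l1) / n)
  }
  (po - pe) / (1 - pe)
}
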