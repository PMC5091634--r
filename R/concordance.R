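PATTERN_LEVELS <- c("OE", "CA", "WT", "CY")
PATTERN_TOKENS <- c(PATTERN_LEVELS, "unscored")
CLASS_LEVELS <- c("GOF", "LOF", "NDM")

pattern_column <- function(method_id) {
  stopifnot(length(method_id) == 1L, method_id %in% 1:4)
  paste0("pattern_m", method_id)
}

#' Cross-tabulate observed IHC pattern against TP53 mutation class
#'
#' Builds the confusion matrix for one assay method in one of two modes:
#' \describe{
#'   \item{binary}{prediction is `abnormal` when the observed pattern is
#'     OE, CA or CY and `normal` for WT; truth is `deleterious` when the
#'     functional class is GOF or LOF, `NDM` otherwise. Only unscored
#'     cases are excluded.}
#'   \item{ternary}{observed OE predicts GOF, CA predicts LOF, WT predicts
#'     NDM; cytoplasmic (CY) cases are moved to the exclusion tally along
#'     with unscored cases.}
#' }
#' Cell counts plus exclusions always add up to the cohort size.
#'
#' @param cohort A classified cohort (see [classify_cohort()]); must carry
#'   `functional_class` and the `pattern_m<method_id>` column.
#' @param mode `"binary"` or `"ternary"`.
#' @param method_id Assay method, 1 to 4.
#' @return A `p53_confusion`: list with `mode`, `method_id`, `table`
#'   (predicted x truth matrix), `excluded` (named counts: `unscored`,
#'   `cytoplasmic`), `n_included`, `n_total`.
#' @examples
#' cm <- build_confusion(classify_cohort(table4_cohort()), "binary", 1)
#' cm$table
#' @export
build_confusion <- function(cohort, mode = c("binary", "ternary"),
                            method_id = 1) {
  mode <- match.arg(mode)
  col <- pattern_column(method_id)
  stopifnot(is.data.frame(cohort))
  if (!col %in% names(cohort)) {
    rlang::abort(sprintf("cohort has no column '%s'", col),
                 class = "p53ihc_validation_error")
  }
  if (!"functional_class" %in% names(cohort)) {
    rlang::abort("cohort is not classified; run classify_cohort() first",
                 class = "p53ihc_validation_error")
  }
  pat <- cohort[[col]]
  pat[is.na(pat)] <- "unscored"
  bad <- setdiff(unique(pat), PATTERN_TOKENS)
  if (length(bad)) {
    offender <- cohort$case_id[match(bad[1], pat)]
    rlang::abort(sprintf("unknown pattern token '%s' (case %s)", bad[1],
                         offender), class = "p53ihc_validation_error")
  }
  cls <- cohort$functional_class

  n_total <- nrow(cohort)
  unscored <- sum(pat == "unscored")

  if (mode == "binary") {
    keep <- pat != "unscored"
    predicted <- factor(ifelse(pat[keep] %in% c("OE", "CA", "CY"),
                               "abnormal", "normal"),
                        levels = c("abnormal", "normal"))
    truth <- factor(ifelse(cls[keep] == "NDM", "NDM", "deleterious"),
                    levels = c("deleterious", "NDM"))
    excluded <- c(unscored = unscored, cytoplasmic = 0L)
  } else {
    keep <- !pat %in% c("unscored", "CY")
    predicted <- factor(c(OE = "GOF", CA = "LOF", WT = "NDM")[pat[keep]],
                        levels = CLASS_LEVELS)
    truth <- factor(cls[keep], levels = CLASS_LEVELS)
    excluded <- c(unscored = unscored, cytoplasmic = sum(pat == "CY"))
  }

  tab <- table(predicted = predicted, truth = truth)
  structure(list(mode = mode, method_id = method_id,
                 table = unclass(tab),
                 excluded = excluded,
                 n_included = sum(tab),
                 n_total = n_total),
            class = "p53_confusion")
}

#' @export
print.p53_confusion <- function(x, ...) {
  cat("<p53_confusion> mode:", x$mode, " method:", x$method_id,
      " included:", x$n_included, "/", x$n_total, "\n")
  print(x$table)
  cat("excluded:", paste(names(x$excluded), x$excluded, sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

# a proportion that is NA (not 0) on a zero denominator, with a warning
safe_prop <- function(num, den, what) {
  if (den == 0) {
    rlang::warn(sprintf("%s is undefined (zero denominator)", what))
    return(NA_real_)
  }
  num / den
}

# exact (Clopper-Pearson) 95% binomial interval on overall accuracy
accuracy_ci <- function(correct, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  unname(stats::binom.test(correct, n)$conf.int)
}

#' Binary diagnostic metrics
#'
#' Sensitivity (abnormal staining among deleterious mutations), specificity
#' (normal staining among NDM), balanced accuracy (their mean), and overall
#' accuracy with an exact 95% Clopper-Pearson binomial confidence interval.
#' Zero-denominator metrics are reported as `NA`, never as 0.
#'
#' @param cm A binary `p53_confusion`.
#' @return A `p53_metrics` list: `mode`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `accuracy`, `ci_low`, `ci_high`, `n_included`,
#'   `excluded`.
#' @export
binary_metrics <- function(cm) {
  stopifnot(inherits(cm, "p53_confusion"))
  if (cm$mode != "binary") {
    rlang::abort("confusion matrix is not in binary mode",
                 class = "p53ihc_validation_error")
  }
  tab <- cm$table
  sens <- safe_prop(tab["abnormal", "deleterious"], sum(tab[, "deleterious"]),
                    "sensitivity")
  spec <- safe_prop(tab["normal", "NDM"], sum(tab[, "NDM"]), "specificity")
  correct <- tab["abnormal", "deleterious"] + tab["normal", "NDM"]
  acc <- safe_prop(correct, cm$n_included, "accuracy")
  ci <- accuracy_ci(correct, cm$n_included)
  structure(list(mode = "binary", method_id = cm$method_id,
                 sensitivity = sens, specificity = spec,
                 balanced_accuracy = mean(c(sens, spec)),
                 accuracy = acc, ci_low = ci[1], ci_high = ci[2],
                 n_included = cm$n_included, excluded = cm$excluded,
                 per_class = NULL),
            class = "p53_metrics")
}

#' Ternary diagnostic metrics
#'
#' One-vs-rest sensitivity, specificity and balanced accuracy per
#' functional class (GOF, LOF, NDM), and overall accuracy (the matrix
#' trace over included cases) with an exact 95% binomial confidence
#' interval.
#'
#' @param cm A ternary `p53_confusion`.
#' @return A `p53_metrics` list whose `per_class` element is a tibble with
#'   one row per class.
#' @export
ternary_metrics <- function(cm) {
  stopifnot(inherits(cm, "p53_confusion"))
  if (cm$mode != "ternary") {
    rlang::abort("confusion matrix is not in ternary mode",
                 class = "p53ihc_validation_error")
  }
  tab <- cm$table
  per <- lapply(CLASS_LEVELS, function(k) {
    tp <- tab[k, k]
    fn <- sum(tab[, k]) - tp
    fp <- sum(tab[k, ]) - tp
    tn <- sum(tab) - tp - fn - fp
    sens <- safe_prop(tp, tp + fn, sprintf("%s sensitivity", k))
    spec <- safe_prop(tn, tn + fp, sprintf("%s specificity", k))
    tibble::tibble(class = k, sensitivity = sens, specificity = spec,
                   balanced_accuracy = mean(c(sens, spec)))
  })
  per <- dplyr::bind_rows(per)
  correct <- sum(diag(tab))
  acc <- safe_prop(correct, cm$n_included, "accuracy")
  ci <- accuracy_ci(correct, cm$n_included)
  structure(list(mode = "ternary", method_id = cm$method_id,
                 sensitivity = NA_real_, specificity = NA_real_,
                 balanced_accuracy = NA_real_,
                 accuracy = acc, ci_low = ci[1], ci_high = ci[2],
                 n_included = cm$n_included, excluded = cm$excluded,
                 per_class = per),
            class = "p53_metrics")
}

#' Diagnostic metrics for either mode
#'
#' Dispatches to [binary_metrics()] or [ternary_metrics()] on the
#' confusion matrix mode.
#'
#' @param cm A `p53_confusion`.
#' @return A `p53_metrics`.
#' @export
diagnostic_metrics <- function(cm) {
  stopifnot(inherits(cm, "p53_confusion"))
  if (cm$mode == "binary") binary_metrics(cm) else ternary_metrics(cm)
}

#' @export
print.p53_metrics <- function(x, ...) {
  cat("<p53_metrics> mode:", x$mode, " n:", x$n_included, "\n")
  if (x$mode == "binary") {
    cat(sprintf("  sensitivity %.3f  specificity %.3f  balanced %.3f\n",
                x$sensitivity, x$specificity, x$balanced_accuracy))
  } else {
    print(x$per_class)
  }
  cat(sprintf("  accuracy %.3f  (95%% CI %.3f-%.3f)\n",
              x$accuracy, x$ci_low, x$ci_high))
  invisible(x)
}

#' Cohen's kappa for two raters
#'
#' Unweighted (equal-weights) Cohen's kappa for two parallel lists of
#' categorical scores over the four-pattern label set. Both lists must be
#' scored (no `unscored` tokens) and of equal length.
#'
#' @param ratings_a,ratings_b Character vectors of pattern labels.
#' @param levels Label set; defaults to the four staining patterns.
#' @return A `p53_kappa` list: `kappa`, `n`, `observed_agreement`,
#'   `expected_agreement`, `table`.
#' @examples
#' cohens_kappa(c("OE", "WT", "CA"), c("OE", "WT", "CA"))$kappa  # 1
#' @export
cohens_kappa <- function(ratings_a, ratings_b, levels = PATTERN_LEVELS) {
  if (length(ratings_a) != length(ratings_b)) {
    rlang::abort("rating lists have different lengths",
                 class = "p53ihc_validation_error")
  }
  if (length(ratings_a) == 0L) {
    rlang::abort("rating lists are empty", class = "p53ihc_validation_error")
  }
  bad <- setdiff(unique(c(ratings_a, ratings_b)), levels)
  if (length(bad)) {
    rlang::abort(sprintf("unscored or unknown label '%s' in ratings", bad[1]),
                 class = "p53ihc_validation_error")
  }
  a <- factor(ratings_a, levels = levels)
  b <- factor(ratings_b, levels = levels)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  structure(list(kappa = kappa, n = n, observed_agreement = po,
                 expected_agreement = pe, table = unclass(tab)),
            class = "p53_kappa")
}

#' @export
print.p53_kappa <- function(x, ...) {
  cat(sprintf("<p53_kappa> kappa %.3f  (Po %.3f, Pe %.3f, n = %d)\n",
              x$kappa, x$observed_agreement, x$expected_agreement, x$n))
  invisible(x)
}
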