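HISTOTYPE_LEVELS <- c("HGSOC", "EC")

#' Read and validate a cohort table
#'
#' Reads a delimited cohort file (comma by default, tab via `delim`), one
#' row per case, with required columns `case_id`, `histotype` (HGSOC or
#' EC) and `variant` (HGVS protein or coding notation, or `NDM`), plus one
#' pattern column per assay method (`pattern_m1`..`pattern_m4`, values OE
#' / CA / WT / CY / unscored; absent methods may be missing entirely).
#' Row-level problems (unknown pattern tokens, unknown histotypes) are
#' aggregated and reported with their line numbers in a single error.
#' By default the table is classified on read.
#'
#' @param path Path to the file.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @param classify Run [classify_cohort()] on the validated table?
#' @return A cohort tibble.
#' @examples
#' path <- system.file("extdata", "table4_cohort.csv", package = "p53ihc")
#' cohort <- read_cohort(path)
#' nrow(cohort)  # 251 cases
#' @export
read_cohort <- function(path, delim = ",", classify = TRUE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such file: '%s'", path),
                 class = "p53ihc_io_error")
  }
  tab <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      col_types = readr::cols(.default = "c"),
                      progress = FALSE),
    error = function(e) rlang::abort(
      sprintf("cannot parse '%s' as delimited text: %s", path,
              conditionMessage(e)),
      class = "p53ihc_schema_error")
  )
  required <- c("case_id", "histotype", "variant")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) || nrow(tab) == 0L) {
    rlang::abort(sprintf(
      "'%s' is not a cohort table: %s", path,
      if (nrow(tab) == 0L) "no data rows"
      else paste("missing column(s)", paste(missing_cols, collapse = ", "))),
      class = "p53ihc_schema_error")
  }
  pattern_cols <- intersect(paste0("pattern_m", 1:4), names(tab))
  if (!length(pattern_cols)) {
    rlang::abort(sprintf("'%s' has no pattern_m1..pattern_m4 column", path),
                 class = "p53ihc_schema_error")
  }

  problems <- character(0)
  line_no <- seq_len(nrow(tab)) + 1L  # header is line 1
  bad_hist <- !tab$histotype %in% HISTOTYPE_LEVELS
  if (any(bad_hist)) {
    problems <- c(problems, sprintf(
      "line %d: unknown histotype '%s'", line_no[bad_hist],
      tab$histotype[bad_hist]))
  }
  for (col in pattern_cols) {
    bad <- !is.na(tab[[col]]) & !tab[[col]] %in% PATTERN_TOKENS
    if (any(bad)) {
      problems <- c(problems, sprintf(
        "line %d: unknown pattern token '%s' in %s", line_no[bad],
        tab[[col]][bad], col))
    }
  }
  if (anyDuplicated(tab$case_id)) {
    problems <- c(problems, sprintf(
      "duplicate case_id '%s'", unique(tab$case_id[duplicated(tab$case_id)])))
  }
  if (length(problems)) {
    rlang::abort(paste0("invalid cohort file '", path, "':\n  ",
                        paste(problems, collapse = "\n  ")),
                 class = "p53ihc_validation_error")
  }
  if (classify) classify_cohort(tab) else tab
}

#' Write a cohort table
#'
#' Writes the validated cohort columns (`case_id`, `histotype`, `variant`,
#' the pattern columns) as delimited text; derived classification columns
#' are not written, so `write_cohort(read_cohort(f))` preserves all
#' validated fields.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  keep <- intersect(c("case_id", "histotype", "variant",
                      paste0("pattern_m", 1:4)), names(cohort))
  readr::write_delim(cohort[keep], path, delim = delim, na = "")
  invisible(path)
}

#' Read per-case TP53 variants from a VCF
#'
#' Alternative variant input channel: a VCF whose records carry HGVS
#' annotations in INFO keys. Each record must name its case in the `CASE`
#' INFO key and carry a protein (`HGVSP`) or coding (`HGVSC`) annotation;
#' records lacking both are skipped with a summary warning. When a case
#' has several records, the classifying variant is selected by the
#' multi-variant priority rule. Cases listed in `case_ids` with no VCF
#' record are returned as NDM.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @param case_ids Optional character vector of expected cases; cases with
#'   no record are marked `NDM`.
#' @return A tibble with `case_id` and normalized `variant` notation.
#' @export
read_vcf_variants <- function(path, case_ids = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    rlang::abort("reading VCF input requires the vcfR package")
  }
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such file: '%s'", path),
                 class = "p53ihc_io_error")
  }
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) rlang::abort(
                    sprintf("malformed VCF '%s': %s", path,
                            conditionMessage(e)),
                    class = "p53ihc_format_error"))
  info <- function(key) vcfR::extract.info(vcf, element = key)
  cases <- info("CASE")
  hgvsp <- info("HGVSP")
  hgvsc <- info("HGVSC")
  n_rec <- nrow(vcf@fix)
  if (n_rec == 0L) {
    notation <- character(0); cases <- character(0)
  } else {
    notation <- ifelse(!is.na(hgvsp) & hgvsp != "", hgvsp, hgvsc)
  }
  usable <- !is.na(cases) & !is.na(notation) & notation != ""
  n_skipped <- n_rec - sum(usable)
  if (n_skipped > 0) {
    rlang::warn(sprintf(
      "%d VCF record(s) lacked CASE or HGVS annotation and were skipped",
      n_skipped))
  }
  by_case <- split(notation[usable], cases[usable])
  picked <- vapply(by_case, function(nots) {
    vars <- lapply(nots, parse_variant)
    format_variant(select_primary_variant(vars))
  }, character(1))
  out <- tibble::tibble(case_id = names(picked), variant = unname(picked))
  if (!is.null(case_ids)) {
    absent <- setdiff(case_ids, out$case_id)
    out <- dplyr::bind_rows(
      out, tibble::tibble(case_id = absent, variant = "NDM"))
    out <- out[match(case_ids, out$case_id), ]
  }
  out
}

round_half_even <- function(x, digits = 2) round(x, digits)

metrics_as_list <- function(m) {
  out <- list(mode = m$mode, method_id = m$method_id,
              accuracy = m$accuracy, ci_low = m$ci_low, ci_high = m$ci_high,
              n_included = m$n_included,
              excluded = as.list(m$excluded))
  if (m$mode == "binary") {
    out$sensitivity <- m$sensitivity
    out$specificity <- m$specificity
    out$balanced_accuracy <- m$balanced_accuracy
  } else {
    out$per_class <- m$per_class
  }
  out
}

#' Build a self-contained concordance report
#'
#' Runs the concordance engine in both modes for the requested methods and
#' collects, in one document: confusion matrices, metrics, exclusion
#' counts, discordance lists, the package version and input digest. Every
#' reported proportion is recomputable from a matrix embedded in the same
#' document.
#'
#' @param cohort A classified cohort.
#' @param method_ids Assay methods to report (those with pattern columns).
#' @param seed Optional seed to record (for synthetic cohorts).
#' @return A list of class `p53_report`, serializable with
#'   [write_report()].
#' @export
concordance_report <- function(cohort, method_ids = 1, seed = NULL) {
  methods <- lapply(method_ids, function(m) {
    res <- lapply(c("binary", "ternary"), function(mode) {
      cm <- build_confusion(cohort, mode, m)
      list(confusion = cm$table, excluded = as.list(cm$excluded),
           n_included = cm$n_included,
           metrics = metrics_as_list(diagnostic_metrics(cm)),
           discordant = find_discordant(cohort, mode, m)$discordant)
    })
    stats::setNames(res, c("binary", "ternary"))
  })
  structure(list(
    methods = stats::setNames(methods, paste0("method_", method_ids)),
    n_cases = nrow(cohort),
    software_version = as.character(utils::packageVersion("p53ihc")),
    input_digest = sprintf("%d cases; %d deleterious", nrow(cohort),
                           sum(cohort$deleterious)),
    seed = seed
  ), class = "p53_report")
}

#' Write a report as JSON
#'
#' @param report A `p53_report` from [concordance_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
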