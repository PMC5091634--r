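class_implied_pattern <- c(GOF = "OE", LOF = "CA", NDM = "WT")

#' Find cases discordant between staining and mutation class
#'
#' Lists the cases whose observed staining pattern disagrees with their
#' mutation classification for one assay method.
#' \describe{
#'   \item{binary}{discordant when abnormal staining (OE/CA/CY) meets an
#'     NDM case, or normal staining (WT) meets a deleterious mutation.}
#'   \item{ternary}{discordant when the class implied by the pattern
#'     (OE implies GOF, CA implies LOF, WT implies NDM) differs from the
#'     mutation class; cytoplasmic cases cannot imply a class and are
#'     reported in the advisory list.}
#' }
#' Unscored (and, in ternary mode, cytoplasmic) cases are never silently
#' dropped: they are returned as a separate advisory tibble.
#'
#' @param cohort A classified cohort (see [classify_cohort()]).
#' @param mode `"binary"` or `"ternary"`.
#' @param method_id Assay method, 1 to 4.
#' @return A list with `discordant` (tibble: `case_id`, `pattern`,
#'   `functional_class`, `mismatch` descriptor) and `advisory` (tibble of
#'   excluded cases with their exclusion reason).
#' @export
find_discordant <- function(cohort, mode = c("binary", "ternary"),
                            method_id = 1) {
  mode <- match.arg(mode)
  col <- pattern_column(method_id)
  stopifnot(is.data.frame(cohort), col %in% names(cohort),
            "functional_class" %in% names(cohort))
  pat <- cohort[[col]]
  pat[is.na(pat)] <- "unscored"
  cls <- cohort$functional_class

  if (mode == "binary") {
    excluded <- pat == "unscored"
    abnormal <- pat %in% c("OE", "CA", "CY")
    deleterious <- cls != "NDM"
    mism <- !excluded & (abnormal != deleterious)
    mismatch <- ifelse(abnormal[mism],
                       "abnormal staining without deleterious mutation",
                       "normal staining with deleterious mutation")
    reason <- rep("unscored", sum(excluded))
  } else {
    excluded <- pat %in% c("unscored", "CY")
    implied <- class_implied_pattern[cls]
    mism <- !excluded & (pat != implied)
    mismatch <- sprintf("observed %s implies %s but mutation class is %s",
                        pat[mism],
                        names(class_implied_pattern)[match(pat[mism],
                                                           class_implied_pattern)],
                        cls[mism])
    reason <- ifelse(pat[excluded] == "CY", "cytoplasmic", "unscored")
  }

  list(
    discordant = tibble::tibble(
      case_id = cohort$case_id[mism],
      pattern = pat[mism],
      functional_class = cls[mism],
      mutation_type = cohort$mutation_type[mism],
      mismatch = mismatch
    ),
    advisory = tibble::tibble(
      case_id = cohort$case_id[excluded],
      pattern = pat[excluded],
      functional_class = cls[excluded],
      reason = reason
    )
  )
}

#' Read a revision-record file
#'
#' Revisions are external bench results (full-section restains,
#' re-sequencing), never inferred by the software. The file is CSV with
#' columns `case_id`, `field` (`ihc_pattern` or `mutation`), `old_value`,
#' `new_value`, `evidence`, and optionally `method_id` (defaults to 1 for
#' `ihc_pattern` revisions).
#'
#' @param path Path to a CSV file.
#' @return A tibble of revision records.
#' @export
read_revisions <- function(path) {
  rev <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("case_id", "field", "old_value", "new_value")
  missing <- setdiff(required, names(rev))
  if (length(missing)) {
    rlang::abort(sprintf("revision file lacks column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "p53ihc_schema_error")
  }
  if (!"evidence" %in% names(rev)) rev$evidence <- NA_character_
  if (!"method_id" %in% names(rev)) rev$method_id <- "1"
  rev$method_id <- as.integer(rev$method_id)
  bad <- setdiff(unique(rev$field), c("ihc_pattern", "mutation"))
  if (length(bad)) {
    rlang::abort(sprintf("unknown revision field '%s'", bad[1]),
                 class = "p53ihc_validation_error")
  }
  tibble::as_tibble(rev)
}

#' Apply revision records to a cohort
#'
#' Books each revision against a copy of the cohort: `ihc_pattern`
#' revisions replace the observed pattern for the record's method,
#' `mutation` revisions replace the variant notation. Every record's
#' `old_value` must match the cohort's current value — a mismatch (e.g.
#' applying the same records twice) raises a stale-revision error rather
#' than double-applying. Derived classifications are recomputed after
#' booking. The input cohort is never modified.
#'
#' @param cohort A classified cohort.
#' @param revisions A tibble of revision records (see [read_revisions()]).
#' @return A list with `cohort` (the revised, re-classified copy) and
#'   `audit` (one row per applied change).
#' @export
apply_revisions <- function(cohort, revisions) {
  stopifnot(is.data.frame(cohort), is.data.frame(revisions))
  out <- cohort
  audit <- vector("list", nrow(revisions))
  for (i in seq_len(nrow(revisions))) {
    r <- revisions[i, ]
    idx <- which(out$case_id == r$case_id)
    if (length(idx) != 1L) {
      rlang::abort(sprintf("unknown case_id '%s' in revision %d", r$case_id, i),
                   class = "p53ihc_validation_error")
    }
    col <- if (r$field == "ihc_pattern") {
      pattern_column(if ("method_id" %in% names(r) && !is.na(r$method_id))
        r$method_id else 1L)
    } else if (r$field == "mutation") {
      "variant"
    } else {
      rlang::abort(sprintf("unknown revision field '%s'", r$field),
                   class = "p53ihc_validation_error")
    }
    current <- out[[col]][idx]
    if (!identical(as.character(current), as.character(r$old_value))) {
      rlang::abort(sprintf(
        "stale revision for case %s: %s is '%s', record expects '%s'",
        r$case_id, col, current, r$old_value),
        class = "p53ihc_stale_revision_error")
    }
    out[[col]][idx] <- r$new_value
    audit[[i]] <- tibble::tibble(
      case_id = r$case_id, field = r$field, column = col,
      old_value = as.character(r$old_value),
      new_value = as.character(r$new_value),
      evidence = if ("evidence" %in% names(r)) r$evidence else NA_character_
    )
  }
  list(cohort = classify_cohort(out), audit = dplyr::bind_rows(audit))
}

#' Paired metrics before and after revision
#'
#' Runs the concordance engine on the cohort as given (primary analysis)
#' and after booking the revision records (secondary analysis), and
#' reports both metric sets with their deltas.
#'
#' @param cohort A classified cohort.
#' @param revisions Revision records (possibly zero rows).
#' @param mode `"binary"` or `"ternary"`.
#' @param method_id Assay method, 1 to 4.
#' @return A list with `primary`, `revised` (both `p53_metrics`), `delta`
#'   (named numeric: accuracy and, for binary, sensitivity/specificity
#'   changes) and `audit`.
#' @export
primary_vs_revised_report <- function(cohort, revisions,
                                      mode = c("binary", "ternary"),
                                      method_id = 1) {
  mode <- match.arg(mode)
  primary <- diagnostic_metrics(build_confusion(cohort, mode, method_id))
  rev <- apply_revisions(cohort, revisions)
  revised <- diagnostic_metrics(build_confusion(rev$cohort, mode, method_id))
  delta <- c(accuracy = revised$accuracy - primary$accuracy)
  if (mode == "binary") {
    delta <- c(delta,
               sensitivity = revised$sensitivity - primary$sensitivity,
               specificity = revised$specificity - primary$specificity)
  }
  list(primary = primary, revised = revised, delta = delta, audit = rev$audit)
}
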