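#' Predict the protein product of a TP53 variant
#'
#' Applies the position rules relating a variant to the p53 protein a
#' tumour cell can display to the DO-7 antibody:
#' \itemize{
#'   \item a premature termination codon (stopgain, or the frameshift-derived
#'     stop) before codon 213 triggers nonsense-mediated decay — no protein;
#'   \item a termination codon at or after codon 245 leaves a detectable
#'     truncated protein of `codon - 1` residues;
#'   \item termination codons in the unruled 213–244 gap are called
#'     non-expressed at `ambiguous` confidence;
#'   \item substitutions and in-frame indels leave a (near) full-length
#'     protein; splicing mutations default to non-expressed at low
#'     confidence.
#' }
#' Frameshifts take their termination codon from the HGVS `fs*N` suffix
#' when present; without one, the frameshift start codon is used as the
#' premature-stop position at low confidence. Epitope (codons 19–26) and
#' nuclear-localization-signal (codons 316–325) retention are computed from
#' the predicted length.
#'
#' @param variant A `p53_variant`.
#' @param domains Reference map from [tp53_domains()].
#' @return A list of class `p53_product`: `expressed`, `nmd_predicted`,
#'   `predicted_length_aa` (`NA` when no protein or unknown),
#'   `full_length` (logical), `retains_epitope`, `retains_nls`,
#'   `confidence` (`high`, `low` or `ambiguous`).
#' @examples
#' predict_protein_product(parse_variant("p.R306X"))
#' @export
predict_protein_product <- function(variant, domains = tp53_domains()) {
  stopifnot(inherits(variant, "p53_variant"))
  plen <- domains$protein_length_aa

  product <- function(expressed, nmd, len, full, confidence) {
    retains <- function(iv) {
      if (!expressed) return(FALSE)
      if (full || is.na(len)) return(TRUE)  # unknown length: N-terminus intact
      len >= iv[2]
    }
    structure(list(
      expressed = expressed,
      nmd_predicted = nmd,
      predicted_length_aa = if (expressed) len else NA_integer_,
      full_length = full,
      retains_epitope = retains(domains$do7_epitope),
      retains_nls = retains(domains$nls),
      confidence = confidence
    ), class = "p53_product")
  }

  ptc_product <- function(ptc, confidence_known = TRUE) {
    if (ptc < domains$nmd_ca_max_codon) {
      product(FALSE, TRUE, NA_integer_, FALSE,
              if (confidence_known) "high" else "low")
    } else if (ptc >= domains$expressed_min_codon) {
      product(TRUE, FALSE,
              if (confidence_known) ptc - 1L else NA_integer_, FALSE,
              if (confidence_known) "high" else "low")
    } else {
      product(FALSE, TRUE, NA_integer_, FALSE, "ambiguous")
    }
  }

  switch(variant$kind,
    none = ,
    synonymous = product(TRUE, FALSE, plen, TRUE, "high"),
    substitution = product(TRUE, FALSE, plen, TRUE, "high"),
    stopgain = ptc_product(variant$codon_start),
    frameshift = {
      if (!is.na(variant$termination_codon)) {
        ptc_product(variant$termination_codon)
      } else {
        # new stop not derivable without the downstream sequence: use the
        # frameshift start as the earliest possible premature stop
        ptc_product(variant$codon_start, confidence_known = FALSE)
      }
    },
    deletion_inframe = ,
    insertion_inframe = {
      delta <- (variant$codon_end - variant$codon_start + 1L) *
        (if (variant$kind == "deletion_inframe") -1L else 1L)
      product(TRUE, FALSE, plen + delta, TRUE, "high")
    },
    splicing = product(FALSE, FALSE, NA_integer_, FALSE, "low"),
    rlang::abort(sprintf("unknown variant kind '%s'", variant$kind))
  )
}

#' @export
print.p53_product <- function(x, ...) {
  cat("<p53_product> expressed:", x$expressed,
      " length:", x$predicted_length_aa,
      " NMD:", x$nmd_predicted,
      " epitope:", x$retains_epitope,
      " NLS:", x$retains_nls,
      " (", x$confidence, ")\n", sep = "")
  invisible(x)
}

#' Predict the expected IHC staining pattern for a variant
#'
#' Rule-based prediction of the p53 staining pattern under an optimized
#' DO-7 assay:
#' \itemize{
#'   \item nonsynonymous substitution → `OE` (stabilized mutant protein
#'     accumulates in nuclei), high confidence;
#'   \item in-frame indel → `OE` at low confidence (likely the same
#'     conformational effect as a nonsynonymous mutation);
#'   \item no mutation or synonymous → `WT`, high confidence;
#'   \item non-expressed products (nonsense-mediated decay, splicing) →
#'     `CA`;
#'   \item expressed truncations lacking the nuclear localization signal
#'     with predicted length 292–306 aa → `CY`, low confidence;
#'   \item other expressed truncations → `WT`, low confidence.
#' }
#' The returned rationale names, in firing order, exactly the rules applied.
#'
#' @inheritParams predict_protein_product
#' @return A list of class `p53_prediction`: `pattern` (`OE`, `CA`, `WT`
#'   or `CY`), `confidence` (`high`, `low`, `ambiguous`), `rationale`.
#' @examples
#' predict_ihc_pattern(parse_variant("p.R175H"))$pattern  # "OE"
#' predict_ihc_pattern(parse_variant("p.R196X"))$pattern  # "CA"
#' predict_ihc_pattern(parse_variant("p.R306X"))$pattern  # "CY"
#' @export
predict_ihc_pattern <- function(variant, domains = tp53_domains()) {
  stopifnot(inherits(variant, "p53_variant"))
  pred <- function(pattern, confidence, rationale) {
    structure(list(pattern = pattern, confidence = confidence,
                   rationale = paste(rationale, collapse = ";")),
              class = "p53_prediction")
  }

  if (variant$kind == "substitution") {
    return(pred("OE", "high", c("nonsynonymous", "stabilized_nuclear_accumulation")))
  }
  if (variant$kind %in% c("deletion_inframe", "insertion_inframe")) {
    return(pred("OE", "low", c("inframe_indel", "conformational_like_nonsynonymous")))
  }
  if (variant$kind %in% c("none", "synonymous")) {
    return(pred("WT", "high", c(variant$kind, "normal_protein")))
  }

  prod <- predict_protein_product(variant, domains)
  if (!prod$expressed) {
    rat <- if (prod$nmd_predicted) {
      if (prod$confidence == "ambiguous") {
        c("ptc_in_213_244_gap", "nmd_presumed")
      } else c("ptc_before_213", "nmd")
    } else c("splicing", "aberrant_transcript")
    return(pred("CA", prod$confidence, c(rat, "no_protein")))
  }

  # expressed truncation (or unresolved frameshift)
  len <- prod$predicted_length_aa
  cy <- domains$cy_length_range
  if (!prod$retains_nls && !is.na(len) && len >= cy[1] && len <= cy[2]) {
    return(pred("CY", "low",
                c("truncation_expressed", "nls_lost", "length_292_306",
                  "cytoplasmic_retention")))
  }
  pred("WT", "low",
       c("truncation_expressed",
         if (prod$retains_nls) "nls_retained" else "nls_lost",
         "detectable_protein"))
}

#' @export
print.p53_prediction <- function(x, ...) {
  cat("<p53_prediction> ", x$pattern, " (", x$confidence, ")  [",
      x$rationale, "]\n", sep = "")
  invisible(x)
}

#' Is an observed pattern concordant with its prediction?
#'
#' Compares a predicted pattern with a scored observation. Unscored
#' observations are not assessable and raise an error. Predictions at
#' `ambiguous` confidence never count as discordance of record: they
#' return `TRUE` regardless of the observed pattern.
#'
#' @param predicted A `p53_prediction`.
#' @param observed An observed pattern string (`OE`, `CA`, `WT`, `CY`).
#' @return Logical scalar.
#' @export
pattern_concordant <- function(predicted, observed) {
  stopifnot(inherits(predicted, "p53_prediction"), is.character(observed),
            length(observed) == 1L)
  if (is.na(observed) || observed == "unscored") {
    rlang::abort("observation is unscored and not assessable",
                 class = "p53ihc_not_assessable_error")
  }
  if (!observed %in% c("OE", "CA", "WT", "CY")) {
    rlang::abort(sprintf("unknown pattern token '%s'", observed),
                 class = "p53ihc_validation_error")
  }
  if (predicted$confidence == "ambiguous") return(TRUE)
  identical(predicted$pattern, observed)
}

#' Predict expected staining patterns for a whole cohort
#'
#' Batch form of [predict_ihc_pattern()]: parses each case's variant,
#' selects the classifying variant for multi-hit cases, and appends
#' `predicted_pattern`, `prediction_confidence` and `prediction_rationale`
#' columns.
#'
#' @param cohort Cohort tibble with `case_id` and `variant` columns.
#' @param domains Reference map from [tp53_domains()].
#' @return The cohort with prediction columns appended.
#' @export
predict_cohort_patterns <- function(cohort, domains = tp53_domains()) {
  stopifnot(is.data.frame(cohort), all(c("case_id", "variant") %in% names(cohort)))
  preds <- lapply(cohort$variant, function(x) {
    predict_ihc_pattern(select_primary_variant(parse_variant(x)), domains)
  })
  out <- cohort
  out$predicted_pattern <- vapply(preds, `[[`, character(1), "pattern")
  out$prediction_confidence <- vapply(preds, `[[`, character(1), "confidence")
  out$prediction_rationale <- vapply(preds, `[[`, character(1), "rationale")
  tibble::as_tibble(out)
}
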