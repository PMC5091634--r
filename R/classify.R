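#' Mutation type of a parsed variant
#'
#' Maps a structured variant onto the five-way mutation-type taxonomy used
#' to head the contingency tables: `nonsynonymous`, `indel`, `stopgain`,
#' `splicing`, `synonymous` or `none`. Substitutions whose alternate
#' residue is a stop are stopgains; deletions, insertions and frameshifts
#' are all `indel` (use [indel_frame()] for the in-frame/frameshift
#' qualifier).
#'
#' @param variant A `p53_variant` from [parse_variant()].
#' @return A single string.
#' @examples
#' mutation_type(parse_variant("p.R273H"))   # "nonsynonymous"
#' mutation_type(parse_variant("p.I255del")) # "indel"
#' @export
mutation_type <- function(variant) {
  stopifnot(inherits(variant, "p53_variant"))
  switch(variant$kind,
    substitution = "nonsynonymous",
    stopgain = "stopgain",
    deletion_inframe = ,
    insertion_inframe = ,
    frameshift = "indel",
    splicing = "splicing",
    synonymous = "synonymous",
    none = "none"
  )
}

#' In-frame / frameshift qualifier for indels
#'
#' @param variant A `p53_variant`.
#' @return `"inframe"`, `"frameshift"`, or `NA` for non-indel variants.
#' @export
indel_frame <- function(variant) {
  stopifnot(inherits(variant, "p53_variant"))
  switch(variant$kind,
    deletion_inframe = ,
    insertion_inframe = "inframe",
    frameshift = "frameshift",
    NA_character_
  )
}

#' Functional class of a mutation type
#'
#' The ternary functional scheme: gain-of-function (GOF) for any
#' nonsynonymous mutation, loss-of-function (LOF) for any stopgain, indel
#' or splicing mutation, and no detectable mutation (NDM) for absent or
#' synonymous mutations. In-frame indels stay LOF under this definition
#' even though they are predicted to stain like nonsynonymous mutations
#' (see [predict_ihc_pattern()]); the class scheme and the staining
#' prediction are deliberately decoupled.
#'
#' @param mtype A mutation-type string from [mutation_type()] (vectorized).
#' @return `"GOF"`, `"LOF"` or `"NDM"` per element.
#' @examples
#' functional_class("nonsynonymous")  # "GOF"
#' functional_class("splicing")       # "LOF"
#' @export
functional_class <- function(mtype) {
  vapply(mtype, function(x) {
    switch(x,
      nonsynonymous = "GOF",
      stopgain = ,
      indel = ,
      splicing = "LOF",
      synonymous = ,
      none = "NDM",
      rlang::abort(sprintf("unknown mutation type '%s'", x))
    )
  }, character(1), USE.NAMES = FALSE)
}

#' Is a mutation type deleterious?
#'
#' A mutation is deleterious exactly when its functional class is not NDM;
#' synonymous mutations and absent mutations are not deleterious.
#'
#' @param mtype Mutation-type string(s).
#' @return Logical vector.
#' @export
is_deleterious <- function(mtype) {
  functional_class(mtype) != "NDM"
}

# priority used when one case carries several variants: conservative
# toward LOF, deterministic
.variant_priority <- function(v) {
  switch(v$kind,
    stopgain = 1L,
    frameshift = 2L,
    splicing = 3L,
    deletion_inframe = ,
    insertion_inframe = 4L,
    substitution = 5L,
    synonymous = 6L,
    none = 7L
  )
}

#' Select the classifying variant for a multi-variant case
#'
#' When a case carries several variants the one used for classification is
#' chosen by fixed priority: stopgain > frameshift indel > splicing >
#' in-frame indel > nonsynonymous > synonymous > none. Ties are broken by
#' input order. All variants are retained by the caller; this only selects
#' which drives the class.
#'
#' @param variants A `p53_variant` or a list of them.
#' @return The selected `p53_variant`.
#' @export
select_primary_variant <- function(variants) {
  if (inherits(variants, "p53_variant")) return(variants)
  stopifnot(is.list(variants), length(variants) >= 1L)
  pr <- vapply(variants, .variant_priority, integer(1))
  variants[[which.min(pr)]]
}

#' Classify every case of a cohort table
#'
#' Parses the `variant` column (HGVS protein or coding notation, `"NDM"`
#' for no detectable mutation, `;`-separated for multi-hit cases), selects
#' the classifying variant by the multi-variant priority rule, and appends
#' derived columns: `mutation_type`, `functional_class`, `deleterious`,
#' `n_variants` and `multi_hit`.
#'
#' @param cohort A cohort tibble with at least `case_id` and `variant`.
#' @return The cohort with derived classification columns appended
#'   (existing derived columns are recomputed).
#' @export
classify_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort), all(c("case_id", "variant") %in% names(cohort)))
  parsed <- lapply(cohort$variant, parse_variant)
  n_var <- vapply(parsed, function(p)
    if (inherits(p, "p53_variant")) {
      if (p$kind == "none") 0L else 1L
    } else length(p), integer(1))
  primary <- lapply(parsed, select_primary_variant)
  mt <- vapply(primary, mutation_type, character(1))
  out <- dplyr::select(cohort, -dplyr::any_of(
    c("mutation_type", "functional_class", "deleterious", "n_variants",
      "multi_hit")))
  out$mutation_type <- mt
  out$functional_class <- functional_class(mt)
  out$deleterious <- is_deleterious(mt)
  out$n_variants <- n_var
  out$multi_hit <- n_var > 1L
  tibble::as_tibble(out)
}
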