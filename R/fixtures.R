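#' Published method-1 contingency counts (after secondary analysis)
#'
#' The revised method-1 cross-tabulation of observed p53 staining pattern
#' against TP53 mutation type over the 249 assessable cases of the
#' combined HGSOC + EC cohort. Rows are observed patterns, columns are
#' mutation types. These counts anchor the acceptance checks of the
#' concordance engine.
#'
#' @return An integer matrix (4 patterns x 5 mutation types).
#' @export
table4_counts <- function() {
  m <- matrix(
    c(115,  2,  2,  2,  0,
        0, 16, 13, 12,  0,
        0,  2,  2,  0,  0,
        0,  4,  0,  3, 76),
    nrow = 4, byrow = TRUE,
    dimnames = list(pattern = c("OE", "CA", "CY", "WT"),
                    mutation_type = c("nonsynonymous", "indel", "stopgain",
                                      "splicing", "NDM"))
  )
  storage.mode(m) <- "integer"
  m
}

#' Printed study counts
#'
#' Headline counts printed in the study report, kept as package constants
#' so derived fractions (endometrioid-carcinoma mutation prevalence,
#' WT-staining-with-LOF fraction, cytoplasmic fraction) are exact
#' arithmetic on the published numbers.
#'
#' @return A named list of integer counts.
#' @export
study_counts <- function() {
  list(
    n_total = 251L, n_hgsoc = 171L, n_ec = 80L,
    hgsoc_deleterious = 169L, ec_deleterious = 7L,
    hgsoc_gof = 112L, hgsoc_lof = 57L,
    ec_gof = 5L, ec_lof = 2L,
    hgsoc_wt_lof = 7L,       # WT staining despite an LOF mutation
    hgsoc_cy = 4L,           # cytoplasmic staining, all HGSOC
    kappa_raters_n = 148L
  )
}

# deterministic variant notations used when expanding the contingency
# counts into case rows; each is syntactically valid and classifies to the
# intended mutation type
.fixture_variants <- list(
  nonsyn_hotspots = c(rep("p.R175H", 9), rep("p.Y220C", 6), rep("p.R273H", 5)),
  nonsyn_pool = c("p.R248Q", "p.R282W", "p.G245S", "p.Y163C", "p.H179R",
                  "p.C176F", "p.V157F", "p.R158L", "p.L194R", "p.I195T",
                  "p.Y234C", "p.S241F", "p.C242F", "p.G266E", "p.R280T",
                  "p.E285K"),
  stopgain_oe = c("p.R342X", "p.E349X"),
  stopgain_ca = c(rep("p.R196X", 4), "p.W91X", "p.Q104X", "p.E171X",
                  "p.R65X", "p.S90X", "p.E62X", "p.Q136X", "p.E198X",
                  "p.W146X"),
  stopgain_cy = c("p.R306X", "p.R306X"),
  indel_oe = c("p.I255del", "p.I255del"),
  indel_ca = c("p.P58fs", "p.S90fs", "p.Q144fs", "p.P151fs", "p.S166fs",
               "p.P27fs", "p.A39fs", "p.T102fs", "p.V122fs", "p.C141fs",
               "p.P177fs", "p.H193fs", "p.E204fs", "p.V97fs", "p.L130fs",
               "p.K139fs"),
  indel_cy = c("p.F270fs*25", "p.L265fs*30"),
  indel_wt = c("p.T256fs*90", "p.D259fs*86", "p.S261fs*23", "p.G262fs*60"),
  splicing_oe = c("c.672+1G>A", "c.673-1G>A"),
  splicing_ca = c("c.356-2delA", "c.96+1G>A", "c.97-1G>A", "c.375+1G>A",
                  "c.376-1G>A", "c.559+1G>A", "c.560-1G>A", "c.782+1G>A",
                  "c.783-1G>A", "c.919+1G>A", "c.920-1G>A", "c.993+1G>A"),
  splicing_wt = c("c.994-1G>A", "c.1100+1G>A", "c.1101-1G>A"),
  unscored = c("p.R248W", "p.C176Y")
)

#' Expand the published contingency counts into a case-level cohort
#'
#' Deterministically expands [table4_counts()] into a 251-row synthetic
#' cohort table: the 249 scored cases of the contingency table plus the 2
#' non-assessable (unscored) cases that complete the 251 evaluable cases.
#' Each row carries a syntactically valid variant notation consistent with
#' its mutation-type column (hotspots at their published multiplicities:
#' 9 x R175H, 6 x Y220C, 5 x R273H, 4 x R196X; both cytoplasmic stopgains
#' are p.R306X; both in-frame indels are p.I255del). Histotype assignment
#' honours every determinable constraint: all cytoplasmic and all
#' WT-with-LOF cases are HGSOC, the 7 deleterious EC cases split 5
#' nonsynonymous + 2 indel, one EC no-detectable-mutation case carries the
#' synonymous p.P72P. The same table ships as
#' `inst/extdata/table4_cohort.csv`.
#'
#' @return A tibble with columns `case_id`, `histotype`, `variant`,
#'   `pattern_m1`.
#' @export
table4_cohort <- function() {
  fv <- .fixture_variants
  n_nonsyn_oe <- 115L
  nonsyn <- c(fv$nonsyn_hotspots,
              rep(fv$nonsyn_pool, length.out = n_nonsyn_oe - length(fv$nonsyn_hotspots)))

  block <- function(variant, pattern, histotype) {
    tibble::tibble(histotype = histotype, variant = variant, pattern_m1 = pattern)
  }

  rows <- dplyr::bind_rows(
    # OE row of the contingency table
    block(nonsyn[1:110], "OE", "HGSOC"),
    block(nonsyn[111:115], "OE", "EC"),
    block(fv$indel_oe, "OE", "HGSOC"),
    block(fv$stopgain_oe, "OE", "HGSOC"),
    block(fv$splicing_oe, "OE", "HGSOC"),
    # CA row
    block(fv$indel_ca[1:14], "CA", "HGSOC"),
    block(fv$indel_ca[15:16], "CA", "EC"),
    block(fv$stopgain_ca, "CA", "HGSOC"),
    block(fv$splicing_ca, "CA", "HGSOC"),
    # CY row (all HGSOC)
    block(fv$indel_cy, "CY", "HGSOC"),
    block(fv$stopgain_cy, "CY", "HGSOC"),
    # WT row; the 7 WT-with-LOF cases are HGSOC
    block(fv$indel_wt, "WT", "HGSOC"),
    block(fv$splicing_wt, "WT", "HGSOC"),
    block(rep("NDM", 3), "WT", "HGSOC"),
    block(c("p.P72P", rep("NDM", 72)), "WT", "EC"),
    # the 2 non-assessable cases completing the 251 evaluable
    block(fv$unscored, "unscored", "HGSOC")
  )
  tibble::tibble(case_id = sprintf("case_%03d", seq_len(nrow(rows))), rows)
}
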