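# method-1 conditional staining distributions P(pattern | mutation type),
# taken from the revised contingency-table column proportions
.method1_conditionals <- function() {
  tab <- table4_counts()
  cond <- apply(tab, 2, function(col) col / sum(col))
  # rows: OE CA CY WT ; columns: mutation types
  lapply(as.data.frame(cond), function(p) stats::setNames(p, rownames(tab)))
}

# weaker-staining assays read some WT as CA and some OE as WT; applied as
# probability-mass shifts on the method-1 conditionals
.perturb_conditional <- function(cond, wt_to_ca, oe_to_wt) {
  lapply(cond, function(p) {
    moved_wt <- p["WT"] * wt_to_ca
    moved_oe <- p["OE"] * oe_to_wt
    p["WT"] <- p["WT"] - moved_wt + moved_oe
    p["CA"] <- p["CA"] + moved_wt
    p["OE"] <- p["OE"] - moved_oe
    p
  })
}

#' Default synthetic-cohort parameters
#'
#' Parameters emulating the statistical structure of the study cohort:
#' 171 HGSOC and 80 EC cases; deleterious-mutation prevalence 169/171
#' (HGSOC) and 7/80 (EC); GOF:LOF mix 112:57 given a mutated HGSOC and
#' 5:2 given a mutated EC; LOF subtype weights 24:17:17
#' (indel:stopgain:splicing) with 2/24 of indels in-frame; substitution
#' hotspots R175H (weight 9), Y220C (6), R273H (5) and stopgain hotspot
#' R196X (4), remaining weight uniform over DNA-binding-domain codons;
#' method-1 conditional staining distributions equal to the revised
#' contingency-table column proportions; methods 2-4 are perturbed copies
#' with progressively inflated WT-to-CA and OE-to-WT confusion; a small
#' non-assessable (unscored) core rate of 2/251.
#'
#' @param n_hgsoc,n_ec Cohort sizes per histotype.
#' @param seed Optional integer seed; [simulate_cohort()] is deterministic
#'   given the seed.
#' @return A `p53_sim_params` list.
#' @export
cohort_params <- function(n_hgsoc = 171, n_ec = 80, seed = NULL) {
  m1 <- .method1_conditionals()
  params <- structure(list(
    n_hgsoc = as.integer(n_hgsoc),
    n_ec = as.integer(n_ec),
    mutation_prevalence = c(HGSOC = 169 / 171, EC = 7 / 80),
    class_mix = list(HGSOC = c(GOF = 112, LOF = 57) / 169,
                     EC = c(GOF = 5, LOF = 2) / 7),
    lof_type_weights = c(indel = 24, stopgain = 17, splicing = 17) / 58,
    indel_inframe_share = 2 / 24,
    hotspot_weights = list(
      nonsynonymous = c(R175H = 9, Y220C = 6, R273H = 5, other = 95) / 115,
      stopgain = c(R196X = 4, other = 13) / 17
    ),
    staining_conditional = list(
      `1` = m1,
      `2` = .perturb_conditional(m1, 0.05, 0.02),
      `3` = .perturb_conditional(m1, 0.12, 0.07),
      `4` = .perturb_conditional(m1, 0.20, 0.12)
    ),
    unscored_rate = 2 / 251,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "p53_sim_params")
  validate_params(params)
  params
}

#' Validate synthetic-cohort parameters
#'
#' Checks counts are positive, probabilities lie in \[0, 1\], and every
#' conditional staining distribution sums to 1 within 1e-9.
#'
#' @param params A `p53_sim_params`.
#' @return The params, invisibly; errors on invalid input.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "p53_sim_params"))
  ok <- function(cond, msg) if (!cond)
    rlang::abort(msg, class = "p53ihc_validation_error")
  ok(params$n_hgsoc > 0 && params$n_ec > 0, "cohort sizes must be positive")
  ok(all(params$mutation_prevalence >= 0 & params$mutation_prevalence <= 1),
     "mutation prevalences must be probabilities")
  for (mix in params$class_mix) {
    ok(abs(sum(mix) - 1) < 1e-9, "class mix must sum to 1")
  }
  ok(abs(sum(params$lof_type_weights) - 1) < 1e-9,
     "LOF subtype weights must sum to 1")
  for (method in params$staining_conditional) {
    for (p in method) {
      ok(all(p >= -1e-12), "staining probabilities must be non-negative")
      ok(abs(sum(p) - 1) < 1e-9, "staining conditionals must sum to 1")
    }
  }
  ok(params$unscored_rate >= 0 && params$unscored_rate <= 1,
     "unscored_rate must be a probability")
  invisible(params)
}

# random variant notation consistent with a drawn mutation type; residue
# letters at non-hotspot codons are random (syntactically valid, not
# sequence-accurate)
.draw_variant <- function(type, params, domains) {
  dbd <- domains$dbd
  rand_codon <- function() sample(dbd[1]:dbd[2], 1L)
  rand_aa <- function(exclude = NULL) sample(setdiff(AA1, exclude), 1L)
  switch(type,
    nonsynonymous = {
      w <- params$hotspot_weights$nonsynonymous
      pick <- sample(names(w), 1L, prob = w)
      if (pick != "other") {
        paste0("p.", pick)
      } else {
        ref <- rand_aa()
        paste0("p.", ref, rand_codon(), rand_aa(exclude = ref))
      }
    },
    stopgain = {
      w <- params$hotspot_weights$stopgain
      pick <- sample(names(w), 1L, prob = w)
      if (pick != "other") paste0("p.", pick)
      else paste0("p.", rand_aa(), rand_codon(), "X")
    },
    indel = {
      if (stats::runif(1) < params$indel_inframe_share) {
        paste0("p.", rand_aa(), rand_codon(), "del")
      } else {
        paste0("p.", rand_aa(), rand_codon(), "fs")
      }
    },
    splicing = {
      ex <- domains$cds_exons
      i <- sample(seq_len(nrow(ex) - 1L), 1L)  # internal junctions only
      if (stats::runif(1) < 0.5) {
        sprintf("c.%d+1G>A", ex$cds_end[i])
      } else {
        sprintf("c.%d-1G>A", ex$cds_start[i + 1L])
      }
    },
    NDM = "NDM"
  )
}

#' Simulate a cohort with the study's statistical structure
#'
#' Draws, per case: histotype (fixed counts), deleterious-mutation
#' presence (histotype prevalence), functional class (histotype class
#' mix), mutation subtype and a syntactically valid variant notation
#' (hotspot-weighted), then an observed staining pattern per assay method
#' from the conditional staining distributions, with a small probability
#' of an unscored (non-assessable) core. All draws derive from the single
#' seed in `params`; the same params give byte-identical tables.
#'
#' @param params A `p53_sim_params` from [cohort_params()].
#' @return A classified cohort tibble (columns `case_id`, `histotype`,
#'   `variant`, `pattern_m1`..`pattern_m4`, plus derived classification
#'   columns).
#' @examples
#' cohort <- simulate_cohort(cohort_params(seed = 1))
#' table(cohort$histotype, cohort$functional_class)
#' @export
simulate_cohort <- function(params = cohort_params()) {
  validate_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  domains <- tp53_domains()

  histotype <- c(rep("HGSOC", params$n_hgsoc), rep("EC", params$n_ec))
  n <- length(histotype)

  draw_case_type <- function(h) {
    if (stats::runif(1) >= params$mutation_prevalence[[h]]) return("NDM")
    cls <- sample(names(params$class_mix[[h]]), 1L,
                  prob = params$class_mix[[h]])
    if (cls == "GOF") "nonsynonymous"
    else sample(names(params$lof_type_weights), 1L,
                prob = params$lof_type_weights)
  }

  types <- vapply(histotype, draw_case_type, character(1), USE.NAMES = FALSE)
  variants <- vapply(types, .draw_variant, character(1), params = params,
                     domains = domains, USE.NAMES = FALSE)

  draw_pattern <- function(type, method) {
    if (stats::runif(1) < params$unscored_rate) return("unscored")
    p <- params$staining_conditional[[method]][[type]]
    sample(names(p), 1L, prob = p)
  }
  patterns <- lapply(c("1", "2", "3", "4"), function(m) {
    vapply(types, draw_pattern, character(1), method = m, USE.NAMES = FALSE)
  })

  cohort <- tibble::tibble(
    case_id = sprintf("sim_%04d", seq_len(n)),
    histotype = histotype,
    variant = variants,
    pattern_m1 = patterns[[1]],
    pattern_m2 = patterns[[2]],
    pattern_m3 = patterns[[3]],
    pattern_m4 = patterns[[4]]
  )
  classify_cohort(cohort)
}

#' Simulate a second rater for inter-observer agreement
#'
#' Takes the scored method observations of a cohort as rater A and
#' produces rater B by independently perturbing each label with the given
#' disagreement probability. Confusions are concentrated between the CA
#' and WT patterns (CA flips to WT and vice versa); OE and CY flip to WT.
#' Unscored cases are dropped from both lists.
#'
#' @param cohort A cohort tibble with the method's pattern column.
#' @param disagreement_rate Per-label perturbation probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @param method_id Assay method, 1 to 4.
#' @return A list with `rater_a` and `rater_b` (equal-length character
#'   vectors of scored patterns).
#' @export
simulate_rater_pair <- function(cohort, disagreement_rate, seed = NULL,
                                method_id = 1) {
  stopifnot(disagreement_rate >= 0, disagreement_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  pat <- cohort[[pattern_column(method_id)]]
  a <- pat[!is.na(pat) & pat != "unscored"]
  flip_to <- c(CA = "WT", WT = "CA", OE = "WT", CY = "WT")
  flip <- stats::runif(length(a)) < disagreement_rate
  b <- a
  b[flip] <- flip_to[a[flip]]
  list(rater_a = a, rater_b = b)
}
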