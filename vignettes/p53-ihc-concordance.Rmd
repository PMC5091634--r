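---
title: "p53 IHC as a predictor of TP53 mutation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{p53 IHC as a predictor of TP53 mutation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53ihc)
```

## The problem

p53 immunohistochemistry is the commonest clinical surrogate for *TP53*
mutation status in ovarian carcinoma. An optimized assay read against an
intrinsic control (stromal fibroblasts and lymphocytes on the same slide)
distinguishes four staining patterns: wild-type (WT, variable-intensity
nuclear staining), overexpression (OE, strong staining in essentially all
tumour nuclei), complete absence (CA, no tumour-nucleus staining with the
control intact), and cytoplasmic (CY, diffuse cytoplasmic staining
without strong nuclear staining). This package quantifies how well those
patterns predict the presence and functional class of a *TP53* mutation,
and explains the discordant cases mechanistically.

## Models and procedures

### Variant classification

Variants are parsed from HGVS protein or coding notation into a
structured form (kind, codon interval, residues) and mapped onto a
five-way mutation-type taxonomy — nonsynonymous, indel, stopgain,
splicing, synonymous/none — and from there onto the ternary functional
scheme: GOF for nonsynonymous, LOF for stopgain/indel/splicing, NDM for
absent or synonymous mutations. The mapping is a pure function of
mutation type, so it is total, deterministic, and exhaustively testable.

Two deliberate decouplings are worth flagging. First, in-frame indels are
class LOF under the definition above even though the staining predictor
expects them to stain OE (an in-frame deletion plausibly has the same
conformational, degradation-resistant effect as a nonsynonymous
substitution); an OE-staining in-frame indel is therefore an expected
class-discordant case, surfaced as such rather than silently re-labelled.
Second, cases carrying several variants are classified by a fixed
priority (stopgain > frameshift indel > splicing > in-frame indel >
nonsynonymous > synonymous), which is conservative toward LOF and
auditable; multi-hit cases keep a flag.

### Staining prediction

The predictor applies position rules tied to the biology of the DO-7
epitope (codons 19–26), nonsense-mediated decay (NMD), and the nuclear
localization signal (NLS, codons 316–325):

| rule | prediction | confidence |
|---|---|---|
| nonsynonymous substitution | OE | high |
| in-frame indel | OE | low |
| no / synonymous mutation | WT | high |
| premature stop before codon 213 | CA (NMD) | high |
| premature stop in 213–244 | CA | ambiguous |
| premature stop ≥ 245, length 292–306 | CY (NLS lost) | low |
| premature stop ≥ 245, other lengths | WT (truncated protein) | low |
| splicing | CA | low |

The 213–244 gap is genuinely unruled by the observations the rules come
from: CA is the majority stopgain outcome, so the gap predicts CA but at
`ambiguous` confidence, and ambiguous predictions never count as
discordance of record. CY is predicted only for expressed truncations
whose predicted length falls in 292–306 aa; longer NLS-lacking
truncations default to WT at low confidence, because WT staining has been
observed for truncations of similar length and no discriminating rule is
available. Splicing defaults to CA at low confidence — a usable default
with an explicit uncertainty channel — since aberrant transcripts mostly
fail to produce protein, though nearby splice mutations have been seen to
produce either CA or OE via alternative splice products.

Frameshift termination codons are taken from the HGVS `fs*N` suffix when
the notation carries one (`termination = start + N − 1`); a bare `fs`
uses the frameshift start codon as the earliest possible premature stop,
at low confidence with unknown product length. Deriving the true
frameshift stop would require reading the downstream coding sequence;
the suffix convention keeps the predictor self-contained and exact
whenever the annotation is complete. For the same reason coding-level
substitutions (`c.524G>A`) are translated to a codon
(`ceiling(position / 3)`) but not to residues, and are treated as
nonsynonymous — a synonymous change written at coding level cannot be
recognized without the nucleotide reference.

Intronic-offset coding notation within ±2 of an exon boundary
(`c.356-2delA`) is classified as splicing. The HGVS offset syntax anchors
itself to an exon boundary by construction, so the parser accepts any
such notation without validating the anchor against the packaged exon
table; offsets beyond the splice window are rejected as unsupported
rather than guessed at.

### Concordance analysis

Two classifiers are evaluated against sequencing as the reference:

- **binary** — abnormal staining (OE, CA or CY) predicts a deleterious
  mutation; WT predicts none. Unscored (non-assessable) cores are
  excluded.
- **ternary** — OE predicts GOF, CA predicts LOF, WT predicts NDM.
  CY cases cannot imply a class and are excluded along with unscored
  cores; exclusions are tallied, never dropped, and cells plus exclusions
  always sum to the cohort size.

Metrics are sensitivity, specificity, balanced accuracy (their mean,
reported per class one-vs-rest in ternary mode), and overall accuracy
with an exact Clopper–Pearson 95% binomial interval — the convention of
the classification toolkit this analysis ecosystem uses (the interval is
cross-checked against `caret::confusionMatrix` in the tests, and against
the Beta closed form). A zero denominator makes a metric `NA` with a
warning, never 0: degenerate cohorts must be visible. Comparisons with
printed two-decimal values use R's default half-even rounding.
Inter-rater agreement uses unweighted Cohen's kappa over the four-pattern
label set, cross-checked against `e1071::classAgreement`.

### Revision workflow

Discordant cases in practice trigger re-extraction, re-sequencing and
full-section restaining; the software only *books* the outcomes. Revision
records are external data (`case_id`, `field`, `old_value`, `new_value`,
`evidence`), each applied against a copy of the cohort only if its
`old_value` matches the current state — re-applying an already-booked set
fails loudly instead of double-applying. Derived classifications are
recomputed after booking, the audit log lists every change, and rows are
never created or destroyed.

## The synthetic generator

`cohort_params()` encodes the study conditions as defaults: 171 HGSOC and
80 EC cases; deleterious-mutation prevalence 169/171 and 7/80; GOF:LOF
mixes 112:57 and 5:2 given mutation; LOF subtype weights 24:17:17
(indel:stopgain:splicing) with 2/24 of indels in-frame; named hotspots
R175H (9), Y220C (6), R273H (5), R196X (4) with the remaining weight
uniform over DNA-binding-domain codons (102–292); method-1 conditional
staining distributions equal to the revised contingency-table column
proportions; and an unscored-core rate of 2/251. Methods 2–4 have no
numeric anchor in the published record beyond bar-plot shapes, so they
default to perturbed copies of method 1 with progressively inflated
WT→CA and OE→WT confusion (5/2%, 12/7%, 20/12%) — free parameters chosen
to reproduce the qualitative ordering that weaker assays misread WT as
CA. All draws derive from one integer seed.

What the generator emulates: histotype-conditional prevalence, class and
subtype mixture, hotspot multiplicity, conditional staining, and
non-assessable cores. What it does not: residue-level sequence accuracy
at non-hotspot codons (letters are random, notation valid), linkage
between a case's staining across methods (draws are conditionally
independent given mutation type), allelic fractions, and within-slide
heterogeneity. Passing tests therefore demonstrate that the *analysis*
machinery is correct under the study's statistical structure, not that
the generator reproduces any real cohort case-for-case.

The second-rater simulator copies the method observations and perturbs
each label independently at a given rate, concentrating confusions
between CA and WT (the pair real raters disagree on); at a 6%
disagreement rate over 148 cases the resulting kappa averages ≈0.9,
inside the "very good agreement" band.

## Packaged data

The published revised method-1 contingency table ships expanded to a
251-row case-level cohort (`table4_cohort()`,
`inst/extdata/table4_cohort.csv`): 249 scored rows matching the cell
counts exactly plus 2 unscored rows completing the evaluable cohort, so
the exclusion logic is exercised on read. Variant notations are
synthetic but consistent with each row's mutation-type column and
hotspot multiplicities; histotype assignment honours every determinable
constraint (all CY and all WT-with-LOF cases HGSOC; the 7 deleterious EC
cases split 5 nonsynonymous + 2 indel; one EC case carries the
synonymous p.P72P). One internal tension in the printed record is worth
noting: the contingency table's NDM column (76) exceeds the count
derivable from the printed prevalences (75); the packaged table follows
the contingency table and absorbs the extra NDM case into the HGSOC WT
row. Headline fractions (8.8% EC prevalence, 4.1% WT-with-LOF, 2.3% CY)
are computed from a separate printed-counts constant (`study_counts()`),
not from the expansion.

## Numerical and testing choices

- Problem sizes: the metric oracle-equivalence property runs 1,000
  random 60-case cohorts against a naive per-case loop; generator
  calibration runs one tenfold cohort (1,710 + 800) and accepts empirical
  conditionals within 2 binomial standard errors (plus a 3/n floor for
  near-degenerate cells); the independence check for kappa uses 20,000
  paired draws. These sizes give stable checks in seconds on one CPU.
- The codon sweep for stopgain monotonicity is exhaustive (1–393).
- Ties, degenerate inputs: empty cohorts produce all-zero matrices;
  zero-denominator metrics are `NA` with a warning; unknown pattern
  tokens and histotypes fail validation with line numbers; duplicate
  case identifiers are rejected.
- The canonical transcript is assumed to be the major 393-aa isoform;
  codon numbering against any other isoform is flagged by range errors
  rather than silently renumbered.

## Known limitations

Primary (pre-revision) per-method performance, the published
discordant-case list, the observed inter-rater table and the full
mutation spectrum require the study's per-case supplementary data, which
is not redistributable here; those analyses are exercised on synthetic
cohorts instead. The predictor models a strong DO-7 assay read against an
intrinsic control; weaker assays (modelled only statistically in the
generator) violate its OE/WT and CA/WT boundaries. CY prediction covers
the one mechanism with a position rule (NLS-truncating products of
292–306 aa); alternative cytoplasmic-retention mechanisms exist and are
not modelled.
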