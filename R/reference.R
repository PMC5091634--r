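#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# package-local cache for the reference fixture
the <- new.env(parent = emptyenv())

#' TP53 reference constants
#'
#' Returns the packaged reference map for the canonical 393-amino-acid p53
#' protein: domain intervals (transactivation domain, DNA-binding domain,
#' tetramerization domain, nuclear localization signal at codons 316-325,
#' DO-7 antibody epitope at codons 19-26), the position rules used by the
#' staining predictor (premature stop codons before codon 213 trigger
#' nonsense-mediated decay; stop codons from 245 onwards leave a detectable
#' truncated protein; truncations of 292-306 aa associate with cytoplasmic
#' staining), and the coding-exon boundaries of the major TP53 transcript.
#'
#' All intervals are 1-based and closed. The object is read once from the
#' packaged JSON fixture and cached; treat it as immutable.
#'
#' @return A list with elements `protein_length_aa`, `cds_length_nt`,
#'   `tad`, `dbd`, `tmd`, `nls`, `do7_epitope` (integer intervals of length
#'   2), `nmd_ca_max_codon`, `expressed_min_codon`, `cy_length_range`, and
#'   `cds_exons` (a tibble of exon coding coordinates).
#' @examples
#' tp53_domains()$nls
#' @export
tp53_domains <- function() {
  if (!is.null(the$domains)) {
    return(the$domains)
  }
  path <- system.file("extdata", "tp53_reference.json", package = "p53ihc",
                      mustWork = TRUE)
  ref <- jsonlite::read_json(path, simplifyVector = TRUE)
  dm <- list(
    protein_length_aa = as.integer(ref$protein_length_aa),
    cds_length_nt = as.integer(ref$cds_length_nt),
    tad = as.integer(ref$domains$tad),
    dbd = as.integer(ref$domains$dbd),
    tmd = as.integer(ref$domains$tmd),
    nls = as.integer(ref$domains$nls),
    do7_epitope = as.integer(ref$domains$do7_epitope),
    nmd_ca_max_codon = as.integer(ref$rules$nmd_ca_max_codon),
    expressed_min_codon = as.integer(ref$rules$expressed_min_codon),
    cy_length_range = as.integer(ref$rules$cy_length_range),
    cds_exons = tibble::as_tibble(ref$cds_exons)
  )
  stopifnot(
    dm$nmd_ca_max_codon < dm$expressed_min_codon,
    dm$cy_length_range[2] < dm$nls[1],
    all(vapply(dm[c("tad", "dbd", "tmd", "nls", "do7_epitope")],
               function(iv) iv[1] >= 1 && iv[2] <= dm$protein_length_aa &&
                 iv[1] <= iv[2], logical(1)))
  )
  the$domains <- dm
  dm
}

# amino-acid code tables ------------------------------------------------

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V", Ter = "*")

# regex alternation matching one residue token (three-letter, one-letter,
# or a stop symbol); X counts as stop in the dialect used here
.aa_rx <- paste0("(?:", paste(names(AA3), collapse = "|"),
                 "|[", paste(AA1, collapse = ""), "]|X|\\*)")

# normalize a residue token to one-letter code ("*" for stop)
aa_norm <- function(tok) {
  if (is.na(tok) || tok == "") return(NA_character_)
  if (tok %in% c("*", "X", "x", "Ter")) return("*")
  if (nchar(tok) == 1L) {
    up <- toupper(tok)
    if (up %in% AA1) return(up)
  }
  if (tok %in% names(AA3)) return(unname(AA3[tok]))
  abort(sprintf("unrecognized amino-acid token '%s'", tok),
        class = "p53ihc_parse_error")
}

# normalize a residue *sequence* token (e.g. the inserted residues of an
# ins/delins), accepting either a run of one-letter codes or a
# concatenation of three-letter codes
aa_seq_norm <- function(tok) {
  if (is.na(tok) || tok == "") return(NA_character_)
  if (grepl(sprintf("^(%s)+$", paste(names(AA3), collapse = "|")), tok)) {
    parts <- regmatches(tok, gregexpr(paste(names(AA3), collapse = "|"), tok))[[1]]
    return(paste(vapply(parts, aa_norm, character(1)), collapse = ""))
  }
  up <- toupper(tok)
  if (grepl(sprintf("^[%sX*]+$", paste(AA1, collapse = "")), up)) {
    return(gsub("X", "*", up, fixed = TRUE))
  }
  abort(sprintf("unrecognized residue sequence '%s'", tok),
        class = "p53ihc_parse_error")
}

# variant constructor ----------------------------------------------------

new_variant <- function(raw, kind, codon_start = NA_integer_,
                        codon_end = NA_integer_, ref_aa = NA_character_,
                        alt_aa = NA_character_,
                        termination_codon = NA_integer_) {
  if (!is.na(codon_start) && !is.na(codon_end) && codon_start > codon_end) {
    abort("codon_start must not exceed codon_end", class = "p53ihc_parse_error")
  }
  structure(
    list(raw = raw, kind = kind,
         codon_start = as.integer(codon_start),
         codon_end = as.integer(codon_end),
         ref_aa = ref_aa, alt_aa = alt_aa,
         termination_codon = as.integer(termination_codon)),
    class = "p53_variant"
  )
}

#' @export
print.p53_variant <- function(x, ...) {
  cat("<p53_variant> ", format_variant(x), "  [", x$kind, "]\n", sep = "")
  invisible(x)
}

check_codon_range <- function(codon, raw) {
  plen <- tp53_domains()$protein_length_aa
  bad <- codon[!is.na(codon) & (codon < 1L | codon > plen)]
  if (length(bad)) {
    abort(sprintf("codon %d in '%s' is outside [1, %d]", bad[1], raw, plen),
          class = "p53ihc_range_error")
  }
  invisible(codon)
}

#' Parse a protein-level HGVS variant
#'
#' Parses TP53 protein variant notation into a structured variant. The
#' accepted dialect covers the forms mixed freely in clinical reports:
#' one-letter or three-letter amino-acid codes; `X`, `*` or `Ter` for a stop
#' codon; substitutions (`p.R175H`), stopgains (`p.R196X`), synonymous
#' changes (`p.R175R` or `p.R175=`), in-frame deletions with an optional
#' trailing length digit (`p.I255del`, `p.I255del1`, `p.I255_K256del`),
#' duplications and insertions (`p.I255dup`, `p.S260_G261insA`), delins
#' (`p.R175delinsGQ`), and frameshifts with an optional new-stop suffix
#' (`p.K382fs`, `p.Q192fs*12`, `p.Lys382Asnfs*40`). The `p.` prefix is
#' optional and case-insensitive. Residues are normalized to one-letter
#' codes with `*` for stop.
#'
#' @param notation A single variant string.
#' @return A `p53_variant`: list with `raw`, `kind` (one of `substitution`,
#'   `stopgain`, `deletion_inframe`, `insertion_inframe`, `frameshift`,
#'   `splicing`, `synonymous`, `none`), `codon_start`, `codon_end`,
#'   `ref_aa`, `alt_aa` and, for frameshifts carrying an `fs*N` suffix,
#'   `termination_codon` (the codon of the new stop, `start + N - 1`).
#' @examples
#' parse_protein_variant("p.R175H")
#' parse_protein_variant("p.Arg196Ter")
#' parse_protein_variant("p.I255del1")
#' @export
parse_protein_variant <- function(notation) {
  stopifnot(is.character(notation), length(notation) == 1L, !is.na(notation))
  raw <- trimws(notation)
  if (raw == "") abort("empty variant string", class = "p53ihc_parse_error")
  body <- sub("^[pP]\\.", "", raw)
  a <- .aa_rx

  m <- function(rx) {
    mm <- regmatches(body, regexec(rx, body, perl = TRUE))[[1]]
    if (length(mm)) mm else NULL
  }

  # frameshift: p.K382fs, p.K382Nfs*40, p.Lys382Asnfs (fsTer40 also seen)
  g <- m(sprintf("^(%s)(\\d+)(%s)?fs(?:(?:\\*|Ter)(\\d+))?$", a, a))
  if (!is.null(g)) {
    codon <- as.integer(g[3])
    check_codon_range(codon, raw)
    term <- if (g[5] != "") codon + as.integer(g[5]) - 1L else NA_integer_
    return(new_variant(raw, "frameshift", codon, codon,
                       aa_norm(g[2]), if (g[4] != "") aa_norm(g[4]) else NA_character_,
                       term))
  }

  # substitution / stopgain / synonymous: p.R175H, p.R196X, p.R175=, p.R175R
  g <- m(sprintf("^(%s)(\\d+)(=|%s)$", a, a))
  if (!is.null(g)) {
    codon <- as.integer(g[3])
    check_codon_range(codon, raw)
    ref <- aa_norm(g[2])
    alt <- if (g[4] == "=") ref else aa_norm(g[4])
    kind <- if (alt == "*") "stopgain" else if (identical(ref, alt)) "synonymous" else "substitution"
    return(new_variant(raw, kind, codon, codon, ref, alt))
  }

  # delins: p.R175delinsGQ, p.A161_S162delinsT
  g <- m(sprintf("^(%s)(\\d+)(?:_(%s)(\\d+))?delins([A-Za-z*]+)$", a, a))
  if (!is.null(g)) {
    cs <- as.integer(g[3])
    ce <- if (g[5] != "") as.integer(g[5]) else cs
    check_codon_range(c(cs, ce), raw)
    return(new_variant(raw, "deletion_inframe", cs, ce,
                       paste0(aa_norm(g[2]), if (g[4] != "") aa_norm(g[4]) else ""),
                       aa_seq_norm(g[6])))
  }

  # in-frame deletion, optional trailing length digit (clinical shorthand
  # "I255del1"): p.I255del, p.I255_K256del
  g <- m(sprintf("^(%s)(\\d+)(?:_(%s)(\\d+))?del\\d*$", a, a))
  if (!is.null(g)) {
    cs <- as.integer(g[3])
    ce <- if (g[5] != "") as.integer(g[5]) else cs
    check_codon_range(c(cs, ce), raw)
    return(new_variant(raw, "deletion_inframe", cs, ce,
                       paste0(aa_norm(g[2]), if (g[4] != "") aa_norm(g[4]) else ""),
                       NA_character_))
  }

  # duplication: p.I255dup, p.S260_G261dup
  g <- m(sprintf("^(%s)(\\d+)(?:_(%s)(\\d+))?dup$", a, a))
  if (!is.null(g)) {
    cs <- as.integer(g[3])
    ce <- if (g[5] != "") as.integer(g[5]) else cs
    check_codon_range(c(cs, ce), raw)
    ref <- paste0(aa_norm(g[2]), if (g[4] != "") aa_norm(g[4]) else "")
    return(new_variant(raw, "insertion_inframe", cs, ce, ref, ref))
  }

  # insertion: p.S260_G261insAL
  g <- m(sprintf("^(%s)(\\d+)_(%s)(\\d+)ins([A-Za-z*]+)$", a, a))
  if (!is.null(g)) {
    cs <- as.integer(g[3]); ce <- as.integer(g[5])
    check_codon_range(c(cs, ce), raw)
    return(new_variant(raw, "insertion_inframe", cs, ce,
                       paste0(aa_norm(g[2]), aa_norm(g[4])),
                       aa_seq_norm(g[6])))
  }

  abort(sprintf("cannot parse protein variant notation '%s'", raw),
        class = "p53ihc_parse_error")
}

#' Parse a coding-level HGVS variant
#'
#' Parses TP53 coding (c.) notation. Intronic offsets of at most 2
#' nucleotides from an exon boundary (the HGVS `+1/+2/-1/-2` splice-site
#' syntax, e.g. `c.356-2delA`) classify the variant as `splicing`; deeper
#' intronic offsets are rejected as unsupported. Exonic positions are
#' translated to codons as `ceiling(cds_position / 3)` against the packaged
#' canonical TP53 coding coordinates. Deletions, insertions, duplications
#' and delins are assigned in-frame or frameshift kinds from the net length
#' change modulo 3. Amino-acid identities are not inferred from nucleotide
#' changes (the reference nucleotide sequence is not consulted), so coding
#' substitutions carry `NA` residues and are treated as nonsynonymous
#' downstream.
#'
#' @param notation A single `c.` variant string.
#' @return A `p53_variant` (see [parse_protein_variant()]).
#' @examples
#' parse_coding_variant("c.356-2delA")
#' parse_coding_variant("c.524G>A")  # codon 175
#' @export
parse_coding_variant <- function(notation) {
  stopifnot(is.character(notation), length(notation) == 1L, !is.na(notation))
  raw <- trimws(notation)
  body <- sub("^[cC]\\.", "", raw)
  if (body == raw) {
    abort(sprintf("not coding notation (missing 'c.' prefix): '%s'", raw),
          class = "p53ihc_parse_error")
  }

  pos_rx <- "(\\d+)([+-]\\d+)?"
  g <- regmatches(body, regexec(
    sprintf("^%s(?:_%s)?(.*)$", pos_rx, pos_rx), body, perl = TRUE))[[1]]
  if (!length(g) || g[2] == "") {
    abort(sprintf("cannot parse coding variant notation '%s'", raw),
          class = "p53ihc_parse_error")
  }
  p1 <- as.integer(g[2]); off1 <- if (g[3] != "") as.integer(g[3]) else 0L
  p2 <- if (g[4] != "") as.integer(g[4]) else NA_integer_
  off2 <- if (g[5] != "") as.integer(g[5]) else 0L
  change <- g[6]

  cds_len <- tp53_domains()$cds_length_nt
  for (p in c(p1, p2)) {
    if (!is.na(p)) {
      if (p < 1L) abort(sprintf("coding positions are 1-based: '%s'", raw),
                        class = "p53ihc_parse_error")
      if (p > cds_len) abort(
        sprintf("coding position %d in '%s' is outside [1, %d]", p, raw, cds_len),
        class = "p53ihc_range_error")
    }
  }

  # intronic offset: HGVS syntax anchors these to an exon boundary by
  # construction; within the 2-nt splice window -> splicing
  if (off1 != 0L || off2 != 0L) {
    if (all(abs(c(off1, off2)) <= 2L)) {
      return(new_variant(raw, "splicing"))
    }
    abort(sprintf("intronic offset beyond the +/-2 splice window in '%s'", raw),
          class = "p53ihc_unsupported_error")
  }

  codon_of <- function(p) {
    cd <- as.integer(ceiling(p / 3))
    if (cd > tp53_domains()$protein_length_aa) {
      abort(sprintf("'%s' affects the translation stop codon; unsupported", raw),
            class = "p53ihc_unsupported_error")
    }
    cd
  }

  # substitution: c.524G>A
  if (grepl("^[ACGT]>[ACGT]$", change)) {
    cd <- codon_of(p1)
    return(new_variant(raw, "substitution", cd, cd))
  }

  # del / dup / ins / delins with nucleotide payloads
  h <- regmatches(change, regexec(
    "^(delins|del|dup|ins)([ACGT]*)(?:ins([ACGT]+))?$", change, perl = TRUE))[[1]]
  if (length(h)) {
    op <- h[2]; seq1 <- h[3]; seq2 <- h[4]
    span <- if (!is.na(p2)) p2 - p1 + 1L else max(1L, nchar(seq1))
    net <- switch(op,
      del = if (seq2 != "") nchar(seq2) - span else -span,  # delAinsTT form
      dup = span,
      ins = nchar(seq1),
      delins = nchar(seq1) - span
    )
    if (op == "del" && seq2 != "") op <- "delins"
    cs <- codon_of(p1)
    ce <- if (!is.na(p2)) codon_of(p2) else cs
    if (net %% 3L != 0L) {
      return(new_variant(raw, "frameshift", cs, cs))
    }
    kind <- if (net < 0L || op == "delins") "deletion_inframe" else "insertion_inframe"
    if (net == 0L && op == "delins") kind <- "deletion_inframe"
    return(new_variant(raw, kind, cs, ce))
  }

  abort(sprintf("cannot parse coding variant notation '%s'", raw),
        class = "p53ihc_parse_error")
}

#' Parse any variant notation
#'
#' Dispatches on prefix: `"NDM"`, `""` or `NA` mean no detectable mutation;
#' `c.`-prefixed strings go to [parse_coding_variant()]; everything else to
#' [parse_protein_variant()]. Multiple variants for one case may be given
#' separated by `;` — a list is returned in that case.
#'
#' @param notation Variant string (or `;`-separated strings).
#' @return A `p53_variant`, or a list of them for `;`-separated input.
#' @export
parse_variant <- function(notation) {
  if (length(notation) != 1L || is.na(notation) ||
      trimws(notation) %in% c("", "NDM", "ndm", "none")) {
    return(new_variant(if (length(notation) == 1L && !is.na(notation))
      notation else "NDM", "none"))
  }
  parts <- trimws(strsplit(notation, ";", fixed = TRUE)[[1]])
  parts <- parts[parts != ""]
  one <- function(x) {
    if (grepl("^[cC]\\.", x)) parse_coding_variant(x) else parse_protein_variant(x)
  }
  if (length(parts) == 1L) one(parts) else lapply(parts, one)
}

#' Format a variant back to normalized HGVS notation
#'
#' Emits the canonical one-letter-code form of a parsed variant (stop as
#' `*`); splicing variants are printed in their original coding notation.
#' Round-trips with the parsers: `parse_variant(format_variant(v))`
#' reproduces `v`'s structured fields.
#'
#' @param v A `p53_variant`.
#' @return A single string.
#' @export
format_variant <- function(v) {
  stopifnot(inherits(v, "p53_variant"))
  switch(v$kind,
    none = "NDM",
    splicing = v$raw,
    substitution = ,
    stopgain = ,
    synonymous = {
      if (is.na(v$ref_aa)) v$raw
      else paste0("p.", v$ref_aa, v$codon_start, v$alt_aa)
    },
    frameshift = {
      suffix <- if (!is.na(v$termination_codon))
        paste0("*", v$termination_codon - v$codon_start + 1L) else ""
      alt <- if (!is.na(v$alt_aa)) v$alt_aa else ""
      paste0("p.", v$ref_aa, v$codon_start, alt, "fs", suffix)
    },
    deletion_inframe = {
      if (is.na(v$ref_aa)) return(v$raw)
      left <- paste0(substr(v$ref_aa, 1, 1), v$codon_start)
      right <- if (v$codon_end > v$codon_start)
        paste0("_", substr(v$ref_aa, 2, 2), v$codon_end) else ""
      tail <- if (!is.na(v$alt_aa)) paste0("delins", v$alt_aa) else "del"
      paste0("p.", left, right, tail)
    },
    insertion_inframe = {
      if (is.na(v$ref_aa)) return(v$raw)
      if (v$codon_start == v$codon_end && identical(v$ref_aa, v$alt_aa)) {
        paste0("p.", v$ref_aa, v$codon_start, "dup")
      } else if (identical(v$ref_aa, v$alt_aa)) {
        paste0("p.", substr(v$ref_aa, 1, 1), v$codon_start, "_",
               substr(v$ref_aa, 2, 2), v$codon_end, "dup")
      } else {
        paste0("p.", substr(v$ref_aa, 1, 1), v$codon_start, "_",
               substr(v$ref_aa, 2, 2), v$codon_end, "ins", v$alt_aa)
      }
    },
    abort(sprintf("unknown variant kind '%s'", v$kind))
  )
}
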