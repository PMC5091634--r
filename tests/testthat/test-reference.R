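test_that("domain map carries the canonical p53 constants and invariants", {
  dm <- tp53_domains()
  expect_equal(dm$protein_length_aa, 393L)
  expect_equal(dm$nls, c(316L, 325L))
  expect_equal(dm$do7_epitope, c(19L, 26L))
  expect_equal(dm$nmd_ca_max_codon, 213L)
  expect_equal(dm$expressed_min_codon, 245L)
  expect_equal(dm$cy_length_range, c(292L, 306L))
  expect_lt(dm$nmd_ca_max_codon, dm$expressed_min_codon)
  expect_lt(dm$cy_length_range[2], dm$nls[1])
  for (iv in dm[c("tad", "dbd", "tmd", "nls", "do7_epitope")]) {
    expect_true(iv[1] >= 1 && iv[2] <= 393 && iv[1] <= iv[2])
  }
  # exon coding coordinates tile the CDS without gaps
  ex <- dm$cds_exons
  expect_equal(ex$cds_start[1], 1L)
  expect_equal(ex$cds_end[nrow(ex)], dm$cds_length_nt)
  expect_true(all(ex$cds_start[-1] == ex$cds_end[-nrow(ex)] + 1L))
})

test_that("protein parser handles the dialect mixed in clinical reports", {
  v <- parse_protein_variant("p.R175H")
  expect_equal(v$kind, "substitution")
  expect_equal(v$codon_start, 175L)
  expect_equal(v$ref_aa, "R")
  expect_equal(v$alt_aa, "H")

  # three-letter and prefix variations parse to the same structure
  for (form in c("p.Arg175His", "P.R175H", "R175H")) {
    w <- parse_protein_variant(form)
    expect_equal(w[c("kind", "codon_start", "ref_aa", "alt_aa")],
                 v[c("kind", "codon_start", "ref_aa", "alt_aa")])
  }

  # stopgain spellings: X, *, Ter
  for (form in c("p.R196X", "p.R196*", "p.Arg196Ter")) {
    s <- parse_protein_variant(form)
    expect_equal(s$kind, "stopgain")
    expect_equal(s$codon_start, 196L)
    expect_equal(s$alt_aa, "*")
  }

  # in-frame deletion, with and without the trailing length digit
  for (form in c("p.I255del", "p.I255del1")) {
    d <- parse_protein_variant(form)
    expect_equal(d$kind, "deletion_inframe")
    expect_equal(d$codon_start, 255L)
  }

  fs <- parse_protein_variant("p.K382fs")
  expect_equal(fs$kind, "frameshift")
  expect_true(is.na(fs$termination_codon))
  fs2 <- parse_protein_variant("p.Q192fs*12")
  expect_equal(fs2$termination_codon, 203L)
  fs3 <- parse_protein_variant("p.Lys382Asnfs*40")
  expect_equal(fs3$codon_start, 382L)
  expect_equal(fs3$alt_aa, "N")

  expect_equal(parse_protein_variant("p.R175R")$kind, "synonymous")
  expect_equal(parse_protein_variant("p.R175=")$kind, "synonymous")
  expect_equal(parse_protein_variant("p.R175=")$alt_aa, "R")

  expect_equal(parse_protein_variant("p.I255dup")$kind, "insertion_inframe")
})

test_that("protein parser rejects out-of-range and malformed input", {
  expect_error(parse_protein_variant("p.Q999X"), class = "p53ihc_range_error")
  expect_error(parse_protein_variant("p.R0H"), class = "p53ihc_range_error")
  expect_error(parse_protein_variant("p.garbage"),
               class = "p53ihc_parse_error", regexp = "garbage")
  expect_error(parse_protein_variant(""), class = "p53ihc_parse_error")
})

test_that("coding parser maps splice-window offsets and exonic codons", {
  expect_equal(parse_coding_variant("c.356-2delA")$kind, "splicing")
  expect_equal(parse_coding_variant("c.672+1G>A")$kind, "splicing")

  sub <- parse_coding_variant("c.524G>A")
  expect_equal(sub$kind, "substitution")
  expect_equal(sub$codon_start, 175L)  # ceiling(524 / 3)
  expect_equal(parse_coding_variant("c.215C>G")$codon_start, 72L)

  # frame of coding indels from net length change
  expect_equal(parse_coding_variant("c.100_102del")$kind, "deletion_inframe")
  expect_equal(parse_coding_variant("c.100_103del")$kind, "frameshift")
  expect_equal(parse_coding_variant("c.100delA")$kind, "frameshift")

  expect_error(parse_coding_variant("c.0A>T"), class = "p53ihc_parse_error")
  expect_error(parse_coding_variant("c.5000G>A"), class = "p53ihc_range_error")
  expect_error(parse_coding_variant("c.100+5G>A"),
               class = "p53ihc_unsupported_error")
  expect_error(parse_coding_variant("p.R175H"), class = "p53ihc_parse_error")
})

test_that("formatting a parsed variant round-trips through the parser", {
  dialect <- c("p.R175H", "p.Arg175His", "p.R196X", "p.Arg196Ter", "p.R196*",
               "p.I255del", "p.I255del1", "p.I255dup", "p.K382fs",
               "p.Q192fs*12", "p.Lys382Asnfs*40", "p.R175R", "p.R175=",
               "p.A161_S162delinsT", "c.356-2delA", "c.672+1G>A", "NDM")
  for (notation in dialect) {
    v1 <- select_primary_variant(parse_variant(notation))
    v2 <- select_primary_variant(parse_variant(format_variant(v1)))
    expect_equal(v2[setdiff(names(v2), "raw")],
                 v1[setdiff(names(v1), "raw")], info = notation)
  }
})

test_that("parsing is deterministic and emitted codons stay in range", {
  notations <- c("p.R175H", "p.R196X", "p.K382fs", "p.I255del", "c.524G>A",
                 "c.1179G>A")
  for (notation in notations) {
    a <- parse_variant(notation)
    b <- parse_variant(notation)
    expect_identical(a, b)
    for (cd in c(a$codon_start, a$codon_end)) {
      if (!is.na(cd)) expect_true(cd >= 1 && cd <= 393)
    }
  }
})

test_that("multi-variant notation yields a list and NDM markers parse to none", {
  v <- parse_variant("p.R175H;p.R196X")
  expect_length(v, 2L)
  expect_equal(v[[2]]$kind, "stopgain")
  expect_equal(parse_variant("NDM")$kind, "none")
  expect_equal(parse_variant(NA_character_)$kind, "none")
})
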