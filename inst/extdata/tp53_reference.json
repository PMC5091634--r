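{
  "protein": "TP53 (cellular tumour antigen p53), canonical 393-aa isoform",
  "transcript": "major TP53 transcript (NM_000546.5 / ENST00000269305 exon structure)",
  "protein_length_aa": 393,
  "cds_length_nt": 1182,
  "domains": {
    "tad": [1, 42],
    "dbd": [102, 292],
    "tmd": [323, 356],
    "nls": [316, 325],
    "do7_epitope": [19, 26]
  },
  "rules": {
    "nmd_ca_max_codon": 213,
    "expressed_min_codon": 245,
    "cy_length_range": [292, 306]
  },
  "cds_exons": [
    {"exon": 2, "cds_start": 1, "cds_end": 74},
    {"exon": 3, "cds_start": 75, "cds_end": 96},
    {"exon": 4, "cds_start": 97, "cds_end": 375},
    {"exon": 5, "cds_start": 376, "cds_end": 559},
    {"exon": 6, "cds_start": 560, "cds_end": 672},
    {"exon": 7, "cds_start": 673, "cds_end": 782},
    {"exon": 8, "cds_start": 783, "cds_end": 919},
    {"exon": 9, "cds_start": 920, "cds_end": 993},
    {"exon": 10, "cds_start": 994, "cds_end": 1100},
    {"exon": 11, "cds_start": 1101, "cds_end": 1182}
  ]
}
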