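Package: pepverify
Title: Targeted Peptide Verification and Sense-Antisense Co-Evolution
    Analysis for Single-ORF Retrotransposon-Like Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to verify that a long open reading frame is expressed as
    a full-length protein and to characterise the evolutionary constraints
    imposed on it by overlapping antisense microRNA.  Implements in-silico
    tryptic digestion with monoisotopic and average peptide masses, b/y
    fragment-ion ladders and multiple-reaction-monitoring transition design,
    tolerance-based matching of observed peptide masses with sequence
    coverage; efficiency-corrected mean normalized expression (MNE) for
    qRT-PCR with genotype contrasts; Nei-Gojobori (1986) counting of
    synonymous and nonsynonymous substitutions with a region-specific dN
    over gene-wide dS statistic for antisense-miRNA footprints and an
    alignment conservation profile; and Lupas COILS sliding-window
    coiled-coil propensity with a 14-residue window.  A seeded synthetic
    data generator produces inputs with the statistical structure each
    analysis assumes, and a pipeline runner chains all stages into a
    reproducible report.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
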