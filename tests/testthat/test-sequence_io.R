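test_that("read_fasta parses, normalises case, and preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "miep", ">p2", "GG", "GA"), f)
  recs <- read_fasta(f, type = "protein")
  expect_length(recs, 2)
  expect_equal(recs[[1]]$id, "p1")
  expect_equal(recs[[1]]$sequence, "MIEP")
  expect_equal(recs[[2]]$sequence, "GGGA")
})

test_that("read_fasta reports malformed input with the line number", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MIEP"), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(c(">p1", "MIEP", ">", "GG"), f)
  expect_error(read_fasta(f), "line 3")
  writeLines(c(">p1", ">p2", "GG"), f)
  expect_error(read_fasta(f), "empty sequence")
  writeLines(c(">a", "AC-G"), f)
  expect_error(read_fasta(f), "gap")
})

test_that("fasta round trip preserves records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  p <- protein_record("x", strrep("MIEPQ", 30))
  write_fasta(p, f)
  back <- read_fasta(f, type = "protein")
  expect_equal(back[[1]]$sequence, p$sequence)
})

test_that("translate_orf applies the standard code and strips the stop", {
  expect_equal(translate_orf(cds_record("t", "ATGGGTTAA"))$sequence, "MG")
  expect_error(translate_orf(cds_record("t", "ATGTAAGGG")),
               "internal stop at codon 2")
  expect_warning(translate_orf(cds_record("t", "GGGTAA")), "ATG")
  # ambiguous codons become X and survive translation
  expect_equal(suppressWarnings(
    translate_orf(cds_record("t", "ATGANTTAA"))$sequence), "MX")
})

test_that("a 3999 nt ORF translates to 1332 residues", {
  set.seed(11)
  body <- random_sense_codons(1332)
  body[1] <- "ATG"
  cds <- cds_record("orf3999", paste(c(body, "TAA"), collapse = ""))
  expect_equal(nchar(cds$sequence), 3999)
  prot <- translate_orf(cds)
  expect_equal(nchar(prot$sequence), 1332)
  # cross-check against the Biostrings translation oracle
  oracle <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds$sequence)))
  expect_equal(prot$sequence, sub("\\*$", "", oracle))
})

test_that("translation is invariant under double reverse-complement", {
  set.seed(12)
  cds <- cds_record("t", paste(c("ATG", random_sense_codons(50), "TGA"),
                               collapse = ""))
  rc2 <- cds_record("t", reverse_complement(reverse_complement(cds$sequence)))
  expect_equal(translate_orf(rc2)$sequence, translate_orf(cds)$sequence)
})

test_that("amplicon arithmetic reproduces the assay table", {
  pairs <- bundled_primer_pairs()
  names(pairs) <- vapply(pairs, `[[`, "", "name")
  expect_equal(amplicon_length(pairs$PEG11_PEG11as), 294)
  expect_equal(amplicon_length(pairs$PEG11as), 100)
  expect_equal(amplicon_length(pairs$rPEG11), 524)
  # inclusive counting gives 227 for the reference-gene row; the printed
  # 226 is off by one under the convention the other rows follow
  expect_equal(amplicon_length(pairs$RPLPO), 227)
})

test_that("amplicon length is symmetric and flags divergent primers", {
  p <- primer_pair("toy", fwd_start = 10, fwd_end = 12,
                   rev_start = 1, rev_end = 3)
  expect_equal(amplicon_length(p), 10)
  swapped <- primer_pair("toy", fwd_start = 1, fwd_end = 3,
                         rev_start = 10, rev_end = 12)
  expect_equal(amplicon_length(swapped), amplicon_length(p))
  div <- primer_pair("div", fwd_start = 100, fwd_end = 80,
                     rev_start = 120, rev_end = 140)
  expect_error(amplicon_length(div), "divergent")
})

test_that("primer tails are added and validated", {
  p <- primer_pair("t", fwd_seq = "AAAACCCC", rev_seq = "GGGGTTTT",
                   fwd_start = 100, fwd_end = 105, rev_start = 1,
                   rev_end = 6, fwd_tail = 2, rev_tail = 2)
  expect_equal(amplicon_length(p), 100 - 1 + 1 + 4)
  expect_error(primer_pair("t", fwd_seq = "AAAA", rev_seq = "GGGG",
                           fwd_start = 1, fwd_end = 4, rev_start = 10,
                           rev_end = 7, fwd_tail = 4),
               "tail")
})

test_that("antisense mapping handles both strands and round-trips", {
  anchor_minus <- genomic_interval("acc", 1001, 1100, "-")
  # full span maps to (1, length)
  expect_equal(unname(map_antisense_interval(
    genomic_interval("acc", 1001, 1100), anchor_minus)), c(1, 100))
  # a 21 nt interval at the high-coordinate genomic edge is the CDS 5' end
  expect_equal(unname(map_antisense_interval(
    genomic_interval("acc", 1080, 1100), anchor_minus)), c(1, 21))
  expect_error(map_antisense_interval(
    genomic_interval("acc", 900, 950), anchor_minus), "outside")

  set.seed(13)
  for (strand in c("+", "-")) {
    anchor <- genomic_interval("acc", 501, 2500, strand)
    for (i in 1:50) {
      s <- sample(501:2400, 1)
      e <- s + sample(0:99, 1)
      cds <- map_antisense_interval(genomic_interval("acc", s, e), anchor)
      back <- map_cds_to_genomic(cds[["cds_start"]], cds[["cds_end"]], anchor)
      expect_equal(c(back$start, back$end), c(s, e))
    }
  }
})

test_that("region files are read as 1-based inclusive intervals", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("acc\t10\t30\tmir-431", "acc\t50\t70\tmir-127"), f)
  df <- read_regions(f)
  expect_equal(df$start, c(10, 50))
  expect_equal(df$name, c("mir-431", "mir-127"))
  writeLines(c("acc\t30\t10\tbad"), f)
  expect_error(read_regions(f), "invalid")
})
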