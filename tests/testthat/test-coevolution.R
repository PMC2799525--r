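test_that("identical sequences give zero substitution counts", {
  s <- paste(c("ATG", "CCT", "GGA", "TTC"), collapse = "")
  cnt <- ng86_pairwise(s, s)
  expect_equal(cnt$Nd, 0)
  expect_equal(cnt$Sd, 0)
  expect_equal(cnt$dN, 0)
  expect_equal(cnt$dS, 0)
})

test_that("a Phe->Leu third-position change is nonsynonymous", {
  cnt <- ng86_pairwise("TTT", "TTA")
  expect_equal(cnt$Nd, 1)
  expect_equal(cnt$Sd, 0)
})

test_that("site counts always sum to three per compared codon", {
  set.seed(41)
  for (i in 1:20) {
    a <- random_sense_codons(30)
    b <- mutated_codons(a)
    cnt <- ng86_pairwise(a, b)
    expect_equal(cnt$N_sites + cnt$S_sites, 3 * cnt$codons_compared)
  }
})

test_that("pairwise counting is symmetric and skips gap/N codons", {
  set.seed(42)
  a <- random_sense_codons(40)
  b <- mutated_codons(a)
  ab <- ng86_pairwise(a, b)
  ba <- ng86_pairwise(b, a)
  expect_equal(ab$Nd, ba$Nd)
  expect_equal(ab$Sd, ba$Sd)
  expect_equal(ab$N_sites, ba$N_sites)
  a[5] <- "A-G"; b[9] <- "ANT"
  cnt <- ng86_pairwise(a, b)
  expect_equal(cnt$codons_compared, 38)
})

test_that("NG86 counting matches the pathway-enumeration oracle", {
  set.seed(43)
  for (i in 1:40) {
    a <- random_sense_codons(25)
    b <- mutated_codons(a)
    got <- ng86_pairwise(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$N_sites, want$N_sites, tolerance = 1e-9)
    expect_equal(got$S_sites, want$S_sites, tolerance = 1e-9)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
  }
})

test_that("saturation raises an informative error", {
  a <- rep("TTT", 30)
  b <- rep("AAA", 30)  # every position differs nonsynonymously
  expect_error(ng86_pairwise(a, b, labels = c("x", "y")), "saturation.*x")
})

test_that("difference counts are additive over a codon partition", {
  set.seed(44)
  sim <- make_codon_alignment(n_taxa = 2, n_codons = 120, seed = 7)
  rows <- lapply(sim$aln$rows, function(r)
    substring(r, seq(1, nchar(r), 3), seq(3, nchar(r), 3)))
  whole <- ng86_pairwise(rows[[1]], rows[[2]])
  idx1 <- 1:50; idx2 <- 51:120
  p1 <- ng86_pairwise(rows[[1]][idx1], rows[[2]][idx1])
  p2 <- ng86_pairwise(rows[[1]][idx2], rows[[2]][idx2])
  expect_equal(p1$Nd + p2$Nd, whole$Nd, tolerance = 1e-9)
  expect_equal(p1$Sd + p2$Sd, whole$Sd, tolerance = 1e-9)
})

test_that("gene_omega averages pairs and is order-invariant", {
  sim <- make_codon_alignment(n_taxa = 4, n_codons = 150, seed = 45)
  g1 <- gene_omega(sim$aln)
  perm <- c(3, 1, 4, 2)
  aln2 <- codon_alignment(stats::setNames(sim$aln$rows[perm],
                                          sim$aln$taxa[perm]))
  g2 <- gene_omega(aln2)
  expect_equal(g1$omega, g2$omega)
  expect_equal(g1$n_pairs, 6)
})

test_that("identical taxa leave omega undefined", {
  aln <- codon_alignment(c(t1 = "ATGCCTGGA", t2 = "ATGCCTGGA"))
  expect_warning(g <- gene_omega(aln), "undefined")
  expect_true(is.na(g$omega))
})

test_that("gene omega is recovered from simulations at omega 0.3", {
  for (s in c(2, 5, 9)) {
    sim <- make_codon_alignment(n_taxa = 4, n_codons = 500, kappa = 1,
                                omega_background = 0.3, seed = s)
    g <- gene_omega(sim$aln)
    expect_gt(g$omega, 0.2)
    expect_lt(g$omega, 0.4)
  }
})

test_that("a whole-gene region reproduces the gene-wide omega", {
  sim <- make_codon_alignment(n_taxa = 3, n_codons = 200, seed = 46)
  g <- gene_omega(sim$aln)
  r <- regional_ratio(sim$aln,
                      list(name = "all", cds_start = 1, cds_end = 600),
                      gene = g)
  expect_equal(r$rho, g$omega, tolerance = 1e-12)
})

test_that("regional_ratio validates regions and includes partial codons whole", {
  sim <- make_codon_alignment(n_taxa = 3, n_codons = 100, seed = 47)
  g <- gene_omega(sim$aln)
  expect_error(regional_ratio(sim$aln,
                              list(name = "tiny", cds_start = 5, cds_end = 6),
                              gene = g), "shorter")
  expect_error(regional_ratio(sim$aln,
                              list(name = "out", cds_start = 290, cds_end = 400),
                              gene = g), "outside")
  # nt 4..8 covers codons 2 and 3 whole
  r1 <- regional_ratio(sim$aln, list(name = "a", cds_start = 4, cds_end = 8),
                       gene = g)
  r2 <- regional_ratio(sim$aln, list(name = "b", cds_start = 4, cds_end = 9),
                       gene = g)
  expect_equal(r1$dN_region, r2$dN_region)
})

test_that("regional classification separates constrained and relaxed regions", {
  rs <- data.frame(name = c("relaxed", "constrained"),
                   cds_start = c(151L, 1051L), cds_end = c(1050L, 1950L),
                   omega = c(1.2, 0.05))
  cls <- vapply(1:10, function(s) {
    sim <- make_codon_alignment(n_taxa = 6, n_codons = 800, region_specs = rs,
                                kappa = 1, branch_divergence = 0.12, seed = s)
    regional_ratio_table(sim$aln, sim$regions)$classification
  }, character(2))
  expect_gte(mean(cls[1, ] == "relaxed"), 0.8)
  expect_gte(mean(cls[2, ] == "enhanced-purifying"), 0.9)
})

test_that("conservation profile scores identity and respects taxon order", {
  aln <- codon_alignment(c(a = strrep("ATGCCT", 20), b = strrep("ATGCCT", 20),
                           c = strrep("ATGCCT", 20)))
  prof <- conservation_profile(aln, window = 9)
  expect_true(all(prof$scores == 1))
  expect_equal(nrow(prof$conserved_intervals), 1)
  expect_equal(unlist(prof$conserved_intervals[1, ]),
               c(start = 1, end = 120))
  aln2 <- codon_alignment(c(c = strrep("ATGCCT", 20), a = strrep("ATGCCT", 20),
                            b = strrep("ATGCCT", 20)))
  expect_equal(conservation_profile(aln2, window = 9)$scores, prof$scores)
})

test_that("random columns score near the 1/4 identity expectation", {
  set.seed(48)
  n <- 2001
  rows <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), n * 3, replace = TRUE),
          collapse = ""), character(1))
  names(rows) <- paste0("t", 1:4)
  aln <- list(taxa = names(rows), rows = unname(rows), length = n * 3)
  class(aln) <- "codon_alignment"
  prof <- conservation_profile(aln)
  expect_equal(mean(prof$scores), 0.25, tolerance = 0.02)
  expect_warning(conservation_profile(
    codon_alignment(c(a = "ATGCCT", b = "ATGCCT")), window = 99), "clamped")
})

test_that("concordance is perfect when conservation equals the annotation", {
  sim <- make_codon_alignment(n_taxa = 4, n_codons = 200,
                              branch_divergence = 0, seed = 49)
  # divergence zero: whole alignment conserved
  prof <- conservation_profile(sim$aln, window = 25)
  regions <- data.frame(name = "all", cds_start = 1, cds_end = 600)
  rep_ <- region_concordance(prof, regions)
  expect_equal(rep_$intervals$jaccard, 1)
  expect_equal(rep_$fraction_in_regions, 1)
  empty <- region_concordance(
    structure(list(conserved_intervals = data.frame(start = integer(0),
                                                    end = integer(0))),
              class = "conservation_profile"), regions)
  expect_equal(nrow(empty$intervals), 0)
})

test_that("conservation concentrated in annotated regions is detected", {
  set.seed(50)
  n_cod <- 300
  regions <- data.frame(name = c("m1", "m2"),
                        cds_start = c(151, 601), cds_end = c(300, 750))
  in_region <- rep(FALSE, n_cod * 3)
  for (i in seq_len(nrow(regions)))
    in_region[regions$cds_start[i]:regions$cds_end[i]] <- TRUE
  anchor <- paste(random_sense_codons(n_cod), collapse = "")
  mutate_outside <- function(s) {
    ch <- strsplit(s, "")[[1]]
    idx <- which(!in_region & runif(length(ch)) < 0.4)
    ch[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
    paste(ch, collapse = "")
  }
  rows <- c(a = anchor, b = mutate_outside(anchor), c = mutate_outside(anchor),
            d = mutate_outside(anchor))
  aln <- list(taxa = names(rows), rows = unname(rows), length = n_cod * 3)
  class(aln) <- "codon_alignment"
  prof <- conservation_profile(aln, window = 25, threshold = 0.9)
  rep_ <- region_concordance(prof, regions)
  expect_gte(rep_$fraction_in_regions, 0.9)
})
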