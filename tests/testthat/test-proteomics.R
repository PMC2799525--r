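table1 <- data.frame(
  peptide = c("DALQDDLQR", "STQGLSIVTHR", "RPLQHPPTQAEALAR",
              "QMESSEGSSETTVETPPGGR", "ALTDFLAAVSTQALPTLVEASPPSER",
              "EMPTSEDAQPLPR", "YLENTEEPIMILLNK"),
  theor_mw = c(1072.51, 1197.65, 1683.92, 2064.89, 2683.41, 1469.68, 1818.94))

test_that("monoisotopic masses reproduce the printed theoretical values", {
  got <- vapply(table1$peptide, monoisotopic_mass, numeric(1))
  expect_equal(round(unname(got), 2), table1$theor_mw)
  expect_equal(round(monoisotopic_mass("G"), 2), 75.03)
})

test_that("fixed modifications shift masses and unknown residues error", {
  expect_equal(monoisotopic_mass("C") - monoisotopic_mass("C", numeric(0)),
               57.02146)
  expect_error(monoisotopic_mass("GBZ"), "unknown residue")
})

test_that("average mass exceeds monoisotopic mass", {
  expect_equal(round(average_mass("G"), 2), 75.07)
  set.seed(21)
  for (i in 1:20) {
    p <- random_peptide(sample(5:40, 1))
    expect_gt(average_mass(p), monoisotopic_mass(p, numeric(0)))
  }
})

test_that("isoelectric point matches the two-group closed form and limits", {
  # GG has only the terminal groups: pI is the midpoint of their pK values
  expect_equal(isoelectric_point("GG"), round(two_group_pi(7.5, 3.55), 2),
               tolerance = 0.011)
  set.seed(22)
  for (i in 1:10) {
    p <- random_peptide(sample(5:50, 1))
    expect_gt(net_charge(p, 0), 0)
    expect_lt(net_charge(p, 14), 0)
    expect_lt(abs(net_charge(p, isoelectric_point(p))), 0.05)
  }
  # acidic sequences have low pI, basic high
  expect_lt(isoelectric_point("DDEEDDEE"), 4.5)
  expect_gt(isoelectric_point("KKRRKKRR"), 10)
})

test_that("digestion cleaves after K/R except before proline", {
  d <- digest("AAAAAKGGGGG", min_len = 1)
  expect_equal(d$sequence, c("AAAAAK", "GGGGG"))
  expect_equal(d$start, c(1, 7))
  expect_equal(d$end, c(6, 11))
  # proline suppression keeps the site intact
  expect_equal(digest("AAAAAKPGGGG", min_len = 1)$sequence, "AAAAAKPGGGG")
  # the same rule retains the internal R-P of RPLQHPPTQAEALAR
  d2 <- digest("AAAKRPLQHPPTQAEALARGGGGG", min_len = 1)
  expect_true("RPLQHPPTQAEALAR" %in% d2$sequence)
})

test_that("digestion agrees with an independent regex oracle", {
  set.seed(23)
  for (i in 1:10) {
    prot <- random_peptide(200)
    got <- digest(prot, min_len = 1, max_len = 200)$sequence
    expect_equal(got, digest_oracle(prot))
  }
})

test_that("zero-missed-cleavage digests tile the protein exactly", {
  set.seed(24)
  for (i in 1:10) {
    prot <- random_peptide(300)
    d <- digest(prot, min_len = 1, max_len = 300)
    expect_equal(d$start[1], 1)
    expect_equal(d$end[nrow(d)], nchar(prot))
    if (nrow(d) > 1)
      expect_equal(d$start[-1], utils::head(d$end, -1) + 1)
    expect_equal(paste(d$sequence, collapse = ""), prot)
  }
})

test_that("digest masses conserve the protein mass", {
  set.seed(25)
  for (i in 1:5) {
    prot <- random_peptide(250)
    d <- digest(prot, min_len = 1, max_len = 250)
    pep_sum <- sum(vapply(d$sequence, monoisotopic_mass, numeric(1),
                          fixed_mods = numeric(0)))
    expect_equal(pep_sum - (nrow(d) - 1) * 18.010565,
                 monoisotopic_mass(prot, numeric(0)), tolerance = 1e-3)
  }
})

test_that("missed cleavages add concatenated peptides", {
  d <- digest("AAKGGKCCK", missed_cleavages = 1, min_len = 1)
  expect_setequal(d$sequence,
                  c("AAK", "GGK", "CCK", "AAKGGK", "GGKCCK"))
  expect_equal(sort(unique(d$n_missed)), c(0, 1))
})

test_that("fragment ladders have the documented termini and complement", {
  lad <- fragment_ions("GK")
  expect_equal(round(unname(lad$y["y1"]), 2), 147.11)
  expect_equal(round(unname(lad$b["b1"]), 2), 58.03)
  set.seed(26)
  peps <- c("DALQDDLQR", replicate(10, random_peptide(sample(3:25, 1))))
  for (p in peps) {
    lad <- fragment_ions(p)
    n <- nchar(p)
    expect_length(lad$b, n - 1)
    expect_length(lad$y, n - 1)
    # b_i + y_(n-i) = MH+ + proton
    comp <- lad$b + rev(lad$y)
    expect_true(all(abs(comp - (lad$mh + 1.007276)) < 1e-4))
  }
  expect_warning(lad1 <- fragment_ions("G"), "length 1")
  expect_length(lad1$b, 0)
})

test_that("MRM transitions use the documented precursor arithmetic", {
  tr <- mrm_transitions("DALQDDLQR")
  z2 <- tr[tr$precursor_charge == 2, ]
  expect_equal(round(z2$precursor_mz[1], 2),
               round((1072.514885 + 2 * 1.007276) / 2, 2))
  # fragment labels parse back to their m/z
  lad <- fragment_ions("DALQDDLQR")
  for (i in seq_len(nrow(tr))) {
    idx <- as.integer(sub("^y", "", tr$fragment_label[i]))
    expect_equal(tr$fragment_mz[i], unname(lad$y[paste0("y", idx)]))
  }
  expect_true(all(tr$fragment_mz < tr$precursor_mz * tr$precursor_charge))
  # top_k larger than the ladder returns every y ion
  tr_all <- mrm_transitions("GAK", charges = 2, top_k = 10)
  expect_equal(nrow(tr_all), 2)
})

test_that("mass matching reproduces the printed mass differences", {
  tab <- detected_peptide_table()
  m <- match_masses(data.frame(mass_da = tab$exp_mw, method = tab$method),
                    unique(tab$peptide))
  expect_equal(nrow(m), 9)
  expect_equal(m$peptide, tab$peptide)
  expect_equal(round(m$delta_m, 2),
               c(0.03, 0.03, 0.01, 0.00, 0.08, 0.65, 0.05, 0.36, 0.50))
})

test_that("mass matching respects tolerance and reports unmatched", {
  m <- match_masses(c(1072.48, 5000), c("DALQDDLQR", "GK"), tol_da = 0.7)
  expect_equal(m$peptide, "DALQDDLQR")
  expect_equal(attr(m, "unmatched")$mass_da, 5000)
  expect_error(match_masses(1000, character(0)), "empty")
  expect_error(match_masses(1000, "GK", tol_da = 0), "positive")
  # ties broken by smaller mass difference, then shorter peptide
  tie <- match_masses(monoisotopic_mass("LGK"),
                      c("IGK", "LGK"))  # isobaric: shorter-equal, same dm
  expect_equal(nchar(tie$peptide), 3)
})

test_that("sequence coverage merges overlaps and hits the printed 8.2%", {
  tab <- detected_peptide_table()
  prot <- synthetic_scaffold_protein(unique(tab$peptide), length = 1332)
  expect_equal(nchar(prot$sequence), 1332)
  m <- match_masses(data.frame(mass_da = tab$exp_mw, method = tab$method),
                    digest(prot))
  cov <- sequence_coverage(m, prot)
  expect_equal(cov$covered_residues, 109)
  expect_equal(round(100 * cov$fraction, 1), 8.2)
  # duplicates across methods counted once: dropping duplicates is a no-op
  m1 <- m[!duplicated(m$peptide), ]
  expect_equal(sequence_coverage(m1, prot)$covered_residues, 109)
})

test_that("coverage edge cases: none and all", {
  prot <- protein_record("p", "MIEPK")
  none <- match_masses(10000, digest(prot, min_len = 1))
  expect_equal(sequence_coverage(none, prot)$fraction, 0)
  all_ <- data.frame(peptide = "MIEPK", start = 1, end = 5)
  expect_equal(sequence_coverage(all_, prot)$fraction, 1)
})
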