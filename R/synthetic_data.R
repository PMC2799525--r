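# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes: a protein with known tryptic peptides and
# mass-error-perturbed observations; Ct replicate tables with a
# genotype-dependent fold change under stated amplification efficiencies;
# codon alignments with region-specific omega; and proteins with an
# embedded heptad repeat.  Every generator returns a ground-truth manifest
# and is byte-deterministic under (seed, parameters).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# background amino-acid frequencies (approximate vertebrate proteome)
AA_BACKGROUND <- c(
  A = 0.074, R = 0.042, N = 0.044, D = 0.059, C = 0.033, E = 0.058,
  Q = 0.037, G = 0.074, H = 0.029, I = 0.038, L = 0.076, K = 0.072,
  M = 0.018, F = 0.040, P = 0.050, S = 0.081, T = 0.062, W = 0.013,
  Y = 0.033, V = 0.068)

#' Synthetic protein with known tryptic peptides and observed masses
#'
#' Builds a protein as a concatenation of tryptic segments (each ending in
#' K or R, no internal cleavage sites, no P after a boundary), marks a
#' detectable subset of peptides with length 5-30, and emits observed
#' masses as theoretical monoisotopic masses perturbed by
#' `Normal(0, sigma)` error.
#'
#' @param length minimum protein length in residues (>= 200; default 1332,
#'   a full-length single-ORF translation scale).
#' @param n_detectable number of detected peptides (default 7).
#' @param sigma mass-error standard deviation in Da (default 0.05).
#' @param seed RNG seed.
#' @return A list: `protein` ([protein_record()]), `observed` (data frame
#'   `mass_da, method`), and `truth` (data frame `peptide, start, end,
#'   true_mass, detected`).
#' @export
make_protein_with_peptides <- function(length = 1332L, n_detectable = 7L,
                                       sigma = 0.05, seed = 1L) {
  if (length < 200L) stop("make_protein_with_peptides: length must be >= 200")
  with_seed(seed, {
    interior <- setdiff(names(AA_BACKGROUND), c("K", "R"))
    w <- AA_BACKGROUND[interior] / sum(AA_BACKGROUND[interior])
    segs <- list()
    total <- 0L
    det_len <- sample(8:26, n_detectable, replace = TRUE)
    queue <- c(det_len, integer(0))
    while (total < length) {
      len <- if (length(queue)) queue[1] else sample(3:40, 1L)
      if (length(queue)) queue <- queue[-1]
      body <- sample(interior, len - 1L, replace = TRUE, prob = w)
      # no P immediately after the previous cleavage site
      if (body[1] == "P") body[1] <- "A"
      seg <- paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
      segs[[base::length(segs) + 1L]] <- seg
      total <- total + nchar(seg)
    }
    protein <- paste(unlist(segs), collapse = "")
    ends <- cumsum(nchar(unlist(segs)))
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    truth <- data.frame(peptide = unlist(segs), start = starts, end = ends)
    truth$true_mass <- vapply(truth$peptide, monoisotopic_mass, numeric(1))
    eligible <- which(nchar(truth$peptide) >= 5L & nchar(truth$peptide) <= 30L)
    if (base::length(eligible) < n_detectable)
      stop("make_protein_with_peptides: infeasible constraints; too few ",
           "eligible peptides")
    det <- sort(sample(eligible, n_detectable))
    truth$detected <- seq_len(nrow(truth)) %in% det
    observed <- data.frame(
      mass_da = truth$true_mass[det] + stats::rnorm(n_detectable, 0, sigma),
      method = sample(c("LC-MALDI-MS/MS", "ESI-LC-MS/MS"), n_detectable,
                      replace = TRUE))
    list(protein = protein_record("synthetic_protein", protein,
                                  source = paste0("make_protein_with_peptides seed ", seed)),
         observed = observed, truth = truth)
  })
}

#' Synthetic qRT-PCR Ct replicate table
#'
#' Mirrors a two-genotype design (wild type `NN` vs paternal heterozygote
#' `NCpat`, n per group) with four technical replicates per assay.
#' Reference Ct is drawn per sample from `Normal(20, 0.2)`; the target Ct
#' baseline is offset so that the group MNE ratio equals `true_fold` in
#' expectation given the assay efficiencies; technical replicates add
#' `Normal(0, noise_sd)`.
#'
#' @param n_per_group samples per genotype (default 4).
#' @param true_fold true MNE fold change of NCpat over NN (default 45).
#' @param e_target,e_ref per-cycle amplification efficiencies (defaults
#'   1.90 and 1.96).
#' @param noise_sd technical-replicate Ct standard deviation (default
#'   0.15).
#' @param n_reps technical replicates per assay (default 4).
#' @param target_gene,reference_gene gene labels in the output table.
#' @param seed RNG seed.
#' @return A list: `ct` (data frame `sample_id, genotype, gene, ct`) and
#'   `truth` (list with the generating parameters).
#' @export
make_ct_dataset <- function(n_per_group = 4L, true_fold = 45,
                            e_target = 1.90, e_ref = 1.96, noise_sd = 0.15,
                            n_reps = 4L, target_gene = "PEG11",
                            reference_gene = "RPLPO", seed = 1L) {
  if (true_fold <= 0) stop("make_ct_dataset: true_fold must be positive")
  with_seed(seed, {
    base_ct_t <- 25
    shift <- log(true_fold) / log(e_target)
    rows <- list()
    for (g in c("NN", "NCpat")) {
      for (i in seq_len(n_per_group)) {
        id <- paste0(g, "_", i)
        ct_ref <- stats::rnorm(1, 20, 0.2)
        ct_t <- base_ct_t - if (g == "NCpat") shift else 0
        # the same biological reference level feeds both assays
        ct_t <- ct_t + (ct_ref - 20) * log(e_ref) / log(e_target)
        for (gene in c(reference_gene, target_gene)) {
          base <- if (gene == reference_gene) ct_ref else ct_t
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = id, genotype = g, gene = gene,
            ct = base + stats::rnorm(n_reps, 0, noise_sd))
        }
      }
    }
    list(ct = do.call(rbind, rows),
         truth = list(true_fold = true_fold, e_target = e_target,
                      e_ref = e_ref, noise_sd = noise_sd,
                      n_per_group = n_per_group, n_reps = n_reps))
  })
}

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Synthetic codon alignment with region-specific omega
#'
#' Evolves `n_taxa` sequences from a random ancestor along a star phylogeny
#' by nucleotide-wise proposal: each proposal picks a site, draws an
#' alternative base with transition bias `kappa`, rejects stop codons,
#' accepts synonymous changes always and nonsynonymous changes with
#' probability omega (background, or the region's omega inside annotated
#' regions).  Expected pairwise dS is approximately `2 * branch_divergence`.
#'
#' @param n_taxa number of taxa (default 6).
#' @param n_codons alignment length in codons (default 500).
#' @param omega_background gene-wide dN/dS (default 0.3).
#' @param region_specs optional data frame `name, cds_start, cds_end,
#'   omega` (1-based inclusive nt); regions must be disjoint and inside
#'   the gene.
#' @param kappa transition/transversion proposal bias (default 2).
#' @param branch_divergence expected proposals per nucleotide site per
#'   branch (default 0.15).
#' @param seed RNG seed.
#' @return A list: `aln` ([codon_alignment()]), `regions` (the region
#'   specs, possibly empty), and `truth` (generating parameters, including
#'   `expected_dS`).
#' @export
make_codon_alignment <- function(n_taxa = 6L, n_codons = 500L,
                                 omega_background = 0.3,
                                 region_specs = NULL, kappa = 2,
                                 branch_divergence = 0.15, seed = 1L) {
  if (omega_background < 0) stop("make_codon_alignment: omega must be >= 0")
  if (!is.null(region_specs) && nrow(region_specs)) {
    if (any(region_specs$omega < 0))
      stop("make_codon_alignment: omega must be >= 0")
    ord <- order(region_specs$cds_start)
    rs <- region_specs[ord, ]
    if (any(rs$cds_end > 3L * n_codons) || any(rs$cds_start < 1L))
      stop("make_codon_alignment: region outside the gene")
    if (nrow(rs) > 1L &&
        any(rs$cds_start[-1L] <= rs$cds_end[-nrow(rs)]))
      stop("make_codon_alignment: regions must be disjoint")
  }
  with_seed(seed, {
    tab <- codon_table()
    omega_by_codon <- rep(omega_background, n_codons)
    if (!is.null(region_specs) && nrow(region_specs)) {
      for (i in seq_len(nrow(region_specs)))
        omega_by_codon[region_codon_index(region_specs$cds_start[i],
                                          region_specs$cds_end[i])] <-
          region_specs$omega[i]
    }
    ancestor <- sample(tab$sense, n_codons, replace = TRUE)
    gc <- tab$gc
    nts <- c("A", "C", "G", "T")
    # global thinning so that regions with omega > 1 realise a
    # nonsynonymous rate above the gene-wide synonymous (neutral) rate
    omega_norm <- max(1, omega_by_codon)
    evolve <- function(codons) {
      n_prop <- stats::rpois(1, 3 * n_codons * branch_divergence)
      for (k in seq_len(n_prop)) {
        site <- sample.int(3L * n_codons, 1L)
        ci <- (site - 1L) %/% 3L + 1L
        pos <- (site - 1L) %% 3L + 1L
        cod <- codons[ci]
        cur <- substring(cod, pos, pos)
        alts <- setdiff(nts, cur)
        wts <- ifelse(alts == TRANSITIONS[[cur]], kappa, 1)
        alt <- sample(alts, 1L, prob = wts)
        new <- cod
        substring(new, pos, pos) <- alt
        if (gc[[new]] == "*") next
        p_acc <- if (gc[[new]] == gc[[cod]]) 1 / omega_norm
                 else omega_by_codon[ci] / omega_norm
        if (stats::runif(1) < p_acc) codons[ci] <- new
      }
      codons
    }
    rows <- vapply(seq_len(n_taxa),
                   function(i) paste(evolve(ancestor), collapse = ""),
                   character(1))
    names(rows) <- paste0("taxon_", seq_len(n_taxa))
    regions <- if (is.null(region_specs))
      data.frame(name = character(0), cds_start = integer(0),
                 cds_end = integer(0), omega = numeric(0))
    else region_specs
    list(aln = codon_alignment(rows),
         regions = regions,
         truth = list(omega_background = omega_background,
                      region_specs = region_specs, kappa = kappa,
                      branch_divergence = branch_divergence,
                      expected_dS = 2 * branch_divergence /
                        max(1, omega_by_codon)))
  })
}

#' Synthetic protein with an embedded heptad repeat
#'
#' A block of `n_heptads` heptads (hydrophobic L/I/V at positions a and d,
#' polar E/K/Q/A elsewhere) embedded between flanks drawn from background
#' amino-acid composition.
#'
#' @param n_heptads heptads in the coiled-coil block (>= 4 for a scoreable
#'   coil; 0 gives a flanks-only control).
#' @param flank_len flank length on each side (default 80).
#' @param seed RNG seed.
#' @return A list: `protein` ([protein_record()]) and `truth` (list with
#'   `cc_start`, `cc_end`; both `NA` when `n_heptads = 0`).
#' @export
make_coiled_coil_protein <- function(n_heptads = 6L, flank_len = 80L,
                                     seed = 1L) {
  with_seed(seed, {
    # flanks are resampled until they carry no coiled-coil signal of their
    # own, so the truth interval is the only coil in the record
    flank <- function(n) {
      repeat {
        f <- paste(sample(names(AA_BACKGROUND), n, replace = TRUE,
                          prob = AA_BACKGROUND), collapse = "")
        if (n < 14) return(f)
        if (max(coils_profile(f, window = 14)$probability) < 0.3) return(f)
      }
    }
    block <- if (n_heptads > 0L) {
      paste(vapply(seq_len(n_heptads), function(i) {
        h <- character(7)
        h[c(1, 4)] <- sample(c("L", "I", "V"), 2L, replace = TRUE)
        h[c(2, 3, 5, 6, 7)] <- sample(c("E", "K", "Q", "A"), 5L,
                                      replace = TRUE)
        paste(h, collapse = "")
      }, character(1)), collapse = "")
    } else ""
    seqs <- paste0(flank(flank_len), block, flank(flank_len))
    truth <- if (n_heptads > 0L)
      list(cc_start = flank_len + 1L, cc_end = flank_len + 7L * n_heptads)
    else list(cc_start = NA_integer_, cc_end = NA_integer_)
    list(protein = protein_record("synthetic_coil", seqs,
                                  source = paste0("make_coiled_coil_protein seed ", seed)),
         truth = truth)
  })
}
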