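# End-to-end pipeline: digestion -> matching -> coverage; MNE -> genotype
# contrast; NG86 -> regional ratios -> conservation concordance; COILS ->
# region summary.  Output is a pure function of (inputs, config, seed);
# timestamps go to the log connection, never into result files.

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and lines starting with `#`
#' are ignored.  Values that parse as numbers become numeric.
#'
#' @param path configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("read_config: malformed line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

default_config <- function() {
  list(seed = 1L, tolerance_da = 0.7, coils_window = 14L,
       cons_window = 25L, cons_threshold = 0.9,
       e_target = 1.90, e_ref = 1.96, true_fold = 45,
       target_gene = "PEG11", reference_gene = "RPLPO")
}

need_file <- function(path, what) {
  if (!file.exists(path))
    stop("run_pipeline: ", what, " input file not found: ", path)
  path
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full verification pipeline
#'
#' Chains all four analysis stages and writes one TSV per stage plus a
#' `summary.json` under `out_dir`.  Inputs may be supplied as file paths in
#' `config` (`protein_fasta`, `observed_csv`, `ct_csv`, `alignment_fasta`,
#' `regions_tsv`, `coil_fasta`); any stage without inputs runs on seeded
#' synthetic data and additionally reports truth-recovery checks.
#'
#' @param config a named list (see [read_config()]); unspecified keys take
#'   package defaults (`seed` 1, `tolerance_da` 0.7, `coils_window` 14,
#'   `cons_window` 25, `cons_threshold` 0.9, efficiencies 1.96/1.90).
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @param log connection or `""` for stderr progress messages.
#' @return The summary list, invisibly classed `pipeline_summary`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, log = "") {
  cfg <- utils::modifyList(default_config(), config)
  seed <- as.integer(cfg$seed)
  note <- function(...) message("[pepverify] ", ...)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  summary <- list(schema_version = 1L, seed = seed)

  ## stage 1: peptide verification -------------------------------------
  if (!is.null(cfg$protein_fasta)) {
    protein <- read_fasta(need_file(cfg$protein_fasta, "protein"),
                          type = "protein")[[1]]
    obs <- utils::read.csv(need_file(cfg$observed_csv, "observed-mass"))
    truth_pep <- NULL
  } else {
    sim <- make_protein_with_peptides(seed = seed)
    protein <- sim$protein; obs <- sim$observed; truth_pep <- sim$truth
  }
  note("proteomics: ", nchar(protein$sequence), " aa, ", nrow(obs),
       " observed masses")
  peps <- digest(protein, missed_cleavages = 0L, min_len = 5L, max_len = 60L)
  matches <- match_masses(obs, peps, tol_da = cfg$tolerance_da)
  cov <- sequence_coverage(matches, protein)
  summary$proteomics <- list(
    n_theoretical_peptides = nrow(peps), n_observed = nrow(obs),
    n_matched = nrow(matches),
    coverage_percent = round(100 * cov$fraction, 1))
  if (!is.null(truth_pep)) {
    truth_cov <- sum(nchar(truth_pep$peptide[truth_pep$detected])) /
      nchar(protein$sequence)
    summary$proteomics$truth_recovery <- list(
      all_detected_matched =
        nrow(matches) == sum(truth_pep$detected) &&
        setequal(matches$peptide, truth_pep$peptide[truth_pep$detected]),
      coverage_matches_truth =
        isTRUE(all.equal(cov$fraction, truth_cov, tolerance = 1e-12)))
  }

  ## stage 2: expression -------------------------------------------------
  if (!is.null(cfg$ct_csv)) {
    ct <- utils::read.csv(need_file(cfg$ct_csv, "Ct"))
    truth_ct <- NULL
  } else {
    sim <- make_ct_dataset(true_fold = cfg$true_fold,
                           e_target = cfg$e_target, e_ref = cfg$e_ref,
                           target_gene = cfg$target_gene,
                           reference_gene = cfg$reference_gene,
                           seed = seed + 1L)
    ct <- sim$ct; truth_ct <- sim$truth
  }
  mtab <- mne_table(ct, cfg$target_gene, cfg$reference_gene,
                    e_target = cfg$e_target, e_reference = cfg$e_ref)
  contrast <- group_fold_change(mtab, "NCpat", "NN")
  note("expression: fold change ", round(contrast$fold_change, 2),
       ", p = ", signif(contrast$p_value, 3))
  summary$expression <- list(
    fold_change = contrast$fold_change, p_value = contrast$p_value,
    n_a = contrast$n_a, n_b = contrast$n_b)
  if (!is.null(truth_ct))
    summary$expression$truth_recovery <- list(
      true_fold = truth_ct$true_fold,
      fold_within_10pct =
        abs(contrast$fold_change / truth_ct$true_fold - 1) <= 0.10)

  ## stage 3: co-evolution ----------------------------------------------
  if (!is.null(cfg$alignment_fasta)) {
    aln <- read_alignment(need_file(cfg$alignment_fasta, "alignment"))
    regions <- utils::read.table(need_file(cfg$regions_tsv, "regions"),
                                 sep = "\t", header = TRUE)
    truth_aln <- NULL
  } else {
    rs <- data.frame(name = c("mir431_like", "mirX_like"),
                     cds_start = c(301L, 901L), cds_end = c(480L, 1080L),
                     omega = c(1.2, 0.05))
    sim <- make_codon_alignment(region_specs = rs, seed = seed + 2L)
    aln <- sim$aln; regions <- sim$regions; truth_aln <- sim$truth
  }
  gene <- gene_omega(aln)
  rtab <- regional_ratio_table(aln, regions)
  prof <- conservation_profile(aln, window = cfg$cons_window,
                               threshold = cfg$cons_threshold)
  conc <- region_concordance(prof, regions)
  note("coevolution: gene omega ", round(gene$omega, 3))
  summary$coevolution <- list(
    dN_gene = gene$dN, dS_gene = gene$dS, omega_gene = gene$omega,
    regions = lapply(seq_len(nrow(rtab)), function(i)
      list(name = rtab$name[i], rho = rtab$rho[i],
           classification = rtab$classification[i])),
    fraction_conserved_in_regions = conc$fraction_in_regions)
  if (!is.null(truth_aln))
    summary$coevolution$truth_recovery <- list(
      omega_truth = truth_aln$omega_background,
      omega_within_band =
        gene$omega >= truth_aln$omega_background / 1.5 &&
        gene$omega <= truth_aln$omega_background * 1.5)

  ## stage 4: coiled coil -------------------------------------------------
  if (!is.null(cfg$coil_fasta)) {
    coil_prot <- read_fasta(need_file(cfg$coil_fasta, "coil protein"),
                            type = "protein")[[1]]
    truth_coil <- NULL
  } else {
    sim <- make_coiled_coil_protein(seed = seed + 3L)
    coil_prot <- sim$protein; truth_coil <- sim$truth
  }
  cprof <- coils_profile(coil_prot, window = cfg$coils_window)
  note("coils: max probability ", round(max(cprof$probability), 3))
  summary$coils <- list(max_probability = max(cprof$probability),
                        argmax_position = cprof$position[
                          which.max(cprof$probability)])
  if (!is.null(truth_coil) && !is.na(truth_coil$cc_start)) {
    inside <- cprof$probability[truth_coil$cc_start:truth_coil$cc_end]
    summary$coils$truth_recovery <- list(
      max_prob_in_truth = max(inside),
      peak_inside_truth = max(inside) >= 0.9)
  }

  if (!is.null(out_dir)) {
    write_tsv(as.data.frame(matches),
              file.path(out_dir, "peptide_matches.tsv"))
    write_tsv(mtab, file.path(out_dir, "mne.tsv"))
    write_tsv(rtab, file.path(out_dir, "regional_selection.tsv"))
    write_tsv(data.frame(column = seq_along(prof$smoothed),
                         score = prof$smoothed),
              file.path(out_dir, "conservation_profile.tsv"))
    write_tsv(as.data.frame(cprof), file.path(out_dir, "coil_profile.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(summary) <- "pipeline_summary"
  invisible(summary)
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("<pipeline_summary> seed", x$seed, "\n")
  cat("  coverage:", x$proteomics$coverage_percent, "%\n")
  cat("  fold change:", signif(x$expression$fold_change, 4),
      " (p =", signif(x$expression$p_value, 3), ")\n")
  cat("  gene omega:", signif(x$coevolution$omega_gene, 3), "\n")
  cat("  coil max probability:", signif(x$coils$max_probability, 3), "\n")
  invisible(x)
}
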