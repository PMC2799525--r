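# Efficiency-corrected qRT-PCR quantification: Mean Normalized Expression
# (MNE) relative to a reference gene, with genotype contrasts.
#
# E is the per-cycle amplification factor (2 = perfect doubling), so
# MNE = E_ref^mean(Ct_ref) / E_target^mean(Ct_target).

#' Mean Normalized Expression for one sample
#'
#' `MNE = E_ref^mean(Ct_ref) / E_t^mean(Ct_t)`.  The SEM follows by
#' first-order (delta-method) propagation of the replicate SEMs of the two
#' Ct means:
#' `SEM = MNE * sqrt((ln E_ref * SEM_ref)^2 + (ln E_t * SEM_t)^2)`.
#'
#' @param ct_target,ct_reference numeric vectors of technical-replicate Ct
#'   values (>= 2 each) for the target and reference assays of one sample.
#' @param e_target,e_reference per-cycle amplification efficiencies in
#'   (1, 2].
#' @param sample_id optional sample label.
#' @return A list of class `mne_result`: `sample_id, mne, sem_mne, n_reps`.
#' @export
mne <- function(ct_target, ct_reference, e_target, e_reference,
                sample_id = NA_character_) {
  stopifnot(length(ct_target) >= 2L, length(ct_reference) >= 2L)
  if (e_target <= 1 || e_target > 2 || e_reference <= 1 || e_reference > 2)
    stop("mne: efficiencies must lie in (1, 2]")
  if (any(c(ct_target, ct_reference) <= 0) ||
      any(c(ct_target, ct_reference) > 40))
    stop("mne: Ct values must lie in (0, 40]")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  m <- e_reference^mean(ct_reference) / e_target^mean(ct_target)
  s <- m * sqrt((log(e_reference) * sem(ct_reference))^2 +
                (log(e_target) * sem(ct_target))^2)
  structure(list(sample_id = sample_id, mne = m, sem_mne = s,
                 n_reps = length(ct_target)),
            class = "mne_result")
}

#' @export
print.mne_result <- function(x, ...) {
  cat(sprintf("<mne_result> %s  MNE = %.4g +/- %.2g (n = %d)\n",
              x$sample_id, x$mne, x$sem_mne, x$n_reps))
  invisible(x)
}

#' Per-sample MNE table from a tidy Ct data frame
#'
#' @param ct_data data frame with columns `sample_id, genotype, gene, ct`
#'   (one row per technical replicate).
#' @param target,reference gene names of the target and reference assays.
#' @param e_target,e_reference per-cycle amplification efficiencies.
#' @return Data frame with one row per sample: `sample_id, genotype, mne,
#'   sem_mne, n_reps`.
#' @export
mne_table <- function(ct_data, target, reference, e_target, e_reference) {
  need <- c("sample_id", "genotype", "gene", "ct")
  miss <- setdiff(need, names(ct_data))
  if (length(miss))
    stop("mne_table: missing column(s): ", paste(miss, collapse = ", "))
  ids <- unique(ct_data$sample_id)
  rows <- lapply(ids, function(id) {
    sub <- ct_data[ct_data$sample_id == id, ]
    ct_t <- sub$ct[sub$gene == target]
    ct_r <- sub$ct[sub$gene == reference]
    if (!length(ct_t) || !length(ct_r))
      stop("mne_table: sample ", id, " lacks ", target, " or ", reference,
           " replicates")
    r <- mne(ct_t, ct_r, e_target, e_reference, sample_id = id)
    data.frame(sample_id = id, genotype = sub$genotype[1], mne = r$mne,
               sem_mne = r$sem_mne, n_reps = r$n_reps)
  })
  do.call(rbind, rows)
}

#' Fold change and significance between two genotype groups
#'
#' Fold change is the ratio of group mean MNEs; the p-value comes from a
#' two-sided Welch t-test on log(MNE), matching the multiplicative noise
#' model implied by exponential Ct arithmetic.
#'
#' @param mne_df a data frame from [mne_table()] (columns `genotype, mne`).
#' @param group_a,group_b genotype labels; fold change is a over b.
#' @return A list of class `group_contrast`: `group_a, group_b,
#'   fold_change, p_value, n_a, n_b`.
#' @export
group_fold_change <- function(mne_df, group_a, group_b) {
  a <- mne_df$mne[mne_df$genotype == group_a]
  b <- mne_df$mne[mne_df$genotype == group_b]
  if (length(a) < 2L || length(b) < 2L)
    stop("group_fold_change: need >= 2 samples per group")
  fold <- mean(a) / mean(b)
  # degenerate replicate-free case: no within-group scatter to test against
  if (stats::sd(log(a)) < 1e-10 && stats::sd(log(b)) < 1e-10) {
    p <- if (isTRUE(all.equal(mean(log(a)), mean(log(b))))) 1 else 0
  } else {
    p <- stats::t.test(log(a), log(b))$p.value
  }
  structure(list(group_a = group_a, group_b = group_b, fold_change = fold,
                 p_value = p, n_a = length(a), n_b = length(b)),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("<group_contrast> %s vs %s: fold = %.3g, p = %.3g (n = %d, %d)\n",
              x$group_a, x$group_b, x$fold_change, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Sense/antisense expression partition
#'
#' Ratio of the dual assay (which sees sense plus antisense transcript) to
#' the antisense-only assay.  When the ratio is much greater than one, the
#' dual assay is a good approximation for the sense transcript alone.
#'
#' @param mne_both `mne_result` (or number) for the dual sense+antisense
#'   assay.
#' @param mne_as_only `mne_result` (or number) for the antisense-only assay.
#' @param sense_dominant_threshold ratio above which the sample is flagged
#'   sense-dominant (default 5).
#' @return A list with `ratio` and logical `sense_dominant`.
#' @export
sense_antisense_partition <- function(mne_both, mne_as_only,
                                      sense_dominant_threshold = 5) {
  b <- if (inherits(mne_both, "mne_result")) mne_both$mne else mne_both
  a <- if (inherits(mne_as_only, "mne_result")) mne_as_only$mne else mne_as_only
  if (a == 0) stop("sense_antisense_partition: antisense MNE is zero")
  r <- b / a
  list(ratio = r, sense_dominant = r > sense_dominant_threshold)
}
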