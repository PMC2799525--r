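# Bundled study tables and a deterministic synthetic scaffold protein.

#' Detected peptide table (bundled)
#'
#' The nine mass-spectrometric peptide observations (seven unique
#' sequences) bundled with the package: columns `peptide, exp_mw, method`.
#' Experimental masses are neutral monoisotopic Da.
#'
#' @return A data frame with 9 rows.
#' @export
detected_peptide_table <- function() {
  utils::read.csv(system.file("extdata", "peg11_peptides.csv",
                              package = "pepverify"),
                  stringsAsFactors = FALSE)
}

#' qRT-PCR primer table (bundled)
#'
#' The four assay primer pairs bundled with the package, anchor
#' coordinates as printed (5' coordinate first; descending = minus
#' strand); tails are non-genomic 5' additions of the recombinant-construct
#' primers.
#'
#' @return A list of [primer_pair()] objects.
#' @export
bundled_primer_pairs <- function() {
  read_primers(system.file("extdata", "peg11_primers.csv",
                           package = "pepverify"))
}

#' Deterministic synthetic scaffold protein embedding given peptides
#'
#' Builds a synthetic protein of exactly `length` residues in which the
#' given tryptic peptides appear as digestion products separated by long
#' lysine-terminated filler blocks (no internal K/R, so fillers exceed the
#' digestion length filter and never confound matching).  The scaffold is
#' a synthetic stand-in for a full-length translation that is not bundled;
#' it preserves the peptide content and total length, nothing else.
#'
#' @param peptides character vector of tryptic peptides (each ending in K
#'   or R, no unsuppressed internal cleavage site).
#' @param length total protein length in residues (default 1332).
#' @return A [protein_record()] named `synthetic_scaffold`.
#' @export
synthetic_scaffold_protein <- function(peptides, length = 1332L) {
  pep_total <- sum(nchar(peptides))
  n_fill <- length(peptides) + 1L
  spare <- length - pep_total - n_fill   # one K terminator per filler
  if (spare < n_fill)
    stop("synthetic_scaffold_protein: length too short for the peptides")
  base <- spare %/% n_fill
  lens <- rep(base, n_fill)
  extra <- spare - base * n_fill
  if (extra > 0L) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  unit <- "ADSTVGELMHFWYQN"   # no K, R, P, C
  filler <- function(n) {
    body <- strrep(unit, n %/% nchar(unit) + 1L)
    paste0(substring(body, 1L, n), "K")
  }
  parts <- character(0)
  for (i in seq_along(peptides))
    parts <- c(parts, filler(lens[i]), peptides[i])
  parts <- c(parts, filler(lens[n_fill]))
  protein_record("synthetic_scaffold", paste(parts, collapse = ""),
                 source = "synthetic scaffold embedding supplied peptides")
}
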