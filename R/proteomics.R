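# Targeted peptide-verification workflow: in-silico tryptic digestion,
# neutral peptide masses, b/y fragment ladders, MRM transition design,
# tolerance-based matching of observed masses, and sequence coverage.
#
# Masses are neutral (uncharged) and carried at full double precision;
# rounding to 2 dp happens only at presentation.

# Monoisotopic residue (amino-acid minus water) masses, Da.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

# Average residue masses, Da.
AA_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

WATER_MONO <- 18.010565
WATER_AVG  <- 18.01524
PROTON     <- 1.007276

#' Default fixed modifications
#'
#' Carbamidomethylation of cysteine (iodoacetamide alkylation), +57.02146 Da,
#' the standard fixed modification of gel-based tryptic workflows.
#' @return Named numeric vector of residue mass shifts.
#' @export
default_fixed_mods <- function() c(C = 57.02146)

residue_masses <- function(sequence, table, fixed_mods) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(table))
  if (length(bad))
    stop("unknown residue(s): ", paste(unique(bad), collapse = ","))
  m <- unname(table[aa])
  if (length(fixed_mods)) {
    idx <- match(aa, names(fixed_mods))
    m <- m + ifelse(is.na(idx), 0, fixed_mods[ifelse(is.na(idx), 1L, idx)])
  }
  m
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water (18.010565 Da) plus any
#' fixed modifications.
#'
#' @param sequence peptide amino-acid string.
#' @param fixed_mods named residue -> mass-shift map; default
#'   [default_fixed_mods()].  Use `numeric(0)` for none.
#' @return Neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(sequence, fixed_mods = default_fixed_mods()) {
  sum(residue_masses(toupper(sequence), AA_MONO, fixed_mods)) + WATER_MONO
}

#' Neutral average peptide mass
#'
#' @inheritParams monoisotopic_mass
#' @return Neutral average mass in Da.
#' @export
average_mass <- function(sequence, fixed_mods = numeric(0)) {
  sum(residue_masses(toupper(sequence), AA_AVG, fixed_mods)) + WATER_AVG
}

# Bjellqvist-style pK values (as used by ProtParam-like calculators).
PK_SIDE <- c(D = 4.05, E = 4.45, H = 5.98, C = 9.0, Y = 10.0, K = 10.0, R = 12.0)
PK_NTERM <- 7.5
PK_CTERM <- 3.55
PK_NTERM_BY_AA <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                    V = 7.44, E = 7.70)

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable groups D, E, C, Y (acidic),
#' H, K, R (basic) and the two termini.
#'
#' @param sequence amino-acid string.
#' @param pH pH value(s).
#' @return Net charge (vectorised over `pH`).
#' @export
net_charge <- function(sequence, pH) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  nterm_pk <- PK_NTERM_BY_AA[aa[1]]
  if (is.na(nterm_pk)) nterm_pk <- PK_NTERM
  basic <- c(unname(nterm_pk),
             unname(PK_SIDE[aa[aa %in% c("H", "K", "R")]]))
  acidic <- c(PK_CTERM,
              unname(PK_SIDE[aa[aa %in% c("D", "E", "C", "Y")]]))
  vapply(pH, function(p) {
    sum(1 / (1 + 10^(p - basic))) - sum(1 / (1 + 10^(acidic - p)))
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which [net_charge()] is zero, by bisection on `[0, 14]`
#' to a precision of 0.01 pH units.  The net-charge function is monotone
#' decreasing in pH, so the root is unique.
#'
#' @param sequence amino-acid string.
#' @return The isoelectric point (pH).
#' @export
isoelectric_point <- function(sequence) {
  if (!nzchar(sequence)) stop("isoelectric_point: empty sequence")
  lo <- 0; hi <- 14
  while (hi - lo > 0.005) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  round((lo + hi) / 2, 2)
}

#' In-silico tryptic digestion
#'
#' Cleaves after every K or R not followed by P, keeps peptides with up to
#' `missed_cleavages` retained internal sites, and applies the length filter
#' last.  Positions are 1-based inclusive in the parent protein.
#'
#' @param protein a [protein_record()] or plain amino-acid string.
#' @param missed_cleavages maximum retained internal cleavage sites
#'   (default 0; at most 3).
#' @param min_len,max_len residue-length bounds applied after digestion
#'   (defaults 5 and 60).
#' @return A data frame of class `peptide_set` with columns
#'   `sequence, start, end, n_missed`.
#' @export
digest <- function(protein, missed_cleavages = 0L, min_len = 5L, max_len = 60L) {
  if (inherits(protein, "protein_record")) protein <- protein$sequence
  stopifnot(missed_cleavages >= 0L, missed_cleavages <= 3L,
            min_len <= max_len)
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  cut <- which(aa %in% c("K", "R"))
  cut <- cut[cut < n & aa[pmin(cut + 1L, n)] != "P"]
  cut <- c(cut, n)                      # segment right ends
  starts <- c(1L, utils::head(cut, -1L) + 1L)
  out <- list()
  nseg <- length(starts)
  for (i in seq_len(nseg)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > nseg) break
      out[[length(out) + 1L]] <- data.frame(
        sequence = paste(aa[starts[i]:cut[j]], collapse = ""),
        start = starts[i], end = cut[j], n_missed = m)
    }
  }
  res <- do.call(rbind, out)
  len <- res$end - res$start + 1L
  res <- res[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("peptide_set", "data.frame")
  res
}

#' b/y fragment-ion ladder for a peptide
#'
#' Singly protonated fragment m/z values:
#' `b_i = sum(residues 1..i) + proton` and
#' `y_j = sum(residues n-j+1..n) + water + proton`.
#'
#' @param peptide amino-acid string (length >= 2 for a non-empty ladder).
#' @param fixed_mods fixed modifications, as in [monoisotopic_mass()].
#' @return A list of class `fragment_ladder` with numeric vectors `b` and
#'   `y` (named b1..b(n-1), y1..y(n-1)) and the precursor `mh` (MH+).
#' @export
fragment_ions <- function(peptide, fixed_mods = default_fixed_mods()) {
  peptide <- toupper(peptide)
  m <- residue_masses(peptide, AA_MONO, fixed_mods)
  n <- length(m)
  if (n < 2L) {
    warning("fragment_ions: peptide of length 1 has an empty ladder")
    return(structure(list(peptide = peptide, b = numeric(0), y = numeric(0),
                          mh = sum(m) + WATER_MONO + PROTON),
                     class = "fragment_ladder"))
  }
  b <- cumsum(m)[1:(n - 1L)] + PROTON
  y <- cumsum(rev(m))[1:(n - 1L)] + WATER_MONO + PROTON
  names(b) <- paste0("b", 1:(n - 1L))
  names(y) <- paste0("y", 1:(n - 1L))
  structure(list(peptide = peptide, b = b, y = y,
                 mh = sum(m) + WATER_MONO + PROTON),
            class = "fragment_ladder")
}

#' @export
print.fragment_ladder <- function(x, ...) {
  cat("<fragment_ladder>", x$peptide, " MH+", round(x$mh, 2), "\n")
  print(round(rbind(b = x$b, y = rev(x$y)), 2))
  invisible(x)
}

#' Design MRM transitions for a peptide
#'
#' Precursor m/z is `(neutral + z * proton) / z` for each charge state; the
#' fragments are the `top_k` highest-m/z singly charged y ions above the
#' precursor m/z where possible, otherwise the highest y ions overall.
#'
#' @param peptide amino-acid string.
#' @param charges precursor charge states (default 2 and 3).
#' @param top_k fragments per precursor (default 4; clamped to the ladder).
#' @param fixed_mods fixed modifications.
#' @return A data frame with columns `peptide, precursor_mz,
#'   precursor_charge, fragment_label, fragment_mz`.
#' @export
mrm_transitions <- function(peptide, charges = c(2L, 3L), top_k = 4L,
                            fixed_mods = default_fixed_mods()) {
  lad <- fragment_ions(peptide, fixed_mods)
  neutral <- lad$mh - PROTON
  y <- sort(lad$y, decreasing = TRUE)
  out <- list()
  for (z in charges) {
    prec <- (neutral + z * PROTON) / z
    above <- y[y > prec]
    sel <- if (length(above) >= min(top_k, length(y))) above else y
    sel <- sel[seq_len(min(top_k, length(sel)))]
    out[[length(out) + 1L]] <- data.frame(
      peptide = peptide, precursor_mz = prec, precursor_charge = z,
      fragment_label = names(sel), fragment_mz = unname(sel))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match observed peptide masses against theoretical peptides
#'
#' Each observed mass is paired with the nearest theoretical neutral mass
#' within `tol_da`; ties are broken by smaller mass difference, then by
#' shorter peptide.  Unmatched observations are kept in the `unmatched`
#' attribute.
#'
#' @param observed data frame with columns `mass_da` and `method`, or a
#'   numeric vector of masses.
#' @param peptides a `peptide_set` from [digest()], or a character vector of
#'   peptide sequences.
#' @param tol_da absolute matching tolerance in Da (default 0.7).
#' @param fixed_mods fixed modifications used for the theoretical masses.
#' @return A data frame of class `peptide_match_table` with columns
#'   `peptide, start, end, theor_mw, exp_mw, delta_m, method`; attribute
#'   `unmatched` holds the unpaired observations.
#' @export
match_masses <- function(observed, peptides, tol_da = 0.7,
                         fixed_mods = default_fixed_mods()) {
  if (tol_da <= 0) stop("match_masses: tol_da must be positive")
  if (is.numeric(observed))
    observed <- data.frame(mass_da = observed, method = "other")
  if (is.character(peptides)) {
    if (!length(peptides)) stop("match_masses: empty theoretical peptide list")
    peptides <- data.frame(sequence = peptides, start = NA_integer_,
                           end = NA_integer_)
  }
  if (!nrow(peptides)) stop("match_masses: empty theoretical peptide list")
  theor <- vapply(peptides$sequence, monoisotopic_mass, numeric(1),
                  fixed_mods = fixed_mods)
  rows <- list(); unm <- list()
  for (i in seq_len(nrow(observed))) {
    dm <- abs(observed$mass_da[i] - theor)
    ok <- which(dm <= tol_da)
    if (!length(ok)) {
      unm[[length(unm) + 1L]] <- observed[i, , drop = FALSE]
      next
    }
    ord <- ok[order(dm[ok], nchar(peptides$sequence[ok]))]
    j <- ord[1]
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = peptides$sequence[j], start = peptides$start[j],
      end = peptides$end[j], theor_mw = unname(theor[j]),
      exp_mw = observed$mass_da[i],
      delta_m = abs(theor[j] - observed$mass_da[i]),
      method = observed$method[i])
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(0), start = integer(0), end = integer(0),
               theor_mw = numeric(0), exp_mw = numeric(0),
               delta_m = numeric(0), method = character(0))
  rownames(res) <- NULL
  attr(res, "unmatched") <- if (length(unm)) do.call(rbind, unm) else NULL
  class(res) <- c("peptide_match_table", "data.frame")
  res
}

#' @export
print.peptide_match_table <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  df$theor_mw <- round(df$theor_mw, digits)
  df$delta_m <- round(df$delta_m, digits)
  print(df)
  un <- attr(x, "unmatched")
  if (!is.null(un)) cat(nrow(un), "observation(s) unmatched\n")
  invisible(x)
}

#' Sequence coverage from matched peptides
#'
#' The union of matched peptide intervals on the parent protein; peptides
#' seen by several methods and overlapping peptides are counted once.
#'
#' @param matches a `peptide_match_table` (or any data frame with `start`
#'   and `end` columns; rows with missing positions are located by string
#'   search in the protein).
#' @param protein a [protein_record()] or amino-acid string.
#' @return A list of class `coverage_result` with `covered_residues`,
#'   `protein_length`, and `fraction`.
#' @export
sequence_coverage <- function(matches, protein) {
  if (inherits(protein, "protein_record")) protein <- protein$sequence
  n <- nchar(protein)
  covered <- logical(n)
  for (i in seq_len(nrow(matches))) {
    s <- matches$start[i]; e <- matches$end[i]
    if (is.na(s) || is.na(e)) {
      hit <- regexpr(matches$peptide[i], protein, fixed = TRUE)
      if (hit < 0)
        stop("sequence_coverage: peptide ", matches$peptide[i],
             " not found in the protein")
      s <- as.integer(hit); e <- s + attr(hit, "match.length") - 1L
    }
    if (e > n) stop("sequence_coverage: peptide interval beyond protein end")
    covered[s:e] <- TRUE
  }
  structure(list(covered_residues = sum(covered), protein_length = n,
                 fraction = sum(covered) / n),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> %d / %d residues (%.1f%%)\n",
              x$covered_residues, x$protein_length, 100 * x$fraction))
  invisible(x)
}
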