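# Independent oracles used across the suite.  Each reimplements the checked
# computation by a different route (regex split, exhaustive enumeration,
# log-space arithmetic, closed forms) and never calls the package path it
# verifies.

# --- digestion oracle: regex split with lookbehind/lookahead --------------
digest_oracle <- function(protein) {
  strsplit(protein, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
}

# --- NG86 oracle: explicit per-codon enumeration --------------------------
.oracle_gc <- Biostrings::GENETIC_CODE
.oracle_stops <- names(.oracle_gc)[.oracle_gc == "*"]

oracle_syn_fraction <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (!(alt %in% .oracle_stops) &&
          .oracle_gc[[alt]] == .oracle_gc[[codon]]) s <- s + 1
    }
  }
  s / 3
}

oracle_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# pathway enumeration between two sense codons; stop-containing pathways
# dropped (all pathways used if every one is blocked, steps into stops
# counted nonsynonymous)
oracle_pair_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(pos)) return(c(nd = 0, sd = 0))
  walk <- function(ord, allow_stops) {
    cur <- a; nd <- 0; sd <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (nxt %in% .oracle_stops) {
        if (!allow_stops) return(NULL)
        nd <- nd + 1
      } else if (.oracle_gc[[nxt]] == .oracle_gc[[cur]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(nd = nd, sd = sd)
  }
  perms <- oracle_permutations(pos)
  paths <- Filter(Negate(is.null), lapply(perms, walk, allow_stops = FALSE))
  if (!length(paths)) paths <- lapply(perms, walk, allow_stops = TRUE)
  colMeans(do.call(rbind, paths))
}

oracle_ng86 <- function(codons_a, codons_b) {
  keep <- !(codons_a %in% .oracle_stops) & !(codons_b %in% .oracle_stops) &
    !grepl("[-N]", codons_a) & !grepl("[-N]", codons_b)
  codons_a <- codons_a[keep]; codons_b <- codons_b[keep]
  s_sites <- sum((vapply(codons_a, oracle_syn_fraction, numeric(1)) +
                  vapply(codons_b, oracle_syn_fraction, numeric(1))) / 2)
  d <- rowSums(vapply(seq_along(codons_a), function(i)
    oracle_pair_diffs(codons_a[i], codons_b[i]), numeric(2)))
  list(N_sites = 3 * length(codons_a) - s_sites, S_sites = s_sites,
       Nd = d[["nd"]], Sd = d[["sd"]])
}

random_sense_codons <- function(n) {
  sense <- names(.oracle_gc)[.oracle_gc != "*"]
  sample(sense, n, replace = TRUE)
}

# partner sequence at moderate divergence (keeps NG86 proportions well
# below the Jukes-Cantor saturation bound)
mutated_codons <- function(a, p_sub = 0.3) {
  sense <- names(.oracle_gc)[.oracle_gc != "*"]
  hit <- runif(length(a)) < p_sub
  a[hit] <- sample(sense, sum(hit), replace = TRUE)
  a
}

# --- misc ------------------------------------------------------------------
random_peptide <- function(n, residues = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(residues, n, replace = TRUE), collapse = "")
}

# closed-form pI for a sequence whose only ionizable groups are the termini
two_group_pi <- function(pk_n, pk_c) (pk_n + pk_c) / 2
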