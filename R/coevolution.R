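# Codon-level selection analysis.
#
# Nei-Gojobori (1986) counting: fractional synonymous/nonsynonymous site
# counts, difference counts averaged over all minimal mutational pathways
# (pathways through stop codons excluded), and Jukes-Cantor multiple-hit
# correction.  The regional statistic divides region-specific dN by the
# gene-wide dS, because synonymous sites inside antisense-miRNA footprints
# are themselves constrained and cannot serve as a neutral yardstick.

.ng_cache <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(.ng_cache$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .ng_cache$gc <- gc
    .ng_cache$sense <- names(gc)[gc != "*"]
    syn <- vapply(names(gc), function(cod) {
      if (gc[[cod]] == "*") return(NA_real_)
      s <- 0
      for (pos in 1:3) {
        for (nt in setdiff(c("A", "C", "G", "T"), substring(cod, pos, pos))) {
          alt <- cod
          substring(alt, pos, pos) <- nt
          # change to a stop codon counts as nonsynonymous
          if (gc[[alt]] != "*" && gc[[alt]] == gc[[cod]]) s <- s + 1 / 3
        }
      }
      s
    }, numeric(1))
    .ng_cache$syn_sites <- syn
  }
  .ng_cache
}

# all orderings of the differing positions between two codons; returns
# c(nd, sd) averaged over pathways that avoid stop codons (all pathways if
# every one is blocked).
codon_pair_diffs <- function(a, b) {
  tab <- codon_table()
  key <- paste(a, b)
  hit <- .ng_cache$pairs[[key]]
  if (!is.null(hit)) return(hit)
  gc <- tab$gc
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0L) {
    res <- c(nd = 0, sd = 0)
  } else {
    perms <- if (k == 1L) list(pos) else
      if (k == 2L) list(pos, rev(pos)) else
        lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
               function(o) pos[o])
    paths <- lapply(perms, function(ord) {
      cur <- a; nd <- 0; sd <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur
        substring(nxt, p, p) <- substring(b, p, p)
        if (gc[[nxt]] == "*") { blocked <- TRUE; break }
        if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      list(nd = nd, sd = sd, blocked = blocked)
    })
    ok <- Filter(function(p) !p$blocked, paths)
    if (!length(ok)) {
      # every ordering passes through a stop; count all orderings, steps
      # into stop codons scored as nonsynonymous
      ok <- lapply(perms, function(ord) {
        cur <- a; nd <- 0; sd <- 0
        for (p in ord) {
          nxt <- cur
          substring(nxt, p, p) <- substring(b, p, p)
          if (gc[[nxt]] == "*" || gc[[nxt]] != gc[[cur]]) nd <- nd + 1
          else sd <- sd + 1
          cur <- nxt
        }
        list(nd = nd, sd = sd)
      })
    }
    res <- c(nd = mean(vapply(ok, `[[`, numeric(1), "nd")),
             sd = mean(vapply(ok, `[[`, numeric(1), "sd")))
  }
  if (is.null(.ng_cache$pairs)) .ng_cache$pairs <- new.env(parent = emptyenv())
  assign(key, res, envir = .ng_cache$pairs)
  res
}

split_codons <- function(x) {
  n <- nchar(x)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

jc_correct <- function(p, what, pair) {
  if (p >= 0.75)
    stop("saturation: ", what, " proportion >= 0.75 for pair ", pair)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori pairwise substitution counts
#'
#' Counts fractional synonymous and nonsynonymous sites (averaged over the
#' two sequences) and differences (averaged over minimal mutational
#' pathways, stop-codon pathways excluded), then applies the Jukes-Cantor
#' correction `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param a,b in-frame coding sequences of equal length (strings or codon
#'   vectors).  Codons with a gap (`-`), an `N`, or a stop in either
#'   sequence are excluded pairwise.
#' @param labels length-2 character vector used in error messages.
#' @return A list of class `substitution_counts`: `N_sites, S_sites, Nd,
#'   Sd, pN, pS, dN, dS, codons_compared`.
#' @export
ng86_pairwise <- function(a, b, labels = c("a", "b")) {
  if (length(a) == 1L) a <- split_codons(toupper(a))
  if (length(b) == 1L) b <- split_codons(toupper(b))
  if (length(a) != length(b))
    stop("ng86_pairwise: sequences differ in codon count")
  tab <- codon_table()
  usable <- !grepl("[-N]", a) & !grepl("[-N]", b) &
    a %in% tab$sense & b %in% tab$sense
  a <- a[usable]; b <- b[usable]
  nc <- length(a)
  if (!nc) stop("ng86_pairwise: no comparable codons for pair ",
                paste(labels, collapse = " vs "))
  s_sites <- sum((tab$syn_sites[a] + tab$syn_sites[b]) / 2)
  n_sites <- 3 * nc - s_sites
  nd <- 0; sd_ <- 0
  for (i in seq_len(nc)) {
    d <- codon_pair_diffs(a[i], b[i])
    nd <- nd + d[["nd"]]; sd_ <- sd_ + d[["sd"]]
  }
  pn <- nd / n_sites
  ps <- sd_ / s_sites
  pair <- paste(labels, collapse = " vs ")
  structure(list(N_sites = n_sites, S_sites = s_sites, Nd = nd, Sd = sd_,
                 pN = pn, pS = ps,
                 dN = jc_correct(pn, "nonsynonymous", pair),
                 dS = jc_correct(ps, "synonymous", pair),
                 codons_compared = nc),
            class = "substitution_counts")
}

#' @export
print.substitution_counts <- function(x, ...) {
  cat(sprintf(
    "<substitution_counts> %d codons  N = %.2f S = %.2f  Nd = %.2f Sd = %.2f  dN = %.4f dS = %.4f\n",
    x$codons_compared, x$N_sites, x$S_sites, x$Nd, x$Sd, x$dN, x$dS))
  invisible(x)
}

#' Build a codon alignment object
#'
#' @param seqs named character vector of aligned coding sequences (gaps
#'   `-`), all the same length, a multiple of 3.
#' @param excluded_taxa_note free-text note on taxa deliberately left out.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(seqs, excluded_taxa_note = "") {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("codon_alignment: sequences must be named")
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("codon_alignment: rows differ in length")
  if (len %% 3L != 0L) stop("codon_alignment: length not divisible by 3")
  gc <- Biostrings::GENETIC_CODE
  for (t in names(seqs)) {
    s <- seqs[[t]]
    if (!grepl("-", s, fixed = TRUE)) {
      cods <- split_codons(s)
      aa <- gc[cods]
      if (any(aa == "*" & seq_along(aa) < length(aa), na.rm = TRUE))
        stop("codon_alignment: internal stop codon in ungapped row '", t, "'")
    }
  }
  structure(list(taxa = names(seqs), rows = unname(toupper(seqs)),
                 length = len, excluded_taxa_note = excluded_taxa_note),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment>", length(x$taxa), "taxa x", x$length, "nt (",
      x$length / 3, "codons )\n")
  invisible(x)
}

#' Read an aligned FASTA file as a codon alignment
#'
#' @param path aligned FASTA.
#' @inheritParams codon_alignment
#' @return A [codon_alignment()].
#' @export
read_alignment <- function(path, excluded_taxa_note = "") {
  codon_alignment(read_fasta(path, allow_gaps = TRUE),
                  excluded_taxa_note = excluded_taxa_note)
}

aln_codon_rows <- function(aln, codon_idx = NULL) {
  rows <- lapply(aln$rows, split_codons)
  if (!is.null(codon_idx)) rows <- lapply(rows, `[`, codon_idx)
  names(rows) <- aln$taxa
  rows
}

pairwise_counts <- function(rows) {
  taxa <- names(rows)
  combs <- utils::combn(length(taxa), 2)
  lapply(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    cnt <- ng86_pairwise(rows[[i]], rows[[j]], labels = taxa[c(i, j)])
    cnt$pair <- paste(taxa[i], taxa[j], sep = ":")
    cnt
  })
}

#' Gene-wide dN, dS and omega
#'
#' Averages pairwise NG86 dN and dS over all taxon pairs (unweighted) and
#' reports `omega = mean dN / mean dS`.
#'
#' @param aln a [codon_alignment()] with at least two taxa.
#' @return A list of class `gene_omega`: `dN, dS, omega, n_pairs` and a
#'   per-pair data frame `pairs`.
#' @export
gene_omega <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$taxa) < 2L) stop("gene_omega: need >= 2 taxa")
  cnts <- pairwise_counts(aln_codon_rows(aln))
  dn <- mean(vapply(cnts, `[[`, numeric(1), "dN"))
  ds <- mean(vapply(cnts, `[[`, numeric(1), "dS"))
  omega <- if (ds == 0) NA_real_ else dn / ds
  if (ds == 0) warning("gene_omega: mean dS is zero; omega undefined")
  pairs <- data.frame(
    pair = vapply(cnts, `[[`, "", "pair"),
    dN = vapply(cnts, `[[`, numeric(1), "dN"),
    dS = vapply(cnts, `[[`, numeric(1), "dS"))
  structure(list(dN = dn, dS = ds, omega = omega, n_pairs = length(cnts),
                 pairs = pairs),
            class = "gene_omega")
}

#' @export
print.gene_omega <- function(x, ...) {
  cat(sprintf("<gene_omega> dN = %.4f  dS = %.4f  omega = %.3f (%d pairs)\n",
              x$dN, x$dS, x$omega, x$n_pairs))
  invisible(x)
}

region_codon_index <- function(cds_start, cds_end) {
  seq.int((cds_start - 1L) %/% 3L + 1L, (cds_end - 1L) %/% 3L + 1L)
}

#' Region-specific dN over gene-wide dS
#'
#' Inside an antisense-miRNA footprint the synonymous sites are themselves
#' conserved, so the usual within-region dS is not a neutral baseline.
#' This statistic therefore divides the region-restricted dN by the
#' gene-wide dS.  Codons partially overlapped by the region are included
#' whole.
#'
#' @param aln a [codon_alignment()].
#' @param region a list or one-row data frame with `name`, `cds_start`,
#'   `cds_end` (1-based inclusive nt on the sense CDS/alignment).
#' @param gene optional precomputed [gene_omega()] result (computed from
#'   `aln` when missing).
#' @return A list of class `regional_selection`: `region, dN_region,
#'   dS_gene, rho, omega_gene, classification`.
#' @export
regional_ratio <- function(aln, region, gene = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(gene)) gene <- gene_omega(aln)
  if (is.na(gene$omega) || gene$dS == 0)
    stop("regional_ratio: gene-wide dS is zero")
  if (region$cds_end - region$cds_start + 1L < 3L)
    stop("regional_ratio: region '", region$name, "' shorter than one codon")
  if (region$cds_start < 1L || region$cds_end > aln$length)
    stop("regional_ratio: region '", region$name, "' outside the alignment")
  idx <- region_codon_index(region$cds_start, region$cds_end)
  cnts <- pairwise_counts(aln_codon_rows(aln, idx))
  dn <- mean(vapply(cnts, `[[`, numeric(1), "dN"))
  rho <- dn / gene$dS
  cls <- if (rho > 1) "relaxed"
  else if (rho < gene$omega) "enhanced-purifying"
  else "neutral-like"
  structure(list(region = region, dN_region = dn, dS_gene = gene$dS,
                 rho = rho, omega_gene = gene$omega, classification = cls),
            class = "regional_selection")
}

#' @export
print.regional_selection <- function(x, ...) {
  cat(sprintf("<regional_selection> %s: dN = %.4f / gene dS = %.4f -> rho = %.3f (gene omega %.3f) [%s]\n",
              x$region$name, x$dN_region, x$dS_gene, x$rho, x$omega_gene,
              x$classification))
  invisible(x)
}

#' Regional selection table over a set of annotations
#'
#' @param aln a [codon_alignment()].
#' @param regions data frame with columns `name, cds_start, cds_end`.
#' @return Data frame with one row per region: `name, cds_start, cds_end,
#'   dN_region, dS_gene, rho, omega_gene, classification`.
#' @export
regional_ratio_table <- function(aln, regions) {
  gene <- gene_omega(aln)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regional_ratio(aln, as.list(regions[i, ]), gene = gene)
    data.frame(name = regions$name[i], cds_start = regions$cds_start[i],
               cds_end = regions$cds_end[i], dN_region = r$dN_region,
               dS_gene = r$dS_gene, rho = r$rho, omega_gene = r$omega_gene,
               classification = r$classification)
  })
  do.call(rbind, rows)
}

#' Window-smoothed conservation profile of an alignment
#'
#' Per column, the fraction of taxon pairs with identical non-gap bases,
#' smoothed by a centred moving average, with maximal runs above a
#' threshold reported as conserved intervals.  This is a deliberately
#' simple identity-based profile standing where a phylogenetic
#' hidden-Markov conservation model would be used on real genome-browser
#' data.
#'
#' @param aln a [codon_alignment()] (>= 2 taxa).
#' @param window moving-average width in columns (default 25; clamped with
#'   a warning when wider than the alignment).
#' @param threshold smoothed-score threshold defining conserved intervals
#'   (default 0.9).
#' @return A list of class `conservation_profile`: `window, threshold,
#'   scores` (raw per-column), `smoothed`, and data frame
#'   `conserved_intervals` (`start, end`).
#' @export
conservation_profile <- function(aln, window = 25L, threshold = 0.9) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$taxa) < 2L) stop("conservation_profile: need >= 2 taxa")
  mat <- do.call(rbind, strsplit(aln$rows, ""))
  ncol_ <- ncol(mat)
  if (window > ncol_) {
    warning("conservation_profile: window wider than alignment; clamped")
    window <- ncol_
  }
  combs <- utils::combn(nrow(mat), 2)
  scores <- vapply(seq_len(ncol_), function(j) {
    col <- mat[, j]
    ok <- which(col != "-")
    valid <- 0L; same <- 0L
    for (k in seq_len(ncol(combs))) {
      i1 <- combs[1, k]; i2 <- combs[2, k]
      if (col[i1] != "-" && col[i2] != "-") {
        valid <- valid + 1L
        if (col[i1] == col[i2]) same <- same + 1L
      }
    }
    if (valid == 0L) NA_real_ else same / valid
  }, numeric(1))
  half <- (window - 1L) %/% 2L
  smoothed <- vapply(seq_len(ncol_), function(j) {
    lo <- max(1L, j - half); hi <- min(ncol_, j + half)
    mean(scores[lo:hi], na.rm = TRUE)
  }, numeric(1))
  above <- !is.na(smoothed) & smoothed >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  structure(list(window = window, threshold = threshold, scores = scores,
                 smoothed = smoothed, conserved_intervals = iv),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d columns, window %d, %d interval(s) >= %.2f\n",
              length(x$scores), x$window, nrow(x$conserved_intervals),
              x$threshold))
  invisible(x)
}

jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
  uni <- (e1 - s1 + 1L) + (e2 - s2 + 1L) - inter
  inter / uni
}

#' Concordance between conserved intervals and annotated regions
#'
#' For each conserved interval, the Jaccard overlap with its
#' best-overlapping (else nearest) annotated region, plus the overall
#' fraction of conserved columns lying inside any region.
#'
#' @param profile a [conservation_profile()].
#' @param regions data frame with `name, cds_start, cds_end` (alignment
#'   coordinates).
#' @return A list of class `concordance_report`: data frame `intervals`
#'   (`start, end, nearest_region, jaccard`) and scalar
#'   `fraction_in_regions`.
#' @export
region_concordance <- function(profile, regions) {
  iv <- profile$conserved_intervals
  if (!nrow(iv)) {
    return(structure(list(
      intervals = data.frame(start = integer(0), end = integer(0),
                             nearest_region = character(0),
                             jaccard = numeric(0)),
      fraction_in_regions = NA_real_), class = "concordance_report"))
  }
  rows <- lapply(seq_len(nrow(iv)), function(i) {
    jac <- vapply(seq_len(nrow(regions)), function(k)
      jaccard(iv$start[i], iv$end[i], regions$cds_start[k],
              regions$cds_end[k]), numeric(1))
    dist <- vapply(seq_len(nrow(regions)), function(k)
      max(0L, max(regions$cds_start[k] - iv$end[i],
                  iv$start[i] - regions$cds_end[k])), numeric(1))
    best <- if (any(jac > 0)) which.max(jac) else which.min(dist)
    data.frame(start = iv$start[i], end = iv$end[i],
               nearest_region = regions$name[best], jaccard = jac[best])
  })
  cons_cols <- unlist(lapply(seq_len(nrow(iv)), function(i)
    iv$start[i]:iv$end[i]))
  reg_cols <- unlist(lapply(seq_len(nrow(regions)), function(k)
    regions$cds_start[k]:regions$cds_end[k]))
  structure(list(intervals = do.call(rbind, rows),
                 fraction_in_regions = mean(cons_cols %in% reg_cols)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  print(x$intervals)
  cat(sprintf("fraction of conserved columns inside annotated regions: %.3f\n",
              x$fraction_in_regions))
  invisible(x)
}
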