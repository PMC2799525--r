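# Sequence and coordinate plumbing shared by every analysis stage.
#
# Coordinate convention: 1-based, inclusive, everywhere.  A primer printed
# as "(151950-151930)" (descending) anchors on the minus strand; its first
# printed coordinate is the 5' terminus.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' A protein sequence record
#'
#' @param id record identifier.
#' @param sequence one-letter amino-acid string (20 standard residues).
#' @param source free-text provenance note.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, source = "") {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("protein_record: empty sequence for '", id, "'")
  bad <- setdiff(strsplit(sequence, "")[[1]], c(AA_ALPHABET, "X"))
  if (length(bad))
    stop("protein_record: non-standard residue(s) ", paste(bad, collapse = ","),
         " in '", id, "'")
  if (grepl("\\*", sequence)) stop("protein_record: internal stop in '", id, "'")
  structure(list(id = id, sequence = sequence, source = source),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$id, "-", nchar(x$sequence), "aa\n")
  invisible(x)
}

#' A coding-sequence record
#'
#' @param id record identifier.
#' @param sequence nucleotide string (ACGT, N allowed).
#' @param frame_offset number of leading nucleotides to trim before
#'   translation (default 0).
#' @return An object of class `cds_record`.
#' @export
cds_record <- function(id, sequence, frame_offset = 0L) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("cds_record: empty sequence for '", id, "'")
  bad <- setdiff(strsplit(sequence, "")[[1]], c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("cds_record: non-nucleotide symbol(s) ", paste(bad, collapse = ","),
         " in '", id, "'")
  if ((nchar(sequence) - frame_offset) %% 3L != 0L)
    stop("cds_record: length minus frame_offset not divisible by 3 for '",
         id, "'")
  structure(list(id = id, sequence = sequence,
                 frame_offset = as.integer(frame_offset)),
            class = "cds_record")
}

#' Read sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; a light
#' pre-validation pass reports malformed headers or empty records with the
#' offending line number.
#'
#' @param path FASTA file.
#' @param type `"protein"`, `"dna"`, or `"auto"` (guess from the alphabet).
#' @param allow_gaps keep `-` characters (multi-sequence alignment mode);
#'   rejected otherwise.
#' @return A list of [protein_record()] or [cds_record()] objects, or, when
#'   `allow_gaps = TRUE`, a named character vector of (gapped) sequences.
#' @export
read_fasta <- function(path, type = c("auto", "protein", "dna"),
                       allow_gaps = FALSE) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("read_fasta: ", path, " is empty")
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("read_fasta: line ", nonblank[1], " of ", path,
         " is not a FASTA header")
  hdr <- which(startsWith(trimws(lines), ">"))
  for (h in hdr) {
    if (!nzchar(trimws(sub("^>", "", lines[h]))))
      stop("read_fasta: empty header at line ", h, " of ", path)
    nxt <- c(hdr, length(lines) + 1L)[match(h, hdr) + 1L]
    body <- lines[seq(h + 1L, length.out = max(0L, nxt - h - 1L))]
    if (!any(nzchar(trimws(body))))
      stop("read_fasta: record at line ", h, " of ", path,
           " has an empty sequence")
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (allow_gaps) return(seqs)
  if (any(grepl("-", seqs, fixed = TRUE)))
    stop("read_fasta: gap characters found; use allow_gaps = TRUE for alignments")
  lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    is_dna <- all(strsplit(s, "")[[1]] %in% c("A", "C", "G", "T", "N"))
    if (type == "dna" || (type == "auto" && is_dna))
      cds_try(names(seqs)[i], s, path)
    else protein_record(names(seqs)[i], s, source = path)
  })
}

# DNA-looking records that are not a multiple of 3 are still readable; the
# frame check happens at translation time.
cds_try <- function(id, s, src) {
  rec <- list(id = id, sequence = s, frame_offset = 0L)
  class(rec) <- "cds_record"
  rec
}

#' Write records to a FASTA file
#'
#' @param records a list of `protein_record`/`cds_record` objects or a named
#'   character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.list(records) && !is.null(records$sequence)) records <- list(records)
  if (is.character(records)) {
    ids <- names(records); seqs <- unname(records)
  } else {
    ids <- vapply(records, `[[`, "", "id")
    seqs <- vapply(records, `[[`, "", "sequence")
  }
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse-complement a nucleotide string
#'
#' @param x nucleotide string.
#' @return The reverse complement, as a character string.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate an open reading frame
#'
#' Standard genetic code; a terminal stop codon is removed; an internal stop
#' is an error (a truncated ORF).  Codons containing `N` translate to `X`.
#'
#' @param cds a [cds_record()].
#' @return A [protein_record()].
#' @export
translate_orf <- function(cds) {
  stopifnot(inherits(cds, "cds_record"))
  s <- substring(cds$sequence, cds$frame_offset + 1L)
  if (nchar(s) %% 3L != 0L)
    stop("translate_orf: length not divisible by 3 for '", cds$id, "'")
  if (substring(s, 1L, 3L) != "ATG")
    warning("translate_orf: '", cds$id, "' does not start with ATG")
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  gc <- Biostrings::GENETIC_CODE
  aa <- ifelse(grepl("N", codons), "X", unname(gc[codons]))
  if (anyNA(aa)) stop("translate_orf: unrecognised codon in '", cds$id, "'")
  stops <- which(aa == "*")
  if (length(stops) && any(stops < length(aa)))
    stop("translate_orf: truncated ORF in '", cds$id, "': internal stop at codon ",
         stops[stops < length(aa)][1])
  if (length(stops)) aa <- aa[-length(aa)]
  protein_record(cds$id, paste(aa, collapse = ""),
                 source = paste0("translated ", nchar(s), " bp ORF"))
}

#' A 1-based inclusive genomic interval
#'
#' @param seq_id sequence/accession name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(seq_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L) stop("genomic_interval: start must be >= 1")
  if (end < start) stop("genomic_interval: end < start")
  if (!strand %in% c("+", "-")) stop("genomic_interval: strand must be + or -")
  structure(list(seq_id = seq_id, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' A qPCR primer pair with genomic anchors
#'
#' Anchor coordinates are stored as printed, 5' coordinate first: a
#' descending pair denotes a minus-strand anchor.  Tails are non-genomic 5'
#' additions (restriction sites, affinity tags) that extend the amplicon but
#' have no genomic footprint.
#'
#' @param name assay name.
#' @param fwd_seq,rev_seq primer sequences (tails included).
#' @param fwd_start,fwd_end,rev_start,rev_end anchor coordinates as printed
#'   (5' first; descending = minus strand).
#' @param fwd_tail,rev_tail tail lengths in nt (default 0).
#' @param seq_id accession the anchors refer to.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(name, fwd_seq = "", rev_seq = "",
                        fwd_start, fwd_end, rev_start, rev_end,
                        fwd_tail = 0L, rev_tail = 0L, seq_id = "") {
  fwd_tail <- as.integer(fwd_tail); rev_tail <- as.integer(rev_tail)
  if (nzchar(fwd_seq) && fwd_tail >= nchar(fwd_seq))
    stop("primer_pair: fwd tail not shorter than the primer")
  if (nzchar(rev_seq) && rev_tail >= nchar(rev_seq))
    stop("primer_pair: rev tail not shorter than the primer")
  structure(list(name = name, fwd_seq = fwd_seq, rev_seq = rev_seq,
                 fwd_start = as.integer(fwd_start), fwd_end = as.integer(fwd_end),
                 rev_start = as.integer(rev_start), rev_end = as.integer(rev_end),
                 fwd_tail = fwd_tail, rev_tail = rev_tail, seq_id = seq_id),
            class = "primer_pair")
}

#' Amplicon length from primer anchors
#'
#' The genomic span is counted inclusively between the two primers' 5'
#' (outermost) coordinates; non-genomic 5' tails are added on top.  The
#' result is symmetric in primer order.  An error is raised when both
#' primers point away from each other (divergent orientation).
#'
#' @param pair a [primer_pair()].
#' @return Amplicon length in bp (integer).
#' @export
amplicon_length <- function(pair) {
  stopifnot(inherits(pair, "primer_pair"))
  f5 <- pair$fwd_start; f3 <- pair$fwd_end
  r5 <- pair$rev_start; r3 <- pair$rev_end
  # each primer extends 5'->3'; divergent = both extend away from the other
  away <- function(p5, p3, other) sign(p3 - p5) != 0 &&
    sign(p3 - p5) == -sign(other - p5)
  if (away(f5, f3, r5) && away(r5, r3, f5))
    stop("amplicon_length: divergent primers in '", pair$name, "'")
  abs(f5 - r5) + 1L + pair$fwd_tail + pair$rev_tail
}

#' Read a primer definition CSV
#'
#' Columns: `name,fwd_seq,rev_seq,fwd_start,fwd_end,rev_start,rev_end,
#' fwd_tail,rev_tail` (coordinates as printed, 5' first).
#'
#' @param path CSV file.
#' @return A list of [primer_pair()] objects.
#' @export
read_primers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "fwd_seq", "rev_seq", "fwd_start", "fwd_end",
            "rev_start", "rev_end", "fwd_tail", "rev_tail")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_primers: missing column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    primer_pair(df$name[i], df$fwd_seq[i], df$rev_seq[i],
                df$fwd_start[i], df$fwd_end[i], df$rev_start[i], df$rev_end[i],
                df$fwd_tail[i], df$rev_tail[i]))
}

#' Read a BED-like region annotation file
#'
#' Four tab-separated columns `seq_id, start, end, name`; coordinates are
#' 1-based inclusive (not BED half-open).
#'
#' @param path tab-separated file.
#' @return A data frame with columns `seq_id, start, end, name`.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("seq_id", "start", "end", "name"))
  if (any(df$start < 1L) || any(df$end < df$start))
    stop("read_regions: invalid interval in ", path)
  df
}

#' Project an antisense genomic interval onto sense CDS coordinates
#'
#' The interval (typically an antisense miRNA footprint) is projected onto
#' the 1-based coordinate system of the sense-strand CDS anchored at
#' `cds_anchor`; ends are flipped so that start <= end.  The mapping is
#' inverted exactly by [map_cds_to_genomic()].
#'
#' @param iv a [genomic_interval()] inside the CDS anchor.
#' @param cds_anchor a [genomic_interval()] giving the genomic footprint and
#'   strand of the sense CDS.
#' @return Integer vector `c(cds_start, cds_end)`.
#' @export
map_antisense_interval <- function(iv, cds_anchor) {
  stopifnot(inherits(iv, "genomic_interval"),
            inherits(cds_anchor, "genomic_interval"))
  if (iv$start < cds_anchor$start || iv$end > cds_anchor$end)
    stop("map_antisense_interval: interval outside the CDS span")
  if (cds_anchor$strand == "+") {
    out <- c(iv$start - cds_anchor$start + 1L, iv$end - cds_anchor$start + 1L)
  } else {
    out <- c(cds_anchor$end - iv$end + 1L, cds_anchor$end - iv$start + 1L)
  }
  stats::setNames(out, c("cds_start", "cds_end"))
}

#' Inverse of [map_antisense_interval()]
#'
#' @param cds_start,cds_end 1-based inclusive CDS coordinates.
#' @param cds_anchor the CDS genomic anchor interval.
#' @return A [genomic_interval()] on the genome.
#' @export
map_cds_to_genomic <- function(cds_start, cds_end, cds_anchor) {
  stopifnot(inherits(cds_anchor, "genomic_interval"))
  len <- cds_anchor$end - cds_anchor$start + 1L
  if (cds_start < 1L || cds_end > len || cds_end < cds_start)
    stop("map_cds_to_genomic: CDS coordinates out of range")
  if (cds_anchor$strand == "+") {
    genomic_interval(cds_anchor$seq_id,
                     cds_anchor$start + cds_start - 1L,
                     cds_anchor$start + cds_end - 1L, "+")
  } else {
    genomic_interval(cds_anchor$seq_id,
                     cds_anchor$end - cds_end + 1L,
                     cds_anchor$end - cds_start + 1L, "-")
  }
}
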