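#' Map read pairs against the consensus with the internal seed-and-extend
#' aligner
#'
#' Exact k-mer seeds against the circular consensus propose candidate
#' placements; each candidate is scored by full-length ungapped extension
#' (+1 match / -2 mismatch) on both strands and the best placement is
#' reported. Mapping quality is 60 for a unique best placement, 0 for a tie,
#' and otherwise `min(60, 6 * score gap)` to the runner-up. Reads scoring
#' below `min_score_frac * read_length` (or seeding nowhere, e.g. host-DNA
#' contamination) are unmapped. The aligner is substitution-only: reads
#' requiring gapped alignment go unmapped.
#'
#' @param pairs A `read_pairs` data frame.
#' @param consensus A [build_consensus()] result, or a plain character
#'   scalar reference sequence.
#' @param k Seed k-mer length (default 21).
#' @param min_score_frac Minimum alignment score as a fraction of read
#'   length (default 0.5, i.e. at most one mismatch per six bases).
#' @return An object of class `read_alignments`: data frame with columns
#'   `id` (pair index), `mate`, `start` (1-based consensus coordinate of the
#'   leftmost aligned base; alignments may wrap past the origin), `strand`,
#'   `mapq`, `seq` and `qual` (both oriented to the reference). Attributes
#'   `consensus_length`, `n_pairs_total` and `n_pairs_mapped` (pairs with at
#'   least one mapped mate) carry the mapping report.
#' @export
map_reads <- function(pairs, consensus, k = 21, min_score_frac = 0.5) {
  stopifnot(inherits(pairs, "read_pairs"))
  ref <- consensus_string(consensus)
  L <- nchar(ref)
  if (nrow(pairs) && L < max(nchar(pairs$seq1), nchar(pairs$seq2)))
    stop("consensus shorter than the reads")
  res1 <- map_reads_cpp(ref, pairs$seq1, as.integer(k), min_score_frac)
  res2 <- map_reads_cpp(ref, pairs$seq2, as.integer(k), min_score_frac)
  build_mate <- function(res, seqs, quals, mate) {
    idx <- which(res$mapped)
    if (!length(idx)) return(NULL)
    minus <- res$strand[idx] == "-"
    seq <- seqs[idx]
    qual <- quals[idx]
    if (any(minus)) {
      seq[minus] <- revcomp_chr(seq[minus])
      qual[minus] <- reverse_strings(qual[minus])
    }
    data.frame(id = idx, mate = mate, start = res$start[idx],
               strand = res$strand[idx], mapq = res$mapq[idx],
               seq = seq, qual = qual, stringsAsFactors = FALSE)
  }
  aln <- rbind(build_mate(res1, pairs$seq1, pairs$qual1, 1L),
               build_mate(res2, pairs$seq2, pairs$qual2, 2L))
  if (is.null(aln))
    aln <- data.frame(id = integer(), mate = integer(), start = integer(),
                      strand = character(), mapq = integer(),
                      seq = character(), qual = character(),
                      stringsAsFactors = FALSE)
  aln <- aln[order(aln$id, aln$mate), , drop = FALSE]
  rownames(aln) <- NULL
  class(aln) <- c("read_alignments", "data.frame")
  attr(aln, "consensus_length") <- L
  attr(aln, "n_pairs_total") <- nrow(pairs)
  attr(aln, "n_pairs_mapped") <- length(unique(aln$id))
  aln
}

consensus_string <- function(consensus) {
  if (inherits(consensus, "consensus_sequence")) consensus$sequence
  else if (is.character(consensus) && length(consensus) == 1L) consensus
  else stop("'consensus' must be a consensus_sequence or a character scalar")
}

reverse_strings <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

#' Write alignment records as SAM
#'
#' Emits a minimal SAM 1.6 file against the consensus as the single
#' reference contig. Because SAM references are linear, alignments that span
#' the circular origin are written with their wrapped tail soft-clipped;
#' their first segment keeps its coordinate.
#'
#' @param alignments A `read_alignments` data frame.
#' @param path Output SAM path.
#' @param contig Reference name (default `"consensus"`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, contig = "consensus") {
  stopifnot(inherits(alignments, "read_alignments"))
  L <- attr(alignments, "consensus_length")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               paste0("@SQ\tSN:", contig, "\tLN:", L)), con)
  if (nrow(alignments)) {
    a <- alignments
    len <- nchar(a$seq)
    aligned <- pmin(len, L - a$start + 1L)
    cigar <- ifelse(aligned == len, paste0(len, "M"),
                    paste0(aligned, "M", len - aligned, "S"))
    flag <- 1L + ifelse(a$strand == "-", 16L, 0L) +
      ifelse(a$mate == 1L, 64L, 128L)
    qname <- sprintf("pair_%07d", a$id)
    writeLines(paste(qname, flag, contig, a$start, a$mapq, cigar,
                     "*", 0L, 0L, a$seq, a$qual, sep = "\t"), con)
  }
  invisible(path)
}

#' Import alignments from SAM/BAM
#'
#' Converts records to the internal alignment representation used by
#' [pileup()]. Secondary and supplementary records are dropped; MAPQ 255
#' ("unavailable" by SAM convention) becomes `NA` and is removed by the
#' pileup MAPQ filter. Soft- and hard-clipped bases are trimmed; records
#' whose CIGAR contains indel or skip operations are dropped (counted in
#' the `n_dropped_cigar` attribute) since the pipeline is substitution-only.
#'
#' @param path SAM or BAM file. SAM input is converted with
#'   [Rsamtools::asBam()].
#' @param consensus A [build_consensus()] result (or character scalar) used
#'   to validate the reference length.
#' @return A `read_alignments` data frame (see [map_reads()]).
#' @export
import_sam <- function(path, consensus) {
  ref <- consensus_string(consensus)
  L <- nchar(ref)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (length(hdr) != 1L || hdr[[1]] != L)
    stop("reference length mismatch: SAM header says ",
         paste(hdr, collapse = ","), ", consensus is ", L, " bp")
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(rec$pos) &
    bitwAnd(rec$flag, 256L) == 0L & bitwAnd(rec$flag, 2048L) == 0L
  qname <- rec$qname[keep]
  flag <- rec$flag[keep]
  pos <- rec$pos[keep]
  mapq <- rec$mapq[keep]
  mapq[!is.na(mapq) & mapq == 255L] <- NA_integer_
  cigar <- rec$cigar[keep]
  seq <- as.character(rec$seq)[keep]
  qual <- as.character(rec$qual)[keep]

  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  parsed <- lapply(ops, function(o) {
    data.frame(n = as.integer(sub("[A-Z=]$", "", o)),
               op = sub("^\\d+", "", o), stringsAsFactors = FALSE)
  })
  simple <- vapply(parsed, function(p) all(p$op %in% c("M", "=", "X", "S",
                                                       "H")), TRUE)
  n_dropped <- sum(!simple)
  out <- vector("list", sum(simple))
  oi <- 0L
  for (i in which(simple)) {
    p <- parsed[[i]]
    lead <- 0L
    j <- 1L
    while (j <= nrow(p) && p$op[j] %in% c("S", "H")) {
      if (p$op[j] == "S") lead <- lead + p$n[j]
      j <- j + 1L
    }
    m <- sum(p$n[p$op %in% c("M", "=", "X")])
    if (m == 0L) next
    oi <- oi + 1L
    out[[oi]] <- data.frame(
      id = qname[i],
      mate = if (bitwAnd(flag[i], 128L) > 0L) 2L else 1L,
      start = pos[i],
      strand = if (bitwAnd(flag[i], 16L) > 0L) "-" else "+",
      mapq = mapq[i],
      seq = substr(seq[i], lead + 1L, lead + m),
      qual = substr(qual[i], lead + 1L, lead + m),
      stringsAsFactors = FALSE)
  }
  aln <- if (oi) do.call(rbind, out[seq_len(oi)]) else
    data.frame(id = character(), mate = integer(), start = integer(),
               strand = character(), mapq = integer(), seq = character(),
               qual = character(), stringsAsFactors = FALSE)
  aln$id <- match(aln$id, unique(aln$id))
  aln <- aln[order(aln$id, aln$mate), , drop = FALSE]
  rownames(aln) <- NULL
  class(aln) <- c("read_alignments", "data.frame")
  attr(aln, "consensus_length") <- L
  attr(aln, "n_pairs_total") <- length(unique(qname))
  attr(aln, "n_pairs_mapped") <- length(unique(aln$id))
  attr(aln, "n_dropped_cigar") <- n_dropped
  aln
}

#' Per-position base counts from alignment records
#'
#' Accumulates A/C/G/T/N counts per consensus position over all alignment
#' records passing the mapping-quality filter. When both mates of a fragment
#' cover a position, the base from the mate with the higher Phred quality at
#' that position is counted once, so overlapping mates never double-count a
#' fragment.
#'
#' @param alignments A `read_alignments` data frame.
#' @param consensus A [build_consensus()] result or character scalar; its
#'   length defines the coordinate circle.
#' @param min_mapq Minimum mapping quality (default 30); records with `NA`
#'   MAPQ are excluded.
#' @param dedup_mates Count overlapping mate positions once per fragment
#'   (default `TRUE`).
#' @return An object of class `pileup_table`: integer matrix (positions x
#'   `A,C,G,T,N`) with attribute `consensus_length`.
#' @export
pileup <- function(alignments, consensus, min_mapq = 30, dedup_mates = TRUE) {
  stopifnot(inherits(alignments, "read_alignments"))
  L <- nchar(consensus_string(consensus))
  a <- alignments[!is.na(alignments$mapq) & alignments$mapq >= min_mapq, ,
                  drop = FALSE]
  if (nrow(a) && max(a$start) > L)
    stop("alignment start beyond consensus length (invariant breach)")
  a <- a[order(a$id, a$mate), , drop = FALSE]
  counts <- pileup_cpp(as.integer(a$id), as.integer(a$start),
                       a$seq, a$qual, L, isTRUE(dedup_mates))
  colnames(counts) <- c(DNA_BASES4, "N")
  structure(counts, class = "pileup_table", consensus_length = L)
}

#' @export
print.pileup_table <- function(x, ...) {
  depth <- rowSums(unclass(x))
  cat("pileup_table:", nrow(x), "positions; mean depth",
      round(mean(depth), 1), "\n")
  invisible(x)
}
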