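#' Write read pairs to paired FASTQ files (Phred+33)
#'
#' @param pairs A `read_pairs` data frame (`id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @param fq1,fq2 Output paths for mate 1 and mate 2.
#' @return `c(fq1, fq2)`, invisibly.
#' @export
write_reads_fastq <- function(pairs, fq1, fq2) {
  stopifnot(inherits(pairs, "read_pairs"))
  write_one <- function(seqs, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- pairs$id
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(pairs$seq1, pairs$qual1, fq1)
  write_one(pairs$seq2, pairs$qual2, fq2)
  invisible(c(fq1, fq2))
}

#' Read paired FASTQ files into a read-pair table
#'
#' @param fq1,fq2 Paths to mate-1 and mate-2 FASTQ files (Phred+33; gzip is
#'   handled transparently). Records must be in matching order.
#' @return A `read_pairs` data frame.
#' @export
read_fastq_pairs <- function(fq1, fq2) {
  r1 <- Biostrings::readDNAStringSet(fq1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fq2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("mate files contain different numbers of records (",
         length(r1), " vs ", length(r2), ")")
  id1 <- sub("\\s.*$", "", names(r1))
  id2 <- sub("\\s.*$", "", names(r2))
  id1 <- sub("/1$", "", id1)
  id2 <- sub("/2$", "", id2)
  if (!identical(id1, id2))
    stop("mate files are not in matching record order")
  pairs <- data.frame(id = id1,
                      seq1 = unname(as.character(r1)),
                      qual1 = as.character(S4Vectors::mcols(r1)$qualities),
                      seq2 = unname(as.character(r2)),
                      qual2 = as.character(S4Vectors::mcols(r2)$qualities),
                      stringsAsFactors = FALSE, row.names = NULL)
  class(pairs) <- c("read_pairs", "data.frame")
  pairs
}

phred_ge_fraction <- function(quals, q_threshold) {
  q <- methods::as(Biostrings::PhredQuality(quals), "IntegerList")
  as.numeric(sum(q >= q_threshold)) / lengths(q)
}

#' Filter read pairs by base quality
#'
#' A pair is kept iff, for each mate, the fraction of bases with Phred
#' quality at or above `q_threshold` is at least `min_fraction` (boundary
#' inclusive: a mate with exactly half its bases at Q30 passes the
#' defaults).
#'
#' @param pairs A `read_pairs` data frame.
#' @param q_threshold Phred threshold (default 30, base-call accuracy
#'   99.9%).
#' @param min_fraction Minimum fraction of bases at or above the threshold
#'   (default 0.5).
#' @return The kept `read_pairs`, with a `filter_report` attribute listing
#'   `n_input`, `n_kept` and `n_discarded`.
#' @export
quality_filter_reads <- function(pairs, q_threshold = 30, min_fraction = 0.5) {
  stopifnot(inherits(pairs, "read_pairs"))
  if (nrow(pairs) == 0L) {
    attr(pairs, "filter_report") <-
      list(n_input = 0L, n_kept = 0L, n_discarded = 0L)
    return(pairs)
  }
  keep <- phred_ge_fraction(pairs$qual1, q_threshold) >= min_fraction &
          phred_ge_fraction(pairs$qual2, q_threshold) >= min_fraction
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_pairs", "data.frame")
  attr(out, "filter_report") <- list(n_input = nrow(pairs),
                                     n_kept = sum(keep),
                                     n_discarded = sum(!keep))
  out
}
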