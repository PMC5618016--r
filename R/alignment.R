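#' Construct a multi-genome alignment object
#'
#' Holds a gapped whole-genome alignment of reference isolates, one row per
#' taxon, together with the genome-group label each taxon represents. This is
#' the input for consensus construction and lineage-specific SNP
#' classification.
#'
#' @param seqs Named character vector of aligned sequences (equal lengths,
#'   alphabet `A/C/G/T/N/-`); names are taxon (isolate) labels.
#' @param groups Named character vector mapping each taxon label to its
#'   genome-group label (e.g. `"A"`..`"E"`). Group labels must be unique:
#'   each group is represented by exactly one reference genome.
#' @return An object of class `genome_alignment` with elements `labels`,
#'   `groups` (named by taxon), `seqs` (named character) and `width`.
#' @export
genome_alignment <- function(seqs, groups) {
  if (length(seqs) < 2L)
    stop("alignment must contain at least 2 taxa")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique taxon names")
  seqs <- toupper(seqs)
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("format error: aligned records have unequal lengths (",
         paste(sort(w), collapse = ", "), ")")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("invalid characters in record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  if (is.null(names(groups)))
    stop("config error: 'groups' must be named by taxon label")
  missing <- setdiff(names(seqs), names(groups))
  if (length(missing))
    stop("config error: no group label for taxa: ",
         paste(missing, collapse = ", "))
  groups <- groups[names(seqs)]
  if (anyDuplicated(groups))
    stop("config error: duplicate genome-group label: ",
         paste(unique(groups[duplicated(groups)]), collapse = ", "))
  structure(
    list(labels = names(seqs), groups = groups, seqs = seqs, width = w),
    class = "genome_alignment"
  )
}

#' Read a multi-genome alignment from aligned FASTA
#'
#' @param path Aligned FASTA file (gap character `-`). All records must have
#'   identical lengths.
#' @param groups Either a named character vector mapping record IDs to
#'   genome-group labels, or the path to a two-column tab-separated sidecar
#'   file (`taxon<TAB>group`, no header).
#' @return A [genome_alignment()] with taxa in file order.
#' @export
read_alignment <- function(path, groups) {
  ss <- Biostrings::readDNAStringSet(path)
  if (is.character(groups) && length(groups) == 1L && is.null(names(groups)) &&
      file.exists(groups)) {
    tab <- read.delim(groups, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("taxon", "group"))
    groups <- setNames(as.character(tab$group), tab$taxon)
  }
  # keep only the first whitespace-delimited token of each FASTA header
  nm <- sub("\\s.*$", "", names(ss))
  seqs <- setNames(as.character(ss), nm)
  genome_alignment(seqs, groups)
}

#' Write a multi-genome alignment to aligned FASTA
#'
#' @param aln A [genome_alignment()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "genome_alignment"))
  ss <- Biostrings::DNAStringSet(aln$seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @export
print.genome_alignment <- function(x, ...) {
  cat("genome_alignment:", length(x$labels), "taxa x", x$width, "columns\n")
  cat("  groups:", paste(sprintf("%s=%s", x$labels, x$groups), collapse = ", "),
      "\n")
  invisible(x)
}

# character matrix view (taxa x columns), used by SNP classification
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$labels
  m
}

# per-column counts of A,C,G,T,N,- over taxa
aln_base_counts <- function(aln) {
  ss <- Biostrings::DNAStringSet(aln$seqs)
  cm <- Biostrings::consensusMatrix(ss)
  need <- c(DNA_BASES4, "N", "-")
  out <- matrix(0L, nrow = length(need), ncol = aln$width,
                dimnames = list(need, NULL))
  have <- intersect(need, rownames(cm))
  out[have, ] <- cm[have, , drop = FALSE]
  # anything outside A/C/G/T/N/- was rejected by the constructor
  out
}

#' Build the majority-rule consensus of a multi-genome alignment
#'
#' The consensus base of each column is the most frequent non-gap base among
#' taxa, with ties broken in the fixed order `A < C < G < T`. Columns where
#' every taxon has a gap are excluded from the consensus and receive no
#' coordinate; all other columns are numbered consecutively from 1, giving
#' the consensus coordinate system shared by the SNP map and the read
#' pileups. Columns whose only non-gap characters are `N` get consensus base
#' `N` (with a warning).
#'
#' @param aln A [genome_alignment()].
#' @return An object of class `consensus_sequence`: list with `sequence`
#'   (character scalar), `column_map` (integer vector over alignment columns,
#'   `NA` for excluded columns) and `length`.
#' @export
build_consensus <- function(aln) {
  stopifnot(inherits(aln, "genome_alignment"))
  cnt <- aln_base_counts(aln)
  acgt <- cnt[DNA_BASES4, , drop = FALSE]
  has_base <- colSums(acgt) > 0L
  has_n <- cnt["N", ] > 0L
  included <- has_base | has_n
  if (!any(included)) stop("alignment has no non-gap columns")
  # max.col with ties.method = "first" encodes the A<C<G<T tie-break
  top <- max.col(t(acgt), ties.method = "first")
  ch <- rep(NA_character_, aln$width)
  ch[has_base] <- DNA_BASES4[top[has_base]]
  n_only <- included & !has_base
  if (any(n_only)) {
    warning(sum(n_only), " column(s) contain only N among non-gap characters; ",
            "consensus base set to N")
    ch[n_only] <- "N"
  }
  column_map <- rep(NA_integer_, aln$width)
  column_map[included] <- cumsum(included)[included]
  structure(
    list(sequence = paste(ch[included], collapse = ""),
         column_map = column_map,
         length = sum(included)),
    class = "consensus_sequence"
  )
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat("consensus_sequence:", x$length, "bp (",
      sum(is.na(x$column_map)), "all-gap columns excluded )\n")
  invisible(x)
}
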