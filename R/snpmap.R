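#' Classify alignment columns into lineage-specific SNP sites
#'
#' A column is a classified SNP site when every taxon carries a non-gap,
#' non-N base and exactly two distinct bases occur. The site's *partition*
#' is the set of genome groups sharing the minority allele (`allele_in`);
#' the remaining groups share `allele_out`. On an even split the partition
#' is the side carrying the non-consensus base, which makes the rule
#' deterministic for any number of taxa. Columns with three or more distinct
#' fully-resolved bases are recorded as `excluded_multiallelic`; columns that
#' are variable but contain a gap or `N` in some taxon are recorded as
#' `excluded_other`. Site coordinates are 1-based positions on the consensus.
#'
#' @param aln A [genome_alignment()].
#' @param cons The [build_consensus()] result for the same alignment.
#' @return An object of class `snp_map`: list with `sites` (data frame with
#'   columns `consensus_position`, `partition`, `allele_in`, `allele_out`,
#'   `site_class`), `groups`, `per_group_counts` (single-group sites per
#'   group), `per_pair_counts`, `n_larger` (partitions of three or more
#'   groups, possible only beyond five taxa), `n_excluded_multiallelic` and
#'   `n_excluded_other`.
#' @export
classify_snp_sites <- function(aln, cons) {
  stopifnot(inherits(aln, "genome_alignment"),
            inherits(cons, "consensus_sequence"))
  if (length(cons$column_map) != aln$width)
    stop("consensus was not built from this alignment (width mismatch)")
  cnt <- aln_base_counts(aln)
  acgt <- cnt[DNA_BASES4, , drop = FALSE]
  n_distinct <- colSums(acgt > 0L)
  gap_or_n <- cnt["N", ] > 0L | cnt["-", ] > 0L
  bi <- which(n_distinct == 2L & !gap_or_n)
  multi <- which(n_distinct >= 3L & !gap_or_n)
  other <- which(n_distinct >= 2L & gap_or_n)

  m <- aln_matrix(aln)
  grp <- unname(aln$groups)
  cons_chars <- strsplit(cons$sequence, "", fixed = TRUE)[[1]]

  rows <- vector("list", length(bi) + length(multi) + length(other))
  ri <- 0L
  for (j in bi) {
    col <- m[, j]
    bases <- DNA_BASES4[acgt[, j] > 0L]
    counts <- acgt[bases, j]
    if (counts[1] != counts[2]) {
      allele_in <- bases[which.min(counts)]
    } else {
      # even split: partition is the side carrying the non-consensus base
      cons_base <- cons_chars[cons$column_map[j]]
      allele_in <- setdiff(bases, cons_base)[1]
    }
    allele_out <- setdiff(bases, allele_in)
    part <- sort(grp[col == allele_in])
    cls <- if (length(part) == 1L) "single"
           else if (length(part) == 2L) "pair" else "multi"
    ri <- ri + 1L
    rows[[ri]] <- data.frame(
      consensus_position = cons$column_map[j],
      partition = paste(part, collapse = ""),
      allele_in = allele_in, allele_out = allele_out,
      site_class = cls, stringsAsFactors = FALSE)
  }
  for (j in multi) {
    ri <- ri + 1L
    rows[[ri]] <- data.frame(
      consensus_position = cons$column_map[j],
      partition = NA_character_, allele_in = NA_character_,
      allele_out = NA_character_, site_class = "excluded_multiallelic",
      stringsAsFactors = FALSE)
  }
  for (j in other) {
    ri <- ri + 1L
    rows[[ri]] <- data.frame(
      consensus_position = cons$column_map[j],
      partition = NA_character_, allele_in = NA_character_,
      allele_out = NA_character_, site_class = "excluded_other",
      stringsAsFactors = FALSE)
  }
  sites <- if (ri) do.call(rbind, rows[seq_len(ri)]) else empty_sites()
  sites <- sites[order(sites$consensus_position), , drop = FALSE]
  rownames(sites) <- NULL
  new_snp_map(sites, sort(unname(aln$groups)))
}

empty_sites <- function() {
  data.frame(consensus_position = integer(), partition = character(),
             allele_in = character(), allele_out = character(),
             site_class = character(), stringsAsFactors = FALSE)
}

new_snp_map <- function(sites, groups) {
  classified <- sites[!startsWith(sites$site_class, "excluded"), , drop = FALSE]
  dup <- duplicated(classified$consensus_position)
  if (any(dup))
    stop("duplicate classified site at consensus position(s): ",
         paste(unique(classified$consensus_position[dup]), collapse = ", "))
  singles <- classified$partition[classified$site_class == "single"]
  per_group <- setNames(integer(length(groups)), groups)
  tg <- table(singles)
  per_group[names(tg)] <- as.integer(tg)
  pairs <- classified$partition[classified$site_class == "pair"]
  per_pair <- if (length(pairs)) {
    tp <- table(pairs)
    setNames(as.integer(tp), names(tp))
  } else setNames(integer(0), character(0))
  structure(
    list(sites = sites, groups = groups,
         per_group_counts = per_group, per_pair_counts = per_pair,
         n_larger = sum(classified$site_class == "multi"),
         n_excluded_multiallelic =
           sum(sites$site_class == "excluded_multiallelic"),
         n_excluded_other = sum(sites$site_class == "excluded_other")),
    class = "snp_map"
  )
}

#' @export
print.snp_map <- function(x, ...) {
  cat("snp_map over groups {", paste(x$groups, collapse = ","), "}\n", sep = "")
  cat("  single-group sites:", sum(x$per_group_counts),
      sprintf("(%s)", paste(sprintf("%s=%d", names(x$per_group_counts),
                                    x$per_group_counts), collapse = ", ")),
      "\n")
  cat("  two-group sites:   ", sum(x$per_pair_counts), "\n")
  if (x$n_larger) cat("  larger partitions: ", x$n_larger, "\n")
  cat("  excluded:          ", x$n_excluded_multiallelic, "multiallelic,",
      x$n_excluded_other, "gap/N\n")
  invisible(x)
}

#' Write a SNP map to a tab-separated file
#'
#' The format is a `#groups=` comment line followed by a header and one row
#' per site: `consensus_position`, `partition` (concatenated group letters,
#' `.` for excluded sites), `allele_in`, `allele_out`, `site_class`.
#'
#' @param map A `snp_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_map <- function(map, path) {
  stopifnot(inherits(map, "snp_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#groups=", paste(map$groups, collapse = ",")), con)
  out <- map$sites
  out$partition[is.na(out$partition)] <- "."
  out$allele_in[is.na(out$allele_in)] <- "."
  out$allele_out[is.na(out$allele_out)] <- "."
  writeLines(paste(colnames(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read a SNP map written by [write_snp_map()]
#'
#' @param path Input path.
#' @return A `snp_map`; summary counts are recomputed from the rows.
#' @export
read_snp_map <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#groups="))
    stop("parse error at line 1: expected '#groups=' header")
  groups <- strsplit(sub("^#groups=", "", lines[1]), ",", fixed = TRUE)[[1]]
  header <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  expected <- colnames(empty_sites())
  if (!identical(header, expected))
    stop("parse error at line 2: unexpected column header")
  body <- lines[-(1:2)]
  if (!length(body)) return(new_snp_map(empty_sites(), groups))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5L))
    stop("parse error at line ", 2L + which(nf != 5L)[1],
         ": expected 5 tab-separated fields")
  sites <- data.frame(
    consensus_position = as.integer(vapply(fields, `[`, "", 1L)),
    partition = vapply(fields, `[`, "", 2L),
    allele_in = vapply(fields, `[`, "", 3L),
    allele_out = vapply(fields, `[`, "", 4L),
    site_class = vapply(fields, `[`, "", 5L),
    stringsAsFactors = FALSE)
  sites$partition[sites$partition == "."] <- NA_character_
  sites$allele_in[sites$allele_in == "."] <- NA_character_
  sites$allele_out[sites$allele_out == "."] <- NA_character_
  if (anyNA(sites$consensus_position))
    stop("parse error: non-integer consensus_position at line ",
         2L + which(is.na(sites$consensus_position))[1])
  known <- c("single", "pair", "multi", "excluded_multiallelic",
             "excluded_other")
  bad <- !sites$site_class %in% known
  if (any(bad))
    stop("parse error at line ", 2L + which(bad)[1], ": unknown site_class '",
         sites$site_class[bad][1], "'")
  for (i in which(!is.na(sites$partition))) {
    letters_i <- strsplit(sites$partition[i], "", fixed = TRUE)[[1]]
    unknown <- setdiff(letters_i, groups)
    if (length(unknown))
      stop("parse error at line ", 2L + i, ": unknown group '",
           unknown[1], "' in partition '", sites$partition[i], "'")
  }
  new_snp_map(sites, groups)
}

#' Export classified SNP sites as BED intervals on the consensus
#'
#' Writes 0-based half-open single-base intervals (one per classified site)
#' with the partition as the feature name, for genome-browser inspection.
#'
#' @param map A `snp_map`.
#' @param path Output BED path.
#' @param contig Name used for the consensus contig.
#' @return `path`, invisibly.
#' @export
write_snp_bed <- function(map, path, contig = "consensus") {
  stopifnot(inherits(map, "snp_map"))
  s <- map$sites[!startsWith(map$sites$site_class, "excluded"), , drop = FALSE]
  bed <- data.frame(contig, s$consensus_position - 1L, s$consensus_position,
                    s$partition)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
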