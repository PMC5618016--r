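#' Generate a panel of lineage genomes with planted group-specific SNPs
#'
#' Simulates an ancestral circular genome and derives one genome per genome
#' group by planting single-group and two-group SNPs at unique positions.
#' Because no indels are planted, stacking the lineage genomes yields a
#' gap-free multiple alignment whose planted site list is the ground-truth
#' oracle for [classify_snp_sites()] and everything downstream.
#'
#' Default planted counts follow the group-specific SNP tallies of the five
#' CpGV genome groups (A: 2, B: 54, C: 356, D: 21, E: 101 single-group
#' sites; 117 two-group sites spread over the seven group pairs that share
#' SNPs).
#'
#' @param n_groups Number of genome groups (default 5, labelled `A`..`E`).
#' @param genome_length Ancestral genome length in nt (default 125000,
#'   matching a granulovirus-sized genome).
#' @param planted_counts Integer vector of single-group SNP counts, one per
#'   group (recycled names from `groups` if unnamed).
#' @param planted_pair_counts Named integer vector of two-group SNP counts
#'   (names like `"AC"`). `NULL` uses the default five-group layout, or none
#'   for other group numbers.
#' @param groups Group labels.
#' @param gc GC content of the ancestral genome (default 0.45).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return An object of class `lineage_panel`: list with `ancestral`,
#'   `genomes` (named by group), `sites` (data frame `position`, `partition`,
#'   `allele_in`, `allele_out`), `groups`, `genome_length`.
#' @export
make_lineage_panel <- function(n_groups = 5,
                               genome_length = 125000,
                               planted_counts = c(2, 54, 356, 21, 101),
                               planted_pair_counts = NULL,
                               groups = LETTERS[seq_len(n_groups)],
                               gc = 0.45,
                               seed = 1) {
  stopifnot(n_groups >= 2, length(groups) == n_groups,
            length(planted_counts) == n_groups)
  if (is.null(names(planted_counts))) names(planted_counts) <- groups
  if (is.null(planted_pair_counts)) {
    planted_pair_counts <- if (n_groups == 5L && identical(groups, LETTERS[1:5]))
      default_pair_counts() else setNames(integer(0), character(0))
  }
  total <- sum(planted_counts) + sum(planted_pair_counts)
  if (total > genome_length / 10)
    stop("too many planted sites (", total, ") for genome length ",
         genome_length)
  set.seed(as.integer(seed))
  anc <- random_dna(genome_length, gc)
  pos <- sort(sample.int(genome_length, total))
  parts <- c(rep(names(planted_counts), planted_counts),
             rep(names(planted_pair_counts), planted_pair_counts))
  parts <- sample(parts)  # interleave partitions along the genome
  anc_chars <- strsplit(anc, "", fixed = TRUE)[[1]]
  allele_out <- anc_chars[pos]
  allele_in <- vapply(allele_out,
                      function(b) sample(setdiff(DNA_BASES4, b), 1L), "")
  sites <- data.frame(position = pos, partition = parts,
                      allele_in = unname(allele_in),
                      allele_out = allele_out,
                      stringsAsFactors = FALSE, row.names = NULL)
  genomes <- setNames(vector("list", n_groups), groups)
  for (g in groups) {
    ch <- anc_chars
    carry <- grepl(g, sites$partition, fixed = TRUE)
    ch[sites$position[carry]] <- sites$allele_in[carry]
    genomes[[g]] <- paste(ch, collapse = "")
  }
  structure(
    list(ancestral = anc, genomes = unlist(genomes), sites = sites,
         groups = groups, genome_length = genome_length),
    class = "lineage_panel"
  )
}

# 117 two-group sites over the seven pairs that share SNPs in the five-group
# reference panel (no sites are shared by pairs AB, BD or AE)
default_pair_counts <- function() {
  c(AC = 17L, AD = 17L, BC = 17L, BE = 17L, CD = 17L, CE = 16L, DE = 16L)
}

#' @export
print.lineage_panel <- function(x, ...) {
  cat("lineage_panel:", length(x$groups), "groups,", x$genome_length,
      "bp genomes,", nrow(x$sites), "planted sites\n")
  invisible(x)
}

#' Gap-free alignment implied by a lineage panel
#'
#' @param panel A [make_lineage_panel()] result.
#' @return A [genome_alignment()] with one taxon per genome group (labels
#'   `syn_<group>`).
#' @export
panel_alignment <- function(panel) {
  stopifnot(inherits(panel, "lineage_panel"))
  labels <- paste0("syn_", panel$groups)
  genome_alignment(setNames(panel$genomes, labels),
                   setNames(panel$groups, labels))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# i.i.d. substitution errors at the given per-base rate
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  nerr <- rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(nerr > 0L)) {
    for (p in sample.int(nchar(seqs[i]), nerr[i])) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES4, old), 1L)
    }
  }
  seqs
}

#' Specify a read-mixture simulation
#'
#' @param proportions Named numeric vector of lineage proportions (names are
#'   group labels); must sum to 1.
#' @param coverage Mean fold-coverage of the viral genome (> 0).
#' @param read_length Read length in nt (default 151).
#' @param fragment_mean,fragment_sd Fragment (insert) length distribution in
#'   nt.
#' @param per_base_error Per-base substitution error probability.
#' @param contamination Fraction of read pairs drawn from an unrelated
#'   host-like sequence (default 0).
#' @param degraded_fraction Fraction of reads given a degraded quality tail
#'   (last 60% of cycles at Phred 2) to exercise the read-quality filter.
#' @param seed Integer seed.
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(proportions, coverage, read_length = 151,
                         fragment_mean = 400, fragment_sd = 60,
                         per_base_error = 0.002, contamination = 0,
                         degraded_fraction = 0, seed = 1) {
  if (is.null(names(proportions)))
    stop("'proportions' must be named by group label")
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1 (got ", sum(proportions), ")")
  if (coverage <= 0) stop("coverage must be > 0")
  if (contamination < 0 || contamination >= 1)
    stop("contamination must lie in [0, 1)")
  structure(
    list(proportions = proportions, coverage = coverage,
         read_length = as.integer(read_length),
         fragment_mean = fragment_mean, fragment_sd = fragment_sd,
         per_base_error = per_base_error, contamination = contamination,
         degraded_fraction = degraded_fraction, seed = as.integer(seed)),
    class = "mixture_spec"
  )
}

#' Simulate mixed paired-end reads from a lineage panel
#'
#' Fragments are assigned a source lineage by the mixture proportions and
#' placed uniformly on the circular genome (wrap-around fragments are
#' handled by coordinate reduction modulo genome length). Both mates receive
#' i.i.d. substitution errors at `per_base_error` and constant Phred strings
#' matching that rate (`Q = -10 log10(error)`, capped at 40). Contaminant
#' pairs are drawn the same way from a seeded random host-like genome (38%
#' GC) using an RNG stream separate from the viral draws, so the viral read
#' sample is identical with and without contamination. The truth manifest
#' records each pair's source and fragment coordinates and is sufficient to
#' recompute every downstream quantity by brute force.
#'
#' @param panel A [make_lineage_panel()] result.
#' @param spec A [mixture_spec()]; `proportions` names must be panel groups.
#' @param out_prefix Optional path prefix; if given, writes
#'   `<prefix>_R1.fastq`, `<prefix>_R2.fastq` (Phred+33) and
#'   `<prefix>_truth.tsv`.
#' @return An object of class `simulated_reads`: list with `pairs` (a
#'   `read_pairs` data frame: `id`, `seq1`, `qual1`, `seq2`, `qual2`),
#'   `manifest` (data frame `read_id`, `source`, `start`,
#'   `fragment_length`), `spec` and `genome_length`.
#' @export
simulate_reads <- function(panel, spec, out_prefix = NULL) {
  stopifnot(inherits(panel, "lineage_panel"), inherits(spec, "mixture_spec"))
  if (!all(names(spec$proportions) %in% panel$groups))
    stop("proportion names must be panel groups")
  L <- panel$genome_length
  rl <- spec$read_length
  if (rl > L) stop("read length exceeds genome length")
  n_viral <- max(1L, round(spec$coverage * L / (2 * rl)))

  set.seed(spec$seed)
  src <- sample(names(spec$proportions), n_viral, replace = TRUE,
                prob = spec$proportions)
  viral <- draw_pairs(panel$genomes, src, L, spec)

  n_host <- round(n_viral * spec$contamination / (1 - spec$contamination))
  if (n_host > 0L) {
    set.seed(spec$seed + 10007L)  # separate stream for the contaminant
    host_genome <- c(host = random_dna(L, gc = 0.38))
    host <- draw_pairs(host_genome, rep("host", n_host), L, spec)
    pairs <- rbind(viral$pairs, host$pairs)
    manifest <- rbind(viral$manifest, host$manifest)
  } else {
    pairs <- viral$pairs
    manifest <- viral$manifest
  }
  if (nrow(pairs) == 0L) warning("zero coverage: no reads simulated")
  pairs$id <- sprintf("sim_%07d", seq_len(nrow(pairs)))
  manifest$read_id <- pairs$id
  manifest <- manifest[, c("read_id", "source", "start", "fragment_length")]
  class(pairs) <- c("read_pairs", "data.frame")
  out <- structure(
    list(pairs = pairs, manifest = manifest, spec = spec, genome_length = L),
    class = "simulated_reads"
  )
  if (!is.null(out_prefix)) {
    write_reads_fastq(pairs, paste0(out_prefix, "_R1.fastq"),
                      paste0(out_prefix, "_R2.fastq"))
    write.table(manifest, paste0(out_prefix, "_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

# draw read pairs for a vector of source labels against named genomes
draw_pairs <- function(genomes, src, L, spec) {
  n <- length(src)
  rl <- spec$read_length
  if (n == 0L) {
    return(list(pairs = data.frame(id = character(), seq1 = character(),
                                   qual1 = character(), seq2 = character(),
                                   qual2 = character(),
                                   stringsAsFactors = FALSE),
                manifest = data.frame(source = character(), start = integer(),
                                      fragment_length = integer())))
  }
  start <- sample.int(L, n, replace = TRUE)
  flen <- pmin(L, pmax(rl, round(rnorm(n, spec$fragment_mean,
                                       spec$fragment_sd))))
  seq1 <- character(n)
  seq2 <- character(n)
  for (g in unique(src)) {
    idx <- which(src == g)
    dbl <- paste0(genomes[[g]], genomes[[g]])
    seq1[idx] <- substring(dbl, start[idx], start[idx] + rl - 1L)
    s2 <- start[idx] + flen[idx] - rl
    seq2[idx] <- revcomp_chr(substring(dbl, s2, s2 + rl - 1L))
  }
  seq1 <- inject_errors(seq1, spec$per_base_error)
  seq2 <- inject_errors(seq2, spec$per_base_error)
  q <- if (spec$per_base_error > 0)
    min(40L, as.integer(round(-10 * log10(spec$per_base_error)))) else 40L
  qual <- strrep(intToUtf8(q + 33L), rl)
  qual1 <- rep(qual, n)
  qual2 <- rep(qual, n)
  if (spec$degraded_fraction > 0) {
    bad <- runif(n) < spec$degraded_fraction
    head_len <- floor(rl * 0.4)
    bad_qual <- paste0(strrep(intToUtf8(q + 33L), head_len),
                       strrep(intToUtf8(2L + 33L), rl - head_len))
    qual1[bad] <- bad_qual
    qual2[bad] <- bad_qual
  }
  list(pairs = data.frame(id = NA_character_, seq1 = seq1, qual1 = qual1,
                          seq2 = seq2, qual2 = qual2,
                          stringsAsFactors = FALSE),
       manifest = data.frame(source = src, start = start,
                             fragment_length = flen))
}

#' Simulate a bioassay mortality table
#'
#' Draws per-replicate treated and control death counts from binomial
#' distributions, emulating a discriminating-concentration bioassay with
#' matched untreated controls.
#'
#' @param true_mortalities Named numeric vector of true mortality
#'   probabilities, one per treatment (names become the `isolate` column).
#' @param control_mortality True control (natural) mortality probability.
#' @param n_per_rep Larvae per replicate (default 50).
#' @param n_reps Replicates per treatment (default 4).
#' @param strain Host strain label (single value or one per treatment).
#' @param seed Integer seed.
#' @return A `bioassay_table` data frame with columns `strain`, `isolate`,
#'   `replicate`, `n_treated`, `n_dead`, `control_n`, `control_dead`.
#' @export
make_bioassay_table <- function(true_mortalities, control_mortality,
                                n_per_rep = 50, n_reps = 4,
                                strain = "CpS", seed = 1) {
  stopifnot(all(true_mortalities >= 0 & true_mortalities <= 1),
            control_mortality >= 0, control_mortality <= 1, n_reps >= 1)
  if (is.null(names(true_mortalities)))
    names(true_mortalities) <- paste0("isolate", seq_along(true_mortalities))
  strain <- rep_len(strain, length(true_mortalities))
  set.seed(as.integer(seed))
  rows <- do.call(rbind, lapply(seq_along(true_mortalities), function(i) {
    data.frame(
      strain = strain[i], isolate = names(true_mortalities)[i],
      replicate = seq_len(n_reps), n_treated = n_per_rep,
      n_dead = rbinom(n_reps, n_per_rep, true_mortalities[i]),
      control_n = n_per_rep,
      control_dead = rbinom(n_reps, n_per_rep, control_mortality),
      stringsAsFactors = FALSE)
  }))
  class(rows) <- c("bioassay_table", "data.frame")
  rows
}
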