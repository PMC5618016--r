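make_pairs <- function(seqs1, quals1, seqs2 = seqs1, quals2 = quals1) {
  p <- data.frame(id = sprintf("r%03d", seq_along(seqs1)), seq1 = seqs1,
                  qual1 = quals1, seq2 = seqs2, qual2 = quals2,
                  stringsAsFactors = FALSE)
  class(p) <- c("read_pairs", "data.frame")
  p
}

phred_string <- function(qs) intToUtf8(qs + 33L)

test_that("quality filter keeps pairs with enough high-quality bases", {
  good <- phred_string(rep(40, 10))
  bad <- phred_string(rep(2, 10))
  boundary <- phred_string(c(rep(30, 5), rep(10, 5)))  # exactly 50% at Q30
  below <- phred_string(c(rep(30, 4), rep(10, 6)))
  pairs <- make_pairs(rep(strrep("A", 10), 4),
                      c(good, bad, boundary, below))
  kept <- quality_filter_reads(pairs)
  expect_identical(kept$id, c("r001", "r003"))  # boundary is inclusive
  rep_ <- attr(kept, "filter_report")
  expect_equal(rep_$n_kept, 2)
  expect_equal(rep_$n_discarded, 2)

  # a pair is dropped when either mate fails
  mixed <- make_pairs(strrep("A", 10), good, strrep("A", 10), bad)
  expect_equal(nrow(quality_filter_reads(mixed)), 0)
})

test_that("degraded-tail reads are removed by the quality filter", {
  panel <- small_panel(genome_length = 2000)
  spec <- mixture_spec(c(A = 1), coverage = 10, per_base_error = 0.001,
                       degraded_fraction = 0.5, seed = 3)
  sim <- simulate_reads(panel, spec)
  kept <- quality_filter_reads(sim$pairs)
  frac_kept <- nrow(kept) / nrow(sim$pairs)
  expect_lt(abs(frac_kept - 0.5), 0.1)
})

test_that("the internal mapper places exact and near-exact reads", {
  panel <- small_panel(genome_length = 3000)
  cons <- build_consensus(panel_alignment(panel))
  exact <- substr(cons$sequence, 1001, 1100)
  two_mm <- exact
  substr(two_mm, 10, 10) <- if (substr(two_mm, 10, 10) == "A") "C" else "A"
  substr(two_mm, 90, 90) <- if (substr(two_mm, 90, 90) == "G") "T" else "G"
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(exact)))
  set.seed(1)
  host <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  pairs <- make_pairs(c(exact, two_mm, rc, host),
                      rep(phred_string(rep(35, 100)), 4))
  aln <- map_reads(pairs, cons)
  m1 <- aln[aln$mate == 1, ]
  expect_identical(m1$id, c(1L, 2L, 3L))  # host read unmapped
  expect_identical(m1$start, rep(1001L, 3))
  expect_identical(m1$strand, c("+", "+", "-"))
  expect_identical(m1$mapq, rep(60L, 3))
  # minus-strand records are reported in reference orientation
  expect_identical(m1$seq[3], exact)
})

test_that("pileup counts match reads and respects input order invariance", {
  set.seed(42)
  cons <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  read <- substr(cons, 11, 40)
  q <- phred_string(rep(35, 30))
  pairs <- make_pairs(read, q)
  aln <- map_reads(pairs, cons, k = 11)
  pile <- pileup(aln, cons)
  depth <- rowSums(unclass(pile))
  expect_identical(unname(depth[11:40]), rep(1, 30))
  expect_identical(unname(depth[-(11:40)]), rep(0, 70))
  # counted bases equal the consensus over the covered span
  covered <- strsplit(substr(cons, 11, 40), "")[[1]]
  hits <- unclass(pile)[cbind(11:40, match(covered, c("A","C","G","T","N")))]
  expect_identical(unname(hits), rep(1L, 30))

  # two reads disagreeing at one position
  ref_base <- substr(cons, 11, 11)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  alt <- read
  substr(alt, 1, 1) <- alt_base
  aln2 <- map_reads(make_pairs(c(read, alt), c(q, q)), cons, k = 11)
  pile2 <- pileup(aln2, cons)
  expect_equal(unname(unclass(pile2)[11, c(ref_base, alt_base)]), c(1L, 1L))
  expect_equal(sum(unclass(pile2)[11, ]), 2)

  # permuting record order leaves the pileup unchanged
  perm <- aln2[c(3, 1, 4, 2), ]
  class(perm) <- class(aln2)
  attr(perm, "consensus_length") <- attr(aln2, "consensus_length")
  expect_identical(unclass(pileup(perm, cons)), unclass(pile2))
})

test_that("overlapping mates are counted once, keeping the better base", {
  set.seed(43)
  cons <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  read1 <- substr(cons, 11, 40)
  read2 <- substr(cons, 31, 60)  # overlaps read1 at 31..40
  # give mate 2 a disagreeing base at position 31 with higher quality
  ref31 <- substr(cons, 31, 31)
  alt31 <- setdiff(c("A", "C", "G", "T"), ref31)[1]
  substr(read2, 1, 1) <- alt31
  q_lo <- phred_string(rep(20, 30))
  q_hi <- phred_string(rep(38, 30))
  aln <- data.frame(id = c(1L, 1L), mate = c(1L, 2L), start = c(11L, 31L),
                    strand = "+", mapq = 60L,
                    seq = c(read1, read2), qual = c(q_lo, q_hi),
                    stringsAsFactors = FALSE)
  class(aln) <- c("read_alignments", "data.frame")
  attr(aln, "consensus_length") <- 100L
  pile <- pileup(aln, cons)
  expect_equal(sum(rowSums(unclass(pile))), 50)  # union of spans, not 60
  expect_equal(unname(unclass(pile)[31, alt31]), 1L)  # higher-quality base won
  expect_equal(unname(unclass(pile)[31, ref31]), 0L)
  # without dedup the overlap is double-counted
  pile_raw <- pileup(aln, cons, dedup_mates = FALSE)
  expect_equal(sum(rowSums(unclass(pile_raw))), 60)
})

test_that("SAM export/import round-trips pileups for non-wrapping records", {
  pipe <- small_pipeline(c(A = 0.5, E = 0.5), coverage = 15,
                         per_base_error = 0, seed = 21,
                         panel = small_panel(genome_length = 3000))
  aln <- pipe$alns
  L <- attr(aln, "consensus_length")
  keep <- aln$start + nchar(aln$seq) - 1L <= L
  sub <- aln[keep, ]
  class(sub) <- class(aln)
  attr(sub, "consensus_length") <- L
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sub, sam)
  back <- import_sam(sam, pipe$cons)
  expect_identical(unclass(pileup(back, pipe$cons)),
                   unclass(pileup(sub, pipe$cons)))
})

test_that("SAM records with MAPQ 255 are excluded by the MAPQ filter", {
  cons <- strrep("ACGT", 25)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               "@SQ\tSN:consensus\tLN:100",
               paste("r1", 0, "consensus", 11, 255, "10M", "*", 0, 0,
                     substr(cons, 11, 20), strrep("I", 10), sep = "\t"),
               paste("r2", 0, "consensus", 21, 60, "10M", "*", 0, 0,
                     substr(cons, 21, 30), strrep("I", 10), sep = "\t")),
             sam)
  aln <- import_sam(sam, cons)
  expect_identical(sum(is.na(aln$mapq)), 1L)
  pile <- pileup(aln, cons)
  expect_equal(sum(rowSums(unclass(pile))), 10)  # only the MAPQ-60 record

  # reference length mismatches are rejected up front
  expect_error(import_sam(sam, strrep("ACGT", 30)), "length mismatch")
})

test_that("an external aligner's SAM yields concordant composition", {
  pipe <- small_pipeline(c(A = 0.35, E = 0.65), coverage = 60, seed = 17)
  est_internal <- estimate_composition(pipe$obs, pipe$map)

  dir <- withr::local_tempdir()
  ref <- file.path(dir, "cons.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(consensus = pipe$cons$sequence)), ref)
  write_reads_fastq(pipe$sim$pairs, file.path(dir, "r1.fq"),
                    file.path(dir, "r2.fq"))
  sam <- file.path(dir, "out.sam")
  expect_equal(system2("bwa", c("index", ref), stdout = FALSE,
                       stderr = FALSE), 0L)
  expect_equal(system2("bwa", c("mem", "-v", "1", ref,
                                file.path(dir, "r1.fq"),
                                file.path(dir, "r2.fq")),
                       stdout = sam, stderr = FALSE), 0L)
  aln <- import_sam(sam, pipe$cons)
  pile <- pileup(aln, pipe$cons)
  obs <- quantify_sites(pile, pipe$map)
  est_external <- estimate_composition(obs, pipe$map)
  share_int <- setNames(est_internal$composition$share,
                        est_internal$composition$combined_group)
  share_ext <- setNames(est_external$composition$share,
                        est_external$composition$combined_group)
  common <- intersect(names(share_int), names(share_ext))
  expect_true(all(abs(share_int[common] - share_ext[common]) < 2))
})
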