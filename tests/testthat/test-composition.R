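fake_detection <- function(median_freq, detected_frac,
                           n_possible = c(A = 2, B = 54, C = 356, D = 21,
                                          E = 101)) {
  df <- data.frame(group = names(n_possible), n_possible = unname(n_possible),
                   n_called = unname(n_possible),
                   n_detected = round(unname(n_possible) * detected_frac),
                   detected_frac = unname(detected_frac),
                   median_freq = unname(median_freq),
                   stringsAsFactors = FALSE)
  structure(df, class = c("detection_summary", "data.frame"))
}

fake_obs <- function(pos, part, freq_in, depth = 500,
                     groups = LETTERS[1:5], L = 20000) {
  df <- data.frame(consensus_position = pos, partition = part,
                   allele_in = "G", allele_out = "A", depth = depth,
                   freq_in = freq_in, freq_out = 1 - freq_in, freq_other = 0,
                   called = TRUE, no_call_reason = NA_character_,
                   stringsAsFactors = FALSE)
  structure(df, class = c("allele_freqs", "data.frame"), groups = groups,
            consensus_length = L)
}

test_that("presence is called from median frequency and detected fraction", {
  det <- fake_detection(
    median_freq = c(A = NA, B = 0.49, C = 0.004, D = 0.006, E = 0.51),
    detected_frac = c(A = 0, B = 1, C = 0.05, D = 0.19, E = 0.96))
  expect_identical(infer_present_lineages(det), c("B", "E"))

  # single-lineage sample: no complement added when median is near 100%
  det1 <- fake_detection(
    median_freq = c(A = NA, B = NA, C = 0.01, D = NA, E = 0.998),
    detected_frac = c(A = 0, B = 0.02, C = 0.05, D = 0, E = 1))
  expect_identical(infer_present_lineages(det1), "E")

  # complement rule: one present lineage far below 100% pulls in the group
  # with the weakest map
  det2 <- fake_detection(
    median_freq = c(A = NA, B = 0.01, C = 0.01, D = NA, E = 0.68),
    detected_frac = c(A = 0, B = 0.07, C = 0.05, D = 0.1, E = 1))
  expect_identical(infer_present_lineages(det2), c("A", "E"))
  expect_identical(infer_present_lineages(det2, complement_candidate = "D"),
                   c("D", "E"))

  det0 <- fake_detection(median_freq = c(A = NA, B = NA, C = NA, D = NA,
                                         E = NA),
                         detected_frac = rep(0, 5))
  expect_error(infer_present_lineages(det0), "no lineage")
})

test_that("allele sides are pooled into combined groups by the present set", {
  obs <- fake_obs(pos = c(100, 200, 300, 400),
                  part = c("AD", "CE", "E", "CD"),
                  freq_in = c(0.32, 0.68, 0.68, 0.004))
  cg <- assign_combined_groups(obs, present = c("A", "E"))
  get <- function(pos, side) cg$combined_group[cg$consensus_position == pos &
                                                 cg$side == side]
  expect_identical(get(100, "in"), "A")    # AD intersect {A,E} = A
  expect_identical(get(100, "out"), "E")   # BCE intersect {A,E} = E
  expect_identical(get(200, "in"), "E")    # CE intersect {A,E} = E
  expect_identical(get(200, "out"), "A")   # ABD intersect {A,E} = A
  expect_identical(get(300, "out"), "A")   # ABCD side pools into A
  expect_identical(get(400, "out"), "QC")  # ABE contains both present groups
  # CD's in-side frequency (0.4%) is below the detection threshold
  expect_length(get(400, "in"), 0)
  # per-site conservation: each retained side's freq + complement <= 1
  expect_true(all(cg$freq >= 0 & cg$freq <= 1))
})

test_that("the residual group is labelled by detected absent lineages", {
  obs <- fake_obs(pos = c(100, 200, 300),
                  part = c("A", "E", "B"),
                  freq_in = c(0.3, 0.7, 0.01))
  cg <- assign_combined_groups(obs, present = c("A", "E"))
  expect_identical(attr(cg, "residual_label"), "B")
  expect_identical(cg$combined_group[cg$consensus_position == 300 &
                                       cg$side == "in"], "B")
  # with no absent lineage detected at all, the label covers all of them
  obs2 <- fake_obs(pos = c(100, 200), part = c("A", "E"),
                   freq_in = c(0.3, 0.7))
  expect_identical(attr(assign_combined_groups(obs2, c("A", "E")),
                        "residual_label"), "BCD")
})

test_that("group summaries use midpoint medians and linear percentiles", {
  obs <- fake_obs(pos = c(10, 20, 30, 40),
                  part = c("A", "A", "A", "E"),
                  freq_in = c(0.1, 0.2, 0.3, 0.5))
  cg <- assign_combined_groups(obs, present = c("A", "E"))
  gs <- summarize_groups(cg)
  a_in <- gs[gs$combined_group == "A", ]
  # combined group A holds the three A in-sides plus the out-side of E (0.5)
  expect_equal(a_in$n, 4)
  expect_equal(a_in$median, median(c(10, 20, 30, 50)))
  single <- summarize_groups(assign_combined_groups(
    fake_obs(pos = c(10, 20), part = c("A", "E"), freq_in = c(0.5, 0.999)),
    present = c("A", "E")))
  arow <- single[single$combined_group == "A", ]
  expect_equal(arow$median, 50)
  expect_equal(c(arow$p_lo, arow$p_hi), c(50, 50))
})

test_that("weighted medians reproduce the published worked examples", {
  # two-thirds E / one-third A isolate with the trace group zeroed out
  comp <- weighted_median_composition(
    c(A = 32, E = 67, BCD = 1), c(A = 160, E = 160, BCD = 50),
    trace_policy = "zero_out", trace_groups = "BCD")
  expect_identical(setNames(comp$share_rounded, comp$combined_group),
                   c(A = 32, E = 68, BCD = 0))
  # near 50:50 B/E isolate with the trace group retained
  comp2 <- weighted_median_composition(
    c(B = 49, E = 51, ACD = 6), c(B = 188, E = 188, ACD = 65),
    trace_policy = "keep")
  expect_identical(setNames(comp2$share_rounded, comp2$combined_group),
                   c(B = 48, E = 50, ACD = 2))
  expect_equal(sum(comp2$share), 100)
})

test_that("weighted medians are symmetric and scale-invariant in n", {
  comp <- weighted_median_composition(c(X = 40, Y = 40), c(10, 10),
                                      trace_policy = "keep")
  expect_equal(comp$share, c(50, 50))
  a <- weighted_median_composition(c(X = 31, Y = 62, Z = 7), c(12, 40, 9),
                                   trace_policy = "keep")
  b <- weighted_median_composition(c(X = 31, Y = 62, Z = 7),
                                   c(12, 40, 9) * 17,
                                   trace_policy = "keep")
  expect_equal(a$share, b$share)
  expect_error(weighted_median_composition(c(X = 0, Y = 0), c(5, 5)),
               "zero")
})

test_that("Tukey-HSD flags equal groups and degenerate input as such", {
  f <- c(0.46, 0.48, 0.5, 0.52, 0.54)  # symmetric: B and E lists identical
  obs <- fake_obs(pos = seq(10, 100, by = 10),
                  part = rep(c("B", "E"), each = 5),
                  freq_in = c(f, 1 - f))
  cg <- assign_combined_groups(obs, present = c("B", "E"))
  cmp <- compare_groups(cg)
  be <- cmp[cmp$pair %in% c("E-B", "B-E"), ]
  expect_true(all(be$not_different))
  expect_true(all(be$p_adj > 0.9))

  # degenerate: zero within-group variance is non-testable
  obs0 <- fake_obs(pos = c(10, 20, 30, 40), part = c("B", "B", "E", "E"),
                   freq_in = c(0.5, 0.5, 0.5, 0.5))
  cmp0 <- compare_groups(assign_combined_groups(obs0, c("B", "E")))
  expect_identical(attr(cmp0, "note"), "non-testable")
  expect_equal(nrow(cmp0), 0)
})

test_that("clearly separated groups are flagged different at alpha 0.05", {
  pipe <- small_pipeline(c(A = 0.32, E = 0.68), coverage = 60, seed = 31)
  est <- estimate_composition(pipe$obs, pipe$map)
  ae <- est$comparisons[grepl("^(E-A|A-E)$", est$comparisons$pair), ]
  expect_false(ae$not_different)
})

test_that("homogeneous mixtures yield no discordant regions", {
  pipe <- small_pipeline(c(A = 0.32, E = 0.68), coverage = 60, seed = 31)
  cg <- assign_combined_groups(pipe$obs, c("A", "E"))
  expect_equal(nrow(flag_discordant_regions(cg)), 0)
  # a window wider than the genome can flag at most one interval
  wide <- flag_discordant_regions(cg, window = 1e6)
  expect_lte(nrow(wide), 1)
})

test_that("a planted recombinant block is flagged as discordant", {
  panel <- small_panel(genome_length = 20000,
                       planted_counts = c(2, 12, 40, 8, 60),
                       seed = 37)
  # swap A and E alleles inside a 5 kb block: reads simulated from the
  # modified genomes carry locally inverted frequencies w.r.t. the map
  block <- c(8000, 13000)
  swap <- panel$sites$position >= block[1] & panel$sites$position < block[2] &
    panel$sites$partition %in% c("A", "E")
  g <- panel$genomes
  for (i in which(swap)) {
    p <- panel$sites$position[i]
    a_in <- panel$sites$allele_in[i]
    a_out <- panel$sites$allele_out[i]
    if (panel$sites$partition[i] == "E") {
      substr(g[["E"]], p, p) <- a_out
      substr(g[["A"]], p, p) <- a_in
    } else {
      substr(g[["A"]], p, p) <- a_out
      substr(g[["E"]], p, p) <- a_in
    }
  }
  recomb <- panel
  recomb$genomes <- g
  # map/consensus from the unmodified reference panel
  aln <- panel_alignment(panel)
  cons <- build_consensus(aln)
  map <- classify_snp_sites(aln, cons)
  spec <- mixture_spec(c(A = 0.3, E = 0.7), coverage = 60, seed = 41)
  sim <- simulate_reads(recomb, spec)
  alns <- map_reads(sim$pairs, cons)
  obs <- quantify_sites(pileup(alns, cons), map)
  cg <- assign_combined_groups(obs, c("A", "E"))
  flagged <- flag_discordant_regions(cg)
  expect_gte(nrow(flagged), 1)
  expect_true(any(flagged$start < block[2] & flagged$end > block[1]))
})

test_that("combined group distributions mirror about 100 percent", {
  pipe <- small_pipeline(c(A = 0.32, E = 0.68), coverage = 60, seed = 31)
  gs <- summarize_groups(assign_combined_groups(pipe$obs, c("A", "E")))
  m <- setNames(gs$median, gs$combined_group)
  expect_lt(abs(m[["A"]] + m[["E"]] - 100), 2)
})
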