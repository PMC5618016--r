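# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so module tests stay fast.

# a hand-sized alignment for consensus/classification unit tests
toy_alignment <- function() {
  # columns:        1234567890
  seqs <- c(iso1 = "GACATACGTA",
            iso2 = "AACATACGTA",
            iso3 = "AAC-TACGTA",
            iso4 = "AACATACGTA",
            iso5 = "AACATACGTA")
  genome_alignment(seqs, setNames(LETTERS[1:5], names(seqs)))
}

small_panel <- function(genome_length = 6000,
                        planted_counts = c(2, 12, 40, 8, 25),
                        planted_pair_counts = c(AC = 4, AD = 4, BC = 4,
                                                BE = 4, CD = 4, CE = 3,
                                                DE = 3),
                        seed = 11) {
  make_lineage_panel(genome_length = genome_length,
                     planted_counts = planted_counts,
                     planted_pair_counts = planted_pair_counts,
                     seed = seed)
}

# panel -> map/consensus plus a simulated mixture run through the pipeline
small_pipeline <- function(proportions, coverage = 80, per_base_error = 0.002,
                           contamination = 0, seed = 7, panel = small_panel(),
                           min_depth = 20) {
  aln <- panel_alignment(panel)
  cons <- build_consensus(aln)
  map <- classify_snp_sites(aln, cons)
  spec <- mixture_spec(proportions, coverage = coverage,
                       per_base_error = per_base_error,
                       contamination = contamination, seed = seed)
  sim <- simulate_reads(panel, spec)
  alns <- map_reads(sim$pairs, cons)
  pile <- pileup(alns, cons)
  obs <- quantify_sites(pile, map, min_depth = min_depth)
  list(panel = panel, aln = aln, cons = cons, map = map, spec = spec,
       sim = sim, alns = alns, pile = pile, obs = obs)
}

# Brute-force allele frequencies from the truth manifest alone: a fragment
# covers a site when either mate's span contains it on the circle; the base
# it contributes is fixed by its source lineage and the planted site list.
oracle_site_freqs <- function(sim, panel, map) {
  L <- sim$genome_length
  rl <- sim$spec$read_length
  man <- sim$manifest[sim$manifest$source != "host", , drop = FALSE]
  s1 <- man$start
  s2 <- man$start + man$fragment_length - rl
  sites <- map$sites[!startsWith(map$sites$site_class, "excluded"), ,
                     drop = FALSE]
  res <- lapply(seq_len(nrow(sites)), function(i) {
    p <- sites$consensus_position[i]
    covered <- (((p - s1) %% L) < rl) | (((p - s2) %% L) < rl)
    src <- man$source[covered]
    part <- strsplit(sites$partition[i], "", fixed = TRUE)[[1]]
    data.frame(consensus_position = p, depth = length(src),
               n_in = sum(src %in% part))
  })
  do.call(rbind, res)
}

# total bases a fragment contributes to a deduplicated pileup: the union of
# its two mate spans on the circle
oracle_total_depth <- function(sim) {
  man <- sim$manifest[sim$manifest$source != "host", , drop = FALSE]
  rl <- sim$spec$read_length
  sum(pmin(man$fragment_length, 2 * rl))
}
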