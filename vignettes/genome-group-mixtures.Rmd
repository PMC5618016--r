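---
title: "Estimating genome-group composition of mixed virus isolates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genome-group composition of mixed virus isolates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvmix)
```

## The problem

Baculovirus biocontrol products are frequently mixtures of phylogenetically
distinct lineages of the same virus. For Cydia pomonella granulovirus
(CpGV), five genome groups (A–E) are each represented by a reference
genome, and host resistance types are directed against specific groups — so
the *composition* of a commercial isolate determines which resistant pest
populations it can still control. Deep sequencing of a pooled DNA sample
reads out that composition: at every genome position where one lineage (or
a small set of lineages) carries a private nucleotide, the frequency of
that nucleotide among the reads estimates the abundance of those lineages
in the mixture.

`gvmix` implements this heuristic end to end, together with a simulator
that plants known truth at every stage. This vignette explains the model,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic tests do and do not establish about real data.

## Lineage-specific SNP map

The input is a gapped multiple alignment with exactly one reference genome
per genome group. Its majority-rule consensus defines the shared coordinate
frame: per column, the consensus base is the most frequent non-gap base;
columns in which every taxon has a gap receive no coordinate; all other
columns are numbered consecutively from 1. Majority ties are broken in the
fixed order A < C < G < T — the rule is arbitrary but deterministic and
makes the consensus invariant to taxa order. Columns whose only non-gap
characters are `N` become `N` with a warning.

A column is a classified SNP site when all taxa are resolved (no gap, no
`N`) and exactly two bases occur. Its *partition* is the set of groups on
the minority side; with five taxa this is one or two groups (the published
CpGV census: 2/54/356/21/101 single-group sites for A–E plus 117 two-group
sites). For even splits — possible with other panel sizes — the partition
is the side carrying the non-consensus base, again for determinism.
Tri-allelic columns are recorded as `excluded_multiallelic` and never
quantified; variable columns containing a gap or `N` in any taxon are
recorded as `excluded_other`. This is a conservative reading of
"gap-ignoring" consensus construction: a column with an indel in one
reference cannot anchor a substitution-only frequency measurement.

The map round-trips through a plain TSV (`write_snp_map()` /
`read_snp_map()`) and exports BED for genome browsers.

## Read processing

Reads are filtered by base quality: a pair is kept iff, for each mate, at
least `min_fraction` (default 0.5) of bases have Phred ≥ `q_threshold`
(default 30), boundary inclusive. The published description of this filter
is ambiguous about whether it applies per read, per pair or per cycle; the
per-mate interpretation used here is the standard operationalization and
both knobs are exposed.

The internal mapper is a seed-and-extend aligner against the *circular*
consensus (the virus has a circular dsDNA genome): exact 21-mer seeds at
non-overlapping offsets propose candidate placements, each candidate is
scored by full-length ungapped extension at +1/−2 on both strands, and the
best placement wins. Mapping quality is 60 for a unique best placement, 0
for a tie, otherwise `min(60, 6 × score gap)`. Reads scoring below
`min_score_frac × read length` (default 0.5) or seeding nowhere — e.g.
host-DNA contamination — are unmapped. The aligner is substitution-only by
design: the simulator plants no indels, and real data mapped with a gapped
aligner enters through `import_sam()` (secondary/supplementary records
dropped, MAPQ 255 treated as missing, clipped bases trimmed, indel-bearing
records counted and dropped). SAM export writes the circular consensus as a
linear reference, so origin-spanning alignments have their wrapped tail
soft-clipped — the standard compromise when a circular genome meets the SAM
model.

Pileups count bases per consensus position over records with MAPQ ≥ 30.
When mates of one fragment overlap, the base with the higher Phred score at
that position is counted once, so a fragment never votes twice at one site.

## Quantification and composition

At every classified map site with depth ≥ `min_depth` (default 20), the
frequencies of the partition allele (`freq_in`), the opposite allele
(`freq_out`) and any other base (`freq_other`) are recorded; lower-depth
sites stay visible as no-calls. The depth floor and the detection threshold
(`detect_threshold`, default 0.5%) are engineering choices, not published
values: 20 reads stabilize a frequency estimate at the coverages involved
(500–2800×), and 0.5% sits between the substitution-error floor
(~0.07–0.1% per specific wrong base at 0.2% error) and the ~1–6% medians
that real trace groups show.

**Presence.** A lineage is called present when the median detected
frequency over its own single-group sites is ≥ `presence_median` (default
5%) and the detected fraction of its sites is ≥ `presence_detected_frac`
(default 50%). These defaults deliberately call trace-level groups absent.
A lineage with a very weak map (group A has only two sites) cannot always
be called from its own sites; when exactly one lineage passes directly and
its median frequency is materially below 100%, the complement must belong
to some other lineage, and the group with the fewest map sites (or an
explicit `complement_candidate`) is added.

**Combined groups.** Each called site contributes two allele sides — its
partition with `freq_in` and the complement with `freq_out`. A side maps to
the combined group named by its intersection with the present set; sides
containing *all* present lineages are quality-control observations
(expected near 100%); sides disjoint from the present set pool into the
residual group of absent lineages. With present = {A, E} this reproduces
the published pooling (A ← A, AD, ACD, ABD, ABCD; E ← BCDE, BCE, BE, CE, E;
residual BCD), and the residual label drops absent lineages with zero
detected sites of their own.

**Estimator.** Per combined group the package reports the data size, the
mean with normal-approximation 95% confidence limits, and the median with
5–95 linear-interpolation percentiles (quantile type 7; medians are
reported to integer percent as is conventional). The mixture estimate
weights each group's median by its data size:

$$\mathrm{share}_g = \frac{\tilde f_g \, n_g}{\sum_h \tilde f_h\, n_h}
\times 100.$$

The residual group's treatment is explicit because both conventions occur
in practice: `zero_out` (default) sets trace groups to 0% and renormalizes
— appropriate when the trace median is sequencing error — while `keep`
retains them, appropriate when a minor component is plausible. Neither is
inferred automatically. Groups are compared by one-way ANOVA with Tukey-HSD
(Tukey–Kramer for unequal sizes, via `stats::TukeyHSD`); the normal-theory
confidence limits on means are a convention choice and should not be
over-interpreted for frequency data near 0 or 1.

**Discordant regions.** Recombination between lineages shows up as blocks
where site frequencies invert relative to their combined group. The
detector slides a 5 kb window (step half a window) and flags windows where
≥ 30% of sites deviate from their group median by more than 3 robust SDs
(1.4826 × MAD of all deviations). An earlier design used the windowed
*median* deviation, which fails exactly on the planted-recombination test:
the two allele sides of a swapped site deviate with opposite signs (signed
medians cancel), and unaffected map sites dilute a block to about half of a
window, where a median is unstable; the outlier-fraction statistic is
robust to both. Flagged intervals are candidates for inspection, not a
formal breakpoint inference.

Two further QC behaviors are intentional: QC sides materially below 100%
and map sites that are systematically absent across samples (suspected
reference errors) remain visible in the observation table rather than being
silently removed.

## Bioassay summaries

Discriminating-concentration bioassays are summarized per replicate:
mortality, Abbott correction against the matched control
(`(treated − control)/(100 − control) × 100`, negatives clipped to 0 and
flagged), then arithmetic mean with both SD and SEM across replicates (both
are emitted because both conventions appear in reports). Treatments are
compared by ANOVA + Tukey-HSD with a compact letter display
(insert-and-absorb). Larvae lost to handling within the first day can be
excluded via an optional `handling_deaths` column. Full dose–response
(LC50) modelling is out of scope — a single discriminating concentration
does not identify a dose–response curve.

## The synthetic-data generator

`make_lineage_panel()` simulates an ancestral circular genome (default
125,000 nt, 45% GC — granulovirus-like) and derives one genome per group by
planting the published SNP census: 2/54/356/21/101 single-group sites and
117 two-group sites. The per-pair breakdown of the 117 is not published
beyond three pairs sharing none (AB, BD, AE); the default spreads them as
evenly as possible over the remaining seven pairs (17×5, 16×2). No indels
are planted, so the stacked genomes *are* the alignment and the planted
site list is an exact oracle for the classifier.

`simulate_reads()` assigns each fragment a source lineage by the mixture
proportions, places it uniformly on the circle (coordinates reduce modulo
genome length; mate positions stay consistent across the origin), and
draws fragment lengths from a normal (default 400 ± 60 nt, a short-insert
library) truncated at the read length (151 nt, the platform's read
length). Substitution errors are i.i.d. per base (default 0.2%); quality
strings are constant at Q = −10·log₁₀(error), with an optional
degraded-tail profile (last 60% of cycles at Q2) to exercise the quality
filter. Host contamination draws the requested fraction of pairs from a
seeded random 38%-GC sequence, using an RNG stream separate from the viral
draws so that adding contamination leaves the viral read sample
bit-identical. The truth manifest (per pair: source, fragment start and
length) suffices to recompute every downstream quantity by brute force,
which the test suite does.

One interaction deserves a warning: at the default 0.2% error rate the
constant-quality model yields Q27 for every base, so the Q30/50% read
filter would discard *every* simulated read — an artifact of the constant
model, not of the filter. Pipelines on constant-quality simulations
therefore skip the (all-or-nothing) filter, which is exercised instead via
the degraded-tail profile and explicit boundary fixtures.

What the simulations do not emulate: position-specific Illumina error
profiles, indel errors, structural variation between lineages, library
preparation biases, and uneven coverage. Passing the synthetic checks shows
the *estimator and plumbing* are correct under the stated error model; it
does not certify performance on real libraries, for which the SAM import
path and the external-aligner concordance test are the bridge.

## Problem sizes and reproducibility

All tests and the simulation-based acceptance checks run on 20,000 nt
genomes carrying the full published SNP census, at 500× coverage with
0.2% error and 151 nt pairs (about 33,000 pairs per run; the contamination
scenario adds 84% host pairs for about 207,000). These sizes keep a full
multi-seed parameter-recovery sweep in the minutes range on one CPU while
preserving the site density and depth of the real study; the generator's
default genome length remains 125,000 nt. Every stochastic step takes an
explicit integer seed and is bit-reproducible.

## Known limitations

* The mapper is ungapped; lineages differing by indels from the consensus
  need an external aligner and `import_sam()`.
* Confidence limits on means use the normal approximation; for skewed
  frequency distributions the 5–95 percentiles are the better spread
  summary.
* The complement rule can only *suspect* a weak-map lineage; two absent
  sites cannot distinguish group A from a novel, unrepresented lineage.
* Median-based shares are insensitive to minor components below the
  detection threshold; a component under ~1% of the mixture is
  indistinguishable from sequencing error at these settings.
* The weighted-median estimator assumes the present lineages jointly
  explain each site (sides summing to ~100%); strong recombination breaks
  that assumption locally, which is why flagged discordant regions should
  be reviewed before trusting genome-wide shares.
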