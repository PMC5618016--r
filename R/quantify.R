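#' Quantify allele frequencies at SNP-map sites
#'
#' Intersects a pileup with the SNP map: for every classified site with
#' depth at or above `min_depth`, reports the read frequency of the
#' partition allele (`freq_in`), of the allele carried by the remaining
#' groups (`freq_out`), and of any other base (`freq_other`). Sites below
#' the depth floor are retained as no-calls with a reason; excluded-class
#' map sites are skipped.
#'
#' @param pile A [pileup()] result.
#' @param map A `snp_map` sharing the pileup's consensus coordinates.
#' @param min_depth Minimum read depth to call a site (default 20).
#' @return An object of class `allele_freqs`: data frame with columns
#'   `consensus_position`, `partition`, `allele_in`, `allele_out`, `depth`,
#'   `freq_in`, `freq_out`, `freq_other`, `called`, `no_call_reason`.
#'   Attribute `groups` carries the map's group universe and
#'   `consensus_length` the coordinate circle.
#' @export
quantify_sites <- function(pile, map, min_depth = 20) {
  stopifnot(inherits(pile, "pileup_table"), inherits(map, "snp_map"))
  s <- map$sites[!startsWith(map$sites$site_class, "excluded"), ,
                 drop = FALSE]
  L <- attr(pile, "consensus_length")
  if (nrow(s) && max(s$consensus_position) > L)
    stop("map position beyond consensus length: map and pileup do not share ",
         "a coordinate system")
  counts <- unclass(pile)
  depth <- rowSums(counts)[s$consensus_position]
  idx_in <- cbind(s$consensus_position, match(s$allele_in, colnames(counts)))
  idx_out <- cbind(s$consensus_position, match(s$allele_out, colnames(counts)))
  n_in <- counts[idx_in]
  n_out <- counts[idx_out]
  called <- depth >= min_depth
  freq_in <- ifelse(called, n_in / depth, NA_real_)
  freq_out <- ifelse(called, n_out / depth, NA_real_)
  obs <- data.frame(
    consensus_position = s$consensus_position,
    partition = s$partition,
    allele_in = s$allele_in, allele_out = s$allele_out,
    depth = as.integer(depth),
    freq_in = freq_in, freq_out = freq_out,
    freq_other = ifelse(called, 1 - freq_in - freq_out, NA_real_),
    called = called,
    no_call_reason = ifelse(called, NA_character_,
                            paste0("depth<", min_depth)),
    stringsAsFactors = FALSE)
  rownames(obs) <- NULL
  structure(obs, class = c("allele_freqs", "data.frame"),
            groups = map$groups, consensus_length = L)
}

#' Per-group detection summary over single-group SNP sites
#'
#' For each genome group, counts how many of its single-group map sites show
#' the group-specific allele above the detection threshold, and the median
#' detected frequency. Low detected fractions together with trace-level
#' median frequencies indicate a lineage that is not a real mixture
#' component (its apparent signal is sequencing error).
#'
#' @param obs An [quantify_sites()] result.
#' @param map The `snp_map` the observations were computed from.
#' @param detect_threshold Minimum `freq_in` for a site to count as detected
#'   (default 0.005, separating sequencing error from real minor
#'   components).
#' @return A `detection_summary` data frame with one row per group:
#'   `group`, `n_possible`, `n_called`, `n_detected`, `detected_frac`,
#'   `median_freq` (median `freq_in` over detected sites; `NA` when none).
#' @export
detection_summary <- function(obs, map, detect_threshold = 0.005) {
  stopifnot(inherits(obs, "allele_freqs"), inherits(map, "snp_map"))
  singles <- obs[nchar(obs$partition) == 1L, , drop = FALSE]
  rows <- lapply(map$groups, function(g) {
    gs <- singles[singles$partition == g, , drop = FALSE]
    called <- gs[gs$called, , drop = FALSE]
    det <- called[called$freq_in > detect_threshold, , drop = FALSE]
    n_possible <- map$per_group_counts[[g]]
    data.frame(group = g,
               n_possible = n_possible,
               n_called = nrow(called),
               n_detected = nrow(det),
               detected_frac = if (n_possible > 0)
                 nrow(det) / n_possible else NA_real_,
               median_freq = if (nrow(det)) median(det$freq_in) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("detection_summary", "data.frame"),
            detect_threshold = detect_threshold)
}
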