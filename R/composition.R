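#' Infer which lineages are present in the sequenced mixture
#'
#' A genome group is called present when the median detected frequency of
#' its group-specific SNPs reaches `presence_median` and the fraction of its
#' map sites at which the allele was detected reaches
#' `presence_detected_frac`. The defaults (5% and 50%) call trace-level
#' groups absent: error-driven signals sit at about 1% median frequency with
#' detection at a small minority of sites.
#'
#' A group represented by very few map sites cannot be called reliably from
#' its own sites. When exactly one lineage passes the direct rule and its
#' median frequency is materially below 100% (below `1 - presence_median`),
#' the unexplained complement must belong to another lineage; the group with
#' the weakest map (fewest sites, or `complement_candidate` if given) is
#' then added as the complement candidate.
#'
#' @param summary A [detection_summary()] result.
#' @param presence_median Minimum median detected frequency (default 0.05).
#' @param presence_detected_frac Minimum detected fraction of map sites
#'   (default 0.5).
#' @param complement_candidate Group label to add under the complement rule;
#'   `NULL` picks the group with the fewest map sites.
#' @return Character vector of present group labels, sorted.
#' @export
infer_present_lineages <- function(summary, presence_median = 0.05,
                                   presence_detected_frac = 0.5,
                                   complement_candidate = NULL) {
  stopifnot(inherits(summary, "detection_summary"))
  direct <- !is.na(summary$median_freq) &
    summary$median_freq >= presence_median &
    !is.na(summary$detected_frac) &
    summary$detected_frac >= presence_detected_frac
  present <- summary$group[direct]
  if (length(present) == 1L) {
    med <- summary$median_freq[summary$group == present]
    if (med <= 1 - presence_median) {
      rest <- summary[summary$group != present, , drop = FALSE]
      cand <- if (!is.null(complement_candidate)) complement_candidate
              else rest$group[which.min(rest$n_possible)]
      present <- c(present, cand)
    }
  }
  if (!length(present))
    stop("no lineage passes the presence call; supply the present set ",
         "manually (e.g. to assign_combined_groups())")
  sort(present)
}

#' Assign allele-frequency observations to combined genome groups
#'
#' Each called site contributes two allele sides: its partition `S` with
#' `freq_in`, and the complement of `S` with `freq_out`. A side is assigned
#' to the combined group named by its intersection with the present set;
#' sides containing every present lineage are quality-control observations
#' (expected near 100%), and sides disjoint from the present set are pooled
#' into the residual combined group of absent lineages (e.g. `"BCD"` when A
#' and E are present). Sides whose frequency does not exceed
#' `detect_threshold` are dropped as undetected.
#'
#' The residual group is labelled by the absent lineages whose own
#' single-group allele was detected at least once (mirroring how an absent
#' group with zero detected sites drops out of the label), falling back to
#' all absent lineages.
#'
#' @param obs An [quantify_sites()] result.
#' @param present Character vector of present group labels (from
#'   [infer_present_lineages()] or supplied manually).
#' @param detect_threshold Minimum side frequency to retain (default 0.005).
#' @return An object of class `combined_groups`: data frame with columns
#'   `consensus_position`, `side` (`"in"`/`"out"`), `side_partition`,
#'   `combined_group` (`"QC"` for quality-control sides) and `freq`.
#'   Attributes: `present`, `groups`, `residual_label`, `consensus_length`.
#' @export
assign_combined_groups <- function(obs, present, detect_threshold = 0.005) {
  stopifnot(inherits(obs, "allele_freqs"), length(present) >= 1L)
  groups <- attr(obs, "groups")
  if (!all(present %in% groups))
    stop("present groups not in the map's group universe: ",
         paste(setdiff(present, groups), collapse = ", "))
  present <- sort(present)
  absent <- setdiff(groups, present)
  called <- obs[obs$called, , drop = FALSE]
  part_sets <- strsplit(called$partition, "", fixed = TRUE)

  detected_single <- unique(called$partition[
    nchar(called$partition) == 1L & called$freq_in > detect_threshold])
  residual_label <- paste(intersect(absent, detected_single), collapse = "")
  if (residual_label == "") residual_label <- paste(absent, collapse = "")
  if (residual_label == "") residual_label <- NA_character_

  side_label <- function(S) {
    if (all(present %in% S)) return("QC")
    inter <- intersect(S, present)
    if (length(inter)) paste(sort(inter), collapse = "") else residual_label
  }
  one_side <- function(S, freq) {
    lab <- vapply(S, side_label, "")
    data.frame(consensus_position = called$consensus_position,
               side_partition = vapply(S, paste, "", collapse = ""),
               combined_group = lab, freq = freq, stringsAsFactors = FALSE)
  }
  inn <- one_side(part_sets, called$freq_in)
  inn$side <- "in"
  comp_sets <- lapply(part_sets, function(S) setdiff(groups, S))
  outt <- one_side(comp_sets, called$freq_out)
  outt$side <- "out"
  cg <- rbind(inn, outt)
  cg <- cg[!is.na(cg$combined_group) & cg$freq > detect_threshold, ,
           drop = FALSE]
  cg <- cg[order(cg$consensus_position, cg$side),
           c("consensus_position", "side", "side_partition",
             "combined_group", "freq")]
  rownames(cg) <- NULL
  structure(cg, class = c("combined_groups", "data.frame"),
            present = present, groups = groups,
            residual_label = residual_label,
            consensus_length = attr(obs, "consensus_length"))
}

#' Summarize combined-group frequency distributions
#'
#' Reports, per combined group, the data size, the mean with its normal
#' 95% confidence limits, and the median with 5-95 linear-interpolation
#' percentiles, all in percent.
#'
#' @param cg An [assign_combined_groups()] result.
#' @param conf_level Confidence level for the mean (default 0.95).
#' @param probs Percentile pair for the median spread (default
#'   `c(0.05, 0.95)`).
#' @param include_qc Include the quality-control side set as a row (default
#'   `FALSE`).
#' @return A `group_summary` data frame: `combined_group`,
#'   `member_partitions`, `n`, `mean`, `cl_lo`, `cl_hi`, `median`, `p_lo`,
#'   `p_hi` (percent).
#' @export
summarize_groups <- function(cg, conf_level = 0.95, probs = c(0.05, 0.95),
                             include_qc = FALSE) {
  stopifnot(inherits(cg, "combined_groups"))
  dat <- if (include_qc) cg else cg[cg$combined_group != "QC", , drop = FALSE]
  if (!nrow(dat)) stop("no retained observations to summarize")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(split(dat, dat$combined_group), function(d) {
    f <- d$freq * 100
    n <- length(f)
    se <- if (n > 1) sd(f) / sqrt(n) else 0
    qs <- quantile(f, probs, names = FALSE, type = 7)
    data.frame(combined_group = d$combined_group[1],
               member_partitions = paste(sort(unique(d$side_partition)),
                                         collapse = ","),
               n = n, mean = mean(f), cl_lo = mean(f) - z * se,
               cl_hi = mean(f) + z * se, median = median(f),
               p_lo = qs[1], p_hi = qs[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("group_summary", "data.frame"),
            present = attr(cg, "present"),
            residual_label = attr(cg, "residual_label"))
}

#' Weighted-median mixture composition
#'
#' Each combined group's median frequency is weighted by its data size and
#' normalized to 100%:
#' `share_g = median_g * n_g / sum_h(median_h * n_h) * 100`.
#' Under `trace_policy = "zero_out"`, groups listed in `trace_groups`
#' (typically the residual group of absent lineages, whose low median is
#' sequencing error, not a real component) are set to 0 and the remaining
#' groups renormalized; `"keep"` retains them.
#'
#' @param medians Named numeric vector of per-group median frequencies (any
#'   common scale; percent and fractions give identical shares).
#' @param data_sizes Numeric vector of data sizes `n`, matching `medians`.
#' @param trace_policy `"zero_out"` (default) or `"keep"`.
#' @param trace_groups Group labels treated as trace under `"zero_out"`.
#' @return A `composition_shares` data frame: `combined_group`, `median`,
#'   `n`, `share` (percent, full precision) and `share_rounded` (integer
#'   percent, as conventionally reported).
#' @export
weighted_median_composition <- function(medians, data_sizes,
                                        trace_policy = c("zero_out", "keep"),
                                        trace_groups = character()) {
  trace_policy <- match.arg(trace_policy)
  if (is.null(names(medians)))
    stop("'medians' must be named by combined group")
  if (length(medians) < 2L)
    stop("need at least two combined groups")
  if (length(data_sizes) != length(medians))
    stop("'data_sizes' must match 'medians'")
  if (!is.null(names(data_sizes)) &&
      !identical(names(data_sizes), names(medians)))
    data_sizes <- data_sizes[names(medians)]
  eff <- medians
  if (trace_policy == "zero_out" && length(trace_groups))
    eff[names(eff) %in% trace_groups] <- 0
  w <- eff * data_sizes
  if (sum(w) <= 0)
    stop("all (effective) medians are zero; composition undefined")
  share <- 100 * w / sum(w)
  out <- data.frame(combined_group = names(medians),
                    median = unname(medians), n = unname(data_sizes),
                    share = unname(share),
                    share_rounded = unname(round(share)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("composition_shares", "data.frame"),
            trace_policy = trace_policy, trace_groups = trace_groups)
}

#' Pairwise Tukey-HSD comparison of combined-group frequencies
#'
#' One-way ANOVA across the combined groups' per-site frequencies followed
#' by Tukey's honestly-significant-difference test (Tukey-Kramer for unequal
#' group sizes, as implemented by [stats::TukeyHSD()]). Pairs whose adjusted
#' p-value exceeds `alpha` are flagged as not significantly different.
#'
#' @param cg An [assign_combined_groups()] result.
#' @param alpha Significance level (default 0.05).
#' @return A `group_comparisons` data frame: `pair`, `diff`, `lwr`, `upr`,
#'   `p_adj`, `not_different`; or, when the within-group variance is
#'   degenerate or fewer than two groups have two or more observations, a
#'   zero-row frame with attribute `note = "non-testable"`.
#' @export
compare_groups <- function(cg, alpha = 0.05) {
  stopifnot(inherits(cg, "combined_groups"))
  dat <- cg[cg$combined_group != "QC", , drop = FALSE]
  sizes <- table(dat$combined_group)
  usable <- names(sizes)[sizes >= 2L]
  dat <- dat[dat$combined_group %in% usable, , drop = FALSE]
  empty <- data.frame(pair = character(), diff = numeric(), lwr = numeric(),
                      upr = numeric(), p_adj = numeric(),
                      not_different = logical(), stringsAsFactors = FALSE)
  if (length(usable) < 2L)
    return(structure(empty, class = c("group_comparisons", "data.frame"),
                     note = "non-testable"))
  dat$combined_group <- factor(dat$combined_group)
  fit <- aov(freq ~ combined_group, data = dat)
  if (stats::deviance(fit) / stats::df.residual(fit) < 1e-12)
    return(structure(empty, class = c("group_comparisons", "data.frame"),
                     note = "non-testable"))
  tk <- TukeyHSD(fit)$combined_group
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"],
                    not_different = tk[, "p adj"] > alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("group_comparisons", "data.frame"), alpha = alpha)
}

#' Flag genome regions whose SNP frequencies deviate from their group
#'
#' Slides a window along the consensus and flags intervals where an excess
#' of site frequencies deviate from their combined group's global median. A
#' site is deviant when its absolute deviation exceeds `z` robust standard
#' deviations (1.4826 x MAD of all deviations); a window is flagged when the
#' deviant fraction reaches `outlier_frac`. Absolute deviations and outlier
#' fractions are used rather than a plain windowed median: in a recombinant
#' block the two allele sides of each site deviate in opposite directions
#' (their signed deviations cancel), and map sites unaffected by the
#' recombination dilute the block's sites to near half of a window, where a
#' median is unstable. Flagged intervals are candidate recombination
#' regions.
#'
#' @param cg An [assign_combined_groups()] result.
#' @param window Window width in nt (default 5000).
#' @param z Robust z threshold for a deviant site (default 3).
#' @param step Window step (default half the width).
#' @param min_sites Minimum observations per window to test (default 5).
#' @param outlier_frac Deviant-site fraction that flags a window (default
#'   0.3).
#' @return Data frame of half-open 1-based intervals (`start`, `end`) with
#'   the deviant fraction over the merged interval's windows
#'   (`outlier_frac`), merged over overlapping flagged windows.
#' @export
flag_discordant_regions <- function(cg, window = 5000, z = 3,
                                    step = ceiling(window / 2),
                                    min_sites = 5, outlier_frac = 0.3) {
  stopifnot(inherits(cg, "combined_groups"))
  dat <- cg[cg$combined_group != "QC", , drop = FALSE]
  empty <- data.frame(start = integer(), end = integer(),
                      outlier_frac = numeric())
  if (!nrow(dat)) return(empty)
  gmed <- tapply(dat$freq, dat$combined_group, median)
  r <- dat$freq - gmed[dat$combined_group]
  sigma <- mad(r)
  if (sigma <= 0) return(empty)  # degenerate: all sites at group medians
  L <- attr(cg, "consensus_length")
  if (is.null(L)) L <- max(dat$consensus_position)
  starts <- seq(1L, max(1L, L), by = step)
  flagged <- list()
  for (s in starts) {
    inw <- dat$consensus_position >= s & dat$consensus_position < s + window
    if (sum(inw) < min_sites) next
    frac <- mean(abs(r[inw]) > z * sigma)
    if (frac >= outlier_frac)
      flagged[[length(flagged) + 1L]] <-
        c(start = s, end = min(s + window, L + 1L), dev = frac)
  }
  if (!length(flagged)) return(empty)
  f <- do.call(rbind, flagged)
  f <- f[order(f[, "start"]), , drop = FALSE]
  out <- list()
  cur <- f[1, ]
  devs <- f[1, "dev"]
  if (nrow(f) > 1) for (i in 2:nrow(f)) {
    if (f[i, "start"] <= cur["end"]) {
      cur["end"] <- max(cur["end"], f[i, "end"])
      devs <- c(devs, f[i, "dev"])
    } else {
      out[[length(out) + 1L]] <- c(cur["start"], cur["end"], median(devs))
      cur <- f[i, ]
      devs <- f[i, "dev"]
    }
  }
  out[[length(out) + 1L]] <- c(cur["start"], cur["end"], median(devs))
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c("start", "end", "outlier_frac")
  res$start <- as.integer(res$start)
  res$end <- as.integer(res$end)
  rownames(res) <- NULL
  res
}

#' Full composition estimate from allele-frequency observations
#'
#' Convenience wrapper running presence inference, combined-group
#' assignment, distribution summaries, the weighted-median composition with
#' trace-group handling, and the Tukey-HSD group comparison.
#'
#' @param obs An [quantify_sites()] result.
#' @param map The `snp_map` used for quantification.
#' @param trace_policy `"zero_out"` (default) or `"keep"`; applied to the
#'   residual combined group of absent lineages.
#' @param present Optional manual present set; `NULL` infers it.
#' @param detect_threshold,presence_median,presence_detected_frac,alpha
#'   Passed to the component steps.
#' @return An object of class `composition_estimate`: list with `present`,
#'   `detection`, `combined`, `group_summary`, `composition`
#'   (a [weighted_median_composition()] frame), `comparisons` and
#'   `discordant_regions`.
#' @export
estimate_composition <- function(obs, map, trace_policy = "zero_out",
                                 present = NULL, detect_threshold = 0.005,
                                 presence_median = 0.05,
                                 presence_detected_frac = 0.5,
                                 alpha = 0.05) {
  det <- detection_summary(obs, map, detect_threshold)
  if (is.null(present))
    present <- infer_present_lineages(det, presence_median,
                                      presence_detected_frac)
  cg <- assign_combined_groups(obs, present, detect_threshold)
  gs <- summarize_groups(cg)
  residual <- attr(cg, "residual_label")
  trace_groups <- if (!is.na(residual)) residual else character()
  comp <- weighted_median_composition(
    setNames(gs$median, gs$combined_group), setNames(gs$n, gs$combined_group),
    trace_policy = trace_policy, trace_groups = trace_groups)
  structure(
    list(present = present, detection = det, combined = cg,
         group_summary = gs, composition = comp,
         comparisons = compare_groups(cg, alpha),
         discordant_regions = flag_discordant_regions(cg)),
    class = "composition_estimate"
  )
}

#' @export
print.composition_estimate <- function(x, digits = 1, ...) {
  cat("Genome-group composition estimate\n")
  cat("  present lineages:", paste(x$present, collapse = ", "), "\n\n")
  gs <- x$group_summary
  comp <- x$composition
  tab <- data.frame(
    combined_group = gs$combined_group,
    n = gs$n,
    `mean (95% CL)` = sprintf("%.0f (%.0f-%.0f)", gs$mean, gs$cl_lo,
                              gs$cl_hi),
    `median (5-95%)` = sprintf("%.0f (%.1f-%.1f)", gs$median, gs$p_lo,
                               gs$p_hi),
    `weighted median` = comp$share_rounded[match(gs$combined_group,
                                                 comp$combined_group)],
    check.names = FALSE)
  print(tab, row.names = FALSE)
  cat("\n  trace policy:", attr(comp, "trace_policy"),
      if (length(attr(comp, "trace_groups")))
        paste0("(trace: ", paste(attr(comp, "trace_groups"), collapse = ","),
               ")") else "", "\n")
  if (nrow(x$comparisons)) {
    nd <- x$comparisons$pair[x$comparisons$not_different]
    if (length(nd))
      cat("  not significantly different (Tukey-HSD):",
          paste(nd, collapse = "; "), "\n")
  }
  if (nrow(x$discordant_regions))
    cat("  discordant regions:",
        paste(sprintf("%d-%d", x$discordant_regions$start,
                      x$discordant_regions$end), collapse = ", "), "\n")
  invisible(x)
}
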