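#' Abbott correction of treated mortality for control mortality
#'
#' `corrected = (treated - control) / (100 - control) * 100`, in percent.
#' Negative corrected values (treated below control) are clipped to 0 and
#' flagged via the `"clipped"` attribute.
#'
#' @param treated_mortality Treated mortality in percent (vectorized).
#' @param control_mortality Control (natural) mortality in percent; must be
#'   below 100.
#' @return Corrected mortality in percent, with logical attribute
#'   `"clipped"`.
#' @export
abbott_correct <- function(treated_mortality, control_mortality) {
  if (any(treated_mortality < 0 | treated_mortality > 100) ||
      any(control_mortality < 0 | control_mortality > 100))
    stop("mortalities must lie in [0, 100]")
  if (any(control_mortality >= 100))
    stop("Abbott correction undefined at 100% control mortality")
  corrected <- (treated_mortality - control_mortality) /
    (100 - control_mortality) * 100
  clipped <- corrected < 0
  corrected[clipped] <- 0
  attr(corrected, "clipped") <- clipped
  corrected
}

#' Summarize a bioassay mortality table
#'
#' Computes per-replicate mortality, applies the Abbott correction against
#' each replicate's matched control, and reports the arithmetic mean with
#' both SD and SEM per treatment. Treatments are compared by one-way ANOVA
#' with a post-hoc Tukey-HSD test; treatments sharing a letter do not differ
#' significantly at `alpha`.
#'
#' @param table A `bioassay_table` (see [make_bioassay_table()]); columns
#'   `strain`, `isolate`, `replicate`, `n_treated`, `n_dead`, `control_n`,
#'   `control_dead`, optionally `handling_deaths`.
#' @param alpha Significance level for the Tukey-HSD letters (default 0.05).
#' @param exclude_handling_deaths If `TRUE` and a `handling_deaths` column
#'   is present, those larvae are removed from the treated denominator
#'   (deaths within the first day of handling are not virus-induced).
#' @return A `bioassay_summary` list: `summary` (per-treatment data frame
#'   with `mean_corrected`, `sd`, `sem`, `n_individuals`, `n_replicates`,
#'   `letters`), `replicates` (per-replicate corrected mortalities), and
#'   `tukey` (pairwise comparisons, or `NULL` when non-testable).
#' @export
summarize_bioassay <- function(table, alpha = 0.05,
                               exclude_handling_deaths = TRUE) {
  req <- c("strain", "isolate", "replicate", "n_treated", "n_dead",
           "control_n", "control_dead")
  if (!all(req %in% names(table)))
    stop("bioassay table must have columns: ", paste(req, collapse = ", "))
  tab <- as.data.frame(table)
  if (exclude_handling_deaths && "handling_deaths" %in% names(tab))
    tab$n_treated <- tab$n_treated - tab$handling_deaths
  tab$treatment <- paste(tab$strain, tab$isolate, sep = ":")
  bad <- is.na(tab$control_n) | tab$control_n <= 0
  if (any(bad))
    stop("missing control for treatment(s): ",
         paste(unique(tab$treatment[bad]), collapse = ", "))
  treated_pct <- tab$n_dead / tab$n_treated * 100
  control_pct <- tab$control_dead / tab$control_n * 100
  tab$corrected <- as.numeric(abbott_correct(treated_pct, control_pct))

  agg <- lapply(split(tab, tab$treatment), function(d) {
    data.frame(strain = d$strain[1], isolate = d$isolate[1],
               n_individuals = sum(d$n_treated), n_replicates = nrow(d),
               mean_corrected = mean(d$corrected),
               sd = sd(d$corrected),
               sem = sd(d$corrected) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, agg)
  summ <- summ[order(-summ$mean_corrected), , drop = FALSE]
  treatments <- rownames(summ)

  tukey <- NULL
  letters_vec <- setNames(rep(NA_character_, length(treatments)), treatments)
  if (length(treatments) >= 2L && all(summ$n_replicates >= 2L)) {
    tab$treatment <- factor(tab$treatment, levels = treatments)
    fit <- aov(corrected ~ treatment, data = tab)
    if (stats::deviance(fit) / stats::df.residual(fit) > 1e-12) {
      tk <- TukeyHSD(fit)$treatment
      tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          significant = tk[, "p adj"] < alpha,
                          stringsAsFactors = FALSE)
      rownames(tukey) <- NULL
      sig <- tukey[tukey$significant, "pair"]
      sig_pairs <- strsplit(sig, "-", fixed = TRUE)
      letters_vec <- compact_letters(treatments, sig_pairs)
    }
  }
  summ$letters <- letters_vec[rownames(summ)]
  rownames(summ) <- NULL
  structure(list(summary = summ, replicates = tab, tukey = tukey),
            class = "bioassay_summary")
}

# insert-and-absorb compact letter display: treatments share a letter iff no
# significant pairwise difference separates them
compact_letters <- function(treatments, sig_pairs) {
  sets <- list(treatments)
  for (pr in sig_pairs) {
    a <- pr[1]; b <- pr[2]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s)
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      else
        new_sets <- c(new_sets, list(s))
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) for (j in seq_along(new_sets)) {
      if (i != j && keep[i] && keep[j] &&
          all(new_sets[[i]] %in% new_sets[[j]]) &&
          (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j))
        keep[i] <- FALSE
    }
    sets <- new_sets[keep]
  }
  sets <- sets[order(vapply(sets, function(s) match(s[1], treatments), 1L))]
  out <- setNames(rep("", length(treatments)), treatments)
  for (i in seq_along(sets))
    out[sets[[i]]] <- paste0(out[sets[[i]]], letters[i])
  out
}

#' @export
print.bioassay_summary <- function(x, ...) {
  cat("Abbott-corrected bioassay summary\n")
  s <- x$summary
  s$mean_corrected <- round(s$mean_corrected, 1)
  s$sd <- round(s$sd, 1)
  s$sem <- round(s$sem, 1)
  print(s, row.names = FALSE)
  invisible(x)
}
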