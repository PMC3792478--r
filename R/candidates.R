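#' Integrate all evidence into tiered SMD candidates
#'
#' Combines the enrichment funnel, splice-signal screen, fold-change filter
#' and junction calls into one evidence vector per gene and assigns tiers:
#'
#' * Tier A: reproducibly Sm-IP enriched AND splice signals in the correct
#'   order AND up-regulated at least `theta`-fold in the splicing mutant
#'   (junction evidence annotates but does not gate this tier).
#' * Tier B: not A, but with canonical junction support AND a branch-point
#'   consensus inside the called intron.
#' * none otherwise.
#'
#' @param funnel A `funnel_report`.
#' @param signals Output of [screen_gene_set()] (defines the gene universe).
#' @param diff Output of [fold_changes()].
#' @param junctions Classified junctions (from [classify_junctions()] /
#'   [bp_within_intron()]); may have zero rows.
#' @param genes A `gene_models` data.frame (for the intron-status
#'   restriction of the fold filter).
#' @param theta Fold-change threshold (default 3).
#' @return data.frame, one row per gene, sorted by (tier, descending fold
#'   change, gene id): `gene_id`, the five evidence flags, `fc`,
#'   `junction_reads`, `tier`.
#' @export
integrate_evidence <- function(funnel, signals, diff, junctions, genes, theta = 3) {
  universe <- sort(signals$gene_id)
  orphans <- c(
    setdiff(funnel$common, universe),
    setdiff(diff$gene_id, universe),
    setdiff(stats::na.omit(junctions$host_gene), universe)
  )
  if (length(orphans)) {
    stop("inconsistent gene universes; orphan gene id(s): ",
         paste(sort(unique(orphans)), collapse = ", "))
  }
  up <- threshold_up(diff, theta, genes, restrict_to = "intronless")
  fc <- stats::setNames(diff$fc, diff$gene_id)[universe]

  has_junc <- rep(FALSE, length(universe))
  has_bp <- rep(FALSE, length(universe))
  jreads <- rep(0L, length(universe))
  if (nrow(junctions)) {
    hosted <- junctions[!is.na(junctions$host_gene) & junctions$canonical, , drop = FALSE]
    if (nrow(hosted)) {
      agg <- tapply(hosted$support, hosted$host_gene, sum)
      idx <- match(names(agg), universe)
      has_junc[idx] <- TRUE
      jreads[idx] <- as.integer(agg)
      if ("bp_in_intron" %in% names(hosted)) {
        bp_hosts <- unique(hosted$host_gene[hosted$bp_in_intron])
        has_bp[match(bp_hosts, universe)] <- TRUE
      }
    }
  }
  ev <- data.frame(
    gene_id = universe,
    sm_enriched = universe %in% funnel$common,
    signals_in_order = stats::setNames(signals$signals_in_order, signals$gene_id)[universe],
    fold_up = universe %in% up,
    junction_support = has_junc,
    bp_in_intron = has_bp,
    fc = unname(fc), junction_reads = jreads,
    stringsAsFactors = FALSE, row.names = NULL
  )
  ev$tier <- assign_tier(ev$sm_enriched, ev$signals_in_order, ev$fold_up,
                         ev$junction_support, ev$bp_in_intron)
  ord <- order(factor(ev$tier, levels = c("A", "B", "none")), -ev$fc, ev$gene_id)
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Tier from an evidence vector
#'
#' Pure function of the five evidence flags; vectorised.
#'
#' @param sm_enriched,signals_in_order,fold_up,junction_support,bp_in_intron
#'   Logical vectors.
#' @return Character vector in `{"A", "B", "none"}`.
#' @export
assign_tier <- function(sm_enriched, signals_in_order, fold_up,
                        junction_support, bp_in_intron) {
  a <- sm_enriched & signals_in_order & fold_up
  b <- !a & junction_support & bp_in_intron
  ifelse(a, "A", ifelse(b, "B", "none"))
}

#' Summarize SMD candidates
#'
#' @param candidates Output of [integrate_evidence()].
#' @param genes A `gene_models` data.frame.
#' @return An `smd_summary`: list with per-tier counts, the number of
#'   intronless genes, and the percentage of intronless genes carrying any
#'   SMD evidence (tier A or B).
#' @export
summarize_candidates <- function(candidates, genes) {
  intronless <- genes$gene_id[genes$intron_status == "intronless"]
  hits <- candidates$gene_id[candidates$tier %in% c("A", "B")]
  hits_il <- intersect(hits, intronless)
  structure(list(
    n_tier_a = sum(candidates$tier == "A"),
    n_tier_b = sum(candidates$tier == "B"),
    n_intronless = length(intronless),
    n_intronless_with_evidence = length(hits_il),
    pct_intronless_with_evidence =
      if (length(intronless)) 100 * length(hits_il) / length(intronless) else 0,
    tier_a_genes = sort(candidates$gene_id[candidates$tier == "A"]),
    tier_b_genes = sort(candidates$gene_id[candidates$tier == "B"])
  ), class = "smd_summary")
}

#' @export
print.smd_summary <- function(x, ...) {
  cat("SMD candidate summary\n")
  cat("  tier A (Sm-IP + signals + fold-up):      ", x$n_tier_a, "\n", sep = "")
  cat("  tier B (junction + BP-in-intron):        ", x$n_tier_b, "\n", sep = "")
  cat("  intronless genes with any SMD evidence:  ",
      x$n_intronless_with_evidence, "/", x$n_intronless,
      sprintf(" (%.1f%%)\n", x$pct_intronless_with_evidence), sep = "")
  invisible(x)
}
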