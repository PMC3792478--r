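#' Rank genes by IP/control enrichment
#'
#' Scores each gene by the pseudocounted, library-size-scaled log2 ratio of
#' IP to control counts:
#' `log2( ((ip + p) / ip_libsize) / ((ctl + p) / ctl_libsize) )`.
#' Ranks are by descending score with ties broken by gene id, so rankings
#' are deterministic.
#'
#' @param ct A `counts_table`.
#' @param ip_sample,control_sample Sample (column) names.
#' @param pseudocount Positive pseudocount (default 1).
#' @return data.frame `gene_id`, `ip`, `control`, `score`, `rank`.
#' @export
enrichment_scores <- function(ct, ip_sample, control_sample, pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount <= 0) stop("pseudocount must be positive")
  m <- ct$counts
  if (!all(c(ip_sample, control_sample) %in% colnames(m))) {
    stop("sample not found in counts table")
  }
  ip <- m[, ip_sample]; ctl <- m[, control_sample]
  ip_lib <- sum(ip); ctl_lib <- sum(ctl)
  score <- log2(((ip + pseudocount) / ip_lib) / ((ctl + pseudocount) / ctl_lib))
  df <- data.frame(gene_id = rownames(m), ip = as.numeric(ip),
                   control = as.numeric(ctl), score = score,
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(-df$score, df$gene_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Intersect the top-K genes of two enrichment replicates
#'
#' @param rep_a,rep_b Outputs of [enrichment_scores()].
#' @param k Top-list size (default 500; must satisfy `0 < k <= n`).
#' @return List with `k`, `top_a`, `top_b` (character vectors of size `k`)
#'   and `common` (their intersection, sorted).
#' @export
topk_intersection <- function(rep_a, rep_b, k = 500L) {
  if (!is.numeric(k) || k <= 0) stop("k must be positive")
  if (k > nrow(rep_a) || k > nrow(rep_b)) stop("k exceeds number of genes")
  top_a <- rep_a$gene_id[rep_a$rank <= k]
  top_b <- rep_b$gene_id[rep_b$rank <= k]
  list(k = as.integer(k), top_a = top_a, top_b = top_b,
       common = sort(intersect(top_a, top_b)))
}

#' Partition a gene set by intron status
#'
#' @param gene_set Character vector of gene ids.
#' @param genes A `gene_models` data.frame covering the set.
#' @return List with character vectors `intronic` and `intronless`
#'   (a disjoint, exhaustive partition of `gene_set`).
#' @export
partition_by_intron_status <- function(gene_set, genes) {
  unknown <- setdiff(gene_set, genes$gene_id)
  if (length(unknown)) stop("gene id(s) not in annotation: ", paste(unknown, collapse = ", "))
  status <- stats::setNames(genes$intron_status, genes$gene_id)[gene_set]
  list(intronic = sort(gene_set[status == "intronic"]),
       intronless = sort(gene_set[status == "intronless"]))
}

#' Cross an enriched intronless set with splice-signal calls
#'
#' @param intronless_set Character vector of intronless gene ids.
#' @param signal_table Output of [screen_gene_set()] covering the set.
#' @return List with counts `n_signals_in_order`, `n_sm_near_5ss` and the
#'   corresponding gene id vectors.
#' @export
cross_with_signals <- function(intronless_set, signal_table) {
  missing <- setdiff(intronless_set, signal_table$gene_id)
  if (length(missing)) stop("no signal row for gene(s): ", paste(missing, collapse = ", "))
  st <- signal_table[match(intronless_set, signal_table$gene_id), , drop = FALSE]
  with_sig <- intronless_set[st$signals_in_order]
  with_sm <- intronless_set[st$signals_in_order & st$sm_near_5ss]
  list(n_signals_in_order = length(with_sig), n_sm_near_5ss = length(with_sm),
       genes_signals_in_order = sort(with_sig), genes_sm_near_5ss = sort(with_sm))
}

#' Build the full Sm-IP enrichment funnel
#'
#' Runs the replicate-intersection funnel end to end: per-replicate
#' enrichment ranking against the control, top-K intersection, partition of
#' the reproducibly enriched set by intron status, and crossing of the
#' enriched intronless genes with the splice-signal screen.
#'
#' @param ct A `counts_table` with two IP samples and one control.
#' @param ip_samples Character vector of the two IP sample names.
#' @param control_sample Control (mock) sample name.
#' @param genes A `gene_models` data.frame.
#' @param signal_table Output of [screen_gene_set()].
#' @param k Top-list size.
#' @param pseudocount Enrichment pseudocount.
#' @return A `funnel_report`: list with per-replicate records, `k`, top
#'   sets, `common`, `intronic`, `intronless`, and the funnel tail counts.
#' @export
funnel_report <- function(ct, ip_samples, control_sample, genes, signal_table,
                          k = 500L, pseudocount = 1) {
  stopifnot(length(ip_samples) == 2L)
  rep_a <- enrichment_scores(ct, ip_samples[1], control_sample, pseudocount)
  rep_b <- enrichment_scores(ct, ip_samples[2], control_sample, pseudocount)
  topk <- topk_intersection(rep_a, rep_b, k)
  part <- partition_by_intron_status(topk$common, genes)
  tail <- cross_with_signals(part$intronless, signal_table)
  structure(list(
    k = topk$k, records = list(rep_a, rep_b),
    top_a = topk$top_a, top_b = topk$top_b, common = topk$common,
    n_common = length(topk$common),
    intronic = part$intronic, intronless = part$intronless,
    n_intronic = length(part$intronic), n_intronless = length(part$intronless),
    n_intronless_signals_in_order = tail$n_signals_in_order,
    n_intronless_sm_near_5ss = tail$n_sm_near_5ss,
    genes_signals_in_order = tail$genes_signals_in_order
  ), class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Sm-IP enrichment funnel (top ", x$k, " per replicate)\n", sep = "")
  cat("  reproducibly enriched: ", x$n_common, "\n", sep = "")
  cat("    intronic:            ", x$n_intronic, "\n", sep = "")
  cat("    intronless:          ", x$n_intronless, "\n", sep = "")
  cat("      with 5'ss+BP in order: ", x$n_intronless_signals_in_order, "\n", sep = "")
  cat("      with Sm site near 5'ss: ", x$n_intronless_sm_near_5ss, "\n", sep = "")
  invisible(x)
}
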