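#' Median-of-ratios library size factors
#'
#' For each sample, the size factor is the median over genes of
#' `count[g, s] / geometric_mean_g(count[g, ])`, where genes containing any
#' zero count are excluded from the median. Dividing each library by its
#' factor equalises the median-ratio gene across libraries.
#'
#' @param ct A `counts_table` (or plain counts matrix).
#' @return Named numeric vector of positive per-sample scale factors.
#' @export
size_factors <- function(ct) {
  m <- if (inherits(ct, "counts_table")) ct$counts else ct
  if (ncol(m) < 2L) stop("need at least two samples")
  nonzero <- rowSums(m == 0L) == 0L
  if (!any(nonzero)) stop("no gene with all-nonzero counts; cannot normalize")
  mm <- m[nonzero, , drop = FALSE]
  geo <- exp(rowMeans(log(mm)))
  sf <- apply(mm / geo, 2L, stats::median)
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factor")
  sf
}

#' Mutant-vs-wild-type fold changes
#'
#' Normalizes each library by its median-of-ratios size factor, averages
#' normalized counts within each condition, and reports
#' `fc = (mean_mut + p) / (mean_wt + p)` per gene.
#'
#' @param ct A `counts_table`.
#' @param wt_samples,mut_samples Sample name vectors (non-empty).
#' @param pseudocount Positive pseudocount on the normalized means
#'   (default 1).
#' @return data.frame `gene_id`, `wt_mean`, `mut_mean`, `fc`.
#' @export
fold_changes <- function(ct, wt_samples, mut_samples, pseudocount = 1) {
  if (length(wt_samples) == 0L || length(mut_samples) == 0L) {
    stop("each condition needs at least one sample")
  }
  m <- ct$counts
  missing <- setdiff(c(wt_samples, mut_samples), colnames(m))
  if (length(missing)) stop("sample(s) not in counts table: ", paste(missing, collapse = ", "))
  sf <- size_factors(ct)
  norm <- sweep(m, 2L, sf, "/")
  wt_mean <- rowMeans(norm[, wt_samples, drop = FALSE])
  mut_mean <- rowMeans(norm[, mut_samples, drop = FALSE])
  data.frame(
    gene_id = rownames(m),
    wt_mean = unname(wt_mean), mut_mean = unname(mut_mean),
    fc = unname((mut_mean + pseudocount) / (wt_mean + pseudocount)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Genes up-regulated at least theta-fold
#'
#' Applies the fold-change threshold and (optionally) restricts to genes of
#' a given intron status -- the default mirrors the screen for intronless
#' transcripts at least threefold up in a splicing mutant. The returned set
#' is monotone in `theta`: raising the threshold can only shrink it.
#'
#' @param records Output of [fold_changes()].
#' @param theta Positive fold-change threshold (default 3).
#' @param genes Optional `gene_models` data.frame for the status
#'   restriction.
#' @param restrict_to `"intronless"`, `"intronic"`, or `NULL` for no
#'   restriction.
#' @return Sorted character vector of gene ids.
#' @export
threshold_up <- function(records, theta = 3, genes = NULL, restrict_to = "intronless") {
  if (!is.numeric(theta) || theta <= 0) stop("theta must be positive")
  up <- records$gene_id[records$fc >= theta]
  if (!is.null(restrict_to) && !is.null(genes)) {
    keep <- genes$gene_id[genes$intron_status == restrict_to]
    up <- intersect(up, keep)
  }
  sort(up)
}
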