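#' Pair each branch point with its nearest downstream acceptor
#'
#' For every branch-point hit in a profile, finds the nearest `AG`
#' dinucleotide starting strictly downstream of the BP start. Spacing is
#' `acceptor_start - bp_start` (both at the first base of their element, in
#' ATG-relative transcript coordinates); a pairing is feasible for the
#' second splicing step iff an acceptor exists and the spacing is at most
#' `d_max`.
#'
#' @param profile A `splice_signal_profile`.
#' @param d_max Maximum BP-to-acceptor spacing in nt for two-step splicing
#'   (default 100; must be positive).
#' @return data.frame with columns `gene_id`, `bp`, `acceptor` (NA when no
#'   downstream AG exists), `spacing`, `feasible_two_step`.
#' @export
pair_bp_to_acceptors <- function(profile, d_max = 100L) {
  if (!is.numeric(d_max) || d_max <= 0) stop("d_max must be positive")
  bp <- profile$bp$start
  if (length(bp) == 0L) {
    return(data.frame(gene_id = character(), bp = integer(),
                      acceptor = integer(), spacing = integer(),
                      feasible_two_step = logical(), stringsAsFactors = FALSE))
  }
  acc <- vapply(bp, function(b) {
    down <- profile$acceptors[profile$acceptors > b]
    if (length(down)) min(down) else NA_integer_
  }, integer(1))
  spacing <- acc - bp
  data.frame(
    gene_id = profile$gene_id, bp = as.integer(bp),
    acceptor = as.integer(acc), spacing = as.integer(spacing),
    feasible_two_step = !is.na(acc) & spacing <= d_max,
    stringsAsFactors = FALSE
  )
}

#' Classify a (donor, BP pairing) as cleavage-only or two-step
#'
#' A donor/BP combination supports complete (two-step) splicing iff the BP
#' has a feasible acceptor pairing; otherwise only the first
#' transesterification (cleavage) can occur and the event is classified
#' `cleavage_only`. Two-step events carry the intron interval from the first
#' base of the donor motif through the G of the acceptor AG.
#'
#' @param donor 5'ss start (ATG-relative).
#' @param pairing One row of [pair_bp_to_acceptors()] output.
#' @param d_max Maximum feasible BP-to-acceptor spacing (nt).
#' @return A `splice_event`: list with `gene_id`, `donor`, `bp`, `acceptor`,
#'   `spacing`, `event_class`, `intron` (`c(start, end)` for two-step, NULL
#'   otherwise), `frame_effect` (`"not_applicable"` until
#'   [classify_frame_effect()]).
#' @export
classify_event <- function(donor, pairing, d_max = 100L) {
  if (!is.numeric(d_max) || d_max <= 0) stop("d_max must be positive")
  if (donor >= pairing$bp) stop("donor must lie upstream of the branch point")
  feasible <- !is.na(pairing$acceptor) && (pairing$acceptor - pairing$bp) <= d_max
  ev <- list(
    gene_id = pairing$gene_id, donor = as.integer(donor),
    bp = as.integer(pairing$bp), acceptor = as.integer(pairing$acceptor),
    spacing = as.integer(pairing$spacing),
    event_class = if (feasible) "two_step" else "cleavage_only",
    intron = if (feasible) c(as.integer(donor), as.integer(pairing$acceptor) + 1L) else NULL,
    frame_effect = "not_applicable"
  )
  structure(ev, class = "splice_event")
}

#' Enumerate splice events for a profiled gene
#'
#' Builds one event per ordered (donor, BP) pair of the profile, using the
#' nearest-acceptor pairing of each BP.
#'
#' @param profile A `splice_signal_profile`.
#' @param d_max Maximum feasible BP-to-acceptor spacing (nt).
#' @return List of `splice_event` objects.
#' @export
splice_events <- function(profile, d_max = 100L) {
  pairings <- pair_bp_to_acceptors(profile, d_max)
  out <- list()
  for (i in seq_len(nrow(profile$ordered_pairs))) {
    d <- profile$ordered_pairs$donor[i]
    b <- profile$ordered_pairs$bp[i]
    p <- pairings[pairings$bp == b, , drop = FALSE][1, ]
    out[[length(out) + 1L]] <- classify_event(d, p, d_max)
  }
  out
}

#' Re-select the acceptor after a sequence edit
#'
#' Applies point substitutions to the transcript (e.g. destroying an
#' acceptor AG) and re-runs nearest-downstream-AG pairing for the same
#' branch point on the edited sequence, mimicking alternative 3'ss selection
#' after site disruption.
#'
#' @param transcript A `transcript` object.
#' @param pairing One row of [pair_bp_to_acceptors()] output.
#' @param edits data.frame with columns `pos` (ATG-relative coordinate) and
#'   `base` (replacement base); zero rows is a no-op.
#' @param d_max Maximum feasible spacing (nt).
#' @return The new pairing row (same columns as [pair_bp_to_acceptors()]).
#' @export
select_acceptor_after_mutation <- function(transcript, pairing, edits, d_max = 100L) {
  seq <- transcript$seq
  if (!is.null(edits) && nrow(edits)) {
    idx <- atg_to_tx(transcript, edits$pos)
    if (any(idx < 1L | idx > nchar(seq))) stop("edit outside transcript")
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[idx] <- norm_base(edits$base)
    seq <- paste(chars, collapse = "")
  }
  ag <- tx_to_atg(transcript, ag_positions(seq))
  down <- ag[ag > pairing$bp]
  acc <- if (length(down)) min(down) else NA_integer_
  data.frame(
    gene_id = pairing$gene_id, bp = as.integer(pairing$bp),
    acceptor = as.integer(acc), spacing = as.integer(acc - pairing$bp),
    feasible_two_step = !is.na(acc) && (acc - pairing$bp) <= d_max,
    stringsAsFactors = FALSE
  )
}

#' Reading-frame consequence of a two-step splice event
#'
#' Classifies what excising the event's intron does to the coding sequence:
#' `utr5_intron`/`utr3_intron` when the intron lies entirely outside the
#' CDS, `frameshift` when the number of CDS bases removed is not a multiple
#' of 3, `ptc_introduced` when the deletion is in-frame but the spliced CDS
#' gains a stop codon before its original stop, and `in_frame_deletion`
#' otherwise.
#'
#' @param event A two-step `splice_event`.
#' @param gene One row of a `gene_models` data.frame.
#' @param transcript The matching `transcript` object.
#' @return One of `"in_frame_deletion"`, `"frameshift"`, `"ptc_introduced"`,
#'   `"utr5_intron"`, `"utr3_intron"`.
#' @export
classify_frame_effect <- function(event, gene, transcript) {
  if (event$event_class != "two_step") {
    stop("frame effect is defined only for two-step events")
  }
  cds_len <- gene$cds_end - gene$cds_start + 1L
  intron <- event$intron  # ATG-relative closed interval
  if (intron[2] < 1L) return("utr5_intron")
  if (intron[1] > cds_len) return("utr3_intron")

  removed_lo <- max(intron[1], 1L)
  removed_hi <- min(intron[2], cds_len)
  n_removed <- removed_hi - removed_lo + 1L
  if (n_removed %% 3L != 0L) return("frameshift")

  cds_seq <- substr(transcript$seq, gene$cds_start, gene$cds_end)
  keep <- setdiff(seq_len(cds_len), removed_lo:removed_hi)
  spliced <- paste(strsplit(cds_seq, "", fixed = TRUE)[[1]][keep], collapse = "")
  usable <- nchar(spliced) - nchar(spliced) %% 3L
  if (usable < 3L) return("in_frame_deletion")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(spliced, 1L, usable)),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
  stops <- which(strsplit(aa, "", fixed = TRUE)[[1]] == "*")
  premature <- any(stops < nchar(aa))
  if (premature) "ptc_introduced" else "in_frame_deletion"
}
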