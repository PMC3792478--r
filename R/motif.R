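#' Degenerate consensus motifs
#'
#' A consensus motif is an ordered list of elements, each one of:
#' a fixed base, a choice set of bases, or a variable-length homopolymer run
#' with a (min, max) length. RNA letters are accepted and mapped `U -> T` so
#' the whole package works over a single DNA alphabet.
#'
#' @param name Motif name.
#' @param elements List of elements built with [motif_fixed()],
#'   [motif_choice()] or [motif_run()].
#' @return A `consensus_motif` object with `min_len`/`max_len` fields.
#' @seealso [splice_motifs()] for the built-in splice-signal consensi.
#' @export
consensus_motif <- function(name, elements) {
  stopifnot(is.character(name), length(elements) >= 1L)
  lens <- vapply(elements, function(e) {
    switch(e$type, fixed = c(1L, 1L), choice = c(1L, 1L), run = c(e$min, e$max))
  }, integer(2))
  min_len <- sum(lens[1, ]); max_len <- sum(lens[2, ])
  if (min_len < 1L) stop("motif minimum length must be >= 1")
  structure(list(name = name, elements = elements,
                 min_len = min_len, max_len = max_len),
            class = "consensus_motif")
}

norm_base <- function(b) {
  b <- chartr("u", "t", chartr("U", "T", toupper(b)))
  if (!all(b %in% c("A", "C", "G", "T"))) stop("invalid base(s): ", paste(b, collapse = ","))
  b
}

#' @rdname consensus_motif
#' @param base A single base.
#' @export
motif_fixed <- function(base) list(type = "fixed", base = norm_base(base))

#' @rdname consensus_motif
#' @param bases A character vector of alternative bases.
#' @export
motif_choice <- function(bases) {
  bases <- unique(norm_base(bases))
  if (length(bases) < 1L) stop("empty choice set")
  list(type = "choice", bases = bases)
}

#' @rdname consensus_motif
#' @param min,max Run length bounds (inclusive).
#' @export
motif_run <- function(base, min, max) {
  if (!is.finite(min) || !is.finite(max) || min > max || min < 1) {
    stop("invalid run bounds: need 1 <= min <= max < Inf")
  }
  min <- as.integer(min); max <- as.integer(max)
  list(type = "run", base = norm_base(base), min = min, max = max)
}

#' Built-in splice-signal and Sm-site consensi
#'
#' The three degenerate elements scanned by the pipeline, in the DNA
#' alphabet: the 5' splice-site donor `GTA[T/C/A]GT`, the branch-point
#' `ACTAAC[G/A/T]` (the branch adenosine is the 6th-from-last position of the
#' heptamer), and the single-stranded Sm-ring binding element
#' `[A/G]AT{4,6}G[A/G]` (purine, A, a run of 4-6 U, G, purine).
#'
#' @return A named list of `consensus_motif` objects:
#'   `five_ss`, `branch_point`, `sm_site`.
#' @export
splice_motifs <- function() {
  list(
    five_ss = consensus_motif("five_ss", list(
      motif_fixed("G"), motif_fixed("T"), motif_fixed("A"),
      motif_choice(c("T", "C", "A")), motif_fixed("G"), motif_fixed("T")
    )),
    branch_point = consensus_motif("branch_point", list(
      motif_fixed("A"), motif_fixed("C"), motif_fixed("T"),
      motif_fixed("A"), motif_fixed("A"), motif_fixed("C"),
      motif_choice(c("G", "A", "T"))
    )),
    sm_site = consensus_motif("sm_site", list(
      motif_choice(c("A", "G")), motif_fixed("A"),
      motif_run("T", 4L, 6L),
      motif_fixed("G"), motif_choice(c("A", "G"))
    ))
  )
}

#' Expand a consensus motif to its literal strings
#'
#' @param motif A `consensus_motif`.
#' @return Character vector of all DNA literals matching the motif; its
#'   length is the product of the element choice counts times the number of
#'   run lengths.
#' @export
expand_consensus <- function(motif) {
  parts <- lapply(motif$elements, function(e) {
    switch(e$type,
      fixed = e$base,
      choice = e$bases,
      run = vapply(e$min:e$max, function(k) strrep(e$base, k), "")
    )
  })
  n <- prod(vapply(parts, length, 1L))
  if (!is.finite(n) || n > 1e6) stop("motif expansion unbounded or too large")
  out <- Reduce(function(a, b) as.vector(outer(a, b, paste0)), parts)
  sort(out)
}

#' Scan a sequence for a consensus motif
#'
#' Reports every start position at which some expansion literal of the motif
#' matches exactly (`N` never matches). For variable-run motifs each start
#' position is reported once, keeping the longest valid match. Hits are
#' sorted by start position.
#'
#' @param seq Character scalar over `A`,`C`,`G`,`T`,`N`.
#' @param motif A `consensus_motif`.
#' @return data.frame with columns `motif`, `start`, `length`, `match`
#'   (`start` 1-based along `seq`).
#' @export
scan_sequence <- function(seq, motif) {
  stopifnot(is.character(seq), length(seq) == 1L)
  subject <- Biostrings::DNAString(seq)
  lits <- expand_consensus(motif)
  hits <- lapply(lits, function(l) {
    m <- Biostrings::matchPattern(l, subject, fixed = TRUE)
    if (length(m) == 0L) return(NULL)
    data.frame(start = Biostrings::start(m), length = nchar(l), match = l,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(motif = character(), start = integer(),
                      length = integer(), match = character(),
                      stringsAsFactors = FALSE))
  }
  ## longest-match rule: one hit per start position
  hits <- hits[order(hits$start, -hits$length), , drop = FALSE]
  hits <- hits[!duplicated(hits$start), , drop = FALSE]
  data.frame(motif = motif$name, start = as.integer(hits$start),
             length = as.integer(hits$length), match = hits$match,
             stringsAsFactors = FALSE, row.names = NULL)
}

ag_positions <- function(seq) {
  m <- Biostrings::matchPattern("AG", Biostrings::DNAString(seq), fixed = TRUE)
  as.integer(Biostrings::start(m))
}

#' Profile the splice signals of one gene
#'
#' Scans the sense-strand transcript for 5'ss, branch-point and Sm-site
#' consensi plus acceptor `AG` dinucleotides, and evaluates the
#' order/spacing criterion: the gene has signals in the correct order iff
#' some branch point starts at least `min_5ss_bp_spacing` nt downstream of
#' some 5'ss. All reported coordinates are ATG-relative (+1 = first base of
#' the start codon).
#'
#' @param gene One row of a `gene_models` data.frame.
#' @param transcript Matching `transcript` object from
#'   [transcript_sequence()].
#' @param min_5ss_bp_spacing Minimum 5'ss-to-BP start spacing in nt
#'   (default 20).
#' @return A `splice_signal_profile`: list with hit tables `five_ss`, `bp`,
#'   `sm` (ATG-relative `start`), `acceptors` (AG starts downstream of the
#'   earliest BP), `ordered_pairs` (all donor/BP pairs meeting the spacing),
#'   and flags `signals_in_correct_order`, `sm_near_5ss` (NA until
#'   [sm_sites_near_5ss()] is applied).
#' @export
call_splice_signals <- function(gene, transcript, min_5ss_bp_spacing = 20L) {
  motifs <- splice_motifs()
  to_atg <- function(df) {
    df$start <- tx_to_atg(transcript, df$start)
    df
  }
  fss <- to_atg(scan_sequence(transcript$seq, motifs$five_ss))
  bp <- to_atg(scan_sequence(transcript$seq, motifs$branch_point))
  sm <- to_atg(scan_sequence(transcript$seq, motifs$sm_site))
  ag <- tx_to_atg(transcript, ag_positions(transcript$seq))
  acceptors <- if (nrow(bp)) sort(ag[ag > min(bp$start)]) else integer()

  pairs <- data.frame(donor = integer(), bp = integer())
  if (nrow(fss) && nrow(bp)) {
    grid <- expand.grid(donor = fss$start, bp = bp$start)
    pairs <- grid[grid$bp - grid$donor >= min_5ss_bp_spacing, , drop = FALSE]
    pairs <- pairs[order(pairs$donor, pairs$bp), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(
    gene_id = gene$gene_id, five_ss = fss, bp = bp, sm = sm,
    acceptors = acceptors, ordered_pairs = pairs,
    signals_in_correct_order = nrow(pairs) > 0L,
    sm_near_5ss = NA, min_5ss_bp_spacing = as.integer(min_5ss_bp_spacing)
  ), class = "splice_signal_profile")
}

#' Flag Sm sites close upstream of a 5' splice site
#'
#' Sets `sm_near_5ss` true iff some Sm-site hit ends within
#' `[donor_start - window, donor_start - 1]` for some 5'ss hit, i.e. the Sm
#' element lies within `window` nt immediately upstream of a donor.
#'
#' @param profile A `splice_signal_profile`.
#' @param window Upstream window in nt (default 50, must be positive).
#' @return The profile with `sm_near_5ss` set.
#' @export
sm_sites_near_5ss <- function(profile, window = 50L) {
  if (!is.numeric(window) || window <= 0) stop("window must be positive")
  flag <- FALSE
  if (nrow(profile$sm) && nrow(profile$five_ss)) {
    sm_end <- profile$sm$start + profile$sm$length - 1L
    for (d in profile$five_ss$start) {
      if (any(sm_end >= d - window & sm_end <= d - 1L)) { flag <- TRUE; break }
    }
  }
  profile$sm_near_5ss <- flag
  profile
}

#' Screen a gene set for splice signals
#'
#' Runs [call_splice_signals()] and [sm_sites_near_5ss()] over every gene and
#' tabulates the screening funnel: number of intronless genes, of those with
#' 5'ss and BP in the correct order, and of those with an Sm site near the
#' 5'ss.
#'
#' @param genes A `gene_models` data.frame.
#' @param genome A named `DNAStringSet`.
#' @param min_5ss_bp_spacing Minimum 5'ss-to-BP spacing (nt).
#' @param sm_window Sm-site upstream window (nt).
#' @return data.frame, one row per gene (`gene_id`, `intron_status`,
#'   `n_5ss`, `n_bp`, `signals_in_order`, `sm_near_5ss`), with the funnel
#'   counts in `attr(, "funnel")` and the per-gene profiles in
#'   `attr(, "profiles")`.
#' @export
screen_gene_set <- function(genes, genome, min_5ss_bp_spacing = 20L, sm_window = 50L) {
  profiles <- vector("list", nrow(genes))
  names(profiles) <- genes$gene_id
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx <- transcript_sequence(genome, g)
    pr <- call_splice_signals(g, tx, min_5ss_bp_spacing)
    pr <- sm_sites_near_5ss(pr, sm_window)
    profiles[[i]] <- pr
    rows[[i]] <- data.frame(
      gene_id = g$gene_id, intron_status = g$intron_status,
      n_5ss = nrow(pr$five_ss), n_bp = nrow(pr$bp),
      signals_in_order = pr$signals_in_correct_order,
      sm_near_5ss = pr$sm_near_5ss, stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  il <- tab$intron_status == "intronless"
  funnel <- c(
    n_intronless = sum(il),
    n_intronless_signals_in_order = sum(il & tab$signals_in_order),
    n_intronless_sm_near_5ss = sum(il & tab$signals_in_order & tab$sm_near_5ss)
  )
  attr(tab, "funnel") <- funnel
  attr(tab, "profiles") <- profiles
  tab
}
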