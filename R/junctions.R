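#' Read a minimal SAM-subset alignment file
#'
#' Parses plain-text SAM records restricted to the fields and operations the
#' junction caller needs: QNAME, RNAME, POS and a CIGAR over `M` (match) and
#' `N` (skip) operations. Header lines (`@`) are ignored. Records violating
#' the subset contract (no `M`, a leading/trailing `N`, non-positive
#' lengths) are rejected.
#'
#' @param path Path to the SAM text file.
#' @return An `alignments` data.frame: `read_id`, `chrom`, `pos`, `cigar`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(structure(data.frame(read_id = character(), chrom = character(),
                                pos = integer(), cigar = character(),
                                stringsAsFactors = FALSE),
                     class = c("alignments", "data.frame")))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(f, length, 1L)
  if (any(nf < 6L)) stop("malformed SAM record: fewer than 6 fields")
  df <- data.frame(
    read_id = vapply(f, `[`, "", 1L),
    chrom = vapply(f, `[`, "", 3L),
    pos = as.integer(vapply(f, `[`, "", 4L)),
    cigar = vapply(f, `[`, "", 6L),
    stringsAsFactors = FALSE
  )
  validate_cigars(df$cigar)
  structure(df, class = c("alignments", "data.frame"))
}

validate_cigars <- function(cigar) {
  if (any(grepl("[^0-9MN]", cigar))) {
    stop("CIGAR contains operations outside the M/N subset")
  }
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  for (i in seq_along(ops)) {
    o <- ops[[i]]; l <- lens[[i]]
    if (!any(o == "M")) stop("alignment without a match operation")
    if (o[1] == "N" || o[length(o)] == "N") {
      stop("skip operation at alignment edge in CIGAR ", cigar[i])
    }
    if (any(l <= 0L)) stop("non-positive CIGAR operation length")
  }
  invisible(TRUE)
}

#' Write alignments as a minimal SAM file
#'
#' @param aln An `alignments` data.frame.
#' @param path Output path.
#' @param genome Optional named `DNAStringSet`; when given, `@SQ` header
#'   lines are emitted.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, genome = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  if (!is.null(genome)) {
    writeLines(paste0("@SQ\tSN:", names(genome), "\tLN:", Biostrings::width(genome)), con)
  }
  if (nrow(aln)) {
    writeLines(paste(aln$read_id, 0L, aln$chrom, aln$pos, 255L, aln$cigar,
                     "*", 0L, 0L, "*", "*", sep = "\t"), con)
  }
  invisible(path)
}

#' Extract intron calls from gapped alignments
#'
#' Emits one junction per skip (`N`) operation per read; the junction's
#' intron interval is the skipped genomic segment (1-based closed) and its
#' support is the number of distinct reads spanning it.
#'
#' @param aln An `alignments` data.frame (see [read_sam()]).
#' @param genome Named `DNAStringSet` (used for bounds checking).
#' @return A junction data.frame: `chrom`, `start`, `end`, `support`.
#' @export
extract_junctions <- function(aln, genome) {
  validate_cigars(aln$cigar)
  skips <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$pos, ops = "N"
  )
  n_per <- S4Vectors::elementNROWS(skips)
  if (sum(n_per) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), support = integer(),
                      stringsAsFactors = FALSE))
  }
  flat <- unlist(skips, use.names = FALSE)
  j <- data.frame(
    read_id = rep(aln$read_id, n_per),
    chrom = rep(aln$chrom, n_per),
    start = IRanges::start(flat), end = IRanges::end(flat),
    stringsAsFactors = FALSE
  )
  if (any(!j$chrom %in% names(genome))) stop("alignment on unknown chromosome")
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(j$end > chrom_len[j$chrom])) stop("skip interval beyond chromosome end")
  key <- paste(j$chrom, j$start, j$end, sep = ":")
  support <- vapply(split(j$read_id, key), function(r) length(unique(r)), 1L)
  parts <- strsplit(names(support), ":", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L)),
    support = as.integer(support),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

## Resolve the host gene of each junction and the sense-strand boundary
## dinucleotides. A junction overlapping two genes is assigned to the gene
## whose strand makes its ends canonical GT..AG; if both or neither qualify
## the host is left NA (status "intergenic" downstream).
annotate_junction_hosts <- function(junctions, genome, genes) {
  n <- nrow(junctions)
  host <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)
  donor <- rep(NA_character_, n)
  acceptor <- rep(NA_character_, n)
  dinucs <- function(chrom, s, e, str) {
    left <- as.character(Biostrings::subseq(genome[[chrom]], s, s + 1L))
    right <- as.character(Biostrings::subseq(genome[[chrom]], e - 1L, e))
    if (str == "+") c(left, right)
    else c(as.character(Biostrings::reverseComplement(Biostrings::DNAString(right))),
           as.character(Biostrings::reverseComplement(Biostrings::DNAString(left))))
  }
  for (i in seq_len(n)) {
    cand <- genes[genes$chrom == junctions$chrom[i] &
                    genes$start <= junctions$start[i] &
                    genes$end >= junctions$end[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    if (nrow(cand) == 1L) {
      pick <- 1L
    } else {
      canon <- vapply(seq_len(nrow(cand)), function(k) {
        dd <- dinucs(junctions$chrom[i], junctions$start[i], junctions$end[i],
                     cand$strand[k])
        dd[1] == "GT" && dd[2] == "AG"
      }, TRUE)
      if (sum(canon) != 1L) {
        warning("junction ", junctions$chrom[i], ":", junctions$start[i], "-",
                junctions$end[i], " overlaps ", nrow(cand),
                " genes without a unique canonical assignment")
        next
      }
      pick <- which(canon)
    }
    host[i] <- cand$gene_id[pick]
    strand[i] <- cand$strand[pick]
    dd <- dinucs(junctions$chrom[i], junctions$start[i], junctions$end[i], strand[i])
    donor[i] <- dd[1]; acceptor[i] <- dd[2]
  }
  ## record plus-strand dinucleotides even for hostless junctions
  hostless <- is.na(host)
  if (any(hostless)) {
    for (i in which(hostless)) {
      dd <- dinucs(junctions$chrom[i], junctions$start[i], junctions$end[i], "+")
      donor[i] <- dd[1]; acceptor[i] <- dd[2]
    }
  }
  junctions$host_gene <- host
  junctions$strand <- strand
  junctions$donor_dinuc <- donor
  junctions$acceptor_dinuc <- acceptor
  junctions$canonical <- !is.na(strand) & donor == "GT" & acceptor == "AG"
  junctions
}

#' Keep canonical, sufficiently supported junctions
#'
#' Annotates each junction with its host gene, sense-strand boundary
#' dinucleotides and canonical flag, then keeps junctions whose sense-strand
#' ends are `GT..AG` and whose read support is at least `min_support`.
#'
#' @param junctions Output of [extract_junctions()].
#' @param genome Named `DNAStringSet`.
#' @param genes A `gene_models` data.frame.
#' @param min_support Minimum distinct-read support (default 2).
#' @return The filtered, annotated junction data.frame.
#' @export
filter_canonical <- function(junctions, genome, genes, min_support = 2L) {
  if (nrow(junctions) == 0L) {
    junctions$host_gene <- character(0); junctions$strand <- character(0)
    junctions$donor_dinuc <- character(0); junctions$acceptor_dinuc <- character(0)
    junctions$canonical <- logical(0)
    return(junctions)
  }
  ann <- annotate_junction_hosts(junctions, genome, genes)
  keep <- ann$canonical & ann$support >= min_support
  out <- ann[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify junctions against the annotation
#'
#' Assigns each junction a status -- `annotated` (interval exactly matches
#' an annotated intron of the host gene), `novel_in_intronic`,
#' `novel_in_intronless`, or `intergenic` (no host) -- and computes the two
#' headline statistics: the percentage of intronic genes with at least one
#' annotated-matching junction, and the percentage of intronless genes with
#' at least one canonical junction.
#'
#' @param junctions Annotated junctions (from [filter_canonical()]).
#' @param genes A `gene_models` data.frame.
#' @return List with `junctions` (status column added) and `stats` (list
#'   with `pct_intronic_with_annotated_junction`,
#'   `pct_intronless_with_canonical_junction`, and the underlying counts).
#' @export
classify_junctions <- function(junctions, genes) {
  n <- nrow(junctions)
  status <- rep("intergenic", n)
  for (i in seq_len(n)) {
    if (is.na(junctions$host_gene[i])) next
    g <- genes[genes$gene_id == junctions$host_gene[i], , drop = FALSE]
    intr <- g$introns[[1]]
    matches_annot <- !is.null(intr) && nrow(intr) &&
      any(intr$start == junctions$start[i] & intr$end == junctions$end[i])
    status[i] <- if (matches_annot) "annotated"
      else if (g$intron_status == "intronic") "novel_in_intronic"
      else "novel_in_intronless"
  }
  junctions$status <- status
  intronic_ids <- genes$gene_id[genes$intron_status == "intronic"]
  intronless_ids <- genes$gene_id[genes$intron_status == "intronless"]
  ann_hosts <- unique(junctions$host_gene[status == "annotated"])
  canon_intronless <- unique(junctions$host_gene[
    junctions$canonical & !is.na(junctions$host_gene) &
      junctions$host_gene %in% intronless_ids
  ])
  pct <- function(num, den) if (den == 0L) 0 else 100 * num / den
  stats <- list(
    n_intronic_genes = length(intronic_ids),
    n_intronless_genes = length(intronless_ids),
    n_intronic_with_annotated_junction = length(ann_hosts),
    n_intronless_with_canonical_junction = length(canon_intronless),
    pct_intronic_with_annotated_junction = pct(length(ann_hosts), length(intronic_ids)),
    pct_intronless_with_canonical_junction = pct(length(canon_intronless), length(intronless_ids))
  )
  list(junctions = junctions, stats = stats)
}

#' Flag junctions whose intron contains a branch-point consensus
#'
#' Scans the sense-strand sequence of each called intron for the BP
#' consensus; when present, records the distance from the BP start to the
#' acceptor AG start (both on the sense strand; for multiple BP hits the
#' one closest to the acceptor is reported).
#'
#' @param junctions Annotated junctions with a host gene.
#' @param genome Named `DNAStringSet`.
#' @param genes A `gene_models` data.frame.
#' @return The junctions with logical `bp_in_intron` and integer
#'   `bp_to_acceptor` columns added.
#' @export
bp_within_intron <- function(junctions, genome, genes) {
  bp_motif <- splice_motifs()$branch_point
  n <- nrow(junctions)
  flag <- rep(FALSE, n)
  dist <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (is.na(junctions$host_gene[i])) next
    str <- junctions$strand[i]
    s <- junctions$start[i]; e <- junctions$end[i]
    iseq <- Biostrings::subseq(genome[[junctions$chrom[i]]], s, e)
    if (str == "-") iseq <- Biostrings::reverseComplement(iseq)
    hits <- scan_sequence(as.character(iseq), bp_motif)
    if (nrow(hits) == 0L) next
    L <- e - s + 1L
    acceptor_local <- L - 1L  # first base of the terminal AG, sense strand
    d <- acceptor_local - hits$start
    d <- d[d > 0L]
    if (length(d) == 0L) next
    flag[i] <- TRUE
    dist[i] <- min(d)
  }
  junctions$bp_in_intron <- flag
  junctions$bp_to_acceptor <- dist
  junctions
}
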