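## Independent brute-force oracles and small fixture builders used across
## the suite. Oracles deliberately avoid the code paths they check:
## motif matching is re-done with vectorized substring comparison, acceptor
## search with a character walk, and translation with a codon table walk.

random_seq <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

## literal-at-every-offset motif scan with longest-match-per-start semantics
oracle_scan <- function(seq, motif) {
  lits <- expand_consensus(motif)
  n <- nchar(seq)
  hits <- NULL
  for (L in sort(unique(nchar(lits)))) {
    if (n < L) next
    ls <- lits[nchar(lits) == L]
    starts <- seq_len(n - L + 1L)
    subs <- substring(seq, starts, starts + L - 1L)
    m <- subs %in% ls
    if (any(m)) {
      hits <- rbind(hits, data.frame(start = starts[m], length = L,
                                     match = subs[m], stringsAsFactors = FALSE))
    }
  }
  if (is.null(hits)) {
    return(data.frame(start = integer(), length = integer(),
                      match = character(), stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$start, -hits$length), , drop = FALSE]
  hits <- hits[!duplicated(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

## nearest AG start strictly downstream of `from` (1-based string coords)
oracle_nearest_ag <- function(seq, from) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- from + 1L
  while (i < n) {
    if (chars[i] == "A" && chars[i + 1L] == "G") return(i)
    i <- i + 1L
  }
  NA_integer_
}

## does a codon walk over a spliced CDS hit a stop before the final codon?
oracle_premature_stop <- function(spliced) {
  stops <- c("TAA", "TAG", "TGA")
  n_cod <- nchar(spliced) %/% 3L
  if (n_cod < 2L) return(FALSE)
  for (k in seq_len(n_cod - 1L)) {
    if (substr(spliced, 3L * k - 2L, 3L * k) %in% stops) return(TRUE)
  }
  FALSE
}

## wrap a raw transcript string into genome + gene model + transcript object
make_gene_fixture <- function(seq, gene_id = "g1", strand = "+",
                              cds_start = 1L, cds_end = nchar(seq),
                              chrom = "chrT") {
  gseq <- if (strand == "+") seq else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  genome <- Biostrings::DNAStringSet(stats::setNames(gseq, chrom))
  gene <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = 1L, end = nchar(seq),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    intron_status = "intronless", stringsAsFactors = FALSE
  )
  gene$introns <- list(data.frame(start = integer(), end = integer()))
  class(gene) <- c("gene_models", "data.frame")
  list(genome = genome, gene = gene,
       tx = transcript_sequence(genome, gene[1, ]))
}

## per-gene flag table standing in for a full planted truth (counts-only runs)
make_flag_truth <- function(n, smd = integer(), sm_bound = integer(),
                            intronic = integer()) {
  ids <- sprintf("g%03d", seq_len(n))
  g <- data.frame(gene_id = ids, intronic = FALSE, smd = FALSE,
                  sm_bound = FALSE, strand = "+", stringsAsFactors = FALSE)
  g$smd[smd] <- TRUE
  g$sm_bound[unique(c(smd, sm_bound))] <- TRUE
  g$intronic[intronic] <- TRUE
  structure(list(genes = g), class = "planted_truth")
}
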