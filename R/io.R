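#' Read a genome FASTA file
#'
#' Reads a (multi-)FASTA file into a named [Biostrings::DNAStringSet].
#' Sequences are uppercased and `U` is converted to `T` on ingest, so all
#' downstream motif matching happens over a single DNA alphabet
#' (`A`,`C`,`G`,`T`,`N`). Duplicate headers are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`; names are the first whitespace-delimited
#'   token of each header.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(raw))
  if (any(nm == "")) stop("malformed FASTA header: empty sequence name")
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA headers: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- chartr("u", "t", toupper(as.character(raw)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ", paste(nm[bad], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' Write a genome FASTA file
#'
#' @param genome A named `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

## Gene models are held in a plain data.frame, one row per gene:
## gene_id, chrom, strand, start, end (1-based closed genomic),
## cds_start, cds_end (1-based along the transcript string),
## intron_status ("intronic"/"intronless"), and a list-column `introns`
## of data.frames with genomic start/end per annotated intron.

new_gene_models <- function(df) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end",
                  "cds_start", "cds_end", "intron_status", "introns") %in% names(df)))
  if (anyDuplicated(df$gene_id)) stop("gene ids must be unique")
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA`, `CDS` and `intron` features (1-based closed
#' coordinates, per the GFF3 standard) into a gene-model table. A gene is
#' flagged `intronic` iff at least one `intron` feature belongs to it, and
#' `intronless` otherwise. CDS coordinates are converted to transcript
#' coordinates (1-based along the spliced-naive gene body, sense strand).
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_models` data.frame with columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `cds_start`, `cds_end`, `intron_status` and a
#'   list-column `introns` of genomic intervals.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  gid <- genes$ID
  if (is.null(gid) || anyDuplicated(gid)) stop("gene features need unique ID attributes")

  ## map mRNA IDs to their parent gene so CDS/intron can be keyed by gene
  parent1 <- function(x) vapply(x, function(p) if (length(p)) p[[1]] else NA_character_, "")
  mrna <- gr[type == "mRNA"]
  mrna_parent <- if (length(mrna)) stats::setNames(parent1(mrna$Parent), mrna$ID) else character()
  to_gene <- function(parents) {
    p <- parent1(parents)
    ifelse(p %in% names(mrna_parent), unname(mrna_parent[p]), p)
  }

  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    g_start <- GenomicRanges::start(g); g_end <- GenomicRanges::end(g)
    g_strand <- as.character(GenomicRanges::strand(g))
    if (!g_strand %in% c("+", "-")) stop("gene ", gid[i], " has no explicit strand")
    glen <- g_end - g_start + 1L

    feat <- gr[type %in% c("CDS", "intron")]
    feat <- feat[to_gene(feat$Parent) == gid[i]]
    ftyp <- as.character(feat$type)
    fs <- GenomicRanges::start(feat); fe <- GenomicRanges::end(feat)
    if (length(feat) && (any(fs < g_start) || any(fe > g_end))) {
      stop("feature outside parent gene span for gene ", gid[i])
    }

    cds <- which(ftyp == "CDS")
    if (length(cds)) {
      cmin <- min(fs[cds]); cmax <- max(fe[cds])
      if (g_strand == "+") {
        cds_start <- cmin - g_start + 1L; cds_end <- cmax - g_start + 1L
      } else {
        cds_start <- g_end - cmax + 1L; cds_end <- g_end - cmin + 1L
      }
    } else {
      cds_start <- 1L; cds_end <- glen
    }
    if (cds_start > glen) stop("CDS start beyond gene length for gene ", gid[i])

    intr <- which(ftyp == "intron")
    introns <- data.frame(start = fs[intr], end = fe[intr])
    introns <- introns[order(introns$start), , drop = FALSE]
    if (nrow(introns) > 1L &&
        any(introns$start[-1L] <= introns$end[-nrow(introns)])) {
      stop("overlapping annotated introns in gene ", gid[i])
    }
    rows[[i]] <- data.frame(
      gene_id = gid[i], chrom = as.character(GenomicRanges::seqnames(g)),
      strand = g_strand, start = g_start, end = g_end,
      cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
      intron_status = if (nrow(introns)) "intronic" else "intronless",
      stringsAsFactors = FALSE
    )
    rows[[i]]$introns <- list(introns)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- df$gene_id
  new_gene_models(df)
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/CDS/intron features readable by [read_gene_models()].
#'
#' @param genes A `gene_models` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  feats <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tid <- paste0(g$gene_id, ".t1")
    glen <- g$end - g$start + 1L
    if (g$strand == "+") {
      cg <- c(g$start + g$cds_start - 1L, g$start + g$cds_end - 1L)
    } else {
      cg <- c(g$end - g$cds_end + 1L, g$end - g$cds_start + 1L)
    }
    rows <- data.frame(
      seqnames = g$chrom,
      start = c(g$start, g$start, cg[1]),
      end = c(g$end, g$end, cg[2]),
      strand = g$strand,
      type = c("gene", "mRNA", "CDS"),
      ID = c(g$gene_id, tid, paste0(tid, ".cds")),
      Parent = c(NA, g$gene_id, tid),
      stringsAsFactors = FALSE
    )
    intr <- g$introns[[1]]
    if (!is.null(intr) && nrow(intr)) {
      rows <- rbind(rows, data.frame(
        seqnames = g$chrom, start = intr$start, end = intr$end,
        strand = g$strand, type = "intron",
        ID = paste0(tid, ".intron", seq_len(nrow(intr))), Parent = tid,
        stringsAsFactors = FALSE
      ))
    }
    feats[[i]] <- rows
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    df$seqnames, IRanges::IRanges(df$start, df$end), strand = df$strand
  )
  gr$source <- "smdscan"
  gr$type <- df$type
  gr$phase <- ifelse(df$type == "CDS", 0L, NA_integer_)
  gr$ID <- df$ID
  gr$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract a sense-strand transcript with its coordinate maps
#'
#' Returns the gene-body sequence on the sense strand (minus-strand genes are
#' reverse-complemented) together with bijective transcript-to-genomic
#' coordinate maps. Transcript positions are 1-based along the returned
#' string; ATG-relative positions (+1 = first base of the start codon, the
#' convention used for all reported splice-signal coordinates) are obtained
#' with [tx_to_atg()].
#'
#' @param genome A named `DNAStringSet`.
#' @param gene One row of a `gene_models` data.frame.
#' @return An object of class `transcript`: a list with `gene_id`, `seq`
#'   (character), `strand`, `chrom`, `gene_start`, `gene_end`, `cds_start`,
#'   `cds_end`.
#' @export
transcript_sequence <- function(genome, gene) {
  if (!gene$chrom %in% names(genome)) stop("chromosome not in genome: ", gene$chrom)
  chrom_len <- Biostrings::width(genome[gene$chrom])
  if (gene$start < 1L || gene$end > chrom_len) stop("gene interval outside chromosome bounds")
  glen <- gene$end - gene$start + 1L
  if (gene$cds_start > glen) stop("CDS start beyond gene length")
  s <- Biostrings::subseq(genome[[gene$chrom]], gene$start, gene$end)
  if (gene$strand == "-") s <- Biostrings::reverseComplement(s)
  structure(list(
    gene_id = gene$gene_id, seq = as.character(s), strand = gene$strand,
    chrom = gene$chrom, gene_start = gene$start, gene_end = gene$end,
    cds_start = gene$cds_start, cds_end = gene$cds_end
  ), class = "transcript")
}

#' Transcript-to-genomic coordinate conversion
#'
#' @param tx A `transcript` object.
#' @param i Transcript positions (1-based along the transcript string).
#' @return Genomic positions (1-based).
#' @export
tx_to_genomic <- function(tx, i) {
  n <- tx$gene_end - tx$gene_start + 1L
  if (any(i < 1L | i > n)) stop("transcript coordinate outside gene body")
  if (tx$strand == "+") tx$gene_start + i - 1L else tx$gene_end - i + 1L
}

#' Genomic-to-transcript coordinate conversion
#'
#' @param tx A `transcript` object.
#' @param g Genomic positions (1-based), within the gene body.
#' @return Transcript positions (1-based along the transcript string).
#' @export
genomic_to_tx <- function(tx, g) {
  if (any(g < tx$gene_start | g > tx$gene_end)) stop("genomic coordinate outside gene body")
  if (tx$strand == "+") g - tx$gene_start + 1L else tx$gene_end - g + 1L
}

#' Convert transcript-string positions to ATG-relative coordinates
#'
#' ATG-relative coordinates put +1 at the first base of the start codon; the
#' base immediately upstream is 0 (an affine map, so distances are plain
#' differences).
#'
#' @param tx A `transcript` object.
#' @param i Transcript positions (1-based along the transcript string).
#' @return ATG-relative coordinates.
#' @export
tx_to_atg <- function(tx, i) i - tx$cds_start + 1L

#' Convert ATG-relative coordinates to transcript-string positions
#' @param tx A `transcript` object.
#' @param a ATG-relative coordinates.
#' @return Transcript positions (1-based along the transcript string).
#' @export
atg_to_tx <- function(tx, a) a + tx$cds_start - 1L

#' Write junctions as BED6
#'
#' Converts 1-based closed genomic intron intervals to 0-based half-open BED
#' intervals. Name is `hostGene|status` (`.` when absent), score is the read
#' support, and rows are sorted by (chrom, start, end) so output is
#' byte-deterministic.
#'
#' @param junctions A junction data.frame (see [extract_junctions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(junctions, path) {
  if (is.null(junctions) || nrow(junctions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  j <- junctions[order(junctions$chrom, junctions$start, junctions$end), , drop = FALSE]
  host <- if ("host_gene" %in% names(j)) ifelse(is.na(j$host_gene), ".", j$host_gene) else rep(".", nrow(j))
  status <- if ("status" %in% names(j)) ifelse(is.na(j$status), ".", j$status) else rep(".", nrow(j))
  strand <- if ("strand" %in% names(j)) ifelse(is.na(j$strand), "*", j$strand) else rep("*", nrow(j))
  gr <- GenomicRanges::GRanges(j$chrom, IRanges::IRanges(j$start, j$end), strand = strand)
  gr$name <- paste(host, status, sep = "|")
  gr$score <- as.integer(j$support)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a counts table TSV
#'
#' The format is a TSV with a `gene_id` column followed by one integer column
#' per sample, optionally preceded by a single comment line
#' `#condition<TAB>sample=label<TAB>...` carrying per-sample condition labels.
#'
#' @param path Path to the TSV.
#' @return A `counts_table`: list with integer matrix `counts`
#'   (genes x samples, dimnames set) and named character vector `conditions`.
#' @export
read_counts_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  conditions <- NULL
  skip <- 0L
  if (startsWith(first, "#condition")) {
    kv <- strsplit(sub("^#condition\t", "", first), "\t")[[1]]
    parts <- strsplit(kv, "=", fixed = TRUE)
    conditions <- stats::setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
    skip <- 1L
  }
  df <- utils::read.delim(path, skip = skip, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("counts TSV must start with a gene_id column")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in counts table")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("negative counts")
  rownames(m) <- df$gene_id
  counts_table(m, conditions)
}

#' Construct a counts table
#' @param counts Integer matrix, genes x samples, dimnames required.
#' @param conditions Optional named character vector of condition labels.
#' @return A `counts_table` object.
#' @export
counts_table <- function(counts, conditions = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts matrix needs gene and sample dimnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(conditions)) conditions <- stats::setNames(colnames(counts), colnames(counts))
  structure(list(counts = counts, conditions = conditions), class = "counts_table")
}

#' Write a counts table TSV
#' @param ct A `counts_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(ct, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#condition\t", paste(names(ct$conditions), ct$conditions,
                                          sep = "=", collapse = "\t")), con)
  df <- data.frame(gene_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
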