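## Seeded generators for synthetic genomes with planted splice signals and
## simulated Sm-IP / mutant RNA-seq libraries. Every generator output is a
## pure function of (config, seed): each entry point runs under its own
## derived seed and restores the caller's RNG state afterwards.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

MOTIF_REGEX <- c(
  five_ss = "GTA[ACT]GT",
  branch_point = "ACTAAC[GAT]",
  sm_site = "[AG]AT{4,6}G[AG]"
)

#' Generator configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults define the
#' study conditions all planted-recovery tests run under: 100 genes of
#' 400-900 nt, 30% intronic, 10% planted SMD targets, uniform base
#' composition, negative-binomial counts at mean depth 500 with dispersion
#' 0.05, IP enrichment factor 8 for Sm-bound genes, 4-fold up-regulation of
#' SMD targets in the splicing-mutant libraries, 4-fold stabilization of
#' SMD junction reads in the exosome-mutant libraries, and 2 replicates per
#' RNA-seq condition.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_genes Number of genes.
#' @param intronic_fraction Fraction of genes given one annotated intron.
#' @param smd_fraction Fraction of genes planted as SMD targets (intronless,
#'   with 5'ss/BP/acceptor and an Sm site near the 5'ss).
#' @param sm_bound_extra_fraction Additional fraction of genes marked
#'   Sm-bound (IP-enriched) beyond the SMD targets.
#' @param gene_length Two-element range of gene lengths (nt).
#' @param base_probs Named A/C/G/T sampling probabilities.
#' @param depth Mean read count per gene per library.
#' @param dispersion NB dispersion alpha (variance `mu + alpha * mu^2`).
#' @param epsilon IP enrichment factor for Sm-bound genes.
#' @param rho Splicing-mutant fold-up factor for SMD genes.
#' @param rrp6_stabilization Multiplier on SMD junction-read depth in the
#'   exosome-mutant condition.
#' @param prp40_junction_factor Multiplier on junction-read depth in the
#'   splicing-mutant condition (splicing is impaired, so fewer junctions).
#' @param replicates Replicates per wt/mutant RNA-seq condition.
#' @param read_length Simulated read length (nt).
#' @param coverage_reads Mean unspliced reads per gene per library.
#' @param junction_depth_intron Mean junction reads per annotated intron.
#' @param junction_depth_smd Mean junction reads per planted SMD intron in
#'   the wild-type-like condition.
#' @param noise_free When TRUE all stochastic depths are replaced by their
#'   expectations (exact planted-recovery mode).
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_genes = 100L, intronic_fraction = 0.3,
                             smd_fraction = 0.1, sm_bound_extra_fraction = 0.1,
                             gene_length = c(400L, 900L),
                             base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             depth = 500, dispersion = 0.05,
                             epsilon = 8, rho = 4,
                             rrp6_stabilization = 4, prp40_junction_factor = 0.3,
                             replicates = 2L, read_length = 50L,
                             coverage_reads = 30, junction_depth_intron = 10,
                             junction_depth_smd = 1, noise_free = FALSE) {
  stopifnot(
    intronic_fraction >= 0, intronic_fraction <= 1,
    smd_fraction >= 0, smd_fraction <= 1,
    intronic_fraction + smd_fraction <= 1,
    epsilon >= 1, rho >= 1, dispersion > 0,
    gene_length[1] >= 200L, gene_length[2] >= gene_length[1],
    abs(sum(base_probs) - 1) < 1e-8, replicates >= 1L
  )
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "generator_config"
  cfg
}

sample_bases <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

## rejection-sample a segment containing no splice-signal/Sm literal
## (and optionally no AG dinucleotide)
sample_clean_segment <- function(n, probs, forbid_ag = FALSE, max_tries = 2000L) {
  if (n == 0L) return(character(0))
  pats <- MOTIF_REGEX
  if (forbid_ag) pats <- c(pats, "AG")
  for (tries in seq_len(max_tries)) {
    x <- sample_bases(n, probs)
    s <- paste(x, collapse = "")
    if (!any(vapply(pats, grepl, TRUE, x = s, USE.NAMES = FALSE))) return(x)
  }
  stop("rejection sampling failed after ", max_tries,
       " tries (segment length ", n, "); consider shorter genes")
}

## Build one transcript (sense strand, char vector) with optional planted
## signals. Coordinates in the returned truth are ATG-relative; cds_start
## is the transcript index of the ATG.
build_gene_transcript <- function(cfg, plant_signals, plant_sm, max_tries = 100L) {
  utr <- 30L
  L0 <- sample(cfg$gene_length[1]:cfg$gene_length[2], 1L)
  cds_len <- (L0 - 2L * utr) - ((L0 - 2L * utr) %% 3L)
  L <- cds_len + 2L * utr
  cds_start <- utr + 1L

  if (!plant_signals) {
    for (t in seq_len(max_tries)) {
      x <- sample_clean_segment(L, cfg$base_probs)
      return(list(seq = x, L = L, cds_start = cds_start, cds_end = utr + cds_len,
                  d = NA_integer_, b = NA_integer_, a = NA_integer_,
                  sm_start = NA_integer_, sm_end = NA_integer_))
    }
  }

  ## planted coordinates (ATG-relative)
  motifs <- splice_motifs()
  for (t in seq_len(max_tries)) {
    d <- 33L
    b <- d + sample(60:120, 1L)
    a <- b + sample(20:80, 1L)
    sm_lit <- if (plant_sm) sample(expand_consensus(motifs$sm_site), 1L) else NULL
    sm_end <- if (plant_sm) d - sample(5:40, 1L) else NA_integer_
    sm_start <- if (plant_sm) sm_end - nchar(sm_lit) + 1L else NA_integer_
    if (plant_sm && sm_start < 2L - utr) next
    d_lit <- sample(expand_consensus(motifs$five_ss), 1L)
    b_lit <- sample(expand_consensus(motifs$branch_point), 1L)

    tx <- function(atg) atg + cds_start - 1L  # ATG -> transcript index
    x <- character(L)
    cursor <- 1L
    put <- function(x, at, lit) {
      x[at:(at + nchar(lit) - 1L)] <- strsplit(lit, "", fixed = TRUE)[[1]]
      x
    }
    fill <- function(x, from, to, forbid_ag = FALSE) {
      if (to >= from) x[from:to] <- sample_clean_segment(to - from + 1L,
                                                        cfg$base_probs, forbid_ag)
      x
    }
    if (plant_sm) {
      x <- fill(x, 1L, tx(sm_start) - 1L)
      x <- put(x, tx(sm_start), sm_lit)
      cursor <- tx(sm_end) + 1L
    }
    x <- fill(x, cursor, tx(d) - 1L)
    x <- put(x, tx(d), d_lit)
    x <- fill(x, tx(d) + 6L, tx(b) - 1L)
    x <- put(x, tx(b), b_lit)
    x <- fill(x, tx(b) + 7L, tx(a) - 1L, forbid_ag = TRUE)
    x <- put(x, tx(a), "AG")
    x <- fill(x, tx(a) + 2L, L)

    ## post-verify: scans must return exactly the planted hits and the
    ## nearest AG downstream of the BP must be the planted acceptor
    s <- paste(x, collapse = "")
    h5 <- scan_sequence(s, motifs$five_ss)
    hb <- scan_sequence(s, motifs$branch_point)
    hs <- scan_sequence(s, motifs$sm_site)
    ag <- ag_positions(s)
    ok <- identical(h5$start, tx(d)) && identical(hb$start, tx(b)) &&
      (if (plant_sm) identical(hs$start, tx(sm_start)) else nrow(hs) == 0L) &&
      min(ag[ag > tx(b)]) == tx(a)
    if (ok) {
      return(list(seq = x, L = L, cds_start = cds_start, cds_end = utr + cds_len,
                  d = d, b = b, a = a, sm_start = sm_start, sm_end = sm_end))
    }
  }
  stop("rejection sampling failed to build a clean signal-bearing gene")
}

#' Generate a synthetic genome with planted splice signals
#'
#' Builds a single-chromosome genome of `n_genes` genes separated by random
#' spacers. Gene backgrounds are rejection-sampled to contain no 5'ss, BP
#' or Sm-site literal, so every motif hit inside a gene is planted and
#' recovery tests are exact. Intronic genes carry one annotated GT..AG
#' intron with an internal BP consensus; planted SMD genes are annotated
#' intronless but carry the same signal architecture (5'ss, BP, acceptor
#' within pairing distance, Sm site upstream of the 5'ss). Strands are
#' random; minus-strand genes are stored as the reverse complement of their
#' designed transcript.
#'
#' @param cfg A `generator_config`.
#' @return List with `genome` (named `DNAStringSet`), `genes`
#'   (`gene_models`), and `truth` (a `planted_truth` list: per-gene flags,
#'   planted signal coordinates, planted/annotated introns).
#' @export
generate_genome <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    n_intronic <- round(n * cfg$intronic_fraction)
    n_smd <- round(n * cfg$smd_fraction)
    n_sm_extra <- round(n * cfg$sm_bound_extra_fraction)
    ids <- sprintf("g%03d", seq_len(n))
    role <- rep("plain", n)
    role[seq_len(n_intronic)] <- "intronic"
    role[n_intronic + seq_len(n_smd)] <- "smd"
    sm_bound <- role == "smd"
    pool <- which(role != "smd")
    sm_bound[sample(pool, min(n_sm_extra, length(pool)))] <- TRUE
    strand <- sample(c("+", "-"), n, replace = TRUE)

    spacer_len <- 60L
    chrom_parts <- list()
    gene_rows <- vector("list", n)
    sig_rows <- vector("list", n)
    intron_rows <- list()
    offset <- 0L
    for (i in seq_len(n)) {
      sp <- sample_bases(spacer_len, cfg$base_probs)
      chrom_parts[[length(chrom_parts) + 1L]] <- sp
      offset <- offset + spacer_len
      plant <- role[i] != "plain"
      g <- build_gene_transcript(cfg, plant_signals = plant, plant_sm = plant && sm_bound[i])
      gseq <- if (strand[i] == "+") g$seq else {
        strsplit(as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(paste(g$seq, collapse = "")))), "", fixed = TRUE)[[1]]
      }
      chrom_parts[[length(chrom_parts) + 1L]] <- gseq
      g_start <- offset + 1L
      g_end <- offset + g$L
      offset <- g_end

      tx_of <- function(atg) atg + g$cds_start - 1L
      genomic_of <- function(txi) if (strand[i] == "+") g_start + txi - 1L else g_end - txi + 1L
      introns <- data.frame(start = integer(), end = integer())
      if (plant) {
        ge <- sort(c(genomic_of(tx_of(g$d)), genomic_of(tx_of(g$a + 1L))))
        intron_rows[[length(intron_rows) + 1L]] <- data.frame(
          gene_id = ids[i], atg_start = g$d, atg_end = g$a + 1L,
          g_start = ge[1], g_end = ge[2],
          annotated = role[i] == "intronic",
          bp_to_acceptor = g$a - g$b, stringsAsFactors = FALSE
        )
        if (role[i] == "intronic") introns <- data.frame(start = ge[1], end = ge[2])
      }
      row <- data.frame(
        gene_id = ids[i], chrom = "chrS", strand = strand[i],
        start = g_start, end = g_end,
        cds_start = g$cds_start, cds_end = g$cds_end,
        intron_status = if (role[i] == "intronic") "intronic" else "intronless",
        stringsAsFactors = FALSE
      )
      row$introns <- list(introns)
      gene_rows[[i]] <- row
      sig_rows[[i]] <- data.frame(
        gene_id = ids[i], five_ss = g$d, bp = g$b, acceptor = g$a,
        sm_start = g$sm_start, sm_end = g$sm_end, stringsAsFactors = FALSE
      )
    }
    chrom_parts[[length(chrom_parts) + 1L]] <- sample_bases(spacer_len, cfg$base_probs)
    chrom <- paste(unlist(chrom_parts), collapse = "")
    genome <- Biostrings::DNAStringSet(c(chrS = chrom))
    genes <- new_gene_models(do.call(rbind, gene_rows))
    truth <- structure(list(
      genes = data.frame(gene_id = ids, intronic = role == "intronic",
                         smd = role == "smd", sm_bound = sm_bound,
                         strand = strand, stringsAsFactors = FALSE),
      signals = do.call(rbind, sig_rows),
      introns = if (length(intron_rows)) do.call(rbind, intron_rows) else
        data.frame(gene_id = character(), atg_start = integer(),
                   atg_end = integer(), g_start = integer(), g_end = integer(),
                   annotated = logical(), bp_to_acceptor = integer())
    ), class = "planted_truth")
    list(genome = genome, genes = genes, truth = truth)
  })
}

#' Deterministic BDF2-like fixture transcript
#'
#' A fully deterministic 1750-nt intronless transcript carrying the splice
#' architecture of the BDF2 worked example at its published ATG-relative
#' coordinates: a 5'ss at +33 (a documented fixture choice; no 5'ss
#' coordinate is published), branch points at +254 and +1660, the proximal
#' acceptor AG at +1672 and the alternative acceptor AG at +1702. The
#' background is G-free (a fixed repeating pattern over A/C/T), so the only
#' motif literals and AG dinucleotides in the entire transcript are the
#' planted ones; the function self-checks this before returning.
#'
#' @return List with `seq` (transcript string), `gene` (a one-row
#'   `gene_models` data.frame, plus strand, CDS starting at base 1 so ATG
#'   coordinates equal transcript indices), `genome` (single-chromosome
#'   `DNAStringSet`), `transcript` (a `transcript` object), and `truth`
#'   (planted coordinates).
#' @export
bdf2_like_fixture <- function() {
  L <- 1750L
  filler <- strsplit("CTTCA", "", fixed = TRUE)[[1]]
  x <- rep_len(filler, L)
  put <- function(x, at, lit) {
    x[at:(at + nchar(lit) - 1L)] <- strsplit(lit, "", fixed = TRUE)[[1]]
    x
  }
  x <- put(x, 33L, "GTATGT")     # 5'ss (fixture placement)
  x <- put(x, 254L, "ACTAACT")   # proximal BP
  x <- put(x, 1660L, "ACTAACT")  # distal BP
  x <- put(x, 1672L, "AG")       # proximal acceptor
  x <- put(x, 1702L, "AG")       # alternative acceptor
  s <- paste(x, collapse = "")

  motifs <- splice_motifs()
  stopifnot(
    identical(scan_sequence(s, motifs$five_ss)$start, 33L),
    identical(scan_sequence(s, motifs$branch_point)$start, c(254L, 1660L)),
    nrow(scan_sequence(s, motifs$sm_site)) == 0L,
    identical(ag_positions(s), c(1672L, 1702L))
  )
  gene <- data.frame(
    gene_id = "BDF2L", chrom = "chrBDF2L", strand = "+",
    start = 1L, end = L, cds_start = 1L, cds_end = 1749L,
    intron_status = "intronless", stringsAsFactors = FALSE
  )
  gene$introns <- list(data.frame(start = integer(), end = integer()))
  gene <- new_gene_models(gene)
  genome <- Biostrings::DNAStringSet(stats::setNames(s, "chrBDF2L"))
  tx <- transcript_sequence(genome, gene[1, ])
  list(seq = s, gene = gene, genome = genome, transcript = tx,
       truth = list(five_ss = 33L, bp = c(254L, 1660L),
                    acceptors = c(1672L, 1702L)))
}

rnb <- function(n, mu, dispersion, noise_free) {
  if (noise_free) return(as.integer(round(mu)))
  as.integer(stats::rnbinom(n, mu = mu, size = 1 / dispersion))
}

#' Simulate Sm-IP and mutant RNA-seq count libraries
#'
#' Draws negative-binomial counts for samples `ip_1`, `ip_2`, `mock`,
#' `wt_*`, `prp40_*` and `rrp6_*`. Gene base means are lognormal around the
#' configured depth; Sm-bound genes are multiplied by `epsilon` in the IP
#' samples, SMD genes by `rho` in the splicing-mutant samples (where
#' intron-containing genes are halved, mirroring a global splicing defect).
#'
#' @param cfg A `generator_config`.
#' @param truth A `planted_truth` (only the per-gene flags are used, so a
#'   hand-built flag table works too).
#' @return A `counts_table` with condition labels
#'   `ip/ip/mock/wt/prp40/rrp6`.
#' @export
simulate_counts <- function(cfg, truth) {
  with_seed(cfg$seed + 1000003L, {
    tg <- truth$genes
    n <- nrow(tg)
    r <- cfg$replicates
    base <- cfg$depth * exp(stats::rnorm(n, 0, 0.3))
    samples <- c("ip_1", "ip_2", "mock",
                 paste0("wt_", seq_len(r)),
                 paste0("prp40_", seq_len(r)),
                 paste0("rrp6_", seq_len(r)))
    conditions <- stats::setNames(
      c("ip", "ip", "mock", rep("wt", r), rep("prp40", r), rep("rrp6", r)),
      samples
    )
    mu_for <- function(cond) {
      mu <- base
      if (cond == "ip") mu <- mu * ifelse(tg$sm_bound, cfg$epsilon, 1)
      if (cond == "prp40") {
        mu <- mu * ifelse(tg$smd, cfg$rho, 1) * ifelse(tg$intronic, 0.5, 1)
      }
      mu
    }
    m <- vapply(samples, function(s) {
      rnb(n, mu_for(conditions[[s]]), cfg$dispersion, cfg$noise_free)
    }, integer(n))
    rownames(m) <- tg$gene_id
    counts_table(m, conditions)
  })
}

#' Simulate gapped spliced alignments for one condition
#'
#' Emits unspliced reads over every gene plus junction-spanning
#' (match-skip-match) reads over annotated introns and planted SMD introns.
#' Junction depths follow the configured per-intron means, multiplied by
#' `rrp6_stabilization` for SMD introns in the `rrp6` condition and by
#' `prp40_junction_factor` for all introns in the `prp40` condition. All
#' skipped intervals have sense-strand GT..AG ends by construction.
#'
#' @param cfg A `generator_config`.
#' @param truth A `planted_truth` from [generate_genome()].
#' @param genes The matching `gene_models`.
#' @param condition One of `"wt"`, `"prp40"`, `"rrp6"`.
#' @return An `alignments` data.frame (see [read_sam()]).
#' @export
simulate_spliced_alignments <- function(cfg, truth, genes, condition = c("wt", "prp40", "rrp6")) {
  condition <- match.arg(condition)
  offset <- 2000003L + 7919L * match(condition, c("wt", "prp40", "rrp6"))
  with_seed(cfg$seed + offset, {
    rl <- cfg$read_length
    anchor <- 20L
    rows <- list()
    rid <- 0L
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      n_u <- if (cfg$noise_free) as.integer(round(cfg$coverage_reads))
             else stats::rpois(1L, cfg$coverage_reads)
      if (n_u > 0L && g$end - g$start + 1L >= rl) {
        pos <- sample(g$start:(g$end - rl + 1L), n_u, replace = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = paste0(condition, "_u", rid + seq_len(n_u)),
          chrom = g$chrom, pos = as.integer(pos),
          cigar = paste0(rl, "M"), stringsAsFactors = FALSE
        )
        rid <- rid + n_u
      }
    }
    tin <- truth$introns
    for (k in seq_len(nrow(tin))) {
      lambda <- if (tin$annotated[k]) cfg$junction_depth_intron else cfg$junction_depth_smd
      if (!tin$annotated[k] && condition == "rrp6") lambda <- lambda * cfg$rrp6_stabilization
      if (condition == "prp40") lambda <- lambda * cfg$prp40_junction_factor
      n_j <- if (cfg$noise_free) as.integer(round(lambda)) else stats::rpois(1L, lambda)
      if (n_j == 0L) next
      ilen <- tin$g_end[k] - tin$g_start[k] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = paste0(condition, "_j", k, "_", seq_len(n_j)),
        chrom = genes$chrom[match(tin$gene_id[k], genes$gene_id)],
        pos = tin$g_start[k] - anchor,
        cigar = paste0(anchor, "M", ilen, "N", anchor, "M"),
        stringsAsFactors = FALSE
      )
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(read_id = character(), chrom = character(),
                 pos = integer(), cigar = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    structure(out, class = c("alignments", "data.frame"))
  })
}
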