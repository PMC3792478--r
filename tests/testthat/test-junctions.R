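test_that("skip operations are converted to intron intervals and aggregated", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 400)))
  aln <- structure(data.frame(
    read_id = c("r1", "r2", "r3"),
    chrom = "chr1", pos = c(101L, 101L, 96L),
    cigar = c("20M100N20M", "20M100N20M", "25M100N20M"),
    stringsAsFactors = FALSE
  ), class = c("alignments", "data.frame"))
  j <- extract_junctions(aln, genome)
  expect_equal(nrow(j), 1L)
  expect_equal(j$start, 121L)  # pos 101 + 20 matched bases
  expect_equal(j$end, 220L)
  expect_equal(j$support, 3L)  # three distinct reads, same skipped interval

  ## duplicate read ids count once
  aln2 <- aln; aln2$read_id <- "r1"
  expect_equal(extract_junctions(aln2, genome)$support, 1L)
})

test_that("SAM subset round trip preserves records and rejects malformed CIGARs", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 100)))
  aln <- structure(data.frame(
    read_id = c("a", "b"), chrom = "chr1", pos = c(5L, 50L),
    cigar = c("50M", "10M30N10M"), stringsAsFactors = FALSE
  ), class = c("alignments", "data.frame"))
  p <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, p, genome)
  back <- read_sam(p)
  expect_equal(back$read_id, aln$read_id)
  expect_equal(back$pos, aln$pos)
  expect_equal(back$cigar, aln$cigar)

  bad <- aln; bad$cigar[1] <- "10N40M"
  expect_error(extract_junctions(bad, genome), "edge")
  bad2 <- aln; bad2$cigar[1] <- "50N"
  expect_error(extract_junctions(bad2, genome), "match|edge")
  bad3 <- aln; bad3$cigar[1] <- "10M5D35M"
  expect_error(extract_junctions(bad3, genome), "subset")
})

test_that("canonical filtering keeps GT..AG at sufficient support only", {
  ## gene on + strand: intron [31,90] with GT..AG; second intron GC..AG
  pre <- strrep("C", 30)
  intr1 <- paste0("GT", strrep("C", 56), "AG")
  mid <- strrep("C", 20)
  intr2 <- paste0("GC", strrep("C", 56), "AG")
  s <- paste0(pre, intr1, mid, intr2, strrep("C", 30))
  fx <- make_gene_fixture(s)
  jraw <- data.frame(
    chrom = "chrT", start = c(31L, 111L, 31L), end = c(90L, 170L, 90L),
    support = c(5L, 5L, 5L), stringsAsFactors = FALSE
  )[1:2, ]
  kept <- filter_canonical(jraw, fx$genome, fx$gene, min_support = 2L)
  expect_equal(kept$start, 31L)  # GC..AG intron dropped
  expect_equal(kept$donor_dinuc, "GT")
  expect_equal(kept$acceptor_dinuc, "AG")
  ## support below threshold is dropped even if canonical
  low <- data.frame(chrom = "chrT", start = 31L, end = 90L, support = 1L,
                    stringsAsFactors = FALSE)
  expect_equal(nrow(filter_canonical(low, fx$genome, fx$gene, min_support = 2L)), 0L)
  expect_equal(nrow(filter_canonical(low, fx$genome, fx$gene, min_support = 1L)), 1L)
})

test_that("minus-strand genes are read on the sense strand for canonical calls", {
  ## transcript has a GT..AG intron; the genome stores its reverse complement
  s <- paste0(strrep("C", 30), "GT", strrep("C", 56), "AG", strrep("C", 30))
  fx <- make_gene_fixture(s, strand = "-")
  ## transcript positions 31..90 map to genomic 90..31 on the minus strand
  g_lo <- tx_to_genomic(fx$tx, 90L); g_hi <- tx_to_genomic(fx$tx, 31L)
  jraw <- data.frame(chrom = "chrT", start = g_lo, end = g_hi, support = 3L,
                     stringsAsFactors = FALSE)
  kept <- filter_canonical(jraw, fx$genome, fx$gene, min_support = 2L)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$strand, "-")
  expect_equal(kept$donor_dinuc, "GT")
  expect_equal(kept$acceptor_dinuc, "AG")
})

test_that("junction recovery on generator output is exact and classified correctly", {
  cfg <- generator_config(seed = 31, n_genes = 40L, noise_free = TRUE,
                          junction_depth_smd = 10)
  gg <- generate_genome(cfg)
  aln <- simulate_spliced_alignments(cfg, gg$truth, gg$genes, "wt")
  j <- extract_junctions(aln, gg$genome)
  planted <- gg$truth$introns
  expect_equal(nrow(j), nrow(planted))  # precision 1: nothing but planted introns
  key <- function(s, e) paste(s, e)
  expect_setequal(key(j$start, j$end), key(planted$g_start, planted$g_end))
  ## requested support is reported exactly in noise-free mode
  ann <- planted$annotated[match(key(j$start, j$end), key(planted$g_start, planted$g_end))]
  expect_true(all(j$support[ann] == cfg$junction_depth_intron))
  expect_true(all(j$support[!ann] == cfg$junction_depth_smd))

  kept <- filter_canonical(j, gg$genome, gg$genes, min_support = 2L)
  expect_equal(nrow(kept), nrow(planted))  # all planted introns are GT..AG
  cl <- classify_junctions(kept, gg$genes)
  st <- cl$junctions$status
  expect_setequal(unique(st), c("annotated", "novel_in_intronless"))
  expect_equal(sum(st == "annotated"), sum(planted$annotated))
  truth <- gg$truth$genes
  expect_equal(cl$stats$pct_intronless_with_canonical_junction,
               100 * sum(truth$smd) / sum(!truth$intronic))
})

test_that("BP-in-intron flag and distance follow the planted geometry", {
  ## planted intron with ACTAACA starting 15 nt upstream of the acceptor AG
  ilen <- 80L
  intron <- paste0("GT", strrep("C", 61L), "ACTAACA", strrep("C", 8L), "AG")
  expect_equal(nchar(intron), ilen)
  s <- paste0(strrep("C", 40), intron, strrep("C", 40))
  fx <- make_gene_fixture(s)
  j <- data.frame(chrom = "chrT", start = 41L, end = 40L + ilen, support = 4L,
                  stringsAsFactors = FALSE)
  kept <- filter_canonical(j, fx$genome, fx$gene, min_support = 1L)
  out <- bp_within_intron(kept, fx$genome, fx$gene)
  expect_true(out$bp_in_intron)
  expect_equal(out$bp_to_acceptor, 15L)

  ## no BP literal inside the intron
  s2 <- paste0(strrep("C", 40), "GT", strrep("C", 76), "AG", strrep("C", 40))
  fx2 <- make_gene_fixture(s2)
  kept2 <- filter_canonical(j, fx2$genome, fx2$gene, min_support = 1L)
  out2 <- bp_within_intron(kept2, fx2$genome, fx2$gene)
  expect_false(out2$bp_in_intron)

  ## BP just outside the 5' intron boundary is not counted
  s3 <- paste0(strrep("C", 33), "ACTAACA", "GT", strrep("C", 76), "AG", strrep("C", 40))
  fx3 <- make_gene_fixture(s3)
  j3 <- data.frame(chrom = "chrT", start = 41L, end = 120L, support = 4L,
                   stringsAsFactors = FALSE)
  kept3 <- filter_canonical(j3, fx3$genome, fx3$gene, min_support = 1L)
  out3 <- bp_within_intron(kept3, fx3$genome, fx3$gene)
  expect_false(out3$bp_in_intron)
})
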