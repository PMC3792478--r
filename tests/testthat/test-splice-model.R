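test_that("BDF2-like fixture reproduces the published pairing geometry", {
  f <- bdf2_like_fixture()
  pr <- call_splice_signals(f$gene[1, ], f$transcript)
  expect_equal(pr$five_ss$start, 33L)
  expect_equal(pr$bp$start, c(254L, 1660L))
  expect_true(pr$signals_in_correct_order)

  p <- pair_bp_to_acceptors(pr, d_max = 100)
  distal <- p[p$bp == 1660L, ]
  proximal <- p[p$bp == 254L, ]
  expect_equal(distal$acceptor, 1672L)
  expect_equal(distal$spacing, 12L)   # BP 12 nt upstream of the 3'ss
  expect_true(distal$feasible_two_step)
  expect_equal(proximal$acceptor, 1672L)
  expect_gt(proximal$spacing, 1400L)  # far from optimal for the second step
  expect_false(proximal$feasible_two_step)

  ## exactly two events from the single donor, one per BP
  evs <- splice_events(pr, d_max = 100)
  expect_length(evs, 2L)
  cls <- vapply(evs, function(e) e$event_class, "")
  expect_equal(cls[vapply(evs, function(e) e$bp, 0L) == 254L], "cleavage_only")
  expect_equal(cls[vapply(evs, function(e) e$bp, 0L) == 1660L], "two_step")
  two <- evs[[which(cls == "two_step")]]
  expect_equal(two$intron, c(33L, 1673L))  # donor start through the acceptor G
})

test_that("acceptor re-selection after disrupting the proximal AG finds +1702", {
  f <- bdf2_like_fixture()
  pr <- call_splice_signals(f$gene[1, ], f$transcript)
  p <- pair_bp_to_acceptors(pr, d_max = 100)
  distal <- p[p$bp == 1660L, ]

  newp <- select_acceptor_after_mutation(f$transcript, distal,
                                         data.frame(pos = 1673L, base = "A"))
  expect_equal(newp$acceptor, 1702L)
  expect_equal(newp$spacing, 42L)
  expect_true(newp$feasible_two_step)

  ## destroying every downstream AG leaves the BP acceptor-less
  gone <- select_acceptor_after_mutation(
    f$transcript, distal, data.frame(pos = c(1673L, 1703L), base = "A"))
  expect_true(is.na(gone$acceptor))
  expect_false(gone$feasible_two_step)

  ## a non-AG edit and the empty edit set are no-ops on the pairing
  same <- select_acceptor_after_mutation(f$transcript, distal,
                                         data.frame(pos = 1690L, base = "C"))
  expect_equal(same$acceptor, distal$acceptor)
  empty <- select_acceptor_after_mutation(f$transcript, distal,
                                          data.frame(pos = integer(), base = character()))
  expect_equal(empty$acceptor, distal$acceptor)
  expect_error(select_acceptor_after_mutation(
    f$transcript, distal, data.frame(pos = 99999L, base = "A")), "outside")
})

test_that("BP-acceptor pairing agrees with a nearest-AG walking oracle", {
  set.seed(77)
  n_checked <- 0L
  for (rep in 1:120) {
    fx <- make_gene_fixture(random_seq(800))
    pr <- call_splice_signals(fx$gene[1, ], fx$tx)
    if (nrow(pr$bp) == 0L) next
    p <- pair_bp_to_acceptors(pr, d_max = 100)
    for (i in seq_len(nrow(p))) {
      want <- oracle_nearest_ag(fx$tx$seq, p$bp[i])
      expect_equal(p$acceptor[i], want)
      if (!is.na(want)) expect_equal(p$spacing[i], want - p$bp[i])
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 10L)  # the random pool actually exercised the pairing
})

test_that("event classification is monotone in d_max and validates its contract", {
  pairing <- data.frame(gene_id = "g", bp = 100L, acceptor = 150L, spacing = 50L,
                        feasible_two_step = TRUE, stringsAsFactors = FALSE)
  expect_equal(classify_event(10L, pairing, d_max = 49)$event_class, "cleavage_only")
  expect_equal(classify_event(10L, pairing, d_max = 50)$event_class, "two_step")
  expect_equal(classify_event(10L, pairing, d_max = 500)$event_class, "two_step")
  ## spacing-1 boundary
  b1 <- data.frame(gene_id = "g", bp = 100L, acceptor = 101L, spacing = 1L,
                   feasible_two_step = TRUE)
  expect_equal(classify_event(10L, b1, 100)$event_class, "two_step")
  ## absent acceptor is always cleavage-only
  na_p <- data.frame(gene_id = "g", bp = 100L, acceptor = NA_integer_,
                     spacing = NA_integer_, feasible_two_step = FALSE)
  expect_equal(classify_event(10L, na_p, 100)$event_class, "cleavage_only")
  expect_null(classify_event(10L, na_p, 100)$intron)
  expect_error(classify_event(100L, pairing, 100), "upstream")
  expect_error(pair_bp_to_acceptors(list(), d_max = -1), "positive")
})

test_that("frame-effect classes follow mod-3 arithmetic and UTR position", {
  mk_event <- function(intron) {
    structure(list(gene_id = "g", event_class = "two_step", intron = intron),
              class = "splice_event")
  }
  ## gene with 60 nt 5'UTR, 300 nt CDS with no internal stop, 60 nt 3'UTR
  cds <- paste(rep("GCT", 99), collapse = "")  # alanine repeat
  cds <- paste0("ATG", cds)                    # 300 nt
  s <- paste0(strrep("C", 60), cds, strrep("C", 60))
  fx <- make_gene_fixture(s, cds_start = 61L, cds_end = 360L)
  g <- fx$gene[1, ]
  expect_equal(classify_frame_effect(mk_event(c(31L, 120L)), g, fx$tx),
               "in_frame_deletion")  # 90 nt, 0 mod 3
  expect_equal(classify_frame_effect(mk_event(c(31L, 121L)), g, fx$tx),
               "frameshift")         # 91 nt
  expect_equal(classify_frame_effect(mk_event(c(-50L, -10L)), g, fx$tx),
               "utr5_intron")
  expect_equal(classify_frame_effect(mk_event(c(310L, 340L)), g, fx$tx),
               "utr3_intron")
  ## in-frame deletion that brings a TAA codon into frame
  cds2 <- paste0("ATG", "GCA", "TAA", "GCG", paste(rep("GCT", 96), collapse = ""))
  fx2 <- make_gene_fixture(paste0(strrep("C", 60), cds2, strrep("C", 60)),
                           cds_start = 61L, cds_end = 60L + nchar(cds2))
  ## remove codon 2 only: the TAA at codon 3 moves to codon 2, still premature
  expect_equal(classify_frame_effect(mk_event(c(4L, 6L)), fx2$gene[1, ], fx2$tx),
               "ptc_introduced")
  cleav <- structure(list(event_class = "cleavage_only", intron = NULL),
                     class = "splice_event")
  expect_error(classify_frame_effect(cleav, g, fx$tx), "two-step")
})

test_that("frame classification matches a codon-walking oracle on random events", {
  set.seed(303)
  for (rep in 1:60) {
    ## random CDS with start codon, random intron inside it
    n_cod <- sample(40:80, 1)
    body <- random_seq(3 * n_cod)
    s <- paste0(strrep("C", 30), "ATG", body, strrep("C", 30))
    cds_len <- 3L + 3L * n_cod
    fx <- make_gene_fixture(s, cds_start = 31L, cds_end = 30L + cds_len)
    lo <- sample(2:(cds_len - 20), 1)
    hi <- lo + sample(3:18, 1)
    ev <- structure(list(gene_id = "g", event_class = "two_step",
                         intron = c(lo, hi)), class = "splice_event")
    got <- classify_frame_effect(ev, fx$gene[1, ], fx$tx)
    ilen <- hi - lo + 1L
    if (ilen %% 3L != 0L) {
      expect_equal(got, "frameshift")
    } else {
      cds_seq <- substr(fx$tx$seq, 31L, 30L + cds_len)
      kept <- strsplit(cds_seq, "")[[1]][-(lo:hi)]
      spliced <- paste(kept, collapse = "")
      want <- if (oracle_premature_stop(spliced)) "ptc_introduced" else "in_frame_deletion"
      expect_equal(got, want)
    }
  }
})
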