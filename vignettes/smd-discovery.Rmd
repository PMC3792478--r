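---
title: "Finding spliceosome-mediated decay targets among intronless genes"
author: "smdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding spliceosome-mediated decay targets among intronless genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdscan)
```

## The biological problem

In budding yeast, a number of mRNAs annotated as intronless carry cryptic
splice signals: a 5' splice-site donor, a branch-point (BP) element, and
acceptor AG dinucleotides. The spliceosome can engage these transcripts and
either cleave them (a first transesterification without exon ligation) or
splice them completely; in both cases the products are unstable and are
degraded by nuclear RNA surveillance, chiefly the exosome subunit Rrp6.
This down-regulation through splicing chemistry — spliceosome-mediated
decay (SMD) — inverts the usual logic of splicing: instead of producing a
mature mRNA, the reaction destroys one.

`smdscan` implements the computational side of an SMD target screen as a
reusable, tested pipeline:

1. **Splice-signal scanning** (`screen_gene_set`): degenerate-consensus
   matching of donor `GUA[U/C/A]GU`, branch point `ACUAAC[G/A/U]`, and the
   Sm-ring binding element `PuAU(4-6)GPu` on sense-strand transcripts, with
   an order criterion (BP downstream of a donor) and an Sm-site proximity
   window upstream of the donor.
2. **Splice-event modelling** (`pair_bp_to_acceptors`, `classify_event`,
   `classify_frame_effect`): each BP is paired with its nearest downstream
   acceptor AG; events with BP-acceptor spacing within a feasibility bound
   complete both splicing steps, events without a reachable acceptor stall
   after cleavage. Complete events are classified by their reading-frame
   consequence.
3. **Sm-IP enrichment funnel** (`funnel_report`): genes are ranked by a
   pseudocounted, library-scaled log2 IP/control ratio per replicate; the
   top-K lists of two replicates are intersected, partitioned by intron
   status, and crossed with the signal screen.
4. **Junction discovery** (`extract_junctions`, `filter_canonical`,
   `classify_junctions`, `bp_within_intron`): introns are read off the skip
   operations of gapped alignments, kept when their sense-strand boundaries
   are GT..AG with sufficient read support, classified against the
   annotation, and checked for an internal BP consensus.
5. **Differential filter** (`fold_changes`, `threshold_up`): median-of-ratios
   normalization and a plain fold-change threshold identifying intronless
   transcripts up-regulated in a splicing-defective mutant.
6. **Candidate integration** (`integrate_evidence`): a tiered rule combining
   the four evidence streams.

A seeded synthetic-data module (`generate_genome`, `simulate_counts`,
`simulate_spliced_alignments`, `bdf2_like_fixture`) supplies genomes with
planted, exactly known signal architecture, so every stage can be tested
against a ground truth rather than against a particular genome release.

## Coordinate conventions

Genomic coordinates are 1-based and closed (the GFF3 dialect); BED output
converts to 0-based half-open intervals at write time. All transcript-level
positions are reported **ATG-relative**: +1 is the first base of the start
codon. Internally this is an affine shift of the transcript-string index, so
the base immediately upstream of the ATG is position 0 rather than -1;
distances are therefore plain differences, and for genes whose CDS starts at
the first transcript base the two coordinate systems coincide. Motif
positions always refer to the **first base of the match**. Whether published
BP coordinates denote the motif start or the branch adenosine is not
something the pipeline can decide; the motif-start convention is fixed
project-wide because it makes the worked example below reproduce the
expected 12-nt BP-to-acceptor spacing.

All scans run on the sense strand only: minus-strand genes are
reverse-complemented before scanning, and RNA alphabets are mapped `U -> T`
at ingest so a single DNA alphabet is used throughout. `N` never matches any
motif element, which is the conservative choice on masked sequence.

## The worked example

The fixture built by `bdf2_like_fixture()` is a deterministic 1750-nt
intronless transcript with a donor at +33, branch points at +254 and +1660,
and acceptor AGs at +1672 and +1702. The donor position is a fixture choice
(no donor coordinate is published); the remaining coordinates follow the
published description of the BDF2 splice architecture. The background is a
fixed G-free repeating pattern, so the planted elements are provably the
only motif literals and the only AG dinucleotides in the sequence.

```{r fixture}
fix <- bdf2_like_fixture()
profile <- call_splice_signals(fix$gene[1, ], fix$transcript)
pairings <- pair_bp_to_acceptors(profile, d_max = 100)
pairings
```

The distal BP (+1660) pairs with the acceptor at +1672, 12 nt downstream —
comfortably within splicing distance, so the donor/BP(+1660) event completes
both steps. The proximal BP (+254) finds no acceptor closer than +1672,
more than 1400 nt away; that event can only cleave:

```{r events}
sapply(splice_events(profile, d_max = 100),
       function(e) setNames(e$event_class, e$bp))
```

Disrupting the proximal acceptor (AG to AA) re-selects the next AG
downstream, at +1702:

```{r mutation}
distal <- pairings[pairings$bp == 1660, ]
select_acceptor_after_mutation(fix$transcript, distal,
                               data.frame(pos = 1673, base = "A"))
```

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `min_5ss_bp_spacing` | 20 | nt | minimum donor-to-BP spacing for the order criterion; a small positive floor motivated by the shortest natural yeast intron spacings. Tightening it can only shrink the ordered-signal count (a tested monotonicity). |
| `sm_window` | 50 | nt | Sm-site search window immediately upstream of a donor; the window applies to the last base of the Sm match. |
| `d_max` | 100 | nt | maximal BP-to-acceptor spacing for the second splicing step. 12 nt supports splicing, >1400 nt does not; 100 covers typical yeast BP-3'ss spacings while excluding clearly infeasible pairings. Increasing `d_max` can only convert cleavage-only events to two-step (tested). |
| `k` | 500 | genes | per-replicate top-list size of the enrichment funnel. |
| `pseudocount` | 1 | counts | on IP/control ratios and on normalized condition means. |
| `theta` | 3 | fold | up-regulation threshold in the mutant contrast; the passing set is nested in `theta` (tested). |
| `min_support` | 2 | reads | minimum distinct-read support per junction; singletons are treated as alignment noise. |

## The candidate tiers

Tier A requires reproducible Sm-IP enrichment, splice signals in the correct
order, and at least `theta`-fold up-regulation in the splicing mutant.
Junction evidence deliberately does **not** gate tier A: a genuine SMD
target whose spliced products are degraded too fast may leave no
junction-spanning reads, so junctions upgrade the annotation but not the
tier. Tier B catches the complementary case — a canonical junction with a BP
consensus inside the called intron, without enrichment support. The tier is
a pure function of the five-flag evidence vector (property-tested over all
32 vectors), and candidate sets are monotone in every threshold.

## What the generator emulates — and what it does not

`generate_genome` plants, per gene, exactly the architecture the scanner
looks for, with rejection-sampled backgrounds: a gene sequence is resampled
until it contains **no** unplanted motif literal, and the BP-to-acceptor gap
of signal genes is additionally AG-free so the planted acceptor is provably
the nearest one. Rejection (rather than masking) keeps recovery tests exact:
sensitivity and precision on clean settings must be 1.0, not approximately 1.
Every constructed gene is post-verified by re-scanning; construction fails
loudly rather than emitting an inconsistent truth.

`simulate_counts` draws negative-binomial counts (variance
`mu + alpha * mu^2`) with lognormal gene base means around the configured
depth, multiplying Sm-bound genes by `epsilon` in IP libraries and SMD genes
by `rho` in the splicing-mutant libraries, where intron-containing genes are
additionally halved (a splicing-defective mutant globally reduces spliced
mRNA). `simulate_spliced_alignments` emits plain and junction-spanning reads,
multiplying SMD junction depth by the stabilization factor in the
exosome-mutant condition and reducing all junction depths in the
splicing-mutant condition. Defaults (`n_genes = 100`, depth 500, dispersion
0.05, `epsilon = 8`, `rho = 4`, stabilization 4, 2 replicates per condition)
are the fixed study conditions of the recovery tests.

The generator does **not** model read errors, positional coverage bias,
multi-mapping, lariat/branch reads, overlapping genes, or alternative
transcript isoforms. Passing recovery tests therefore demonstrate
correctness of the pipeline's logic under its stated statistical
assumptions, not robustness to real-library artefacts; on real data the
funnel counts are additionally sensitive to the annotation release, which is
why no genome-release-dependent number is asserted anywhere.

## Numerical choices and degenerate inputs

* **Acceptor choice** is the nearest downstream AG from the BP start
  (strictly downstream, so a BP 1 nt before an AG has spacing 1). Ties are
  impossible; acceptor-less BPs yield cleavage-only events.
* **Longest-match rule**: variable-length Sm-site matches are collapsed to
  one hit per start position, keeping the longest run, so site counts are
  well-defined under overlaps.
* **Rank ties** in the enrichment funnel break lexicographically by gene id,
  making top-K sets deterministic across runs.
* **Junctions overlapping two genes** are assigned to the gene whose strand
  makes them canonical; if both or neither qualify the junction is flagged
  intergenic with a warning.
* **Normalization** is the self-contained median-of-ratios estimator
  (genes containing any zero are excluded from the median); it requires at
  least one all-nonzero gene and fails loudly otherwise. On all-positive
  tables it agrees with the standard RNA-seq implementation of the same
  estimator, which the test suite uses as an independent cross-check.
* **Frame classification** of introns that straddle a CDS boundary uses the
  number of CDS bases removed (mod 3), then a stop-codon scan of the spliced
  CDS.

## Known limitations

* The enrichment score is a pseudocounted ratio, not a test statistic; no
  significance is attached to the funnel, mirroring the fold-only design of
  the screen it implements.
* Median-of-ratios normalization assumes most genes are unchanged. When a
  noticeable fraction of genes is shifted in one direction in one condition
  (as the generator's mutant libraries deliberately arrange), the affected
  library's size factor absorbs part of the shift and fold-change estimates
  acquire a small systematic bias toward 1. This is a property of the
  estimator itself, shared with the standard implementations, and is visible
  in the calibration tests.
* BP feasibility is a hard distance cutoff; no kinetic competition between
  branch points is modelled (their selection is treated as outside the
  model's scope).
* The SAM reader supports exactly the M/N text subset the junction caller
  consumes; it is not a general alignment parser.

## Problem sizes used by the test suite

Module tests run on genes of a few hundred nt and genomes of 15-80 genes.
The deeper recovery and calibration tests use 100-gene genomes at depth 500
over 20 seeds (tier-A recovery and top-K sensitivity), 100 seeds of
counts-only simulation (fold-change calibration), 1000 random 1-kb sequences
(scanner-vs-oracle equivalence), 20 noise-free seeds (junction recovery),
and 20 paired seeds for the wild-type vs exosome-mutant junction contrast.
These sizes were chosen so each statistical check has enough replication to
be stable under its fixed seeds while the whole suite stays desk-scale.
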