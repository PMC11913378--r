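---
title: "Methods: TAD-boundary gene pairs and repressive p300/H3K27me3 loops"
author: "tadloops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TAD-boundary gene pairs and repressive p300/H3K27me3 loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures `tadloops` implements,
the parameters that matter and their defaults, what the synthetic-data
generators emulate, and the numerical and design choices made where more
than one reasonable convention exists.

## Coordinate conventions

All genomic containers are `GRanges` in the Bioconductor convention
(1-based, closed). BED/BEDPE input is converted on read and back on write,
so a read–write round trip is byte-identical; GTF is read through
`rtracklayer` and kept 1-based. Overlap always means at least one shared
base pair on the same chromosome; strand never enters an overlap test. No
minimum-overlap fraction is offered anywhere — classification questions in
this pipeline are presence/absence questions, and a fraction threshold
would introduce a tuning knob with no principled default.

Strand matters only for derived gene elements:

* **promoter** = TSS ± 1 kb (`promoter_flank`, bp);
* **terminator** = TES ± 5 kb (`terminator_flank`, bp);
* **gene body** = the full annotated span (promoter/terminator windows are
  *not* subtracted from it);
* **3' half** = the half of the span nearest the TES, used as an
  alternative "3' region" in head-to-tail screening.

Multi-isoform genes are collapsed to one model per `gene_id` (union span,
merged exons). Which isoform's 3' end defines "the end of the transcript"
is genuinely ambiguous for multi-isoform loci; the union-span collapse is
the most conservative single choice and is applied uniformly.

## p300-only peaks and feature annotation

H3K27ac peaks are extended ±1 kb (`k27ac_flank`); p300 peaks overlapping
none of the extended set form the p300-only class, the remainder the
shared class. The two outputs always partition the input, and enlarging
the flank can only shrink the p300-only set (both properties are tested).

Feature annotation assigns each peak by its **midpoint** — the simplest
fully reproducible rule, avoiding dependence on any annotation package's
internal heuristics — with priority
`promoter > first intron > other intron > exon > 3'-end > distal
intergenic`. "First intron" is counted in transcription order (the last
intron by coordinate on the minus strand). The 3'-end label covers
positions within 1 kb of a TES (`tes_flank`) that match nothing above it.

`signal_matrix()` tiles ±5 kb windows (`flank`) around site midpoints into
`n_bins` bins and computes the length-weighted mean of a bedGraph track
per bin; absent coverage counts as zero, and windows running past a
chromosome end average over the available bp only. `2*flank` must be
divisible by `n_bins` so bins have integer width. Coverage input is
bedGraph rather than bigWig to keep the core dependency-free.

## Interaction categories

Loop anchors (or the two ±5 kb boundary windows of one TAD, which form
that TAD's single boundary interaction — inter-TAD boundary pairs are not
formed) are labelled by overlap with p300-only peaks, H3K27me3 peaks,
promoters, terminators and gene bodies. Two exclusion labels follow the
display convention of boundary-interaction summaries: **gene** means a
gene-body anchor free of both chromatin marks, **intergenic** an anchor
free of genes and both marks.

Because an anchor can carry several labels, classification needs a
precedence order. A single combined list cannot serve both label
universes (an unmarked gene-body anchor would always be absorbed by a
gene-body class before any exclusion class could fire), so `mode` selects
one of two rule tables:

* `"chromatin"` — {p300_only, H3K27me3, gene, intergenic}, with
  `p300only–H3K27me3` first so the repressive class is never absorbed by a
  broader one, then mark–mark, mark–gene, gene–gene, …;
* `"genes"` — {promoter, terminator, gene_body}:
  `PP > PT > PG > TT > TG > GG`.

Anything unmatched is `"other"`. The table is an ordinary `data.frame`
argument, so custom precedences are one line of code. By default the
repressive class requires the two marks on *opposite* anchors; an anchor
carrying both marks alone does not qualify (the stricter reading).

`merge_loops()` collapses loops from several call sets when **both**
anchor centers lie within `tolerance` bp; connected groups under this
relation are replaced by their first member in sorted order. One matrix
bin is the sensible tolerance at a given resolution. The operation is
idempotent and matches a union-find oracle in the tests.

## Hi-C: VC_SQRT, virtual 4C, APA

Contact matrices are symmetric per-chromosome bin matrices (default 25 kb
bins) stored as plain-text triplets with a one-line header, keeping every
test and example download-free; each triplet is mirrored on load.

**VC_SQRT** balancing divides `c_ij` by `sqrt(r_i) * sqrt(r_j)` (row sums
`r`), leaves zero-coverage rows at zero, and rescales by a single scalar
so the grand sum is preserved — making normalized matrices comparable to
raw ones in total signal. The operation is deliberately not idempotent
(it is a one-shot correction, not an iterative balancer) and refuses to
run twice.

**Virtual 4C** is exactly row extraction: the anchor maps to the bins it
overlaps (midpoint semantics at equal widths), several rows are averaged,
and the profile over a region is returned untouched. No smoothing is
applied; that belongs to plotting.

**APA** extracts, for every cis loop whose anchor-midpoint bins `(i, j)`
satisfy `j − i > 2·window` and whose neighbourhood fits in the matrix,
the `(2·window+1)²` submatrix centered on `(i, j)` (window 6 gives
13 × 13) and averages element-wise. The diagonal guard keeps submatrices
from crossing the diagonal, where distance decay would dominate the
signal; edge-clipped loops are skipped and counted. The score is
`P2LL = center / mean(corner)` with a `ceiling(window/2)`-sized (3 × 3
for window 6) lower-left corner — the pixels with larger first-anchor and
smaller second-anchor coordinates, i.e. the near-diagonal side, the
standard convention for this score. A constant matrix scores exactly 1.

P2LL treats the corner as a local background estimate. That assumption
needs (a) loops far enough from the diagonal that decay across the window
is mild and (b) enough aggregate signal that the single center pixel is
not noise-dominated. The generator defaults reflect this: planted pixels
at 100–300 bin distances (2.5–7.5 Mb) and a depth (`base_count = 1000`
expected counts at distance 0) on the scale of deep in situ Hi-C at
25 kb resolution.

## Head-to-tail screening

For every TAD with boundary windows L and R, `detect_head_to_tail()`
enumerates same-strand gene pairs (U, D), U upstream of D in
transcription order, where U's terminator window *or* 3'-half gene body
overlaps one window and D's promoter overlaps the other (sides must
differ). Both 3' interpretations are accepted because usage alternates
between "3' region" and "gene body/terminator"; the element that matched
is recorded per pair (terminator preferred in the record when both hit).
Genes may extend outside the TAD — no containment is imposed, since
promoter-anchored genes typically point outward. All candidate pairs per
TAD are reported; no best-pair selection is attempted. The implementation
is checked against a brute-force enumeration oracle and against a
mirror-symmetry property (mirroring coordinates and flipping strands maps
the pair set onto its mirror image).

`oncogene_pair_summary()` reports, per role (3'-anchored vs
promoter-anchored) and class (oncogene/TSG/neither), both the fraction of
pairs and the fraction of the supplied list, with explicit denominators —
the two normalizations answer different questions and are easy to
conflate. Gene lists are user inputs; no list ships with the package.
`promoter_mutation_summary()` counts a sample at most once per gene
regardless of mutation multiplicity, and its overall fraction is
`samples with ≥1 hit in any target promoter / all distinct samples`.

## Expression statistics and qPCR

Expression enters as TPM and is analysed as `log2(TPM + 1)`; zero-TPM
genes are retained (log value 0), not filtered. Genes looped to
p300-only anchors are split by gene-span overlap with H3K27me3, each gene
counted once however many loops it appears in. Boundary-type comparisons
(PT/PG/PP) attach the expression of genes overlapping either boundary
window of each classified TAD, deduplicated per (gene, category); the
alternative — averaging per pair — is a one-line change on the returned
table. Group comparisons use the two-sample Wilcoxon rank-sum test (the
groups are independent gene sets, so the unpaired variant is the right
reading) via `stats::wilcox.test` (exact for small untied samples,
tie-corrected normal approximation otherwise) and `stats::kruskal.test`
for three or more groups.

ΔCt is computed per replicate against the reference gene of the same
(sample, replicate); replicates without a reference measurement are
dropped with a warning. ΔΔCt subtracts the *mean* control ΔCt per gene
(the standard convention), giving `fold = 2^−ΔΔCt` and `log2FC = −ΔΔCt`
exactly. Error bars can honestly be drawn two ways, so both are reported:
`sd_fold` (sd of per-replicate folds) and `sd_fold_prop` (sd propagated
from ΔΔCt as `ln2 · fold · sd`). Replicate tests default to Welch's
unequal-variance t-test; the pooled Student variant is a flag for exact
replication of legacy analyses. Amplification-efficiency correction
(Pfaffl) is out of scope.

## The synthetic genome

`sim_config(seed)` fixes every generator; identical configs give
byte-identical files. Defaults: 2 chromosomes × 10 Mb, 25 kb bins, 300
TADs of 35–50 kb separated by 16–20 kb gaps, 12 planted head-to-tail
pairs, 200 interior filler genes (2–5 exons, both strands), 200 p300 and
250 H3K27ac peaks with a 0.4 planted shared fraction (shared peaks placed
within 1 kb of an H3K27ac peak, true p300-only peaks at least 2 kb from
all of them), 60 H3K27me3-marked genes, 5 TADs planted as the repressive
boundary class, 8 + 8 TADs planted as PG and PP boundary pairs, 400 loops
with planted class proportions led by 8.33% for the repressive class,
distance-decay contacts `λ(d) = base·(d+1)^−α` with α = 1 and Poisson
sampling (negative binomial over-dispersion is unnecessary at toy scale),
a 1.6× intra-TAD factor, 5× enrichment at planted loop pixels,
log2(TPM+1) ~ N(3, 1.2²) with a −1.0 log2 shift on marked genes, qPCR
folds {4, 0.5, 1} at Ct noise σ = 0.05 with 3 replicates, and 1000
mutation samples with a 1% planted promoter-mutation rate plus one
uniform background mutation each.

Planted head-to-tail genes put the TES/TSS inside the boundary windows
with up to ±4 kb jitter, so detection is a genuine overlap computation
rather than an equality check. Planted gene length (5–6.5 kb) plus jitter
is deliberately smaller than `gap − boundary_flank`: longer genes would
reach across the gap into a neighbour TAD's boundary window and create
*additional genuine* head-to-tail conformations spanning the intermediate
TAD — a correct but unwanted property when the ground truth must be
exactly the planted set. Loop anchors are drawn from construction pools
checked for label purity (e.g. a "gene" anchor sits inside an unmarked
gene at least an anchor-width away from any peak), so each loop's class
is guaranteed by construction, not by running the classifier.

What the generators do **not** emulate: realistic sequence content, read
counts or peak-calling noise, overlapping genes and nested transcripts,
CTCF orientation, trans contacts, copy-number or mappability artifacts,
and genome-scale annotation density. Passing tests therefore demonstrate
the correctness of the computations under controlled conditions, not
robustness to every pathology of real data.

## Problem sizes and degenerate inputs

Tests and the acceptance script run the generators at their default sizes
(the largest being 5000 loops for class-fraction recovery and a 400-bin
contact matrix for APA), chosen so the planted effects are estimated with
comfortable margins while the whole suite stays quick on a laptop.

Degenerate inputs are defined rather than left to chance: empty peak sets
give empty partitions or a warning (feature distribution), an empty
subject makes `any_overlap` all-false, TADs shorter than twice the
boundary flank are skipped with a warning, a zero-length boundary flank
is an error, APA errors when no loop passes the guard, VC_SQRT leaves
dead rows at zero, the ECDF of an empty sample and rank tests on empty
groups are errors, and Ct tables with duplicate (sample, gene, replicate)
rows are rejected on read.

## Known limitations

* Feature annotation is midpoint-based; peaks straddling a feature edge
  are assigned to one side only.
* H3K27me3 input is an interval set; thresholding a coverage track into
  such intervals is the user's responsibility.
* `merge_loops()` is quadratic in the number of loops and intended for
  call-set-sized inputs, not genome-wide pixel lists.
* Contact matrices are dense in memory; at 25 kb bins this is fine for
  per-chromosome human-scale matrices but the triplet format is not meant
  for 1 kb genome-wide data.
* TAD boundary interactions pair the two edges of one TAD only; nested or
  overlapping domain calls are classified independently, not reconciled.
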