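---
title: "flowreg: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flowreg: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the models and their assumptions, the parameters that
matter, what the synthetic-data generator does and does not emulate,
and the design choices made where the design was genuinely open. It
states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The analysis problem

A two-condition chromatin experiment (e.g. endothelial cells under
laminar shear stress vs static culture) produces, per condition and per
assay (H3K27ac ChIP-Seq marking active enhancers, ATAC-Seq marking open
chromatin), two replicate peak sets, plus a differential-expression
table from matched RNA-Seq. The questions the pipeline answers are:
which regulatory elements are gained, lost or unchanged between
conditions; do the two chromatin assays change together; where do the
changing elements sit relative to genes; are the genes near gained
(lost) elements the ones that go up (down); and which transcription
factor motifs distinguish the changing elements.

## Coordinate and distance conventions

All intervals are 0-based half-open (`[start, end)`, the BED
convention) internally; 1-based formats are converted at I/O boundaries
only. The distance between two intervals is the gap between their
nearest ends: overlapping **or book-ended** intervals have distance 0,
and intervals on different chromosomes have undefined distance. The
widely used closest-feature tool reports 1 for book-ended features;
we diverge deliberately (a zero-length gap is distance 0), which
affects only exact-boundary cases, and we define "within 100 bp" as
distance ≤ 100 under our convention. Nearest-neighbour ties
(equidistant candidates) are broken by smaller start coordinate, then
lexicographic name — determinism is required for testability; no
convention is standard. Strand is ignored for peak–peak distances
(peaks are unstranded) and used only for TSS/TTS orientation.

The engine is built on `GenomicRanges::distanceToNearest` (whose gap
convention matches ours) with the tie-break applied on top; the test
suite checks it exactly against an independent exhaustive scan.

## Peak dynamics

Replicate consensus retains a peak iff it overlaps (distance 0) a peak
in the other replicate, merging retained overlapping peaks to their
union interval — a set-level surrogate for joint replicate peak
calling. Classification pools the two conditions' consensus sets and
merges touching intervals into components: components with members from
both conditions are `common` (union interval), flow-only components are
`gained`, static-only are `lost`. Two invariants follow by
construction and are asserted on every run: gained + lost + common
equals the merged-union size, and swapping conditions exchanges gained
and lost exactly.

The 100 bp tolerance is **not** used here: set-overlap (distance 0) is
the gained/lost/common rule, while "within 100 bp" applies only to
cross-assay pairing, mirroring the two distinct uses in the source
analyses.

An optional count-based refinement is provided for when per-peak read
counts exist: a two-sided exact binomial test of the condition-2 count
against the library-size null `p0 = lib2/(lib1+lib2)`, BH-adjusted,
with an FDR < 0.05 gate. A transparent exact test was chosen over a
dispersion-modelling fit (the field's tool for that is a full package
and out of scope); with pooled replicate counts it is anti-conservative
relative to a replicate-aware model, which is why it is a refinement
flag, not the primary classification.

## Cross-assay matrix

Each classified query peak (say, a gained ATAC peak) is paired with its
nearest subject peak (H3K27ac) within `max_gap = 100` bp; the pair
contributes one count to the (query class, subject class) cell, or to
(query class, none). Row sums therefore equal query class sizes and
row-normalisation gives the published-style "x% of gained ATAC peaks
overlap gained H3K27ac peaks" fractions. The 100 bp rule is applied to
peak edges, not summits — summit positions are not part of the input
contract, and edge semantics match the cited closest-feature usage.

## Annotation

Each peak is assigned by its **midpoint** (not any-overlap; one
unambiguous feature per peak, no double counting of long peaks) with
priority promoter > TTS > exon > intron > intergenic. The promoter
window is strand-oriented `[TSS − 1000, TSS + 100)` and the TTS window
is ±1000 bp around the transcript end; both are configurable since the
source tooling's windows are not stated in the analyses we mirror.
UTRs are collapsed into exons — the summary granularity used downstream
does not resolve them. Genes without a transcript end contribute
promoter calls only. Ties across genes are resolved by feature
priority, then smallest |TSS distance|, then gene id, making annotation
invariant to gene-list order.

## Regulatory domains and gene association

Domains follow the basal-plus-extension rule: every gene owns a basal
region (5 kb upstream, 1 kb downstream of the TSS, strand-oriented)
extended in both directions to the nearest neighbouring gene's basal
edge, capped at 1 Mb from the TSS and clipped to the chromosome. A
domain always contains its own basal region even when neighbouring
basal regions overlap it (zero extension on that side rather than
truncation). Whether the original analysis used this rule or a
"two nearest genes" variant is not stated; basal-plus-extension is
implemented as the default because it is the cited algorithm's default
association rule, and the association step is pluggable (any domain
table with `gene_id/chrom/start/end` works).

A peak associates with every gene whose domain contains its midpoint.
The cross-tab reports, per expression direction (up/down at
FDR < 0.05), the percentage of genes with at least one associated peak
of each dynamics class and the mean peaks per gene. The count–expression
relationship is summarised by Pearson's r between per-gene peak count
and log2 fold change with the t-distribution p-value on n − 2 degrees
of freedom (`stats::cor.test`; the tests verify the textbook formula to
1e-12). Genes with zero associated peaks enter with count 0 — dropping
them would condition on the association signal being present.

For cross-species comparisons, `gene_set_overlap` reports **both**
denominators — |∩|/|∪| (Jaccard) and |∩|/|A| — because published
"x% overlap" figures rarely state which one they use; an optional
many-to-many ortholog map translates the second set first, and a gene
counts as shared if any ortholog matches.

## Motif enrichment

Motifs are position probability matrices over A/C/G/T. JASPAR-style
count records are converted with a per-base pseudocount
(`(c + 0.25)/(N + 1)`); HOMER-style records are probability rows and
are regularised at a nominal depth of 100 (`(100p + 0.25)/(100 + 1)`) —
the pseudocount rule is defined for counts, so probabilities are
treated as counts at that depth.

Scanning scores every window on both strands by log2-odds against a
background composition (default: the empirical base frequencies of the
combined target + background sequences, guarding against composition
mismatch between the motif's reference background and the input).
Windows containing N are skipped. A window is a hit when its score
reaches `threshold_frac` (default 0.8) of the maximum achievable score.
A score-fraction threshold was chosen over a per-motif p-value cutoff
because it is self-contained — no score-distribution calibration — and
configurable; 0.8 of maximum corresponds to allowing roughly one
low-information mismatch in a sharp 10-mer.

Enrichment uses sequence-level counting (a sequence either has ≥ 1 hit
or not), matching the hypergeometric sampling model: with
`N = |T| + |B|` sequences of which `m = k + b` carry a hit, the p-value
is the upper tail `P(X ≥ k)` for `X ~ Hypergeometric(N, m, |T|)`. The
intended background is the **common**-class peak sequences, so that
enrichment is relative to constitutive regulatory sequence rather than
genomic background. BH adjustment is applied across motifs. A
GC-matched background subsampler is provided (equal-width GC bins,
resampling the background to the targets' histogram) for user-supplied
backgrounds with composition bias; the synthetic common-peak background
shares the targets' composition by construction, so the pipeline does
not apply it by default.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline is
designed to detect, at desk scale. Stated world (defaults):

* 3 chromosomes × 10 Mb, 500 genes with uniform TSSs — gene density of
  one per 60 kb, enough that 1 Mb domains are usually bounded by
  neighbours, as in a real genome.
* 400 common / 200 gained / 150 lost peaks per assay, 200–500 bp —
  class ratios mirror the published experiment's order-of-magnitude
  asymmetry (more gained than lost), scaled down ~20×.
* 20% of genes up, 15% down; DE log2 fold changes ~ Normal(±2, 0.5),
  non-DE ~ Normal(0, 0.1); FDR values are *assigned* below/above the
  0.05 threshold rather than computed from a count model — the pipeline
  consumes DE calls, and differential-expression model fitting is out
  of scope.
* Association probability π = 0.7: each gained (lost) peak is placed
  inside a uniformly chosen upregulated (downregulated) gene's
  regulatory domain with probability π, else uniformly on the genome.
* Replicates are the same peaks shifted by at most ±10 bp — technical
  jitter that keeps replicate consensus trivially resolvable (no
  replicate-concordance statistics exist to calibrate against).
  Distinct peaks of one assay are kept ≥ 30 bp apart so jitter can
  never merge two planted peaks; without this, random collisions alone
  would corrupt planted-class labels at these densities.
* Sequences have i.i.d. bases at 41% GC (human-like). A synthetic
  KLF-like G-rich 10-mer is planted in gained-peak sequences with
  probability `q_target = 0.6` and an ETS-like GGAA-core 10-mer in lost
  peaks, both at `q_background = 0.05` elsewhere. The fixtures are
  labelled `_synthetic` — they are stand-ins for the factor families,
  not database motifs. Their per-position consensus probability is
  0.97, chosen so that an instance *sampled from the PWM* passes the
  default 0.8 × s_max threshold with high probability (~0.74 for a
  10-mer); at lower sharpness a single sampled mismatch already fails
  the threshold and the planted-recovery construction breaks.
* Cross-assay coupling: with probability `cross_link_prob = 0.25` an
  ATAC peak is placed within 0–100 bp of a same-class H3K27ac peak.
  This field is a generator addition (the minimal structure needed for
  the cross-assay matrix to show the diagonal enrichment seen in real
  data); everything else about the two assays is independent.

Not emulated: read-level data, peak-calling noise, replicate
disagreement, chromatin domain structure, dinucleotide sequence
composition, motif clustering. A green recovery test therefore
establishes that the *analysis logic* recovers planted structure — not
that the upstream experimental steps would produce such structure.

## Numerical and degenerate-input choices

* `bh_adjust` implements the step-up rule directly
  (`min_{j≥i} m p_(j)/j`, clipped at 1) and is verified against
  hand-computed values and `stats::p.adjust`.
* A peak with zero total count in the occupancy test gets p = 1; a
  motif with zero background hits gets fold = ∞ (0/0 → NA).
* Zero variance in either correlation variable returns a flagged
  undefined result rather than an error.
* Empty dynamics classes produce all-zero annotation rows (flagged by
  `n = 0`) and NA association cells.
* All randomness flows from explicit seeds; library functions that
  need randomness (`gc_matched_subsample`, `plant_motif` via the
  generator) either take a seed or document that the caller seeds.
  Identical configuration + seed reproduces output bundles
  byte-identically (asserted by the acceptance suite).

## Known limitations

The occupancy test ignores replicate structure (pooled counts); the
annotation has no UTR/CpG/repeat resolution; domains ignore chromatin
contacts (no Hi-C-informed linking); the motif scanner uses a
zeroth-order background; and the generator's uniform placement model
makes domain occupancy slightly optimistic relative to clustered real
genomes. These are scope boundaries, not accidents.
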