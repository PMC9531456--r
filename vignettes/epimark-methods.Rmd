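---
title: "epimark: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epimark: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`epimark` analyses sparse-background histone-mark coverage profiles
(CUT&Tag-style) together with matched gene expression. The pipeline
enters at bedGraph coverage tracks and count matrices — read-level
processing (trimming, alignment, duplicate handling) is out of scope —
and covers: replicate merging, signal-block peak calling, blacklist
filtering and union peak lists, region quantification with CPM/RPKM
normalisation, base-pair overlap enrichment statistics, multivariate
Bernoulli HMM chromatin-state discovery, combinatorial promoter and
enhancer marking classification integrated with expression, distal
enhancer-to-gene linkage, and pairwise differential marking. A
synthetic-data generator provides ground-truthed inputs for every
stage.

# Coordinate conventions

All coordinates are 0-based half-open throughout, the BED/bedGraph
convention; conversion to the 1-based closed convention used by the
GenomicRanges machinery happens only at internal call boundaries.
Chromosome names are taken verbatim; a name present in one file and not
another is an error rather than a silent zero overlap, because that is
the most common integration bug in interval work. All base-pair sums in
the enrichment formulas are computed on merged (unioned) interval sets,
which makes them invariant to fragmentation and internal overlap of the
inputs. One shared base pair counts as an overlap everywhere.

# Peak calling

CUT&Tag background is near-empty, so peaks are *signal blocks*: maximal
runs of contiguous non-zero coverage, scored by their total signal
(AUC = sum of value times width). `call_peaks_stringent()` keeps the
`ceiling(f * B)` blocks of highest AUC, with `f = 0.01` ("top 1%") as
the default; nearest-rank selection is deterministic and all blocks
tied at the cut are retained so the result cannot depend on sort order.
No gap-tolerant joining is performed (gap = 0): nearby blocks merge only
if the coverage between them is non-zero, which we treat as emergent
behaviour rather than a rule.

Replicates are combined *before* calling: `merge_replicates()` builds
the union breakpoint grid and averages values, with an absent replicate
contributing zero. The mean (rather than the sum) keeps block AUCs on
the same scale regardless of replicate count, so a single threshold is
comparable across samples. Only merged tracks are ever fed to the
caller or the binarizer.

# Quantification and normalisation

`quantify()` integrates value x width over regions; the library size is
the genome-wide integral, so counts over any partition (e.g. the
3000-bp tiles used for sample clustering) sum exactly to the library
size. CPM is `count * 1e6 / library`; RPKM adds the per-region length
correction `* 1e9 / (library * length)`; the log2 variants add a
pseudocount of 1 so that zero stays zero.

# Enrichment statistics

Two explicit formulas are implemented exactly as printed in the
standard workflow:

* feature fold enrichment:
  `overlap_bp * genome_size / (bp_peaks * bp_feature)` — equals 1.0 in
  expectation under uniform placement (verified by a 1000-permutation
  shuffle test) and exactly 1 when the feature is the whole genome;
* pairwise set enrichment: `overlap_bp / (bp_setA * bp_setB)`,
  symmetric and fragmentation-invariant; matrices of such values are
  column z-scaled (`zscale_columns()`) only for heatmap display.

Peak annotation assigns exactly one label per peak by a fixed priority
(promoter > 5'UTR > exon > intron > 3'UTR > downstream > intergenic,
each by at least 1 bp of overlap). The priority is promoter-first
because the questions the package serves are promoter-centric; the
`downstream` feature is the conventional 3 kb past the gene end.
Promoters are the TSS +/- 2000 bp window; a promoter is "CGI" if it
shares at least 1 bp with a CpG island. Signed TSS distances use peak
midpoints and the strand of the nearest gene.

# Chromatin states

Tracks are binarized into 200-bp bins: the bin count is the rounded
signal integral, the background rate lambda is the genome-wide mean
count, and a bin is "present" when the Poisson upper-tail probability
P(X >= c | lambda) is at most 1e-4. These are the documented defaults
of the standard binarization tool; the threshold is checked against
brute-force pmf summation in the tests.

The state model is a K-state HMM whose emissions are independent
Bernoulli probabilities per channel. A channel is normally one mark
within one tissue; in the *across-tissues* mode the channels are the
same mark in different tissues, which converts tissue specificity into
state structure (a state per tissue plus a shared state). Fitting is
Baum-Welch EM with a C++ scaled forward-backward core (no underflow up
to at least 1e7 bins); chromosomes are independent sequences sharing
parameters. Initialisation is k-means on the binary bin patterns plus
seeded random perturbations with `n_restarts = 3`, deterministic given
the seed. EM stops at `max_iter = 200` or a log-likelihood improvement
below `tol = 1e-4`; the trace is non-decreasing by construction and
asserted in tests.

Decoding labels each bin with the maximum posterior state
(forward-backward), matching the behaviour of the reference tool
family; Viterbi is available behind `method = "viterbi"`. K is never
chosen automatically: `compare_models()` (per-state best emission
correlation against a reference model) and the log-likelihood trace are
reported, and the user fixes K by judgment. State-element enrichment is
the ratio of the in-state overlap fraction to the genome-wide overlap
fraction; empty states yield NA rather than a number.

Label switching in all recovery tests is undone by `match_states()`,
which maximises summed emission correlation over state permutations
(exhaustive up to K = 7).

# Integration with expression

The marking table scores each element (promoter window or
enhancer-like element) for each mark by >= 1 bp peak overlap. The three
headline groups are group1 = H3K18la+H3K27ac+H3K4me3, group2 =
H3K27ac+H3K4me3 without lactylation, group3 = H3K4me3 only; all other
non-empty Venn cells are retained under their own labels (the
lactylation-only cell is itself informative for distal elements) so the
cells partition the actively marked set. Group expression differences
use two-sided Mann-Whitney U tests: exact below a combined n of 24
without ties, normal approximation with tie and continuity correction
otherwise. Mark-versus-mark comparisons use Pearson correlation;
mark-versus-expression uses Spearman, because the planted (and
biological) link is monotone but not linear.

Sample clustering uses the "leading fold-change" style distance — the
root-mean-square of the top 500 absolute log2 differences, computed per
sample pair — followed by classical (Torgerson) multidimensional
scaling, with each axis sign-fixed so the first sample is non-negative.

Each distal enhancer-like element (dELS) is linked to the
protein-coding gene whose promoter window has the smallest edge-to-edge
distance without overlapping the element; exact ties go to the smaller
promoter start, then the lexicographically smaller gene id. The
promoter-to-gene map is 1:1 by construction (one TSS per gene model);
multi-TSS genes are out of scope.

# Differential marking

`differential_regions()` implements a conditional exact test for
negative-binomial counts with one common dispersion, rather than
wrapping an external count-model package: counts are scaled to the
geometric-mean library size, summed within condition, and the two-sided
p-value sums all conditional splits of the total whose probability does
not exceed the observed one. The common dispersion is a method-of-
moments estimate pooled across regions from within-condition
variability; if either condition has a single replicate the estimate
pools all samples (and then absorbs part of the condition effect — a
logged limitation), and a non-positive estimate falls back to the
conditional binomial (Poisson) test. Fold changes are
`log2((CPM_A + 0.5) / (CPM_B + 0.5))`: the 0.5 pseudocount keeps them
finite and exactly antisymmetric under condition swap. Multiplicity is
Benjamini-Hochberg; the default significance gates are FDR < 0.05 with
|log2FC| > 0.5, a stricter |log2FC| > 1.5 gate for per-class counts of
strongly changed regions, and nominal P < 0.01 with |log2FC| > 0.5 for
treatment-response gene lists. For change-change correlation the
marks side is FDR-filtered while the expression side is filtered on
fold change only by default; an expression-side FDR filter is exposed
as an argument because the convention is genuinely ambiguous.

One analytic subtlety verified in the tests: with 100 of 2000 regions
planted at 4-fold, CPM normalisation shifts the expected estimated
log2FC to `log2(4) - log2(2300/2000) = 1.795`, not 2.0 — composition
bias from the planted signal inflating the library of one condition.

# The synthetic world

The generator plants the co-occurrence structure the pipeline is meant
to detect, on a toy genome whose defaults are 3 chromosomes of 1 Mb, 60
genes, 3 tissues, 4 marks and 2 replicates per track.

* **Layout.** Genes occupy regular slots so each has room for its
  +/-2000 bp promoter window, a 200-bp PLS over the TSS, a 300-bp pELS
  at 200-2000 bp, and so that 350-bp dELS can always be placed more
  than 2000 bp from every TSS (violations are an explicit error, and a
  guard assertion re-checks the clearance after placement).
* **Classes.** Housekeeping genes (fraction 0.3) always carry a CpG
  island and the active-CGI promoter class; non-housekeeping genes are
  poised with probability 0.2, otherwise active with or without a CGI
  (fraction 0.4). Half the dELS are tissue-specific by default,
  assigned round-robin so every tissue owns some.
* **Occupancy.** Each (element, mark, tissue) indicator is Bernoulli
  with a class-dependent probability (see `default_occupancy()`):
  H3K4me3 at promoters, H3K27ac at active promoters and enhancers,
  H3K18la highest at active CGI promoters and at the owning tissue's
  specific dELS, H3K27me3 at poised promoters. Housekeeping-gene
  elements use one constitutive draw shared across tissues; a
  tissue-specific dELS is zero outside its owner. A pELS whose gene has
  a poised promoter inherits the poised probabilities: both elements
  lie inside the scored promoter window, and an active proximal
  enhancer under a poised promoter would contaminate the planted Venn
  cell (it would also be biologically incoherent).
* **Coverage.** Poisson counts per 25-bp micro-bin with mean
  `background_rate = 1`, multiplied by `enrichment_fold = 8` inside
  occupied elements, run-length encoded to bedGraph. The 25-bp grid
  makes the Poisson binarization model well-specified; element
  boundaries snap to it. The study this design follows does not report
  effect sizes for enhancer lactylation, so the background and fold are
  free parameters chosen once as a realistic sparse-assay regime; the
  recovery criteria are run at exactly these defaults.
* **Expression.** Gene counts are `round(2^(3 + 2 * intensity + e))`
  with `e ~ N(0, 1)`, where the planted promoter intensity is the
  weighted sum of the active-mark indicators at the promoter
  (weights 1.0 for H3K18la, 0.6 for H3K27ac, 0.3 for H3K4me3). A pure
  H3K18la-only intensity could not plant the required
  group1 > group2 > group3 expression ordering — groups 2 and 3 are
  both lactylation-free — so the intensity is mark-weighted with
  lactylation dominant. With zero noise the intensity-to-count map is
  exactly monotone, which the determinism tests exploit.

What a green test does **not** establish: the generator has no
fragment-length structure, no copy-number or mappability artefacts, no
correlated replicate noise, no multi-TSS genes, and its element classes
are disjoint by construction — real data violate all of these. Green
recovery therefore certifies the statistical machinery, not performance
on any particular published dataset, whose printed percentages derive
from deposited sequencing data outside this package's scope.

# Fixture sizing in the acceptance tests

Two acceptance fixtures are sized analytically rather than by trial:

* *Peak recovery*: a top-1% caller can recover 200 planted elements
  with few spurious calls only if the track holds about 20,000 signal
  blocks. With background 1 per 25-bp bin and two averaged replicates,
  P(zero bin) = e^-2 and the expected block count is
  `G/25 * e^-2 * (1 - e^-2) ~ G * 0.0047`, giving a 4.2 Mb genome.
* *Inside/outside calibration at fold 1*: the 5% agreement band is
  stated at >= 1e4 occupied bins, so that world plants ~2.7e5 bp of
  occupied elements.

# Known limitations

Single-replicate dispersion estimation absorbs condition effects (see
above). The HMM assumes channel independence given the state — marks
that co-vary within a state are summarised, not modelled. The
enhancer-gene linkage is nearest-promoter only; no chromatin-contact
information is used. The binarization threshold interacts with the
200-bp grid: elements much shorter than a bin dilute below threshold.
K selection is deliberately manual.
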