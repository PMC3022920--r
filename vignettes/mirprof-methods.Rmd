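---
title: "Methods: small-RNA processing and isomir statistics in mirprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA processing and isomir statistics in mirprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirprof)
```

`mirprof` quantifies mature miRNA expression from small-RNA sequencing
reads at isomir resolution. This vignette is the package's account of
the underlying model and procedures, the parameters that matter, the
synthetic-data generator used for validation, and the numerical and
design choices made where more than one reasonable option existed.

## Read preprocessing

**Adapter trimming.** Small-RNA library inserts (typically 19-24 nt)
are shorter than the sequencer read, so every read runs into the
ligated 3' adapter. The trimmer anchors on the adapter's first 8 nt
(default `CGCCTTGG`) and scans each read left to right, truncating at
the first window whose Hamming distance to the prefix is within the
mismatch budget (default 1). Two consequences of this design are worth
stating explicitly:

* *Leftmost-first, not exact-first.* A mismatched window earlier in
  the read beats an exact window later. This reproduces
  regular-expression-style matching semantics. The trade-off is a small
  probability of premature truncation when an insert happens to contain
  a near-copy of the prefix; with an 8-nt anchor and one mismatch this
  affects roughly 0.5% of random 20-nt inserts. Shorter anchors (4-6
  nt) would make this failure mode common, which is why the default
  anchor is 8 nt.
* *`N` counts as a mismatch against every adapter base*, so runs of
  uncalled bases cannot spuriously match the adapter.

**Length rules.** Post-trim sequences below `min_len` (default 15 nt)
are dropped and accounted for in the report's below-minimum bucket;
sequences above `max_len` (default 32 nt, the classic aligner input
limit for this assay) keep their first 32 bases. Since mature miRNAs
average ~21-22 nt, both bounds are generous for the signal of interest.

**Demultiplexing.** Samples are identified by 6-nt barcodes, either as
an inline read prefix (stripped on assignment) or as a separate tag
read. The `exact` policy assigns only perfect matches; `levenshtein1`
assigns a read if and only if exactly one sample tag lies within edit
distance 1 — a read equidistant from two tags stays unassigned, so
barcode sets should maintain pairwise edit distance of at least 3 when
this policy is used. Read counts are conserved exactly at this and
every later stage (assigned + unassigned = input), and the tests assert
those identities.

## Alignment and uniqueness strata

Collapsed tags (identical sequences summed, ordered by descending count
then sequence for reproducible output) are placed on the genome with at
most 2 substitutions. The search is a seeded exact-candidate scheme: an
exact k-mer index over the forward genome (default k = 5), with each
tag split into `max_mismatch + 1` segments; the pigeonhole principle
guarantees any placement within the budget matches at least one segment
exactly, so seeding the first k bases of every segment finds *all*
qualifying placements. Minus-strand hits come from querying the
reverse complement. The default k = 5 keeps seeding complete for 15-nt
tags at 2 mismatches (`floor(15/3) = 5`); larger k would be faster but
silently incomplete for the shortest tags.

Each tag is classified at the lowest populated mismatch level:
`U0`/`U1`/`U2` when that level holds exactly one placement, `R` when it
holds several, `NM` when nothing is within budget. A tag unique at 0
mismatches but repeated at 1 is `U0`: uniqueness is judged within the
best level only, matching the disjoint stratum accounting of the
classic report layout. Repeat placements are stored up to a cap
(default 64) purely as a memory bound; the stratum itself is computed
from the complete count. `N` in a tag mismatches every genome base.
The test suite proves stratum and placement-set equality against a
brute-force Hamming scan of every genome window for ~1,000 random
mutated tags, and the alignment TSV import path allows an external
aligner's output to replace the built-in search without changing any
downstream stage.

Only `U0` and `U1` tags are annotated; `U2` and `R` reads count toward
the alignment report and (by default) the tpm denominator but never
toward transcripts. This mirrors the conservative practice of trusting
only high-confidence unique placements for expression.

## Arm derivation and transcript assignment

miRNA annotation often lists only one mature product of a hairpin. The
package names products by precursor arm (5p/3p) rather than
mature/star, and infers a missing arm geometrically: with precursor
length $L$ and the known arm at precursor-relative positions $[p, q]$,
the inferred arm is $[L+1-q+2,\; L+1-p+2]$ — the mirror image through
the hairpin axis, shifted 2 nt toward the precursor 3' end so that both
strands of the duplex carry the characteristic Dicer 2-nt 3' overhang
under perfect stem pairing. The formula is an exact involution
(inferring back recovers the original interval), intervals running off
the precursor are clamped and flagged, and inferred arms carry `~` in
identifiers so downstream users can distinguish annotated from inferred
coordinates. No secondary-structure prediction is attempted; for a
bulged, asymmetric hairpin the inferred interval can be off by a few
nucleotides, which the 50% assignment rule absorbs.

A uniquely aligned tag is assigned to every locus it overlaps by at
least 50% **of the tag length** (inclusive boundary: 11 of 22 bases
qualifies). Measuring against the tag rather than the locus was chosen
deliberately: 3'-trimmed or extended isomirs vary in length, and a
read-based criterion keeps short variants annotatable to their arm.
One tag may be assigned to several overlapping loci; all assignments
are reported and each assigned transcript counts the tag, which can
double-count reads in the tpm of overlapping annotations (flagged here
as a caveat; the report's class accounting attributes each tag once, to
its highest-overlap locus, so its partition identities stay exact).
A read overlapping both arms of a very short hairpin at 50% is assigned
to both, visibly, rather than silently to one.

## Quantification

Isomirs are keyed by (placement, sequence): the same sequence at two
places is two isomirs; two reads with the same sequence and place are
one isomir with a summed count. Per transcript and sample the
expression table reports three summaries — the sum over all isomirs,
the perfect-match-only sum, and the most abundant isomir (ties broken
by lexicographically smallest isomir id for determinism) — plus the
count of distinct isomirs. All three summaries are highly correlated in
practice; the sum of isomirs is used as *the* expression value by the
statistics stages.

Counts scale to tags-per-million: `tpm = counts / denominator * 1e6`.
The default denominator is all genome-aligned reads
(`U0+U1+U2+R`), the plain reading of scaling by "aligned tags"; an
`aligned_unique` (`U0+U1`) policy is provided because annotation only
uses unique reads. The choice shifts absolute tpm by a constant factor
per sample and cancels in fold changes. The square-root transform
stabilizes counting variance (for Poisson-like counts, `sd(sqrt(x))` is
approximately constant), and statistics operate on `sqrt(tpm)`.

## Differential expression

Per transcript, a two-sample t-test on `sqrt(tpm)`; BH adjustment over
all tested transcripts; significance requires all of `q <= fdr_alpha`
(0.05), fold change at least `min_fold` (1.5, computed on the tpm scale
as larger-group-over-smaller from Table-style group means), and at
least `min_tpm` (5) in one group's mean. The fold threshold is applied
on the tpm scale, not sqrt(tpm), because reported fold differences in
this field are tpm-scale ratios.

Two tests are offered. `plain_t` is Welch's t with Satterthwaite
degrees of freedom — simple and assumption-light, but with only two
replicates per group its df can drop toward 1, putting a floor of
roughly 0.01 on attainable p-values regardless of effect size.
`moderated_t` pools information across transcripts: per-transcript
pooled variances are shrunk toward a scaled inverse-chi-square prior
whose scale and degrees of freedom are estimated by method-of-moments
on `log s^2` (digamma/trigamma moment equations, Newton inversion of
the trigamma), and the t statistic is referred to `d + d0` degrees of
freedom. This reproduces the empirical-Bayes variance-moderation idea
standard for few-replicate expression designs; a test cross-checks its
ranking against an established implementation. For duplicate-level
designs the moderated test is the appropriate choice and is what the
package's own acceptance analysis uses.

## The isomir global test

Differential expression on the per-transcript sum discards the isomir
complement. The global test asks, per miRNA, whether its set of isomir
profiles is associated with the group labels. With centred group
indicator $y$ and centred isomir columns $x_i$ (on `sqrt(tpm)`), the
statistic is

$$Q = \frac{1}{m} \sum_{i=1}^{m} (x_i^\top y)^2,$$

a quadratic score form whose per-isomir contributions
$Q_i = (x_i^\top y)^2 / m$ sum exactly to $Q$ and carry the sign of
each isomir's association. Significance comes from label permutations:
exhaustive over all distinct labelings when there are at most 10,000 of
them (2 vs 2 gives 6; 4 vs 4 gives 70), otherwise Monte-Carlo with an
add-one correction and a recorded seed. This permutation null was a
deliberate design choice over the asymptotic distribution of the
original formulation: it is distribution-free and exact at the tiny
sample sizes typical of sequencing designs, at the cost that p-values
are granular (never below 2/#labelings, since the complement labeling
always ties $Q$) and will not numerically match asymptotic
implementations.

Pre-test filters follow the established workflow: isomirs whose
sequence contains `N` are excluded; an isomir is kept only if its
within-group tpm sum reaches 10 in **at least one** group (the source
phrasing "for either group" is ambiguous; the inclusive reading was
chosen and is documented here); miRNAs retain at least 2 isomirs or are
not tested. BH runs across miRNAs, and results whose most abundant
isomir does not exceed 50 tpm (group-mean scale) are flagged as below
the abundance reporting filter rather than dropped, so the caller
decides.

For significant miRNAs, `isomir_subsets()` clusters isomirs by
average-linkage on `1 - Pearson correlation` across samples, applies
the global test to every node of the tree (leaves included), and
Holm-adjusts across all tested nodes at level 0.1. Reported are every
node's adjusted p, the significant leaves, and the *maximal*
significant nodes — when a whole branch moves together, the branch (up
to the root) is reported as the unit of differential expression instead
of any single isomir.

## The synthetic-data generator

`simulate_reference()` draws a uniform-random genome and places
non-overlapping hairpin precursors (70-100 bp) on random strands; each
carries a 5p arm (20-24 nt, the canonical mature length range) and a 3p
arm positioned by the same overhang geometry the annotator inverts. A
configurable fraction (default 0.3) of precursors is annotated with
only one arm, so arm inference is exercised on every simulated study.
`simulate_library()` draws reads from a log-normal arm-expression
profile (meanlog 0, sdlog 1.5 — spanning the several orders of
magnitude seen in real miRNA profiles), then applies an isomir model:
geometric 5'/3' end offsets (5' tighter than 3', matching the
observation that 5' ends are Drosha/Dicer-anchored while 3' ends vary),
non-templated 3' A/T additions (probability 0.05), and rare internal
substitutions (0.02). The 3' adapter (beginning `CGCCTTGG`) is
appended and the read truncated to 32 nt; a small fraction (0.02) of
random unalignable reads models library noise. Every generative choice
is recorded in a read-level truth table, and all randomness flows from
a single seed in documented order, so fixtures are reproducible
byte-for-byte.

Defaults — 50 precursors, 100,000 reads — are the package's standard
validation conditions; the test suite runs most stages on smaller
instances (6-10 precursors, 2,000-10,000 reads) and the aligner oracle
on 100-kb genomes with 1,000 tags.

**What passing these simulations does and does not show.** The
generator emulates composition (arm profiles over orders of magnitude),
end-variation isomirs, barcodes, adapters and unalignable noise. It
does not emulate position-dependent sequencer error profiles, ligation
sequence bias, quality-score structure, cross-mapping between paralogous
miRNA families (precursors are placed at random, so near-identical
family members do not arise), or genuinely structured hairpins. Recovery
results on simulated data therefore validate the pipeline's
*bookkeeping and statistics* — not robustness to the biases of any
particular chemistry.

## Numerical choices and degenerate inputs

* Ties for the most abundant isomir break on the lexicographically
  smallest isomir id; collapse order is count-descending then sequence;
  both make outputs byte-stable across runs.
* Permutation p-values use `>=` with a relative tolerance of `1e-12`
  so floating-point jitter cannot drop the identity labeling.
* A constant isomir matrix gives `Q = 0`, `p = 1`; a single-isomir
  subset is a valid (trivial) node; zero-variance transcripts with
  equal means give `p = 1`, with unequal means `p -> 0`.
* `fold_change(0, x) = Inf` for `x > 0`; `0/0` is `NaN` (undefined),
  and such transcripts are never significant.
* The trigamma inversion in the moderated test runs Newton iterations
  to relative tolerance `1e-10`; when the observed spread of
  `log s^2` is below the theoretical sampling spread, the prior df is
  infinite and all variances collapse to the common estimate.
* Zero aligned reads make the tpm denominator an error, not a silent
  division by zero.

## Known limitations

* Substitutions only: no indel alignment, so templated-deletion
  isomirs land in `NM` or misalign at 1-2 substitutions.
* tpm is compositional — strong true changes in abundant transcripts
  shift every other transcript's tpm. Fold-change filters partially
  mask this; no compositional normalization (median-of-ratios etc.) is
  applied because the unit of this workflow is tpm.
* Multi-locus assignment double-counts reads across overlapping
  annotations (documented above).
* The permutation global test cannot reach small p-values at tiny
  designs (minimum `2/#labelings`), so 2 vs 2 designs bound per-miRNA
  p at 1/3; subset detection needs more samples to be informative.
* SCARF parsing assumes the common colon-delimited dialect (sequence
  second-to-last field, quality last); other dialects need conversion.
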