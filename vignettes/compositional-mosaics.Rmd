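---
title: "Mapping compositional mosaics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping compositional mosaics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind `gcmosaic`, the
choices made where the methodology was genuinely open, and what the
package's synthetic-data validation does and does not establish about
real genomes.

## The compositional model

The working model is that a genome is a mosaic of segments drawn from a
small number of compositional families. Each family is characterized by
a mean GC level; segments are long (on the order of 100 kb) and fairly
homogeneous internally, so the genome-wide distribution of DNA *by
weight* across GC is multimodal, with one mode per family. The analysis
chain estimates that structure from sequence alone.

### Windows

Chromosomes are cut into fixed, non-overlapping windows
(`segmentation_params()`, default `window_size = 25000`). 25 kb is a
compromise: small enough that the short chromosomes of unicellular
eukaryotes (often just a few hundred kb) yield enough windows to see
structure, large enough that the binomial sampling error of window GC
is small (s.e. ≈ 0.32% GC at 50% GC). The trailing remainder of a
chromosome shorter than one window is discarded — not padded, not
merged — so that all windows are equal length and a segment's GC is the
plain mean of its member windows. Window GC is 100·(G+C)/(A+C+G+T):
ambiguity codes (assembly gaps above all) are excluded from numerator
and denominator so gaps do not drag GC estimates down. Windows with
fewer than `min_valid_fraction` (default 0.5) unambiguous bases are
flagged invalid, excluded from all statistics, and *break* segments:
merging DNA across an assembly gap would fabricate continuity the
assembly does not support.

### Segments

The published isochore-mapping methodology this follows is
threshold-based but its exact merge rule is not restated in the
source literature available to us, so the package fixes an explicit,
configurable rule: **greedy mean-tracking merge**. Scanning left to
right, the first valid window opens a segment; each next valid window
joins if |window GC − running mean of the open segment| ≤
`merge_threshold` (default 1.5% GC), else it opens a new segment. The
rule is deliberately simple, its two parameters are exposed, and the
test suite pins its semantics against an independently written
brute-force implementation over thousands of enumerated and random
window sequences — so the algorithm is exactly what it claims to be,
not an approximation of something unstated. Known properties of this
class of method apply: it tends to overestimate homogeneity (the sd of
a region's GC decreases with region size), and a window just past the
threshold founds its own single-window segment, so segment-GC
distributions acquire small satellite tails around each family mean.
No smoothing is applied to window GC before merging, and there is no
minimum segment size.

### Binning and family detection

Segments are pooled into left-closed bins `[x, x+0.5)` anchored at 0%
GC, each segment contributing its full length ("distribution by
weight"). Families were evidently read off such histograms by eye in
the original methodology; the package replaces that with a
reproducible surrogate (`detect_families()`):

1. smooth the binned weights with a centered moving average over
   `smooth_bins` bins (default 3; zero weight assumed outside the
   occupied range);
2. every local maximum of the smoothed profile is a candidate family
   (plateaus count once, at their central bin);
3. boundaries sit at the lowest smoothed bin between consecutive
   maxima — the valley bin joins the left family, an arbitrary but
   deterministic tie-break;
4. candidates holding less than `min_family_fraction` (default 0.02)
   of the total weight are merged into the heavier of their flanking
   neighbours until none remain.

Family weight, mean and span are computed from the *raw* weights of
member bins; the mean uses bin midpoints, which is what a
histogram-based reading supports (pass `segments` to compute it from
raw segment GC instead — the difference is below a quarter bin in
practice). Family means are classified against cutpoints 37/41/46/53%
GC, chosen to bracket the canonical vertebrate family averages
(36.2/39.1/43.3/48.3/54.8% GC for L1/L2/H1/H2/H3); means below 30% or
at/above 57.5% GC are labelled `extreme-low`/`extreme-high` rather
than force-fitted to the vertebrate scheme — these bounds keep the
classical averages inside L1–H3 while the published extreme genomes
(19–28% and 59% GC) fall outside. All cutpoints are configurable
(`family_boundaries()`).

### Scaffold assemblies

For genomes available only as contigs/scaffolds, `scaffold_stats()`
reports the genome GC and the megabase split around a length cutoff
(default 100 kb). The cutoff is inclusive on the large side (exactly
100,000 bases counts as large): the two classes must be exhaustive and
the boundary assignment is otherwise arbitrary, so it is documented
rather than hidden. Rounding to one decimal happens only in written
reports; all internal values are full precision.

### Codon-position GC and orthogonal regression

`codon_gc()` computes GC1/GC2/GC3 over a CDS's codons; a codon
containing any ambiguity code is skipped at *all three* positions, so
the identity gc = (gc1+gc2+gc3)/3 holds exactly. The terminal stop
codon is included by default (the CDS is defined through its stop;
`include_stop = FALSE` drops it). CDS sets are first cleaned
(`clean_cds()`): description keywords (partial, putative, hypothetical
protein, rRNA/tRNA, mitochondrial, …) matched case-insensitively as
substrings; then start codon (ATG only by default — ciliate-style
reassignments are an explicit option), terminal stop, no internal
stop, length divisible by 3; finally exact duplicate sequences are
removed keeping the first. Exact-duplicate removal is a deliberate
minimal reading of "redundancy removal": the threshold of the
historical cleanup program is not documented, so no similarity
clustering is implied.

"Orthogonal regression" is implemented as the **major axis**: the
first principal axis of the raw 2×2 covariance matrix, the line
minimizing summed squared perpendicular distances. This is the
textbook choice when both variables share units (% GC here); reduced
major axis (sd-ratio slope) is available as `method = "rma"` but is
not the default because it fixes |slope| to sd(y)/sd(x) regardless of
correlation. The reported R is the ordinary Pearson correlation, and
n ≥ 3 with nonzero variance in both variables is required — a
zero-variance side leaves the fit undefined and `pairwise_position_fits()`
reports such cells as absent rather than inventing a slope. Histogram
overlap between two gene sets is the summed bin-wise minimum of the
two normalized histograms (bin width 2.5%): 1 for identical
histograms, 0 for disjoint support.

## The synthetic-data generator

`simulate_genome()` emulates exactly the structure the analysis
assumes: chromosomes are concatenations of segments; a segment's
family is drawn by the family proportions; its length is Gaussian
(default mean 100 kb, sd 50 kb — the typical segment scale in these
genomes), truncated at one window and rounded to whole windows so the
truth aligns with the 25-kb grid and boundary-recovery scoring is
exact; each window's target GC is the family mean plus Gaussian noise
(default sd 1% GC, a realistic local scatter at 25 kb); bases are
i.i.d. given the window target, G:C and A:T split evenly. What it does
**not** emulate: dinucleotide structure and repeats (the analysis uses
only mononucleotide GC), GC skew (a switch exists, default 0),
coding/non-coding mosaic, or any evolutionary process. Passing tests
therefore show that the pipeline recovers the compositional structure
it models, not that real genomes satisfy that model.

`simulate_orthologs()` draws per-gene (GC1, GC2, GC3) targets for
species A from a trivariate Gaussian (equicorrelated, default 0.5,
clipped to (0,100)); species B repeats the same targets with GC3
shifted (default −25% GC) — the scenario of two related genomes whose
compositional divergence acts at the third position. CDS of 300 codons
realize the targets through per-position base draws, with the first
codon forced to ATG and the last to TAA. Two quantifiable artifacts
are worth knowing:

* **codon sampling noise**: realized per-gene GC adds binomial noise
  (s.e. ≈ 2.9% GC at 300 codons), which *attenuates* between-position
  correlations below the target value; the tests compare fitted r to
  the closed-form attenuated expectation, not to the raw input.
* **stop-codon exclusion bias**: internal stop codons are resampled so
  every generated CDS passes `clean_cds()`; since stops all begin with
  T, this raises realized GC1 by ≈ 2% at default targets (≈ +0.3/+0.7
  at positions 2/3). The bias is common to both species and all genes,
  leaving shifts, overlaps and correlations — the quantities under
  study — unaffected.

## Validation problem sizes and numerical choices

The test suite validates the chain end to end at sizes chosen to be
representative of the genomes the method targets (roughly 10–100 Mb):

* family recovery: 100 seeded genomes of 20 Mb (4 × 5 Mb chromosomes,
  ~250 segments each) with 1–3 families at the canonical means
  (38.8/43.5/48.8% GC, ≥ 4% apart) and window noise sd 1%; recovery of
  the exact family count, means within 0.5% GC and amounts within 3
  points is required in ≥ 95% of replicates. Substantially smaller
  genomes (a few Mb, < 100 segments) make the binned histogram itself
  lumpy — single 0.5% bins can carry > 2% of the genome by sampling
  accident — and family *counting* degrades for statistical, not
  algorithmic, reasons. That is a real phenomenon users profiling very
  small genomes should expect; raising `min_family_fraction` or
  `smooth_bins` is the appropriate response there.
* window-size robustness: on strongly compartmentalized 20 Mb genomes
  (segments ~500 kb), heterogeneity (sd of window GC) at 25 kb exceeds
  that at 100 kb only slightly, and the two dominant family modes
  agree across window sizes within 0.5% GC. At 100-kb windows a small
  intermediate-GC mass appears from windows straddling family
  boundaries — unavoidable once the window approaches the segment
  length — so cross-window-size comparisons are made on the dominant
  modes.
* segmentation semantics: exhaustive enumeration of all window
  sequences up to 6 windows over 4 GC levels (plus 2,000 random deeper
  sequences) against an independent brute-force implementation, at
  thresholds below, between and above the level spacings.
* regression: a 5,000-point bivariate normal cloud with a known
  population major axis (slope 0.8) and closed-form population R.

Degenerate inputs are handled by explicit contract: records shorter
than one window give an empty window set with a warning (not an
error); an all-invalid chromosome yields no segments; an empty segment
set cannot be binned; heterogeneity requires ≥ 2 valid windows;
regression requires ≥ 3 complete pairs and positive variance on both
sides. Ties in family detection (plateau maxima, equal valleys) break
deterministically (central bin, first minimum, valley-joins-left) so
identical inputs always give identical output.

## Known limitations

* The greedy merge is order-dependent (left to right) and
  threshold-based; likelihood or change-point segmentation methods are
  out of scope by design, and the published segment maps it emulates
  were produced by a methodology whose exact parameters are not
  public. Conclusions should rest on the binned family structure,
  which is robust to how segments are delimited, more than on
  individual segment boundaries.
* Family detection reads a histogram; families closer than ~2 bins
  plus smoothing width, or lighter than `min_family_fraction`, merge
  by construction.
* The classification cutpoints translate vertebrate conventions;
  for genomes outside 30–57.5% GC the extreme labels deliberately
  avoid claiming homology with vertebrate isochore families.
* Ortholog pairing is an *input*; the package neither infers orthology
  nor corrects for paralogy.
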