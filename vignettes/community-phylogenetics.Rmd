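---
title: "Community phylogenetics of forest-dynamics plots: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community phylogenetics of forest-dynamics plots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestphylo)
library(dplyr)
```

forestphylo implements the analysis chain used to ask whether the tree
community of a forest-dynamics plot is assembled at random with respect to
phylogeny, or shows the clustering expected under habitat filtering of
conserved traits (or the overdispersion expected under limiting
similarity). The chain runs from DNA-barcode haplotype preparation through
chronogram dating, per-subplot diversity metrics with a randomisation null,
topographic habitat typing, and the statistical comparisons across trees
and habitats. This vignette describes the models, the tunable parameters,
the numerical choices, and what the synthetic-data experiments do and do
not demonstrate.

## The metrics and their null model

For each subplot (quadrat) with at least two taxa, three quantities are
computed on an ultrametric phylogeny of the species pool:

* **Faith's PD** — the sum of branch lengths of the minimal spanning
  subtree connecting the subplot's taxa, in million years. By default the
  path to the tree root is included (`include_root = TRUE`), the
  long-standing convention of the toolchain this package mirrors; a
  single-taxon subplot then has PD equal to its root-to-tip depth. The
  option exists because the literature is split on the convention.
* **MPD** — the mean patristic distance over heterospecific pairs. With
  abundance weighting,
  $MPD = \sum_{i \ne j} d_{ij} n_i n_j / \sum_{i \ne j} n_i n_j$.
  Conspecific self-pairs are excluded from both
  numerator and denominator: a pair of stems of the same taxon carries no
  information about *inter*specific relatedness, and the nearest-taxon
  metric is explicitly heterospecific, so the two weighted metrics stay on
  the same footing. (Some implementations include the zero-distance
  self-pairs in the denominator; the difference is largest in low-richness,
  high-dominance subplots.)
* **MNTD** — for each taxon the distance to its closest heterospecific
  relative, averaged (abundance-weighted or not) over the subplot.

The null model is a **tip shuffle across the entire tree**: each
randomisation relabels the full distance matrix by a uniformly random
permutation and recomputes the metric with the subplot's observed richness
and abundance vector. For a subplot of richness *s* this is equivalent in
distribution to drawing *s* pool taxa uniformly at random and carrying the
abundances over, which is how it is implemented (one subset draw per
randomisation). Shuffling across the *whole* tree, not a pre-pruned
community subset, is the default because the species pool an ecologist
supplies is usually the plot-wide phylogeny itself; pruning first
(`prune_to_taxa()`) remains available when a narrower pool is wanted.

From a null ensemble of `n_rand` values (default 1000), the standardised
effect size is `ses = (obs - mean(rand)) / sd(rand)`, and

* **NRI** = −SES of MPD,
* **NTI** = −SES of MNTD,

so positive indices mean phylogenetic clustering. Significance is judged
by the rank of the observation among observation plus randomisations,
`q = rank / (n_rand + 1)`: two-tailed at level α (default 0.05), a subplot
is *clustered* when `q ≤ α/2` and *overdispersed* when `q ≥ 1 − α/2`.
The rank criterion rather than `|SES| > 1.96` is the default because null
metric distributions are skewed at low richness; both one-tailed testing
and the SES cut-off can be reproduced by the user from the returned
columns. A degenerate null (zero spread — e.g. the community equals the
whole pool, or a star phylogeny) yields `SES = NA`, `q = 1`, and a
`degenerate` flag rather than an error.

Reproducibility of the nulls: each (subplot × metric) stream draws its
seed from the global seed plus a counter keyed to the *rank of the subplot
id*, so results are identical across runs and invariant to row order.

## Dating: two pseudo-chronogram methods

**Even-spacing adjustment (`bladj()`).** Given a topology and a set of
node ages (internal labels or MRCA-of-two-tips addressing; the root must
be aged), every calibrated node keeps its age exactly and every
uncalibrated node is interpolated. The implementation is a preorder sweep:
a node is placed between its parent's (already assigned) age and the
oldest constraint below it — the maximum-age calibrated descendant, or the
tip level at age zero reached through the longest uncalibrated chain. On
an unbranched chain of *k* uncalibrated nodes between anchors at ages
$a_{top} > a_{bot}$ this telescopes to exact even spacing,
$a_i = a_{top} - i\,(a_{top}-a_{bot})/(k+1)$. The sequential
formulation (rather than spacing every node on one globally chosen chain)
is deliberate: on asymmetric branchings a global chain can place a child
older than its parent, while the preorder sweep is monotone by
construction. The output is ultrametric to machine precision and the
operation is idempotent — re-dating its own output with the same
calibrations changes nothing.

**Mean-path-length dating (`mpl_date()`).** For a tree with substitution
branch lengths: (1) the raw depth of every internal node is the mean path
length to its descendant tips; (2) depths are rescaled so the single
`fixed`-age node matches its calibration; (3) `min`-age constraints raise
violating nodes; (4) one root-ward sweep restores parent ≥ child
monotonicity. This is a transparent simplification of rate-smoothing
dating: no correction for among-lineage rate heterogeneity is attempted,
so it is exact on clock-like trees (the test suite verifies node-age
recovery to a relative error below 1e-6 on simulated clock trees, and
invariance to a global rescaling of branch lengths) and approximate
otherwise. Minimum ages above the fixed root age, or a sweep that would
displace the fixed node, are conflicts and raise errors.

No calibration age is built into the package; ages always arrive via
`calibration_set()` or a whitespace-delimited calibration file
(`fixed|min tipA,tipB|label age`).

## Topography and habitats

From a corner-elevation lattice (10 m spacing by default):

* **Elevation** of a quadrat is the mean of its four corners.
* **Slope** is the mean angular slope of the four planes through each
  subset of three corners (the plane normal's angle to the vertical) — the
  convention of forest-plot survey toolkits.
* **Convexity** of an interior quadrat is its mean corner elevation minus
  the mean of the 12 boundary lattice points of the surrounding 3 × 3
  quadrat block (a 4 × 4 lattice minus its 4 interior points — the only
  reading of "12 points along a grid of eight subplots" that is
  geometrically consistent). On any affine surface this is exactly zero.
  For edge quadrats the rule degrades to centre-point minus corner mean;
  without a measured centre the centre is bilinearly interpolated, which
  makes edge convexity identically zero — a documented limitation, not a
  bug, removable by supplying measured centres.

Habitats follow the five-way slope/elevation/convexity rule table
(valley, low slope, high slope, high gully, ridge top). The published rule
set overlaps at `S = S_mean` with `E ≥ E_mean` and is silent at `C = 0`;
the classifier resolves both deliberately — threshold slope with high
elevation goes to the high-slope/high-gully branch, and zero convexity to
high slope — making the classification total and mutually exclusive
(property-checked over a dense (S, E, C) sweep). Thresholds default to the
means of the supplied table but should be passed explicitly when
reproducing a published classification, since a published mean may be
computed over a different quadrat set.

## Barcode preparation

Haplotype collapsing groups aligned sequences by exact identity; `strict`
mode (default) treats gap/ambiguity symbols as ordinary mismatching
characters because it is deterministic and order-independent, while
`wildcard` mode lets `-`, `N`, `?` match anything (first-compatible-group
assignment, order-dependent — use knowingly). Alignment statistics count a
column as variable when it shows at least two distinct non-missing states,
and report the percentage of missing cells over the whole matrix (the
"any missing cell" reading; a column-wise alternative is easy to derive
from the returned pieces). The pseudogene screen translates in a fixed
frame and flags internal TAA/TAG/TGA — the stop set shared by the standard
and bacterial/plastid codon tables, so no table choice can change the
outcome for these motifs.

Community-matrix assembly from tagged stems applies the standard
assignment rule: sequenced stems count under their haplotype; unsequenced
stems with a morphological identification inherit the haplotype of
sequenced conspecifics. When a morphotaxon maps to several haplotypes the
default assigns to the most frequent one among sequenced stems (logged per
morphotaxon); the conservative alternative excludes such stems. Stems with
neither identification are excluded and counted, and assigned + excluded
always equals the input stem count.

## The synthetic-data generator

Because the field data of a real plot cannot ship with a package, every
stage is exercised on generated data with known ground truth:

* **Pool phylogeny** — a pure-birth (Yule) tree in time units
  (`simulate_pool_tree()`), the standard minimal model of a regional pool.
* **Traits** — Brownian motion along branches; tip covariance equals
  σ² × shared path length (verified by Monte-Carlo in the suite). This is
  the trait-conservatism premise that links habitat filtering to
  phylogenetic clustering.
* **Communities** — `neutral` draws species uniformly; `filter` weights
  species by exp(−(trait − optimum)²/2w²); `repulsion` builds the
  community by sequential max-min spacing on Euclidean niche distance.
  One design decision deserves emphasis: with a *single* trait axis,
  max-min spacing is an unreliable generator of phylogenetic
  overdispersion — even spacing on one axis can repeatedly select inside
  trait-dense clades, and across seeds the mean NTI sign flips. The
  repulsion regime therefore uses a three-axis Brownian niche by default
  (`simulate_traits(k = 3)`), under which niche distance tracks
  phylogenetic distance well enough that mean NTI is consistently and
  strongly negative. This mirrors the general finding that limiting
  similarity is much easier to detect in a multidimensional niche.
* **Abundances** — Fisher log-series (default x = 0.9), the classic
  shape for tropical stem counts; geometric available.
* **Topography** — a random linear trend plus low-frequency cosine waves,
  rescaled to a target elevation band (default 160–320 m, a steep
  hill-and-valley plot). `smoothness = Inf` collapses to an exact affine
  surface, the degenerate case used to verify the convexity identity.
* **Study bundle** — `simulate_study()` ties the pieces together: under
  the `filter` regime the per-subplot trait optimum follows elevation and
  the filter width narrows with convexity (ridges filter harder), so a
  positive convexity–NRI association is part of the ground truth the
  pipeline should recover.

What passing these experiments shows: the metrics, null model, dating and
classification are internally correct and statistically calibrated (the
neutral regime is called clustered at ≈ α/2, and the directional regimes
are recovered with the right signs). What it does not show: anything about
sequencing error, spatial autocorrelation of real communities, dispersal
limitation, or phylogenetic uncertainty — none of which the generator
emulates.

## Problem sizes and numerical choices

The test suite validates the metrics against brute-force oracles on trees
of up to 12 tips and the null model against exhaustive subset enumeration
on 8–9-tip pools; calibration experiments use a 64-tip pool with 500
neutral subplots (399 randomisations each) and 80-tip pools with 60
subplots per directional regime — sizes chosen so the whole suite runs in
well under a minute while leaving the binomial and t-tests adequately
powered. The acceptance script runs a 140-species pool, 70 subplots of
richness 10–25 on a 20 × 20 quadrat grid, 999 randomisations per subplot
and metric — a deliberate one-seventh-scale model of a 555-haplotype,
2500-quadrat study that keeps a full run near twenty seconds.

Other numerical choices: ultrametricity is judged on the relative spread
of root-to-tip depths (default tolerance 1e-8; 1e-4 when reading trees
back from 6-significant-digit newick); branch lengths are emitted with six
significant digits; ages are stored as node ages and converted to edge
lengths once, so no cumulative subtraction error enters; the tip-shuffle
draw uses `sample.int()` on the pool indices, never label strings.

## Known limitations

* `mpl_date()` deliberately ignores rate heterogeneity; trees with strong
  among-lineage rate variation will date poorly, and the package makes no
  attempt to warn about this beyond the documented property.
* Edge-quadrat convexity is zero unless measured centre elevations are
  supplied.
* The tip-shuffle null is the only null model; richness- or
  abundance-preserving swap nulls are out of scope.
* The constraint-tree builder resolves nothing below the order level by
  design (species hang as one polytomy per order).
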