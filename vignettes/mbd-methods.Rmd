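---
title: "Modified Band Depth methods: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modified Band Depth methods: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbdepth)
```

## The depth model

A data depth assigns to each observation of a sample a measure of how
central it lies, generalising univariate ranks and medians to many
dimensions. For an n × d expression matrix (samples in rows), the
Modified Band Depth of a row **y** is the average over all C(n,2) pairs
of rows of the proportion of coordinates of **y** falling inside the
coordinate-wise [min, max] *band* of the pair. It requires no
distributional assumptions beyond finiteness of the entries, is defined
for d far larger than n, and depends on the data only through the
within-column orderings — so any strictly increasing per-column
transformation (log, standardisation per gene, unit changes) leaves all
depths, orderings and downstream decisions unchanged.

Two consequences of the definition are worth keeping in mind. In-sample
depths are bounded below by 2/n, because every coordinate of a row is an
endpoint of its n−1 own bands; out-of-sample depths (of new rows relative
to a reference matrix) live in [0, 1], and a point beyond the reference's
coordinate-wise range in every column has depth exactly 0. For continuous
data the deepest attainable in-sample value approaches 1/2 + 1/n rather
than 1; values near 1 occur only with heavy ties.

### The fast route and ties

`mbd()` never enumerates pairs by default. Each column is ranked once;
with l the minimal rank of a value in its column and η its multiplicity,
the value lies inside (n−l+1)(l−1+η) − η² + C(η,2) of the C(n,2) bands.
Summing across columns and normalising reproduces the pairwise definition
exactly — the package keeps the O(d·n³) pairwise implementation
(`method = "pairwise"`) purely as an independent oracle, and the test
suite asserts agreement below 1e−12 across hundreds of random matrices
with and without ties. The analogous counting formula for new
observations uses l₁ = #{reference values < x} and l₂ = #{≤ x} per
column; a row of the reference evaluated against it recovers its
in-sample depth exactly, which the suite also asserts.

Ties are resolved by exact floating-point equality — no epsilon. Equal
values share a multiplicity and each counts as inside the bands it
bounds. Users standardising data should be aware that values equal after
rounding but not bitwise are *not* tied. Non-finite entries are rejected
rather than imputed: a depth for a missing coordinate has no definition
here, and silent imputation would change orderings invisibly.

### Ordering

`depth_ordering()` sorts deepest-first and breaks equal depths by
ascending original row index. Any deterministic rule would do; this one
makes orderings stable under replication and is asserted in the tests.

## Depth-derived statistics

**Trimmed mean.** `tmean(x, alpha)` keeps the `ceiling((1−alpha)·n)`
deepest rows and averages them per column, so `alpha = 0` reproduces the
ordinary column mean exactly and at least one row is always retained.
The ceiling convention (rather than flooring the discard count) was fixed
once so that a 25% proportion of 25 samples yields 7 central curves and a
0.25 trimming retains 19 — the counts every other function in the package
also uses.

**Central bands and the scale curve.** `central_band(x, p)` spans the
per-column min/max of the `ceiling(p·n)` deepest rows; bands are nested
in p because the central sets are. `scale_curve()` integrates the band
width over the variable index by the trapezoidal rule with unit spacing.
"Area" has no canonical definition over an unordered gene axis; trapezoid
versus rectangle sums only rescales the curve and changes none of its
properties (monotone in p, invariant to adding a constant profile,
proportional under global scaling), so the choice is cosmetic. Two
degenerate cases follow from the definition and are deliberate: a
one-sample central set has zero area, and d = 1 gives a zero-width
integration domain, hence an identically-zero curve. The default p grid
is k/n for k = 1..n — exactly the proportions at which the central-set
size changes.

**Rank test.** `rank_test(x, y, n, m, seed)` draws, without replacement,
n rows of the first group and m of the second, computes the depth of all
n+m with respect to the non-drawn remainder of the *first* group, ranks
the depths jointly (average ranks on ties), and takes W = the rank sum of
the second group. Three genuinely open choices were settled as follows
and are part of the package's definition of the test:

* *Reference set*: the non-sampled remainder of the first population.
  This is what forces `n < nrow(x)` (in fact `nrow(x) − n ≥ 2`, since a
  band needs two reference rows) and makes the test asymmetric in its
  arguments; both orientations control size under the null, which the
  suite checks, but W itself differs.
* *Sidedness*: one-sided against "the second sample is less deep". When
  two populations differ — in location, scale or shape — the second
  group's rows sit systematically outside the first group's bands, so
  their depths shrink; a two-sided alternative would spend power on an
  implausible direction.
* *p-value*: normal approximation with continuity correction and the
  standard tie correction of the rank-sum variance. For n+m ≤ 12 the
  exact permutation tail over all C(n+m, m) assignments of the observed
  ranks is used instead (`p_method = "auto"`); the exact route handles
  ties natively and coincides with the closed-form Wilcoxon tail when
  ranks are untied, which is asserted against `stats::pwilcox`, as the
  normal route is against `stats::wilcox.test`.

Reproducibility is part of the contract: the generator is pinned
(Mersenne-Twister, inversion normals, rejection sampling) and seeded per
call, and the caller's RNG state is restored afterwards.

Note what this test is sensitive to: it compares *depth* distributions.
A mean shift confined to a few genes out of hundreds barely moves MBD
(which averages over all columns) and is better attacked with the
classifiers after gene ranking; dispersion or gross distributional
differences are where the rank test shines.

**Classifiers.** `class_ds()` assigns a test row to the class whose
depth-trimmed mean is nearest; `class_tad()` scores each class by a
weighted average Euclidean distance to its `ceiling((1−alpha)·n_g)`
deepest members and picks the smallest. The TAD weights — within-class
depth of each retained member, normalised to sum one — are the central
interpretive decision of the module: "weighted average distance" admits
several readings, and depth-proportional weights make the deepest
(most representative) members dominate while trimmed-out external members
contribute nothing. Euclidean distance is the default metric for both
rules. Ties in the arg-min go to the class appearing first in the
learning labels, so predictions are deterministic; with `alpha = 0`, DS
is exactly nearest-centroid on ordinary class means, and when trimming
leaves one member per class TAD collapses to DS's single-prototype rule —
both identities are asserted in the tests. The classifiers output hard
labels only; no posterior probabilities are defined.

## Preprocessing and gene ranking

`preprocess_expression()` applies, in this order: clipping to
[10, 16000] units; removal of genes varying less than 5-fold relatively
*or* less than 500 units absolutely (an OR-exclusion, both computed after
clipping — clipping first means a gene whose variation lives entirely in
the saturated tails is correctly discarded); log₁₀; and standardisation
of each sample to zero mean and unit (sample) variance across the
surviving genes. The first three steps are idempotent for data already
within the clipping range; standardisation intentionally is not, since it
rescales every sample. Defaults are the customary Affymetrix-era
thresholds and are all overridable.

`bw_rank_genes()` ranks genes by the ratio of between-class to
within-class sums of squares (class means about the grand mean, weighted
by class size). Degenerate genes are ordered by convention: zero within-
class variance with separated means gives an infinite ratio and ranks
first; a gene constant across all samples (0/0) is assigned 0 and ranks
last.

## What the synthetic generator does and does not emulate

`simulate_two_class()` produces standardised two-class Gaussian matrices
shaped like a small post-preprocessing microarray study: by default 25
samples per class on 100 genes — of which the first `n_informative = 10`
would carry a mean shift of `shift` units were one requested — with
optional exchangeable within-sample correlation `rho` and a fraction of
rows displaced by `outlier_magnitude` in every coordinate to mimic gross
contamination (failed hybridisations, mislabeled arrays). The default
`shift = 0` makes the two classes identically distributed — the null
fixture of the rank test. Everything is determined by `seed`.

The generator emulates dimensionality, class structure, contamination
and (optionally) a crude correlation structure. It does *not* emulate
heavy-tailed intensity noise, gene-specific variances, realistic
correlation blocks, batch effects, or the mean–variance coupling of real
arrays. Passing tests therefore demonstrate the *contracts* of the
methods — oracle equality, invariances, size control, robustness to the
modelled contamination — not performance guarantees on any particular
real dataset.

Problem sizes used throughout the suite were chosen to exercise the
methods at realistic scale while keeping a full run in tens of seconds on
one CPU: 200 random matrices (n ≤ 30, d ≤ 100) for the oracle
comparison, 500 null replicates at n₁ = n₂ = 25, d = 50, n = m = 12 for
the empirical size of the rank test, 200 replicates per factor for its
power against scale inflations {1, 2, 3, 5}, 100 train/test splits for
the classifier benchmark (mean shift 3 on 10 of 50 genes, 20 learning +
5 test rows per class), and a single 500 × 2000 matrix for the fast
route's wall time.

## Known limitations

* MBD weighs all variables equally; signal confined to few genes is
  diluted, so gene selection (e.g. `bw_rank_genes`) belongs *before*
  depth-based inference, not inside it.
* The rank test's subsampling makes its p-value a function of the seed;
  report the seed alongside the result, or aggregate over seeds.
* Band "area" orders variables by column index; permuting genes changes
  scale-curve values (though not their monotonicity or comparisons
  between groups measured on the same gene order).
* No missing-value support by design; impute or filter upstream.
* The preprocessing recipe targets classic expression summaries; counts
  from sequencing would need their own variance-stabilising pipeline
  first.
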