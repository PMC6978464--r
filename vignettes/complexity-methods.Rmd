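---
title: "Methods: complexity measures for parcellated brain signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complexity measures for parcellated brain signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexbold)
```

This vignette is the package's own account of what it computes, which
conventions it fixes where the literature leaves room, and what its tests do
and do not establish.

## Input model and preprocessing

The unit of analysis is a scan: a numeric matrix with one row per
parcellated brain region and one column per timepoint, assumed to be
band-passed, nuisance-regressed BOLD series (that upstream preprocessing is
out of scope). Every measure operates on the Hilbert envelope of each row —
the modulus of the analytic signal, computed by FFT (double the
positive-frequency coefficients, zero the negative ones, inverse-transform).
Two caveats are deliberate:

* **No edge mitigation.** The analytic signal is computed without padding or
  tapering, so the first and last few samples of each envelope carry edge
  distortion. For the ~200-sample series this package targets, the effect is
  small relative to the measures' own variance, and mitigation schemes would
  introduce their own conventions.
* **No re-standardisation.** Envelopes are consumed as-is; only operations
  that define their own normalisation (binarisation about the row mean,
  feature scaling before PCA, correlation) rescale them.

A constant row degenerates to a constant envelope; this is allowed but
warned about, and propagates to a flagged, degenerate Lempel–Ziv result
rather than an error.

## Temporal measures

### Normalised Lempel–Ziv compressibility

Each envelope row is binarised at its **own** mean (ties map to 1, so a
constant row is all ones). The binary matrix is flattened column-wise, so
each consecutive `X`-length block is one timepoint's spatial activation
pattern; Lempel–Ziv phrases are therefore patterns *across regions* as they
recur through time, which is what makes this the one temporal measure that
also sees spatial structure. The LZ76 exhaustive-history parsing extends
each phrase while it occurs as a substring of everything before its last
symbol and closes it at the first novelty; the trailing partial phrase
counts as one. The implementation computes phrase lengths from a
longest-previous-factor array (suffix array, Kasai LCP, Crochemore–Ilie
pass), which is effectively linear in the input length; its exact
equivalence to a naive substring-search parser is asserted in the tests on
every binary string up to length 12 and on 1000 random strings.

The raw count is normalised by the count of a surrogate in which every
binary row is independently permuted (seeded, default one surrogate;
averaging over several is available). Shuffling the *binarised* rows is
equivalent in distribution to binarising shuffled raw rows — the row mean is
permutation-invariant — and cheaper. The surrogate conserves each row's
activation rate while destroying all temporal and cross-regional order, so
structureless input scores ≈ 1; the tests verify calibration to
[0.9, 1.1] on fair-coin matrices at study scale. An all-constant binarised
matrix makes both counts equal and minimal; the ratio is then 1 but the
result carries a `degenerate` flag rather than a claim of meaning.

### Sample entropy

`SampEn(m, r) = −log(A/B)` with Chebyshev distance, embedding `m = 2`, and
tolerance `r = 0.3 σ` of the series. Three conventions are fixed:

* **Non-strict matching** (`distance ≤ r`). With strict inequality, a
  constant series (tolerance 0) would have no matches at all; non-strict
  matching yields the canonical SampEn-of-a-constant-is-0 behaviour and is
  the standard convention.
* **Self-matches excluded**, and both template sets run over the same
  `N − m` starting positions (the Richman–Moorman counting), so `A ≤ B`
  always.
* **Degenerate regimes are flagged, not fudged**: `A = 0` gives `+Inf` with
  a warning, `B = 0` gives `NA` with a warning; per-scan averages drop
  non-finite regions with a warning.

Counts are checked against an O(n²m) brute-force counter — exact `A`, `B`,
and value — on 200 random series. Note one property that is *not* asserted:
SampEn is not globally monotone in `r`. The match counts `A` and `B` are
each non-decreasing in `r`, but their ratio can dip locally when widening
`r` admits new `m`-matches whose continuations diverge; the tests assert the
count monotonicity and the broad-range decreasing trend instead.

### PCA compressibility

Timepoints are observations and regions are features (so the component count
is bounded by the region count); each feature is centred and scaled to unit
variance (zero-variance features are centred only, with a warning), and the
reported value is the smallest number of components whose cumulative
explained variance reaches 0.95. The orientation choice matters — the
transpose would bound the count by the timepoint count instead — and is
fixed, not asserted as the only defensible reading.

### Hurst exponent (rescaled range)

For window sizes `n` (powers of two from `min_window = 8` to half the series
length, at least three sizes required), the series is cut into
non-overlapping segments; per segment the cumulative departure from the
segment mean is profiled, and R/S = (max − min of profile) / segment sd.
Segments with zero sd are skipped. `H` is the least-squares slope of
`log(mean R/S)` against `log(n)`. The scaling is written here as
`R(n)/S(n) ∝ n^{+H}` — the convention under which white noise gives 0.5 and
persistent signals approach 1, which is also the direction-of-effect this
pipeline relies on. Estimator recovery on exact fractional Gaussian noise
(H ∈ {0.6, 0.7, 0.8}, n = 1024, 20 seeds) shows mean absolute error well
under 0.07 with the default window range; the classic upward small-sample
bias lives mostly in the shortest windows, and `min_window` is exposed for
users who want to trade variance against it.

### Higuchi fractal dimension

The canonical Higuchi (1988) construction: for lag `k = 1…k_max` and offsets
`m = 1…k`, the normalised curve length
`L_m(k) = [Σ |x_{m+ik} − x_{m+(i−1)k}|] · (N−1) / (⌊(N−m)/k⌋ · k²)` is
averaged over offsets, and `D` is the negative slope of `log⟨L(k)⟩` on
`log(k)`. Offsets with no usable points are skipped; a `k` with no usable
offsets is dropped with a warning. `k_max` defaults to 32 — appropriate for
~190-sample series, where the `N > 2k` feasibility rule already excludes 64
and 128 — and `select_kmax()` implements the stability heuristic: evaluate
candidate powers of two on a sample of series and return the smallest
candidate in the longest run where successive estimates move by less than
0.05.

One point of care: the textbook relation `D = 2 − H` is a statement about
fractional *Brownian motion* — the graph of fBm with Hurst index `H` has box
dimension `2 − H`. Applied directly to stationary fractional Gaussian
*noise*, Higuchi's estimator correctly reads the signal as noise-like
(`D ≈ 2`) for any `H`. The parameter-recovery tests therefore cumulate the
fGn generator's output into fBm tracks before applying the estimator, where
the relation is the right mathematics (recovered to within 0.15 across
H ∈ {0.6, 0.7, 0.8}).

## Topological measures

The functional connectivity matrix is the Pearson correlation of envelope
rows, with the diagonal zeroed (simple graph) and negative entries set to 0
— the most common convention in network neuroscience, with the known caveat
that anticorrelations carry physiological information that is discarded.
Zero-variance rows yield zero connectivity with a warning.

**Proportional thresholding.** "Keep the strongest k% of edges" is read as:
the cutoff `P_k` is the `(100−k)`th percentile (type-7 quantile) of the
upper-triangular weights, and an edge is present wherever its weight
`≥ P_k`. Ties at the cutoff are all included, so realised density can
slightly exceed `k`; the realised density is recorded on the graph object.
An all-equal weight matrix makes any threshold degenerate (all edges or
none) and is flagged.

**Algebraic connectivity** is λ₂ of the combinatorial Laplacian
`L = D − A`, by dense symmetric eigendecomposition — exact and cheap at a
few hundred nodes. Values below 10⁻⁹ are reported as exactly 0 (the
disconnected case). The tests pin λ₂ against closed-form spectra
(complete graph: `n`; path P₃: 1; disconnected: 0), the Fiedler bound
(λ₂ ≤ minimum degree for non-complete connected graphs), zero-iff-
disconnected against a BFS component count, and monotonicity under edge
addition.

**Graph compressibility** flattens the adjacency matrix row-major (the
matrix is symmetric, so the choice is low-stakes, but it is fixed for
bit-exact reproducibility) and applies the same LZ76 count.

Both measures are evaluated at thresholds 10%, …, 90% and integrated with
the trapezoid rule at spacing 10 (threshold-percent units). Any constant
spacing rescales all scans identically and cannot change rank-based
statistics; 10 matches the natural axis. λ₂ curves are non-decreasing in
`k` (edges are only added), which the tests assert on random matrices.

## Higher-order analysis

Per-scan profiles (seven metrics) are pooled across subjects *and*
conditions for both the inter-metric correlation matrix and the
overall-complexity PCA — pooling is what yields enough rows for a stable
seven-variable PCA at realistic cohort sizes. Metric columns are
standardised before the PCA: raw scales differ by five orders of magnitude
(graph LZ integrals ~10⁵ against normalised LZC ~1), so an unstandardised
PCA would be degenerate. The first component's sign is arbitrary; it is
oriented so the LZC loading is negative, purely as a reporting convention.
The explained-variance share is invariant to flipping the sign or rescaling
any column, which the tests assert exactly (10⁻¹²).

Condition comparisons are non-parametric throughout: Kruskal–Wallis omnibus
across all conditions, paired Wilcoxon signed-rank for each condition pair
(exact p for n ≤ 25 where ties permit; tie-degenerate all-equal pairs return
p = 1 and statistic 0 rather than an error). P-values are reported
uncorrected by default — matching common practice for small post-hoc
families — with a Holm option. Dose–response uses Pearson correlation over
sedated scans only (zero-dose awake scans carry no concentration
information and are excluded); Spearman is available behind a flag.

## The synthetic cohort generator

The generator exists so that every estimator and the end-to-end pipeline are
testable with known ground truth. Each subject × condition scan is built
from community-coupled AR(1) processes: region `i` in community `c` gets
`x_i = √(1−w)·e_i + √w·f_c`, with both the innovations' AR coefficient and
the coupling weight `w` increasing with the condition's `complexity_grade`
in [0, 1]:

* AR coefficient: `0.30 + 0.55 · grade` — more memory, so LZC, sample
  entropy and Higuchi dimension fall and the Hurst exponent rises with
  grade;
* coupling: `0.10 + 0.50 · grade` — stronger shared community factors, so
  fewer PCA components, and a more modular thresholded graph, so lower
  algebraic connectivity and a more compressible adjacency.

Scans are shifted strictly positive (envelope-like), the design is paired
(every subject appears in every condition), and everything is determined by
the cohort specification's single seed. Defaults mirror a realistic two-condition sedation
study: 16 subjects, awake/deep, grades 0/0.8, 234 regions × 190 timepoints
(a plausible scan length for a TR of 2 s), innovation sd 1, and a
synthetic serum-concentration covariate of 0 for awake and mean
`750 · grade` (sd 150) ng/ml-like units for sedated conditions — chosen
once as round numbers in the range reported for moderate propofol sedation.
The grade endpoints are free parameters of the generator, not calibrated to
any particular empirical effect size.

The generator deliberately does **not** model haemodynamics (no
balloon/BOLD forward model), scanner noise, motion or physiological
artefacts, spatial smoothness, or inter-subject anatomical variability.
Passing the directional tests on this cohort therefore shows that the
pipeline's estimators respond correctly to controlled changes in temporal
memory and coupling — not that real sedation data would show effects of any
particular size.

The exact fractional Gaussian noise generator (Davies–Harte circulant
embedding of the fGn autocovariance) is the oracle for the Hurst and
Higuchi recovery tests; it fails loudly if the embedding ever loses positive
semi-definiteness rather than truncating silently.

## Problem sizes used by the test-suite

The oracle-equivalence suites run exhaustively to length 12 and on 1000
random strings (LZ76) and 200 random series (SampEn). Estimator recovery
uses n = 1024 and 20 seeds per Hurst index. The end-to-end directional
suite runs 20 cohort seeds at the full default scale (16 paired subjects ×
2 conditions, 234 regions × 190 timepoints) and asserts the seven-metric
sign pattern, paired-test detection rates, and the PC1 variance share;
smaller cohorts (dozens of regions) are used in the per-module tests where
scale adds nothing to the property under test.

## Known limitations

* Hilbert-envelope edge effects are unmitigated (documented above).
* The R/S estimator retains some small-sample bias; it is quantified by the
  recovery tests, not corrected analytically (no Anis–Lloyd-type
  adjustment).
* The proportional-threshold reading of `P_k` (percentile of upper-
  triangular weights, non-strict, ties included) is one defensible
  convention among several; it is fixed and recorded on the output rather
  than asserted as canonical.
* Negative functional-connectivity edges are discarded, which may affect
  conditions asymmetrically in real data.
* The higher-order PCA pools conditions; with very few subjects per
  condition the component can be dominated by between-condition separation
  itself.
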