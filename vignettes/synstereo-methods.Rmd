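---
title: "Methods: serial-section synaptic morphometry and stereology in synstereo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial-section synaptic morphometry and stereology in synstereo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synstereo)
```

## The measurement problem

Serial-section transmission electron microscopy yields, per ultrathin
section of nominal thickness *t* ≈ 50 nm, closed contour annotations for
volume-bearing structures (synaptic boutons, mitochondria, astrocytic
profiles, postsynaptic targets), open polylines for the membrane
specializations of the active zone (PreAZ and PSD), and point records for
synaptic vesicles. `synstereo` turns these annotations into the synapse-level
parameters used to characterise cortical boutons: geometry, active-zone
size, vesicle pool structure, synapse density, and astrocytic coverage. No
image processing is involved — the package starts from annotations, which is
also where its synthetic ground-truth generator plugs in.

All coordinates are nanometres internally. A contour with section index
*i* sits at the section mid-plane *z = i·t*; a section therefore owns the
slab *(i·t − t/2, i·t + t/2]*. No shrinkage correction is applied anywhere:
estimates refer to the fixed, sectioned tissue as annotated.

## Geometry estimators

**Volume** is the section sum `V = Σ areaᵢ · t` (a Cavalieri-type
estimator with the contour's shoelace area as the profile area). Missing
interior sections are filled by linear interpolation of area, with a
warning — at 50 nm a single lost section is small against a ~1 µm bouton.
On sliced spheres this midpoint rule is accurate to well under 2 % for
radii ≥ 5·t, which the test suite asserts against the closed form.

**Surface area** triangulates a ribbon between each pair of consecutive
contours: both rings are resampled to a common vertex count (64 by
default) at equal arc-length steps, oriented counter-clockwise, and matched
at the cyclic offset minimising total squared inter-ring distance
("minimal twist"). Because contours sit on mid-planes, the object extends
half a section past its outermost contours; the estimator closes it with a
half-slab prism band plus the two planar end caps. A single-section object
uses the closed-slab convention `2·area + perimeter·t`. The conventions are
exact on stacked cuboids and within 5 % of `4πr²` on sliced spheres with
r ≥ 5·t; no meshing rule is canonical in the annotation tools this package
mirrors, so this one is fixed here and validated by those oracles.

**PreAZ area** uses the same ribbon idea on open polylines: consecutive
per-section polylines are resampled, oriented consistently, and
triangulated. For straight stacked lines this reduces exactly to the
trapezoid `mean(Lᵢ, Lᵢ₊₁)·t`; on curved membranes it additionally captures
local slant. One resolution caveat is inherent: the membrane between the
outermost annotated polyline and the true zone edge (up to half a section
on either side) is not annotated, so zones whose extent is only a few
sections are underestimated by several percent. The cap-area oracle in the
tests therefore uses patches spanning many sections; for cohort active
zones (~0.2 µm², 4–10 sections) the bias is of order −5 to −10 % and is a
property of the section spacing, not of the estimator.

**PSD area** uses the perimeter-ratio estimate
`SA_PSD = SA_PreAZ · L_PSD / L_PreAZ`, justified by the two membrane
specializations running parallel across the cleft. Whether the lengths are
per-section or summed does not matter as long as both are treated
identically; the package uses the mean per-section polyline length for
both, which makes the ratio the mean length ratio. **Cleft width** records
the two lateral measurements and the central one, averaging the lateral
pair per cleft; cohort aggregation is left to the statistics layer.

## Vesicle pools

The perimeter *p* of a vesicle is the minimum Euclidean distance from its
centre to the PreAZ surface minus its radius, so *p* < 0 means membrane
overlap (docking/fusion) and *p* can never fall below −diameter. Distances
are computed in full 3D — against the triangulated PreAZ ribbon in
reconstruction mode and against analytic patches (plane/disc or spherical
cap) in synthetic mode; both routes are held to the same brute-force
surface-sampling oracle (≤ 0.5 nm) in the tests.

Pool boundaries, in nm of perimeter: readily releasable pool at the
cumulative criteria `p ≤ 10` and `p ≤ 20` (p20 includes p10 — both
thresholds describe the same pool at different stringency); recycling pool
`[60, 200]`; resting pool `> 200`, with the `≥ 500` tail also reported;
docked `p ≤ 0`. Two conventions are deliberate:

* Vesicles in `(20, 60)` are reported as an explicit *unassigned* band
  rather than silently dropped; no functional pool claims that interval.
* Every boundary value belongs to the pool named after it (10 → p10,
  60 and 200 → recycling, 500 → the ≥ 500 tail), a documented tie-break for
  exact-boundary values.

The geometric contact criterion `p ≤ 0` is the reproducible surrogate for
tomographically identified docked vesicles; visual omega-shape
identification has no counterpart in coordinate data. The p10 pool and the
docked count are reported side by side and not reconciled — they measure
different things and are known to disagree.

## Stereology

The **physical disector** counts objects present in a reference section but
absent (by persistent id) from the adjacent look-up section, inside an
unbiased counting frame; identity by id replaces the visual continuity
judgement of a human counter. The frame includes its left and bottom edges
and excludes the right and top edges together with their full-line
extensions. Density is `Nv = ΣQd / (n · A · t)`, reported per mm³. The
suite verifies frame unbiasedness by Monte-Carlo inclusion probability and
disector unbiasedness on Poisson-generated blocks at the cortical density
scale (~5·10⁸ mm⁻³); the unbiasedness oracle uses 400 disector pairs so
that sampling noise (≈ 3 % SE) sits well inside the 10 % check. A 20-pair
sample at this density carries ≈ 15 % relative SE and is not individually
informative.

The **Cavalieri estimator** converts point-grid hits to a volume fraction
(`100 · ΣP_hit / ΣP`) and an absolute volume `V = a(p) · ΣP · t`. The
default `a(p)` is 0.64 µm² (0.8 × 0.8 µm squares). Counting protocols are
sometimes described with a 1 × 1 µm overlay while the estimator's `a(p)` is
given as 0.8 × 0.8 µm²; the value entering the formula wins here, and
`a_p` is a plain configuration parameter. **Astrocytic coverage** of an
active zone is classified from two flank annotations (process reaching the
cleft on both sides / one side / neither); summaries report percentages per
target type, averaged across patients when patient ids are present.

## Descriptive and comparative statistics

`describe()` reports n, mean, sample SD (n − 1), median and IQR with
type-7 (linear interpolation) quantiles, CV = SD/mean, variance, and the
adjusted Fisher–Pearson skewness `g₁·√(n(n−1))/(n−2)`; constant data give
skewness NaN rather than an error. Report tables round half-up to two
decimals — the display precision of the published tables this layout
mirrors — and flag skewness > 3 as non-normal. Which skewness estimator
legacy statistics packages used is rarely documented; the adjusted
Fisher–Pearson form is fixed here and validated against a naive
implementation rather than against published skewness values.

Pooled layer rows are the *unweighted* mean of the two sublaminar means.
That rule is not usually stated in publications; it was verified against
three published rows (total pool, recycling pool, resting pool reproduce
the printed pooled values exactly) and then fixed. Fold differences report
one decimal, truncated toward zero (5.90/1.29 → 4.5).

Group comparisons run Kruskal–Wallis followed by a two-sided Mann–Whitney
U (both via the base R implementations), exact by full enumeration when
both groups have n ≤ 20 without ties, otherwise tie-corrected normal
approximation. R² bands: 0 none, (0, 0.5) weak, [0.5, 0.8) good,
[0.8, 1] strong. Fisher's r-to-z compares two correlations via
`z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3))`.

## The synthetic-data generator

The generator exists so that every estimator above can be exercised against
exact ground truth; its defaults are the published layer-1 study
conditions, shipped as YAML profiles (`l1`, `l1a`, `l1b`) holding only
published means ± SDs plus two derived quantities (the p20 increment over
p10, and the unassigned-band mean as the remainder of the total pool).

Three deliberate design choices:

* **Spheres, not generic convex bodies.** A bouton is a sphere of radius
  set by its drawn volume. Spheres give closed-form truth for volume,
  surface, cap area and vesicle-to-cap distance, which is what the recovery
  tests need. The cost is shape realism: a sphere of the calibrated mean
  volume (0.50 µm³) has 3.0 µm² of surface, whereas real boutons of that
  volume average ~5.5 µm² — real boutons are strongly non-spherical. The
  generator therefore calibrates volume, and surface truth is the sphere's
  own analytic area; cohort surface means are *not* expected to match
  published cohort tables and no test pretends they do.
* **Moment-matched truncated normals.** Published tables give mean ± SD
  only, so positive quantities are drawn from truncated normals. Naive
  truncation shifts the mean — at the p10 pool's calibration
  (5.90 ± 5.05, bounded below by 0) a plain truncated normal would average
  ≈ 7.06. The generator instead solves for the location parameter such that
  the *post-truncation* (and, for counts, post-rounding) mean equals the
  published mean. Per-object draws use stratified inverse-CDF sampling
  (jittered, permuted strata), which leaves the marginal distribution
  unchanged while tightening cohort means — appropriate because the
  published values being reproduced are themselves cohort means.
* **Distance-first vesicle placement.** Pool membership is ground truth by
  construction: per-pool counts are drawn first, a perimeter is sampled
  inside each pool's interval, and the vesicle centre is then placed
  radially under the cap at exactly that membrane distance (resting-pool
  vesicles are instead rejection-sampled uniformly in the interior against
  the exact analytic distance). The manifest records every vesicle's pool
  and true perimeter.

Mitochondria are 1–3 interior spheres realising a drawn volume fraction;
the PreAZ is a spherical cap of drawn area with horizontal axis (so section
planes cut it into open arcs, as in real annotations), and the PSD
polylines are the same arcs scaled to the drawn perimeter ratio at the
drawn cleft offset. Dense-core vesicles (~58 nm) are sprinkled sparsely to
exercise the type system; they carry no pool membership. Spine vs shaft
targets are Bernoulli (0.80 spine), coverage classes multinomial with the
published proportions. Neuropil blocks for disector counting place synapse
"tops" as a homogeneous Poisson process, which makes the per-pair count
exactly Poisson with mean `density · A · t`. Tomography-mode active zones
draw docked counts from the discretised matched truncated normal and place
docked vesicles at p ≤ 0 on a planar patch.

What the generator does **not** emulate: non-spherical bouton shape (see
above), annotation noise and tracing error, perforated or horseshoe
active-zone topologies (shape class is an input annotation, not derived
from geometry), spatial clustering of vesicles beyond pool structure, and
any correlation between bouton size and pool size (sizes and pools are
drawn independently; published correlation results are mixed). Passing
recovery tests therefore demonstrates correctness of the estimators on
clean geometry, not robustness to annotation artefacts.

## Determinism and problem sizes

Every generator is a pure function of an integer seed (no time-based
entropy), and the pipeline writes byte-identical outputs under identical
configuration — the run manifest (package version, seed, configuration)
fully determines the artifacts. The test suite exercises: cohorts of
190 boutons for fraction recovery and 10 × 190 boutons for pool-mean
recovery; 100 tomography active zones; 400 disector pairs; 50 Cavalieri
grid offsets on 200 × 200-pixel masks; 1000-vesicle distance-oracle
comparisons against ~10⁵-point sampled surfaces augmented with
deterministic edge subdivisions. These sizes keep each statistical check's
sampling error comfortably inside its asserted tolerance.

## Known limitations

* The PreAZ ribbon underestimates few-section membrane patches (rim
  truncation, above); treat absolute active-zone areas from very thin
  zones with caution.
* The disector trusts persistent object identity; with real annotations the
  id-matching step inherits any tracking errors made upstream.
* Exact Mann–Whitney p-values are only available without ties; tied data
  fall back to the corrected normal approximation at all sample sizes.
* Published summary tables are reproduced at their printed precision;
  where a printed CV or variance is inconsistent with its own printed
  mean ± SD (pre-rounding artefacts), the package's recomputation is the
  self-consistent one and no attempt is made to match the inconsistent
  digit.
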