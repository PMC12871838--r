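---
title: "Methods: membrane cross-section morphometrics and amyloid simulation metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane cross-section morphometrics and amyloid simulation metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LysoMorph)
```

LysoMorph quantifies lysosomal membrane shape from segmented tomographic
volumes and complements that with the trajectory statistics used to
characterize amyloid-membrane systems in molecular dynamics, plus the
small formulas behind puncta counting, colocalization and liposome
leakage assays. This vignette explains the models, the parameters that
matter, the numerical choices, and what the synthetic data do and do not
establish.

## The morphometrics model

The input is an integer-labeled voxel volume in (z, y, x) order, one
positive label per segmented membrane. Because membranes in a
cross-section are thin closed or clipped-open curves rather than filled
regions, each z-slice is reduced to its *centerline*:

1. **Thinning.** Zhang-Suen iterative thinning produces an 8-connected,
   single-pixel-wide skeleton. The algorithm preserves the topology of
   each component; a thin closed ring stays a closed ring.
2. **Ordering.** Skeleton pixels become an ordered sequence by
   nearest-neighbour traversal. End-points (pixels with one neighbour)
   anchor the traversal, starting from the one nearest the image border
   — clipped arcs enter the field of view at the border. Junction pixels
   from imperfect thinning are resolved by taking the longest geodesic
   path between end-points (short spurs drop out). A skeleton with no
   end-point is a closed loop: it is cut at the border-nearest pixel and
   flagged, since every boundary is treated downstream as an open arc. A
   greedy nearest-neighbour walk is used for loops because redundant
   staircase pixels create local 3-cycles that shortest-path ordering
   would shortcut.
3. **Spline parametrization.** A least-squares cubic B-spline over a
   chord-length parameter in [0, 1], sampled at 200 uniform parameter
   values with analytic first and second derivatives. Contours with
   fewer than 4 distinct points are rejected (reason code
   `too_short`); fits with arc length below 50 px are excluded from
   downstream analysis ("below" read strictly, so exactly 50 px is
   retained; `passesLengthFilter(strict = FALSE)` flips the boundary).
4. **Per-slice measurements.** Perimeter (spline arc length), signed
   curvature κ = (x′y″ − y′x″)/(x′² + y′²)^{3/2} from the analytic
   derivatives (NA where the speed vanishes, never infinite), bounding
   box and aspect ratio, centroid of the samples. Because traversal
   orientation is arbitrary for open arcs, curvature summaries use |κ|.

### Automatic spline smoothing

The smoothing target follows the FITPACK convention s = (m − √(2m))·σ²,
with m the number of contour points, interpreted as a residual
sum-of-squares budget. The per-point noise σ² is estimated locally from
fourth-order differences of the ordered points, which annihilate any
cubic trend: a smooth arc contributes O(h⁴) while iid noise contributes
a known multiple (70σ² per coordinate). Raw nearest-neighbour spacing
would conflate the arc step itself with noise and force ~1 px
smoothing residuals even on noise-free data, destroying curvature
accuracy; the roughness-based estimate instead drives the target to ~0
for clean contours. Interior knots are placed uniformly in parameter and
doubled until the residual drops below the target; for essentially
noise-free contours (target below numerical resolution) the knot count
is set directly to m/2 — two points per coefficient keeps the
least-squares problem well conditioned and makes the fit symmetric under
traversal reversal. The value of s actually used is stored in the
`smoothingValue` slot of every `SplineCurve`.

### Two-stage ellipse fitting

Per retained slice, an ellipse is fitted to the 200 spline samples:

* **Initialization** by the direct least-squares conic fit with the
  ellipse constraint 4AC − B² = 1 (Fitzgibbon/Pilu/Fisher), computed via
  the numerically stable reduced 3×3 eigenproblem of Halir and Flusser
  after centring the points. By construction the solution cannot be a
  hyperbola or parabola; collinear input raises a typed failure.
* **Refinement** by orthogonal distance regression: Levenberg-Marquardt
  over (cx, cy, a, b, θ) minimizing the sum of squared *exact*
  perpendicular distances. The point-to-ellipse distance solves the
  first-quadrant nearest-point problem by bisection of the standard
  rational auxiliary function to double precision (a C++ kernel; the
  bootstrap would otherwise dominate the run time). Residuals are signed
  (negative inside), which keeps them smooth across the boundary. The
  optimizer accepts only objective-decreasing steps, so the refined
  objective provably never exceeds the initialization; convergence is a
  relative objective change below 1e-10 or 200 iterations, and
  non-convergence is flagged while keeping the best iterate. Parameters
  are canonicalized to a ≥ b > 0, θ ∈ [0, π).

Fit quality: RMSE of the perpendicular residuals, and R² = 1 − Σdᵢ² /
Σ‖pᵢ − p̄‖². A regression-style R² on algebraic residuals is not well
defined for orthogonal fitting, so residual orthogonal scatter against
total point scatter about the centroid is used; it approaches 1 for
good fits and is the quantity fed to the confidence tiers.

### Bootstrap and confidence tiers

Semi-axis uncertainty comes from resampling the 200 spline sample points
with replacement (the resampling unit is the spline sample, not the raw
skeleton pixel), repeating the full two-stage fit, and taking the 2.5th
and 97.5th percentiles over 500 iterations. The seed defaults to 42 and
is configurable; given a seed the bounds are bit-identical across runs.
Failed iterations are skipped and counted; above 20% failures the
interval is flagged unreliable. In the pipeline the interval is computed
on the median retained slice of each object, which is the slice reported
in the per-object table.

Per object, z-coverage = retained slices / z-extent, where z-extent is
the inclusive span of slices containing any object voxels. Confidence is
High (R² > 0.5 and coverage > 0.7), Medium (R² > 0.3 and coverage >
0.5), else Low — thresholds strict exactly as stated, using the *mean*
slice R² (configurable design point; median or worst-slice would be
defensible alternatives). Mean ellipse area (π·a·b), mean perimeter and
the equivalent diameter 2√(mean area/π) — the diameter of the circle
with the object's mean cross-sectional area, a convention recorded here
because "equivalent diameter" is not otherwise pinned down — are
converted to nm via the voxel size. In-plane pixels are assumed
isotropic (the y voxel size is used and the assumption recorded in the
output); anisotropic in-plane data should be resampled first.

### Group statistics

`compareGroups()` gates on Shapiro-Wilk normality of each group at
α = 0.05: both normal → Welch t-test (unequal variances, the safer
default where "independent samples t-test" leaves the variant open),
otherwise a two-sided Mann-Whitney U. Cohen's d uses the classical
pooled SD. `bhAdjust()` delegates to the standard step-up implementation
(`stats::p.adjust`); the test suite verifies it against a literal
enumeration of the step-up definition over the full 0.05-grid of p-value
lists up to length 6. In `runComparison()` the BH family is all metric
comparisons within one condition pair, and Low-confidence objects can be
excluded by flag. Comparisons are two-sided throughout. Samples larger
than 5000 are thinned to 5000 evenly spaced order statistics for the
normality test (its implementation limit), deterministically.

## Trajectory metrics

Hydrogen bonds use the DSSP electrostatic model: E = 27.888·(1/r_ON +
1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with distances in Ångström (the
prefactor equals the 0.084·332 form to the printed precision), accepted
below −0.5 kcal/mol, with near-contact geometries clamped at −9.9.
Same-residue and covalent peptide-bond pairs are excluded per DSSP
convention; each accepted (donor, acceptor) pair yields one record (DSSP
permits two acceptors per carbonyl; counting per pair rather than per
donor is the recorded choice). Missing amide hydrogens are rebuilt 1.01
Å from N along the preceding carbonyl O→C direction — DSSP's own
fallback — or reported as an error when reconstruction is disabled.
Minimum-image distances, orthorhombic boxes only.

Registry classification applies only to inter-monomer bonds: parallel
when the acceptor is residue i−1, antiparallel when it is L+1−i, with
the (4→3) pairing excluded as ambiguous (it satisfies both rules for
L = 6). Enumeration for hexapeptides yields 4 parallel and 5
antiparallel admissible pairings — the imbalance behind the 0.8 weight
in f_p,sheet = n_p/(n_p + 0.8·n_ap + 1), whose +1 denominator keeps the
fraction defined (and 0) when no bonds exist. `countAdmissiblePairings`
also excludes the degenerate same-index pairing that arises only for odd
monomer lengths. The sheet-order series samples every 10 ns by default
(the stride used for this statistic; other metrics default to 1 ns).

Trajectory unwrapping removes inter-frame jumps larger than half a box
vector per axis, then aligns each frame on the reference by Kabsch
superposition of the backbone atoms; RMSD is then computed against the
t = 0 configuration with an optional monomer exclusion hook (a peptide
that detaches and re-enters through the boundary inflates RMSD through
poor alignment, and can be dropped from the selection). Insertion depth
is the z distance between the mass-weighted protein centre of mass and
the (unweighted, single-element) phosphorus centre of mass; pore-water
counts use a closed interval |Δz| ≤ 0.5 nm, a measure-zero choice fixed
for determinism.

## Image quantification

Maximum z-projections are elementwise maxima. Puncta counting binarizes
at one shared threshold per batch, labels 8-connected components
(matching the particle-analysis convention of the original tooling),
keeps particles strictly larger than 15 px, and assigns each to the cell
mask containing its centroid (components straddling masks follow their
centroid; orphans land in an "unassigned" bucket). Manders coefficients
are exposed in both classic (thresholds 0, the default) and thresholded
variants, since the plugin-produced variant in typical workflows is not
always documented; neither is asserted as canonical.

The leakage normalization (F_sample − F_control)/(F_Triton − F_control)
× 100 is applied pointwise to traces and deliberately not clipped to
[0, 100]: out-of-range values are diagnostic of drift or mismatched
controls.

## Synthetic data: what it emulates, and what it does not

* `makeEllipsoidShellVolume` voxelizes a hollow ellipsoidal shell: a
  voxel is foreground when the approximate signed Euclidean distance of
  its centre to the surface (normalized radius minus one over the local
  gradient magnitude) is within half the shell thickness. Per-slice
  ground truth (a(z), b(z), centre, area) is recorded analytically
  before degradation. Orientation is restricted to an in-plane rotation
  about z so cross-sections remain analytic ellipses; boundary jitter,
  salt-and-pepper flips and per-slice angular clipping (forcing open
  arcs) emulate segmentation noise and field-of-view loss. It does not
  emulate tomographic physics — missing wedge, CTF, anisotropic
  resolution — so passing tests demonstrate correctness of the
  geometry pipeline, not robustness to reconstruction artefacts.
* `makeIdealBetaSheet` places backbone atoms on an idealized β-strand
  lattice (3.4 Å rise, 4.8 Å strand spacing, strands shifted one rise
  per parallel interface so registry partners align) such that exactly
  the admissible donor/acceptor pairs satisfy the DSSP criterion:
  intended N-H groups point at their acceptor (r_ON = 2.9 Å,
  near-linear), all other N-H and C=O groups are rotated out of plane.
  The ambiguous (4→3) geometry is deliberately not built, so detection
  recovers exactly the enumerated sets. These are schematic geometries,
  not force-field minimized conformations.
* `makeMembraneFrame`, `makePunctaImage` and `makeGroupSamples` place
  waters, blobs of exact pixel area (with a guard ring so blobs never
  merge under 8-connectivity) and distributional samples with known
  truth (counts, per-cell puncta above the 15 px filter, analytic
  Cohen's d).

All generators draw from one seeded private RNG stream per call and
restore global RNG state, so outputs are bit-reproducible per seed and
never perturb a caller's random sequence.

## Default parameters

| Parameter | Default | Unit | Where |
|---|---|---|---|
| spline samples | 200 | — | `fitContourSpline` |
| arc-length filter | 50 (strict) | px | `passesLengthFilter` |
| bootstrap iterations | 500 | — | `bootstrapEllipseCI` |
| bootstrap seed | 42 | — | `bootstrapEllipseCI` |
| normality α | 0.05 | — | `compareGroups` |
| confidence tiers | R² 0.5/0.3, coverage 0.7/0.5 | — | `classifyConfidence` |
| DSSP acceptance | −0.5 | kcal/mol | `detectBackboneHbonds` |
| antiparallel weight | 0.8 | — | `parallelFraction` |
| pore slab half-width | 0.5 (closed) | nm | `poreWaterCount` |
| sheet-order stride | 10 | ns | `computeSheetOrderSeries` |
| puncta size filter | >15 (strict) | px | `countPuncta` |

The pipeline derives per-object bootstrap seeds deterministically as
master seed + object label, so objects can be processed concurrently
with byte-identical results to serial execution.

## Problem sizes and verification

The test suite builds everything it checks: phantoms with semi-axes up
to (40, 30, 20) px, 200-point spline samples, 50-arc ellipse-recovery
ensembles at σ = 0.5 px noise, 100-phantom bootstrap-coverage
simulations at 500 iterations each, exhaustive BH verification over all
~230k non-decreasing p-lists of length ≤ 6 on the 0.05 grid, and
100-replicate routing simulations for the normality gate. These sizes
were chosen to make sampling error negligible relative to the tested
tolerances while keeping the suite comfortably fast on a laptop. No
empirical claim is made here that the tests or the acceptance script do
not themselves compute.

## Known limitations

* Skeleton-pixel quantization limits per-slice curvature accuracy on
  real masks; the 2%-accurate curvature regime requires sub-pixel
  contours (e.g. spline samples of a prior fit), and near-pole slices of
  closed organelles bias the mid-shell ring radius outward relative to
  the analytic mid-surface cross-section — central slices are the
  reliable ones, which is why per-object summaries lean on z-coverage
  and tiers.
* Full 3D ellipsoid fitting is intentionally absent: the method fits 2D
  ellipses per slice and aggregates.
* Non-orthorhombic simulation boxes are not supported; curvature of 3D
  surfaces (curvedness) belongs to external surface-mesh tooling.
* The ellipse R² definition and the equivalent-diameter convention are
  package choices, documented above; comparisons across tools should
  compare definitions first.
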