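---
title: "Measuring intracellular sperm-egg interactions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intracellular sperm-egg interactions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iseimorph)
```

## The measurement problem

In *Drosophila* the whole sperm enters the egg, and its flagellum adopts a
folded, possibly helical 3D conformation in the cytoplasm that changes as
the zygote develops. `iseimorph` turns a confocal z-stack of a fixed,
antibody-labelled egg into a small set of numbers describing that
conformation — the intracellular sperm-egg interaction (ISEI) parameters —
and compares them across developmental stages (PN, 2N, 4N, 8N), species,
and reciprocal hybrid crosses.

The pipeline has five stages, each usable on its own: seeded threshold
masking, landmark localisation, centerline tracing, curve geometry, and
comparative statistics. A synthetic-egg generator with analytic ground
truth closes the loop: every stage is validated against curves whose true
descriptors are known in closed form.

## Masking and landmarks

`paint_threshold()` formalises interactive "paint with threshold"
segmentation as the pair (seed voxels, intensity window): the mask is the
26-connected component of in-window voxels reachable from the seeds, so
other structures that happen to share the intensity range are ignored.
Connectivity is configurable (6/18/26); 26 is the default because it is the
permissive choice matching how an operator paints. The intensity window is
always explicit configuration — there is no auto-thresholding.

`compute_center()` reduces a pronucleus or polar-body mask to the
arithmetic mean of its voxel coordinates. Two conventions coexist
deliberately: the *index-unit* centre averages raw integer indices (so two
voxels at [3,9,7] and [5,3,7] have centre [4,6,7]), while the *mm* centre
places voxel centres at `(index - 0.5) * spacing` and is what all distance
computations use. Polar bodies migrate to effectively one position and are
masked (and centred) as a single structure by default.

## Centerline tracing

The tracer extracts an ordered polyline from the flagellum mask:

1. Every masked voxel gets a **density score**, the sum of
   `1 / (1 + d_mm)` over masked neighbours within the density window.
   The window is per-axis in voxels with a physically roughly isotropic
   default (reach about 1.5x the coarsest spacing per axis); with an
   index-isotropic window on anisotropic grids the score would plateau
   across the tube interior instead of peaking on its axis.
2. The start is the neighbourhood centroid (score-weighted) of the
   highest-scoring voxel; the second point maximises
   `score x w_d(distance)`, where `w_d` is a triangular kernel peaking at
   the preferred step `s0`.
3. Each subsequent step considers only unconsumed voxels ahead of the
   current direction (positive projection, within the forward cone,
   default half-angle 80 degrees — a strict half-space would re-admit the
   perpendicular branch at a self-crossing). The preferred step shrinks
   linearly with candidate angle, `s(theta) = s0 (1 - gain * theta / pi)`,
   so the tracer slows into turns. The next point is the neighbourhood
   centroid of the best candidate; during stepping only the *transverse*
   component of the centroid shift is applied, because recentring across
   the tube must not drag points along it (that would shorten curved
   sections).
4. After each step all masked voxels within the consumption radius of the
   new segment are **consumed** — removed from candidacy. This is what
   lets one trace pass through a self-crossing instead of switching onto
   the already-visited branch. The radius defaults to a tube-radius
   estimate from `mask volume / (pi * pilot trace length)` plus half a
   voxel diagonal; without that margin, boundary voxels of the tube
   survive at a crossing and re-attract the tracer.
5. Tracing stops when no candidate remains or the step falls below the
   minimal distance `eps`; a final tip-completion point (the centroid of
   the remaining in-cone voxels just ahead) closes the half-step gap the
   minimal-step rule leaves at the tube end.
6. The process repeats in the opposite direction with the two seed points
   swapped (the backward pass starts with the forward pass's first segment
   already consumed), and the concatenated polyline is resampled at
   uniform spacing — 0.002 mm by default, the canonical confocal z-step,
   so point spacing is consistent between samples. Resampling interpolates
   with a cubic spline rather than linearly so the polygonized chords of
   the coarse trace are not frozen into later measurements.

Defaults (all in `trace_params()`): `s0 = 3 x max spacing` (0.006 mm),
`eps = 0.5 x max spacing`, cone 80 degrees, gain 1, kernel width equal to
the preferred step. The functional forms — inverse-distance density,
triangular distance kernel, linear angle shrink — are the simplest
monotone choices for the roles they play and are all exposed as
parameters.

## Curve geometry

Curvature needs second derivatives and torsion third; differencing raw
traced points would amplify voxel-scale jitter at every order. Instead,
each coordinate is fitted against the chord-length parameter with a
smoothing spline, evaluated at the knots, and re-interpolated with a cubic
spline that supplies analytic derivatives to order three. Both ends are
padded by odd reflection before fitting: a smoothing spline's natural
boundary conditions force zero second derivative at the ends, which
otherwise flattens curvature over the outer portion of the curve (about a
9% downward bias on the average curvature of a circle-arc fixture).

The smoothing default is a fixed moderate `spar = 0.4`. Two adaptive
alternatives were evaluated on the synthetic recovery suite and rejected
as defaults: generalized cross-validation collapses to interpolation
(tracer noise is serially correlated along the curve), and a
discrepancy-principle fit (`smoothing = "auto"`, residual RMS matched to a
second-difference noise estimate) over-shrinks arc length at coarse point
spacing, where curvature itself contaminates the noise estimate. The
"auto" mode remains available and is the better choice for externally
supplied points with independent jitter; `smoothing = 0` interpolates
exactly and is what the closed-form validation tests use.

Descriptor conventions:

* *Net length* is the 3D end-to-end distance — the only reading under
  which a straight curve has aspect ratio exactly 1 and a wavy one a
  larger value, both of which are fixed properties of the measure.
* *Total curvature* is `integral kappa ds`, in radians; this makes the
  identity `average curvature = total curvature / arc length`
  dimensionally exact. (Descriptions of total curvature sometimes carry a
  1/mm label; the radians convention is the one under which the identity
  holds and is used throughout.)
* *Torsion* is undefined where the curve is locally straight
  (`kappa < 1e-6 /mm`); such stretches are masked out of the average. The
  outer 5% of arc length at each end is also excluded from the average:
  torsion rests on a third derivative, and spline boundary behaviour
  produced endpoint spikes two orders of magnitude above interior values.
  The profile is still reported everywhere.
* *Writhe* is the open-curve Gauss double integral, evaluated by pairwise
  summation over the segments of the uniformly resampled polygon with the
  diagonal and adjacent pairs excluded (they are singular). It uses
  tangents only — no spline derivatives — which keeps it exactly zero for
  planar curves and exactly antisymmetric under mirror reflection.
* All integrals use a fixed uniform parameter grid (composite trapezoid,
  4001 nodes): a fixed grid is exactly equivariant under rigid motion and
  uniform scaling, so the bookkeeping identities (lengths scale with the
  curve, aspect ratio / total curvature / writhe invariant, average
  curvature inversely) hold to 1e-9 rather than to quadrature noise.

## Stage gating and positional descriptors

At the pronuclear stage all seven parameters are measured: sperm
positioning, pronuclei distance, arc length, net length, aspect ratio,
average curvature, total curvature. After karyogamy the pronuclei have
fused and the polar bodies disintegrated, so from 2N onward only the five
shape descriptors are recorded; the table builder enforces this totally
(no positional value ever appears outside PN). *Sperm positioning* is the
mean distance from the polar-body centre to the uniformly resampled
centerline points — with uniform resampling this is an arc-length-weighted
average over the whole flagellum, matching the idea of "distance to points
along the sperm" without privileging any particular point.

## Statistics

The three analysis families mirror the experimental questions: one-way
ANOVAs within a conspecific cross across stages, one-way ANOVAs across
species within a stage, and two-way ANOVAs (female origin, male origin,
interaction) on parental-plus-reciprocal-hybrid cohorts. Sums of squares
are sequential (Type I) in the fixed order female, male, interaction —
with unbalanced group sizes the decomposition depends on this order, so it
is fixed and documented rather than left to default. Post hoc Tukey HSD
tests (Tukey–Kramer SE under unequal n, studentized-range adjusted p) are
gated on parent-test significance at alpha = 0.05. No multiple-testing
correction is applied across descriptors; the descriptor families are
reported side by side and readers should treat marginal p-values
accordingly. Degenerate inputs (all values equal; zero within-group
variance with differing means) are flagged explicitly instead of being
reported as ordinary F statistics. Cells that cannot be analysed — a
species observed at one stage, an empty female-by-male cell (as happens in
real designs when one cross yields no embryos at a stage) — are skipped
and listed, never imputed.

## The synthetic-egg generator

`rasterize_scene()` emulates the relevant features of a confocal stack of
a fertilized egg: an ellipsoidal egg volume (default semi-axes
0.20 x 0.075 x 0.075 mm, plausible for an *obscura*-group egg),
anisotropic voxel spacing (0.002 mm z — the standard acquisition step —
and 0.0005 mm in-plane), a flagellum tube whose intensity falls off as a
Gaussian of distance to the generating curve with half-peak exactly at the
tube radius (0.0025 mm default, the smallest radius resolvable at the
z-step), Gaussian landmark blobs, and additive Gaussian noise at 10% of
tube peak (Poisson optional, off by default). Tubes are truncated at the
endpoint planes: spherical stamp caps would extend the mask about one tube
radius past the generating curve, and a correct tracer would then rightly
measure a longer centerline than the nominal ground truth.

Curve families provide the analytic ground truth: straight lines (aspect
ratio exactly 1), circle arcs (curvature exactly 1/r), helices
(`kappa = a/(a^2+b^2)`, `tau = b/(a^2+b^2)`, sign giving handedness) — the
closed forms were verified against a finite-difference oracle before being
frozen into tests — a figure-of-eight for the self-crossing case, and
constrained random splines. Two figure-8 parameters matter and are fixed
in the generator, not tuned per test: the end gap (0.7 rad trimmed per
end) keeps the curve genuinely open — if the two ends approach within the
tracer's step-kernel reach (`2 s0`), any tracer will bridge the gap and
loop, with or without consumption — and the lobe compression
(`squeeze = 0.6`) sets the self-crossing angle to about 62 degrees, inside
the 80-degree forward cone, which is the regime where the consumption rule
is genuinely load-bearing. Random splines are drawn from a momentum random
walk and rejected until they satisfy resolvability constraints (bend
radius at least 0.0075 mm, self-separation at least 0.0065 mm): a tube of
radius 0.0025 mm has no recoverable centerline across tighter features,
so unconstrained curves would test rasterization artefacts rather than
tracing.

`generate_experiment()` turns a design table (female, male, stage, n) into
a cohort: per-egg helix parameters are the group-level values (an
`effect_model()` maps groups to multiplicative shifts on helix radius and
pitch) times lognormal between-egg variation with 8% coefficient of
variation, a between-egg spread in the range reported for morphometric
traits. With rasterization enabled each egg becomes a 16-bit multi-page
TIFF plus ground-truth JSON; in tables-only mode the records carry the
analytic descriptors directly, which is what large statistical
calibrations use (rasterizing hundreds of stacks tests the imager, not
the statistics).

What the generator does **not** emulate: the optical point-spread
function, chorion autofluorescence, antibody labelling variability,
multi-channel registration, or real sperm conformations beyond the stated
families. Passing tests therefore demonstrate that the algorithms recover
known geometry under controlled imaging physics — not that segmentation
of real eggs is operator-independent.

## Problem sizes and determinism

The validation suite runs at deliberately compact sizes: synthetic eggs of
roughly 0.08 x 0.04 x 0.04 mm (about 1.3 million voxels), flagella of
0.1-0.3 mm arc length traced as 40-120 raw points, 100-replicate jitter
studies, and 200-replicate null calibrations in tables-only mode. Every
stochastic component is seed-controlled: a scene spec plus seed determines
the stack bit-for-bit, and identical configuration reproduces the cohort
CSV byte-for-byte.

## Known limitations

* The tracer assumes one connected flagellum mask with a tube-like local
  geometry; it does not handle branched masks or gaps (a broken mask
  yields two partial traces, not a bridged one).
* Torsion near the resolution limit is the least stable descriptor; its
  average is meaningful only where a substantial fraction of the curve has
  well-defined curvature (the `defined_fraction` diagnostic is reported).
* Writhe of nearly self-touching curves is sensitive to the resample
  spacing through the excluded-adjacent-pair rule.
* The interactive seed-and-window step of real masking is inherently
  operator-dependent; the package makes it reproducible by recording it as
  configuration, not by removing the choice.
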