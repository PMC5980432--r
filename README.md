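# iseimorph

Quantitative geometry of sperm inside fertilized *Drosophila* eggs.

In *Drosophila* (and many other taxa) the **entire** sperm — head and
flagellum — enters the egg at fertilization, so the sperm's 3D conformation
inside the egg cytoplasm is itself a phenotype: an *intracellular sperm–egg
interaction* (ISEI). `iseimorph` measures that phenotype from confocal
z-stacks of antibody-labelled eggs and runs the comparative statistics that
ask how it varies across development, between species, and between parental
and reciprocal hybrid crosses. Because real confocal material is scarce, the
package ships a synthetic-egg generator with analytic ground truth, so every
stage of the pipeline is testable end to end.

## What it computes

From a voxel stack with physical spacing (canonically 0.002 mm between
z slices) the pipeline extracts:

1. **Masks** — seeded threshold segmentation ("paint with threshold"): the
   26-connected component of voxels with intensity in `[lo, hi]` reachable
   from operator-chosen seeds; disconnected in-range structures are ignored.
2. **Landmarks** — each pronucleus / polar-body mask is reduced to the
   arithmetic mean of its voxel coordinates (e.g. voxels at [3,9,7] and
   [5,3,7] give the centre [4,6,7]).
3. **Centerline** — an iterative directed tracer: voxels are scored by the
   number and distance of their masked neighbours, the next point is the
   neighbourhood centroid of the best-weighted candidate ahead of the
   current direction (triangular distance kernel peaking at an
   angle-adapted step), and voxels along each new segment are *consumed* so
   the trace can pass through a curve crossing over itself. The trace runs
   in both directions from the densest voxel and is resampled at uniform
   0.002 mm spacing.
4. **Shape descriptors** of the centerline `r(s)`:
   - arc length `L = ∫ |r′| ds` and net length `|r(L) − r(0)|`;
   - aspect ratio `L / net length` (1 for a straight sperm);
   - curvature `κ = |r′ × r″| / |r′|³` (the reciprocal best-fit-circle
     radius), total curvature `∫ κ ds` and average curvature
     `total / L`;
   - torsion `τ = ((r′ × r″)·r‴) / |r′ × r″|²` (local helicity and
     handedness), averaged over arc length;
   - writhe `Wr = (1/4π) ∬ (t(s) × t(s′)) · (r(s) − r(s′)) / |r(s) − r(s′)|³ ds ds′`
     (Gauss double integral over the open curve, computed by pairwise
     segment summation).
5. **Positional descriptors** (pronuclear stage only, before karyogamy):
   sperm positioning (mean distance from the polar-body centre to the
   points along the flagellum) and the 3D distance between the male and
   female pronuclei.
6. **Statistics** — one-way ANOVAs (within species across stages, between
   species per stage), sequential two-way ANOVAs (female origin, male
   origin, interaction) for parental vs reciprocal hybrid crosses, and
   Tukey HSD post hoc tests (Tukey–Kramer SE for unequal group sizes).

Derivatives are never taken from raw traced points: each coordinate is
fitted with a smoothing spline against arc length (reflection-padded at the
ends) and differentiated analytically.

## Worked example

Simulate one egg with a known right-handed helical flagellum
(radius a = 0.01 mm, pitch b = 0.003 mm, so κ = a/(a²+b²) = 91.7 /mm and
τ = +27.5 /mm), rasterize it with 10% additive noise, then segment, trace
and measure:

```r
library(iseimorph)

spec <- curve_spec("helix", a = 0.01, b = 0.003, turns = 3,
                   rotation = rbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0)),
                   translation = c(-pi * 3 * 0.003, 0, 0))
truth <- make_curve(spec, n_samples = 400)
scene <- scene_spec(egg_semiaxes = c(0.04, 0.02, 0.02), noise_sd = 0.1,
                    seed = 1)
egg <- rasterize_scene(scene, truth)

seed_voxel <- which(egg$grid$data == max(egg$grid$data), arr.ind = TRUE)[1, ]
mask <- paint_threshold(egg$grid, seed_voxel,
                        range = c(scene$background + scene$peak / 2, Inf))
centerline <- trace_centerline(mask, egg$grid)
desc <- curve_descriptors(centerline)
```

This prints (formatting added):

```
arc length        0.1915 mm   (true 0.1968)
aspect ratio      3.34       (true 3.48)
avg curvature     97.0 /mm   (true 91.7)
avg torsion       +23.7 /mm   (true +27.5)
writhe            1.51       (true 1.52)
```

The traced helix recovers arc length within ~3%, curvature within ~6%, and
the torsion sign (right-handed) correctly; a mirrored (left-handed) helix
flips the sign of torsion and writhe.

For a full in-silico experiment — Table-style designs of crosses × stages,
per-egg stacks, the cohort descriptor table and the ANOVA/Tukey report —
see `generate_experiment()`, `run_paper_design()` and the `isei` command
line script in `inst/scripts/` (subcommands `simulate`, `trace`, `measure`,
`stats`, `pipeline`).

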