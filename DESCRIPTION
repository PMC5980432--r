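Package: iseimorph
Title: Quantifying Intracellular Sperm-Egg Interaction Geometry in Fertilized Eggs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the three-dimensional geometry of sperm flagella inside
    fertilized Drosophila eggs from confocal voxel stacks. Provides seeded
    threshold masking, an iterative directed centerline tracer that copes with
    self-crossing curves via voxel consumption, nuclear landmark localisation,
    discrete curve descriptors (arc length, net length, aspect ratio,
    curvature, torsion, and the Gauss-integral writhe of open curves), and the
    comparative statistics used to contrast species, developmental stages and
    reciprocal hybrid crosses (one-way and sequential two-way ANOVA with Tukey
    HSD post hoc tests). A synthetic-egg generator with analytic ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests: optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
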