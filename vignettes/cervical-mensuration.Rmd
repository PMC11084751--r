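---
title: "Sagittal cervical mensuration and its reliability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sagittal cervical mensuration and its reliability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervimetrics)
```

## The measurement model

A lateral cervical radiograph is digitized as a fixed landmark scheme: three
points on the atlas (anterior tubercle, the midpoint of C1 at the posterior
margin of the dens, and the midpoint of the posterior spinal laminar line)
and four body corners on each of C2–C7 (anterior-superior, posterior-superior,
anterior-inferior, posterior-inferior). From these 27 points the package
computes the 18 standard sagittal alignment variables:

* **ARA** (°) — the absolute rotation angle, the overall cervical curve:
  the angle between the posterior body tangents of C2 and C7. The posterior
  tangent of a vertebra is the line through its posterior-inferior and
  posterior-superior corners, directed superiorly (the Harrison posterior
  tangent method).
* **RRA23 … RRA67** (°) — relative rotation angles, the segmental
  contributions: the angle between the posterior tangents of each adjacent
  pair. Because all five segments share the C2 and C7 tangents pairwise, the
  five RRAs telescope exactly: ARA = RRA23 + RRA34 + RRA45 + RRA56 + RRA67.
  This identity is enforced to 1e-9° in the test suite and is a structural
  property of the shared sign convention, not a numerical coincidence.
* **KA23 … KA67** (°) — segmental Cobb angles: the angle between the facing
  endplate lines across each disc (inferior endplate of the upper body
  against superior endplate of the lower). For parallelogram-shaped bodies
  KA equals RRA at the same level; endplate wedging drives them apart.
* **ST23 … ST67** (mm) — segmental translations: the signed perpendicular
  distance from the upper body's posterior-inferior corner to the infinite
  posterior tangent line of the lower body (a George's-line step-off),
  positive anteriorly.
* **C1H** (°) — the atlas plane angle: inclination of the line from the
  anterior tubercle to the posterior laminar midpoint, relative to true
  horizontal. The dens midpoint landmark is stored for completeness but
  enters no measurement; no standard variable is defined on it.
* **TR** (mm) — anterior head translation: the horizontal offset of the C2
  posterior-superior corner from a vertical through the C7 posterior-inferior
  corner.

### Frame and sign conventions

Coordinates are continuous physical positions in millimetres after
calibration (a per-image `mm_per_unit` factor applied at file read), with
x positive toward the patient's anterior and y positive superior. All angles
are counterclockwise-positive in that frame and reported in (−180°, 180°];
anatomical values are far from the wrap. Under these conventions extension
(lordosis) is positive for ARA/RRA/KA and anterior translation is positive
for ST/TR. Some clinical software reports lordosis with the opposite sign;
that is a display convention and can be applied to exported tables if
needed.

Two of the 18 variables are deliberately not rigid-motion invariant: C1H is
defined against true horizontal (so it is equivariant — a global rotation of
the image adds exactly that rotation), and TR is a horizontal offset (so it
is translation- but not rotation-invariant). The other 16 are invariant
under any global rotation + translation, and the two distances scale
linearly under uniform scaling while all angles are unchanged. These are the
package's core correctness properties and are tested as such.

### Missing and degenerate input

A landmark set without the atlas is still "complete" for the 17 body-derived
variables; only C1H is reported missing. Inside `measure_all()` a degenerate
construction (coincident posterior corners, zero-length endplate) yields a
per-variable missing value with a warning rather than failing the image —
consistent with tolerant handling of imperfect clinical data — while file
*validation* is strict: collinear body quads (shoelace signed area ≤ 1e-9
mm²), duplicate points, and malformed records are typed errors at read time.

## Reliability statistics

Two measurement tables (trials) are compared per variable on image-matched
pairs; pairs with a missing side are dropped per variable, not listwise.
For each variable the report carries the mean absolute and mean signed
error, the sample standard deviation of the signed errors, RMSE
(`sqrt(mean(e^2))`, which satisfies `rmse² = mean² + ((n−1)/n)·sd²`
exactly), the intraclass correlation with a 95% confidence interval, and
the regression R².

**ICC model.** The default is ICC(2,1) — two-way random effects, absolute
agreement, single measures — the strict, standard choice for test–retest
designs, computed from the two-way mean squares with k = 2 raters. The
consistency variant ICC(3,1) is available; the difference matters exactly
when one trial carries a systematic offset, which lowers agreement but not
consistency. Confidence intervals use the standard F-based construction;
under perfect agreement the residual mean square is zero and the interval is
undefined, so its bounds are reported missing while the estimate is exactly 1.

**R².** For simple regression the coefficient of determination equals the
squared Pearson correlation, so it is symmetric in the two trials; it is
computed that way, with bit-identical series short-circuited to exactly 1.
R² values are banded two ways: a reliability grouping used to sort variables
by how cleanly a second annotation reproduces the first (super-clean
R² ≥ 0.90, clean [0.75, 0.90), semi-clean [0.50, 0.75), unreliable below),
and a conventional effect-size scale (none/very-weak < 0.3, weak [0.3, 0.5),
moderate [0.5, 0.7), strong [0.7, 1), perfect = 1). A published 18-variable
concurrent-validity R² column with its published grouping ships in
`published_validity_r2()`; the band classifier reproduces that grouping
exactly, which pins the interval edges.

No hypothesis tests or multiplicity corrections are performed: the analysis
is descriptive reliability, and the report schema carries no p-values.

## The synthetic spine generator

Real annotated radiograph cohorts of this kind are not publicly deposited,
so validation runs on a parametric generator whose ground truth is exact by
construction. The spine is parametrized directly by posterior-tangent
direction angles: the C7 tangent is tilted by a base angle and each level
adds its configured share of the total lordosis, so ARA equals the
configured total and each RRA equals its share *identically* — parameter
recovery is an equality test (tolerance 1e-6, absorbing only float error),
not an approximation. Bodies are stacked along the curve with disc gaps;
listhesis is injected as an offset along the disc's anterior normal;
endplate wedging rotates anterior corners about posterior ones, moving KA
away from RRA by the wedge difference; the atlas plane line is placed above
C2 at a configured absolute inclination, so C1H truth is that inclination
plus the global image rotation.

Default population parameters (all configurable, chosen once as plausible
for an adult cervical cohort in the absence of published cohort geometry):
total lordosis α ~ N(20°, 10°), C7 base tilt ~ N(0°, 5°), equal segmental
weights, posterior body heights 18 mm (C2) and 11 mm (C3–C7), body depths
16 mm, disc gaps 5 mm, atlas span 45 mm, endplate wedge SD 1°, listhesis SD
0.5 mm (the wedging and listhesis emulate a cohort in which degenerative
change is allowed), global image rotation SD 2° and translation SD 5 mm.

**Annotation noise.** Each simulated digitization trial displaces every
landmark by isotropic Gaussian noise. The default σ = 0.15 mm is calibrated
so that the simulated test–retest error SD of ARA is near 2°, matching the
magnitude of repeatability reported for expert digitization: by linear error
propagation the ARA test–retest error SD is √2·√2·σ·√(1/h<sub>C2</sub>² +
1/h<sub>C7</sub>²)·180/π ≈ 12.2·σ degrees (one √2 for two corners per
tangent, one for the difference of two trials), giving σ ≈ 0.16 mm; 0.15 mm
is used. With between-patient ARA SD of 10° this places the simulated
retest ICC for ARA in the excellent band, the qualitative pattern expected
of an expert rater. A per-landmark σ override exists because endplate
corners are the less reliable landmarks on degenerated spines.

**The three trials.** A simulated study emits two independent human trials
(US1, US2) and a computer-vision annotator (CV) modeled as any deterministic
landmark source: one fixed deviation from truth (its own σ, configurable to
0 for a perfect annotator) that is bit-identical every time it is
re-measured. Re-measuring the CV trial twice is therefore an exact identity
experiment — every variable must give ICC = 1, RMSE = 0, R² = 1 — and the
pipeline asserts precisely that. The CV annotator's *accuracy against truth*
is a free parameter: concurrent-validity numbers depend on the private
images behind any published table and are not a target of the simulation.

**Randomness contract.** A single master seed derives labelled substreams
per (rater, trial, image) through a deterministic hash, so results are
byte-reproducible and independent of evaluation order, and no global RNG
state leaks to the caller.

### What the generator does and does not emulate

It emulates between-patient variation in global and segmental alignment,
base tilt and head posture, segmental listhesis, endplate wedging, image
pose (rotation/translation/scale), and annotator jitter. It does not render
images, so it cannot exercise landmark *detection* (the upstream computer
vision problem), osteophytes or other shape pathology beyond wedging,
flexion/extension poses, or rater biases that correlate across landmarks
(e.g. a systematically shifted endplate reading). Passing tests therefore
validate the measurement geometry and the statistical machinery end to end,
not the behavior of any detector on real radiographs.

## Numerical choices

* Angles come from `atan2(cross, dot)` of direction vectors — no arccos of
  normalized dots, so near-parallel lines lose no precision; the result is
  confined to (−180°, 180°] with no unwrapping needed.
* Degenerate direction vectors (norm < 1e-12) are typed errors, not NaNs.
* ICC estimates are clamped to [−1, 1]; the undefined case (no
  between-subject *and* no residual variance) is a typed error.
* Validation thresholds: quad signed area ≤ 1e-9 mm² is degenerate; segment
  weights must sum to 1 within 1e-12.
* File round trips preserve coordinates to better than 1e-9 mm (JSON and
  CSV are written at full double precision).

## Problem sizes

The test suite exercises the geometric invariants on 1000 randomly generated
landmark sets (telescoping, oracle agreement) and 150 random rigid motions;
the identity experiment runs a full 254-image simulated study; ICC parameter
recovery uses 200 replicates of 254 paired draws with subject variance 9 and
error variance 1 (true ICC 0.9, recovered mean within ±0.02). These sizes
were chosen to make the property checks sharp while keeping the default
suite fast on a single CPU.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_images = 50, seed = 42)
res <- replicate_experiment(list(config = cfg, noise = noise_model()),
                            out_dir = tempfile("study"))
res$summary$cv_vs_cv_identity   # TRUE: the deterministic annotator agrees
                                # with itself exactly on all 18 variables
subset(res$reports$us_vs_us, variable == "ARA",
       select = c(n_pairs, rmse, icc, r2, r2_class))
```

## Known limitations

* The exact endplate pairing used by segmental Cobb readings differs
  between software packages; this implementation uses the facing endplates
  across the disc, which reduces to RRA for parallelogram bodies.
* Segmental translation is implemented as the perpendicular step-off from
  the lower posterior tangent. A horizontal-offset construction would differ
  on rotated images; the perpendicular form is preferred precisely because
  it is rigid-motion invariant.
* The standard deviation column reported here is the conventional sample SD
  of the signed errors, tied to the RMSE by the exact decomposition above;
  published tables do not always document which dispersion statistic they
  print, so SD columns are not directly comparable across sources.
* ICC confidence intervals assume the two-way normal-effects model; they are
  informational and not produced for the degenerate perfect-agreement case.
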