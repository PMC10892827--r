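---
title: "Measuring nanometer-scale particles in TEM micrographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nanometer-scale particles in TEM micrographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoPSD)
```

## The measurement problem

Bright-field TEM micrographs of cyanobacteria that have biosynthesized
metallic nanoparticles show small dark condensations (the particles, roughly
2–12 nm across) embedded in a cellular matrix whose membranes, thylakoids
and granules can be just as dark. Quantifying such particles means making a
chain of small decisions — how a threshold is defined, what counts as
contiguous, what happens to interior holes and to regions cut by the image
edge, how an ellipse is fitted — and each decision moves the measured sizes.
nanoPSD fixes every one of those decisions explicitly, implements them
deterministically, and pairs them with a synthetic-image generator so the
whole chain can be validated against exact ground truth.

The pipeline mirrors the standard particle-analysis workflow: calibrate
(nm/px from the scale bar) → optionally crop / smooth / sharpen → threshold
→ label contiguous pixels → include holes, exclude edge-touching regions,
restrict by area → measure per-particle descriptors → aggregate into
distributions → cross-check against re-imaging at other magnifications.

## Thresholding

The threshold is expressed as a percentage TH of the gray histogram: for
dark-foreground polarity the cutoff is the smallest gray value whose
cumulative histogram fraction reaches TH/100 (`quantile(…, type = 1)`), and
a pixel is foreground iff its gray value is at or below the cutoff. This
definition is exactly computable, reproduces the qualitative behavior that a
low TH admits too few pixels while a moderate TH is acceptable, and makes
the foreground monotone in TH (a property the test suite asserts). On a
constant image every pixel equals the cutoff, so every pixel is foreground
for any TH — a convention, but one that keeps the definition total.

`suggestThreshold()` converts Otsu's gray cutoff into this TH percentage.
It is reliable when particles occupy a nontrivial fraction of the image
(a few percent or more, as in cropped analysis regions); on a nearly
unimodal histogram — a huge field of view with a handful of tiny particles —
Otsu splits the background instead, so for such images TH should be chosen
per image, which is how the multi-magnification comparisons are configured
(each series entry carries its own TH).

## Segmentation details

* **Connectivity** defaults to 8 (diagonal pixels are contiguous), the usual
  particle-analysis convention; 4 is available. Labeling is a run-based
  union–find, checked in the tests against a brute-force flood fill.
* **Hole inclusion** fills interior background: background components (under
  the complement connectivity) not reachable from the image border are
  assigned to the surrounding region; the per-region filled-pixel count is
  reported. Areas are taken after filling.
* **Edge exclusion** removes any region containing a border pixel — regions
  cut by the frame would otherwise be measured too small. Inside local
  analysis windows the same rule applies to the window border.
* **Area restriction** bounds are inclusive at both ends, both in pixels
  (`minAreaPx`, default 50 px — components below it are treated as noise in
  automatic runs; set it smaller at coarse calibrations where a real
  particle covers few pixels) and in nm² (`restrictionSweep()` supports the
  interval sweeps used to separate particles from similar-gray cellular
  components, e.g. narrowing to 26–160 nm²).
* **Ordering**: surviving regions are renumbered row-major by centroid
  (y, then x), so ids are deterministic across runs.

## Morphometry conventions

For a region of `N` pixels at calibration `s` nm/px:

* area `A = N s²`; `ECD = sqrt(4A/π)` (the diameter of the equal-area
  circle — exact only for round particles, which is why shape descriptors
  accompany it).
* The **ellipse fit** uses the second central moments of the pixel centers
  plus the 1/12 variance of a unit pixel, so a solid `n`-pixel-wide
  rectangle gets variance `n²/12` exactly; orientation and axis ratio come
  from the eigendecomposition, and the axes are rescaled so the ellipse area
  equals `A` (area-preserving normalization, the convention of the common
  particle-analysis toolchains; boundary least-squares fits were rejected
  for determinism). `a` and `b` are full axis lengths, so a perfect ellipse
  has `FMR ≈ 1`. A single pixel gets `a = b =` the ECD of one pixel.
* The **Feret diameter** is the maximum caliper distance over the convex
  hull of the region's pixel outer corners (each pixel contributes its four
  corners), computed by rotating calipers and equal — exactly, and the tests
  assert it exactly — to the brute-force maximum pairwise corner distance.
  A single pixel therefore has `D_f = √2` px.
* `RAR = b/a`, `FMR = D_f/a`. RAR at or below the classification scale's
  lower bound 0.12 is tagged "out of scale" rather than erroring: such
  needle-like regions are excluded from the six-class breakdown but kept in
  the particle table. Class boundaries are upper-inclusive, so RAR exactly
  0.70 is "rounded", not "very rounded".

Two discretization effects are worth knowing. First, the corner-based Feret
exceeds the continuous diameter by roughly one pixel diagonal, so FMR of a
digitized disk is ≈ 1.03–1.06 and only falls below 1.05 once the radius
exceeds ~13 px. Second, for elongated *blocky* shapes the area-preserving
moment ellipse's major axis can exceed the hull caliper — a solid 10 × 30 px
rectangle has FMR ≈ 0.93 — so FMR ≥ 1 is a reliable expectation only for
compact convex particles. Both behaviors are asserted in the test suite as
documented properties.

## Distribution summaries

`summarizePSD()` reports N, the arithmetic mean, the standard error of the
mean (sample standard deviation, n − 1 denominator, divided by √n), a
histogram over half-open bins `[lo, lo + w)` (defaults: 1 nm for ECD,
10 nm² for area, 0.05 for RAR/FMR), the per-bin cumulative percentage
(always ending at 100 for nonempty input), and the 10/25/75/90th percentiles
(R's default linear interpolation), matching the usual
histogram-plus-box-plot reporting. Empty input yields a valid summary
flagged "empty"; a single particle reports SE 0 with a flag so report tables
stay rectangular.

Local distributions (`localPSD()`) crop a window (default 500 × 500 nm²),
re-threshold it on its own histogram with the base TH (or a per-window
override), and report the same fields plus the window's origin and limits.
Re-thresholding locally is deliberate — it is how windowed analyses are done
in practice, since local gray statistics differ — but it means a particle's
measurements can differ slightly between the global and a windowed run
unless the cutoffs coincide; particles straddling a window edge are excluded
by the edge rule. Window placement is user-supplied or seeded-random
(`sampleWindows()`), making "randomly selected areas" reproducible.

## Cross-magnification quality control

The same specimen region imaged at different magnifications should yield
the same particle sizes; how much it does not is the practical error bar.
`matchParticles()` takes a series of micrographs registered in a shared nm
frame (registration is supplied by the user for real images and is exact for
synthetic renders; automatic image registration is out of scope), segments
each with its own TH, and matches particles one-to-one to the
finest-calibration reference greedily by nearest centroid within a tolerance
(default: two pixels of the coarsest image, in nm; equidistant candidates
resolve to the lower particle id, making matching symmetric under input
order). `deviationTable()` then tabulates per-particle signed ECD deviations
against the reference and the maximum absolute deviation per magnification;
rows whose reference ECD is below 3.5 nm are kept in the table but excluded
from the maxima, since values that small are routinely disregarded in
automatic runs near the resolution limit.

## The synthetic generator

`sceneSpec()` describes a scene in nm: disk and ellipse particles (analytic
truth), amorphous blobs (base radius perturbed by a low-order harmonic
series — default total amplitude 20 % over 5 harmonics of order ≥ 2, so the
perturbation does not translate the shape; truth area is the shoelace area
of the densely sampled boundary polygon, truth axes come from the polygon's
exact second moments), and a background with a base gray, a linear
illumination gradient, a correlated texture field (iid normals on a grid at
the correlation length, bilinearly upsampled) and an optional dark membrane
band. Particles are darker than the background, as in bright-field TEM; an
inversion flag exists for robustness tests.

`buildScene()` realizes all geometry from the scene seed and freezes the
ground truth, so the nm-space truth is provably identical across renderings;
`renderScene()` draws only texture and noise from its own seed, composes
pixel gray as background + coverage-weighted particle contrast + Gaussian
noise, and quantizes to 8-bit. Boundary pixels get fractional coverage
(4 × 4 subpixel sampling), which is what makes sub-pixel ECD recovery
testable at all. Particles whose true area covers less than one pixel are
flagged in the truth table.

What the generator does **not** emulate: electron-optical image formation
(defocus, contrast transfer, scattering), ultrathin-section artifacts, stain
granularity, or particle agglomeration. Passing the ground-truth tests
therefore demonstrates that the measurement chain is correct and stable
under realistic gray statistics — not that any particular threshold choice
is optimal for a given real instrument.

## Study conditions used by the tests and the acceptance script

The validation suites run at sizes chosen to represent the imaging
conditions while keeping runs quick:

* recovery: 100 disks (diameters ≥ 10 px at 0.5 nm/px, contrast 60 gray
  levels, noise sd 5) and 50 ellipses (major axis ≥ 15 px); measured ECD is
  required within 3 % of truth for ≥ 95 % of disks and the axis ratio within
  5 % for ellipses.
* cross-magnification robustness: one scene of 30 particles with true ECD
  3.5–12 nm rendered at 0.1 / 0.3 / 1.5 nm/px — the 1:3:15 calibration
  ratio of a 150k/50k/10k magnification series on a camera that delivers
  ≈ 0.1 nm/px at 150k — requiring ≥ 90 % of matched particles within 1.0 nm
  of the finest rendering. Observed maxima are ≈ 0.5–0.7 nm, consistent
  with the ±1 nm error budget expected for conventional-mode imaging.
* the published two-triplet ECD table across 150k/100k/10k is fed through
  `deviationTable()` and must reproduce its printed deviations exactly.

## Known limitations

* TH is a histogram percentile; images whose particle fraction is far below
  the background tail need a manually chosen TH (the Otsu suggestion is a
  convenience, not a guarantee).
* The moment-ellipse/Feret combination makes FMR slightly resolution- and
  shape-dependent (see above); FMR comparisons are most meaningful between
  particles measured at similar scales.
* Matching is centroid-greedy; scenes with particle spacing below the
  matching tolerance at the coarsest calibration can mismatch neighbors.
* No automatic scale-bar detection or cross-image registration; both are
  supplied by the user.
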