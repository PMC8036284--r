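---
title: "Uptake-contour transformation and GDM2 ranking of PET lung nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uptake-contour transformation and GDM2 ranking of PET lung nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petcontour)
```

## Scope and model

`petcontour` ranks solitary hypermetabolic pulmonary nodules
(SUVmax ≥ 2.5, diameter 10–30 mm) by malignancy likelihood using only the
PET signal. The chain is:

PET DICOM series → SUV volume → VOI → per-slice transform (resample to
1 mm, min–max normalise, superlevel-set contour tree) → four ordinal
features → GDM2 synthetic variable from the pattern object →
maximum-gradient groups I–IV → classification at distance ≤ 0.4.

The package deliberately ignores everything CT-derived (margins, subsolid
appearance, calcification), respiratory-motion correction, and any
learned/neural component: the method is a hand-crafted radiomics pipeline
whose every stage is inspectable.

## SUV and the volume of interest

SUV = concentration · weight / injected activity, with concentration kept
in the mass-based unit convention (mCi/kg) so the ratio is dimensionless.
Whether a scanner reports Bq/mL converted at unit density is site-specific;
the reader exposes the dose unit as an argument (`dose_unit`) and defaults
to the convention above. Decay correction is assumed done by the scanner —
no decay arithmetic is performed.

The default VOI is automatic: seed at the global SUV argmax, grow the
26-connected component of voxels with SUV ≥ 2.5, pad its bounding box by
5 mm. A series whose SUVmax falls below 2.5 is not a hypermetabolic
nodule and is rejected — that is an inclusion rule of the method, not an
error of the data. A manual bounding box per nodule (CSV override)
mirrors the clinical workflow, where the VOI is drawn by the operator;
the synthetic-cohort pipeline uses that path because its phantoms contain
a reference structure hotter than the nodule (below).

## The transform and its numerical choices

*Resampling.* Bilinear, pixel-centre aligned, edge-clamped, to exactly
1 × 1 mm. The output side is the physical extent rounded half away from
zero: 192 px · 3.6458 mm → 700 px. Rounding half-to-even (the base R
default) would give the same figure here but differs on exact halves,
hence the explicit choice. A constant slice stays exactly constant and
mean intensity of smooth fields is preserved to well under 1 %.

*Normalisation.* (x − min)/(max − min) per transformed slice; a constant
slice maps to all zeros (a flat slice carries no contours and a division
by zero helps nobody). Cohort- and VOI-scoped normalisation are available
as options but off by default, since the published pipeline normalises
each image independently.

*Rendering.* The literal renderer reproduces the byte-level recipe —
8-bit quantisation, bitwise OR with a matrix of ones (merging adjacent
intensity pairs into bands), composited as black ink over white:
`gray = 255 − (round(255 v) | 1)`. "OR with an all-ones matrix" is
ambiguous in prose (OR with 255 would whiten everything); OR with the
*value one* is the only reading that produces the banded topographic
images, so that is what literal mode does. Because it is still debatable
whether the published contour appearance arises purely from this banding
or from an extra plotting step, an explicit mode additionally draws the
superlevel boundaries at the tree thresholds; features never depend on
either rendering.

*The contour tree.* Features are measured on the explicit superlevel-set
structure, not on PNG bytes: connected components of {v ≥ k/L},
k = 1…L−1, restricted to the VOI window, with containment edges. L = 8
resolves the deepest nesting seen in practice while staying robust to
noise; it is configurable. In-plane connectivity is 4-neighbour
(the convention of the underlying labeller, applied consistently in code
and test oracles). A component whose pixel set coincides with its
parent's is the *same* visible contour, not a new nesting level, and is
merged — so binary plateaus count once and the chain length of a smooth
unimodal peak equals the number of thresholds below its value.

## The four features as quantitative proxies

The clinical workflow scores the features visually. The package's
measurements are declared proxies, with every binning cut point in one
`binning_config()` so that manual score tables and automated extraction
are interchangeable inputs to the ranking:

1. **Nesting degree** — the longest containment chain over the slice
   sequence; binned 0–1 → 1, 2 → 2, 3 → 3, ≥ 4 → 4.
2. **Shape change** — mean over consecutive slice pairs of 1 − Jaccard
   overlap of the outer nodule contours after centroid alignment *and
   isotropic rescaling to a common area*. The size normalisation is a
   deliberate design choice: without it, the axial taper that every blob
   shows towards its poles (concentric contours of shrinking area but
   unchanged shape) dominates the measure and masks true shape
   alteration. Cut points 0.15 / 0.35.
3. **Maximum-uptake shift** — the largest consecutive-slice displacement
   of the per-slice uptake maximum, normalised by the nodule equivalent
   radius (radius of the circle matching the largest outer-contour
   area). Cut points 0.2 / 0.5. Because both features 2 and 3 are
   computed after centroid alignment or as *relative* displacement,
   bulk translation of the whole structure (respiratory drift) moves
   neither.
4. **Enclosing-contour size** — the largest area of the smallest contour
   around the per-slice maximum. "Small/medium/large" is inherently
   relative, so the default binning is cohort terciles, with fixed area
   cut points available for single-nodule runs.

Aggregation across slices is max for features 1, 3, 4 (the scales ask
for the highest degree / largest size) and mean for feature 2 (robust to
a single noisy pair). Undefined cases (fewer than two usable slices)
degrade to score 1 with a warning rather than failing the nodule.

None of the cut points can be inferred from published material — the
ordinal anchors there are verbal ("low/moderate/high") — so the defaults
above are declared package constants, frozen before the acceptance
experiments and shared by every consumer of the config.

## GDM2 and the pattern object

GDM2 compares objects only through the signs of coordinate differences
against every member of the analysed set, which makes it the right
distance for ordinal scales — and makes every distance context-dependent:
**adding or removing cohort members changes all distances**. The context
here is the analysed cohort plus the pattern object, nothing else.

The pattern object's coordinates are the scale maxima on the stimulant
variables (4, 3, 3) — the standard upper-pole pattern of linear-ordering
analysis. A neutral variable has no preferred direction, yet its printed
weight (0.05) must enter somewhere; the package sets its pattern value to
the scale midpoint 2 (configurable). Keeping the pattern inside the
context set is the default; a leave-pattern-out variant (the l-sums
restricted to the cohort) is exposed as `include_pattern = FALSE`. The two
differ only through the pattern's own terms in the normalising sums; with
the pattern out and an all-tied cohort the denominator can vanish, which
the package reports as an explicit degeneracy error. Distances are not
rescaled after computation — GDM2 is already bounded in [0, 1].

Ties and determinism: the maximum-gradient segmentation takes the three
largest consecutive gaps of the sorted distances; equal gaps are broken
toward the smaller index, and boundaries sit at gap midpoints. Reported
percentages are rounded to one decimal, half away from zero.

A note on monotonicity: it is tempting to assume that dominating another
record on all stimulant variables guarantees a smaller distance to the
pattern. Because of context dependence this is not a theorem of GDM2; on
the exhaustive 108-record grid the anti-pattern record (1, 1, 1, ·) does
attain the maximum distance and the pattern profile attains 0 (both
asserted in the tests), but the package does not claim the general
dominance property.

## The phantom generator: what it emulates, what it does not

A phantom is a uniform lung background plus one or more Gaussian uptake
foci inside a nodule of radius 5–15 mm, plus additive Gaussian noise
clipped at zero — the simplest controllable perturbation; Poisson count
statistics, attenuation, scatter and motion are explicitly not modelled.
Malignant-like phantoms draw several foci stacked at three or more
amplitude levels, each drifting in-plane across slices; benign-like ones
a single stable focus. The regimes are frozen in
`inst/extdata/cohort_regimes.json` (64 × 64 × 14 grids at the scanner
geometry 3.6458 mm in-plane / 3.3 mm slices).

One modelling addition matters: each cohort phantom contains a
*reference structure* — a hot Gaussian column standing in for the
mediastinal blood pool, placed away from the nodule. Real thoracic slices
almost always contain tissue hotter than the nodule, so per-slice min–max
normalisation leaves the nodule peak at an intermediate gray band and the
number of contour levels it spans carries information (the nodule's
metabolic contrast). Without a reference, the nodule itself is the slice
maximum, every peak normalises to 1.0, and the nesting feature saturates
for all nodules alike. The reference is optional and absent by default in
hand-built phantoms, so the generator's elementary contracts (a zero-focus
phantom is exactly the background, the argmax of a static focus sits at
the focus centre) hold verbatim.

Because the reference, not the nodule, is the global SUV argmax, the
synthetic-cohort pipeline passes the nodule boxes from the generation
manifest as manual VOIs — the same override path a clinician's drawn
rectangles would use. The automatic VOI is exercised on reference-free
phantoms.

What passing the phantom tests shows: the pipeline measures what the
generator encodes (contrast, heterogeneity, drift) and the GDM2 ordering
separates the two regimes at the published 0.4 threshold. What it cannot
show: performance on real FDG-PET, where texture, motion, partial-volume
effects and biological variability are far richer than two parametric
regimes.

## Problem sizes and reproducibility

The test suite and acceptance script use: the exhaustive 108-record
ordinal grid plus 1,000 random cohorts (n ≤ 30) for the GDM2 oracle
equivalence at 1e−12; 1,000 random distance vectors (n ≤ 50) against
exhaustive boundary-triple search; and a 40 + 29 phantom cohort for
end-to-end label recovery (≥ 90 % agreement required; the frozen regimes
achieve 98–100 % across seeds). Every random quantity is driven by a
single seed; phantom voxel data are byte-identical across reruns of the
same seed.

## Known limitations

- The feature proxies are calibrated on the phantom regimes, not on
  clinical images; the visual-scoring path (`read_feature_table()`)
  exists precisely so human scores can replace them.
- GDM2 distances shift when the cohort changes; single-nodule scoring
  against a fixed reference cohort is not implemented.
- The DICOM codec is deliberately minimal (single-frame, Explicit VR
  little endian, the tags the SUV formula needs). It round-trips its own
  files bit-exactly and is read back verbatim by pydicom, but it is not
  a general DICOM implementation.
- Contours are strictly per-slice; no volumetric (3-D surface) contour
  analysis is attempted.
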