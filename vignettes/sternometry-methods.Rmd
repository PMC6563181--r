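---
title: "Automated sternal osteometry: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated sternal osteometry: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sternometry)
```

## The problem

Sex estimation from skeletal remains is a core task of forensic
anthropology, and the sternum — a comparatively well-preserved bone — is a
useful sex indicator when measured osteometrically. Five standard
measurements are taken on 2D projections of the two sternal segments:

* on the **manubrium**: its length **M** (from the superior border point
  midway between the jugular and clavicular notches to the manubriosternal
  junction) and its width **MW** (along the line through the first costal
  notches);
* on the **sternal body (corpus)**: its length **B** (manubriosternal to
  mesoxiphoid junction) and two widths, **CSW1** at the level midway
  between costal notches 2 and 3 and **CSW2** midway between notches 4 and
  5.

Three indices are derived: the sternal index `SI = 100 M / B`, the sternal
area `SA = (M + B)(MW + CSW1 + CSW2) / 3` (cm²) and the combined length
`CL = M + B`. Sex is then estimated with linear discriminant functions of
these variables: the package ships nine published functions (coefficients,
constants and sectioning points; scores above the sectioning point classify
as male), supports refitting on new samples, and quantifies
manual-vs-automatic method agreement.

This vignette documents the models and numerical choices behind each
stage, the synthetic phantom that underpins validation, and what the
validation does and does not show.

## Segmentation model

The silhouette of a bone is recovered in four stages, each with its own
parameters (`segmentation_params()`):

1. **Adaptive threshold on local areas.** A pixel is foreground iff its
   intensity exceeds the mean of its local window (default 31 px, clipped
   at image edges) by more than an offset (default 0.07 on a 0–1 intensity
   scale). Local-mean thresholding responds to *edges*: for a bone wider
   than the window the interior equals its own local mean, so the
   foreground is a band along the cortical rim rather than a filled
   region. The rest of the pipeline is designed around this: the band is
   closed and filled downstream.
2. **Border filtering by topological potential.** Border pixels of the
   mask are scored with a Gaussian-kernel-weighted count of nearby border
   pixels (kernel scale 2.5 px, acceptance threshold 3, both tunable).
   Isolated speckles score near zero and are removed; dense borders
   survive and are grouped into 8-connected chains. On images up to
   32×32 the implementation is tested against an exhaustive per-pixel
   oracle.
3. **Break reconstruction.** Chains that do not enclose an interior are
   open; their endpoints are the two graph-diameter extremes of the
   chain's pixel graph (a double breadth-first search), which is robust
   to pixel-thick tips and frayed noise offshoots. Endpoint pairs within
   the maximum gap (default 24 px) whose outward tangents are compatible
   with the bridge (cosine ≥ 0.5 at both ends) are joined by straight
   segments, greedily nearest-first, no endpoint used twice.
4. **Contour tracing and classification.** Each chain that encloses an
   interior is filled and its boundary traced into a closed polygon with
   quality features: shoelace area, area-weighted centroid, perimeter,
   mean interior intensity, interior-vs-surround contrast, elongation
   (major/minor axis ratio) and solidity (area over convex-hull area). A
   contour is accepted iff every feature is inside its configured bounds;
   among accepted contours the largest is returned (ties: higher interior
   intensity, then smaller centroid row). If nothing survives — the
   typical cause is a border break that leaves a closed but leaking chain
   network with no endpoints to bridge — a morphological-closing rescue
   pass (dilate–fill–erode, radius 3) seals pin-hole leaks and re-traces;
   the rescue only seeds from substantial chains (≥ 64 px) so that
   speckle cannot be sealed into fake silhouettes.

Segmentation involves no randomness: identical images and parameters give
identical contours.

Default classifier bounds (area ≥ 1500 px², interior intensity ≥ 0.35,
contrast ≥ 0.15, elongation ≤ 6, solidity ≥ 0.75) were chosen from the
geometry of adult sterna at the default pixel spacing (0.05 cm/px) and
verified by the training protocol below; they reject small bright
distractors (area), hollow ring-like structures (interior intensity), and
noise-sealed blobs (contrast).

## Landmark model

An accepted contour is resampled to uniform arc length (step 1.25 px),
offset half a pixel along the outward normal (traced boundaries run
through pixel centers, half a pixel inside the physical intensity edge),
and lightly smoothed (3 samples for geometry; 9, applied twice, for
curvature). Curvature is computed by central differences on the closed
polygon; notches are local curvature minima below −0.025 px⁻¹.

The anatomical frame uses a prior: the corpus is elongated cranio-caudally
(principal major axis), the manubrium is broader than long (principal
minor axis). Both bones are wider superiorly, which orients the axis; for
the corpus the orientation is additionally checked against the expected
costal-notch layout (notches 2–5 at fractions 0.18/0.42/0.66/0.90 of the
length), because a strongly flaring lower body can defeat the end-width
cue. Left/right notch candidates are paired by axial position (tolerance
0.07 of the length) and assigned one-to-one to the expected slots
(tolerance 0.10); a missing notch falls back to its expected position with
reduced confidence, and a contour with no notch pairs at all is flagged
(confidence 0) rather than fatal — only the manubrium's jugular,
clavicular and first costal notches are strictly required, since M and MW
are undefined without them.

Measurement endpoints:

* **B**: midpoints of the two end caps. The transverse midline is the
  midpoint of the full-width chord 10 px inside the extreme (insensitive
  to cap dents); the axial position is the upper convex hull of the cap
  boundary evaluated at that midline, which bridges inward break dents.
* **CSW1/CSW2**: outer width at the level midway between the assigned
  notch pairs. The baseline is the exact line–polygon chord; a local
  inward dent is stepped over by taking the outermost border position in
  a ±6 px band, then a ±18 px band; a residual one-sided deficit larger
  than 3.5 px — measured against a robust straight midline fitted to
  full-width chord midpoints along the axis — is resolved by mirroring
  the intact side (the sternum is bilaterally symmetric).
* **M**: from the superior border point at the transverse position midway
  between the jugular and the (more lateral) clavicular notch — evaluated
  on the outer hull of the superior border, again to step over dents — to
  the inferior cap midpoint (the manubriosternal junction is treated as
  the inferior extreme midpoint of the bone, since it is a between-bone
  landmark not visible on a single-bone image; its confidence reflects
  this).
* **MW**: the chord along the line through the two detected first-costal
  notch centers (the defining section line), clipped to the contour. Using
  the actual notch-to-notch line rather than a frame-horizontal line
  self-corrects residual frame tilt.

Each measurement is the Euclidean landmark distance × pixel spacing (cm).
Where alternate candidate estimates exist (cap fits vs raw extremes,
detected vs expected width levels), the candidate lengths are reduced by
one-dimensional single-linkage clustering with a gap threshold of 5% of
the median candidate: within a cluster the highest-confidence candidate
wins, and the winner of the most populous cluster is reported. In clean
images all candidates agree and the primary estimate is returned
unchanged; the clustering exists to out-vote artifact-corrupted
candidates.

## Parameter training

`tune_parameters()` evaluates a parameter grid exhaustively: for each
parameter set every training image is segmented and measured, and an image
counts as a success when *all* its measurements fall within a relative
tolerance (default 5%) of the reference (phantom truth or manual record).
Efficiency is the success fraction; the argmax parameter set is returned,
ties toward the earlier grid entry. The default grid crosses threshold
windows {31, 25, 37} with offsets {0.07, 0.05, 0.10}, defaults first. The
5% tolerance operationalizes "efficiency", which the source material for
this package's protocol does not define formally; it echoes the reported
discrepancy bound.

## Sex estimation

`fit_discriminant()` implements the classic two-group Fisher rule: the
coefficient vector is proportional to the inverse pooled within-group
covariance times the group mean difference, scaled so the pooled
within-group score variance is 1 (the usual "unstandardized coefficient"
convention); the constant centers the grand-mean score at zero; the
sectioning point is the unweighted midpoint of the group mean scores
(equal priors, standard in osteometric work; a prior-weighted point is
available via `prior_weighted = TRUE`); orientation is normalized so males
score higher. Scores exactly at the sectioning point are indeterminate by
default because the published rules define only strict inequalities.
`loocv_classification()` refits on each n−1 subset (leave-one-out) or
applies a fixed function; reported per-sex rates are combined into an
overall rate weighted by group sizes. `sex_difference_test()` uses the
pooled-variance (Student) t test — the conventional reading of an
unqualified "t test" — with Welch's form behind a flag.

## Method agreement

`agreement_summary()` reports, per measurement: the mean distance (mean
absolute manual−automatic difference over subjects matched by id),
the percentage discrepancy (100 × mean distance / mean automatic value —
the automatic mean is the documented denominator, switchable to the
manual mean), a two-tailed paired t test (a zero-variance difference
vector leaves t missing rather than infinite), and an 11-bin equal-width
histogram of the signed differences, whose bin widths therefore vary
across measurements with their ranges; a degenerate all-equal difference
vector is widened by a machine-epsilon-scaled margin so the single bin is
well defined.

## The synthetic phantom

No imaging data are distributable with the package, so every stage is
validated against a synthetic phantom with exactly known ground truth.

**Population.** `population_spec()` draws the five measurements from
per-sex multivariate normals with a single inter-measurement correlation
(default 0.5, a typical inter-trait correlation for skeletal
measurements). The published reference sample reports only pooled moments
(M 5.25 ± 0.57, MW 5.63 ± 0.53, B 9.46 ± 1.60, CSW1 2.66 ± 0.37, CSW2
3.11 ± 0.59 cm; 73 men, 55 women), so the sex split is derived from
per-measurement standardized separations back-solved from the published
single-variable classification accuracies (Δ = 2·Φ⁻¹(accuracy), giving
Δ = 0.94–1.89 across measurements); the within-sex SD is then chosen so
that mixing the sexes at the reference sample sizes reproduces the pooled
moments exactly. Deep-tail negative draws are rejected and redrawn.

**Geometry.** `render_phantom()` builds a smooth outline per bone: the
corpus is a vertical blade between half-elliptic end caps whose half-width
profile is splined through the two width constraints, with cos² costal
notches 2–5 on both sides; the manubrium is a trapezoid narrowing
inferiorly with a jugular notch and two clavicular notches on the superior
border and the first costal notches on the lateral borders; its vertical
extent is solved so that the M landmark pair is exactly the requested
length. All landmark pairs reproduce their requested lengths to 10⁻⁶ cm
by construction. Intensities mimic a CT projection: dark background
(0.12), trabecular interior (0.55), brighter cortical rim (0.86, 4 px
wide), light speckle (SD 0.02).

**Corruption.** `corruption_spec()` adds, in order: border breaks (arcs of
the outline erased to background over a disk of half-width 5 px — the
classic low-contrast failure mode that severs the rim and leaves inward
detours), bright distractor blobs away from the bone, a linear intensity
gradient, and Gaussian noise. Defaults (2 breaks × 12 px, 2 blobs r = 5,
gradient 0.06, noise SD 0.035) were fixed once as the study's corruption
conditions. An all-zero specification is the identity.

**What the phantom does not emulate.** Real projections have
partial-volume blur, anatomical asymmetry and shape variation beyond the
five measured lengths, overlapping structures (ribs, clavicles),
calcification, and reslicing-angle errors. Passing the phantom batches
therefore shows that the pipeline recovers the defined landmarks
accurately under noise, border breaks and distractors on anatomically
plausible silhouettes — not that it would reach the same accuracy on
clinical images. Conversely the break-dent robustness (hull caps, banded
widths, symmetry fallback) is exercised hard by the corruption model.

## Problem sizes and determinism

The validation batches mirror the reference protocol: 126 corrupted
phantoms (63 corpus + 63 manubrium) for the discrepancy analysis, 35
corrupted corpus phantoms for parameter training, n = 10 000 per group for
discriminant recovery, and 1 000 random records for the index invariants.
Every stochastic step is seeded: the population seed, per-image render and
corruption seeds derived from one master seed, and fixed seeds in the test
suite. `scripts/acceptance.R` reruns the full analysis from any seed.

## Known limitations

* One bone per image; multi-bone scenes are out of scope beyond
  distractor rejection.
* DICOM is not read directly; export to TIFF and pass the pixel spacing
  (DICOM reports mm; the package works in cm).
* The bilateral-symmetry fallback for width measurements assumes a
  roughly symmetric bone; a genuinely asymmetric pathological sternum
  with a one-sided border artifact could be mis-measured.
* The manubriosternal junction on single-bone images is approximated by
  the inferior extreme midpoint; on real bones the junction surface is
  oblique and this is a simplification.
* Classification rates from refitted functions on phantom populations
  reflect the synthetic dimorphism model, not a new population standard.
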