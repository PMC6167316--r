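---
title: "Measuring larval tail regeneration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring larval tail regeneration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailquant)
```

`tailquant` quantifies zebrafish larval tail regeneration from calibrated
2-D micrographs.  After tail excision, a stereotyped sequence unfolds:
the trunk contracts along the anterior-posterior axis, notochord cells
are squeezed out of the sheath onto the stump (the "notochord bead"),
reactive oxygen species (ROS, chiefly H~2~O~2~) flare along the wound
edge, and over the following days a wound epithelium and blastema form
and the tail regrows.  Each of those events has a quantitative readout,
and this package implements the full set behind one shared data model:
blinded scoring, stain-area measurement, wound-ROS scoring, membrane
curvature, morphometry, and mitotic-figure counting.

All images are assumed oriented anterior-left and dorsal-up, so the
x axis points towards the wound (posterior) and anterior means smaller
x.  Coordinates are 0-based, origin top-left, with the centre of matrix
pixel `[r, c]` at `(c - 0.5, r - 0.5)`.  Pixels must be isotropic; every
physical quantity is derived from a single pixel size in µm/px, read
from TIFF resolution metadata or supplied explicitly.  Anisotropic
metadata is rejected rather than averaged, because every formula below
assumes isotropy.

## Blinded analysis

`blind_folder()` duplicates a folder of images under random zero-padded
six-digit codes (extensions preserved) and writes a bijective key table;
`unblind_table()` maps scored results back to the original names.
Without a seed the codes are entropy-seeded — that is the point of
blinding — while a seed makes keys reproducible for pipelines and tests.
Originals are never modified.

## Stain area by RGB windowing

Chromogenic in situ signal (oxidised BCIP, a blue precipitate) is
segmented by per-channel intensity windows: a pixel is selected iff its
R, G and B values each fall inside `[min, max]`, *bounds inclusive on
both ends*.  Whether the original interactive workflow treated its
bounds as inclusive is not recorded anywhere we could verify, so
inclusivity is fixed and documented here to keep results bit-stable.
Windows are calibrated per staining experiment (enzymatic staining
strength varies between rounds) and then held constant across the whole
batch — `quantify_stain_batch()` deliberately accepts a single threshold
and no per-image overrides, because comparability within a batch is the
property the measurement depends on.  Artefacts (bubbles, debris) are
excluded via polygon ROIs rather than interactive mask edits, so the
exclusion step is reproducible.  `preview_threshold()` writes an overlay
for the visual trial-and-error calibration of the windows.

## Wound-ROS score

`quantify_wound_ros()` computes

$$ S = \operatorname{mean}\big(F \mid d \le 50\,\mu m\big) -
       \operatorname{median}\big(F \mid 1000 \le d \le 1100\,\mu m\big) $$

where $F$ is the reporter fluorescence and $d$ the distance from the
wound edge.  Subtracting the trunk median controls for each embryo's
basal oxidative state, which makes the score exactly invariant under a
uniform intensity offset and linear in a gain change.

Design choices where the assay description leaves room:

* **Embryo outline.** Otsu's criterion on the brightfield histogram,
  polarity chosen so the embryo is the class under-represented on the
  image border (the border is background and the embryo is darker),
  then the largest 8-connected component with holes filled.  A
  user-supplied mask overrides detection, which also guarantees
  testability of the downstream arithmetic.
* **Wound edge.** The boundary arc within 25 µm of the maximal-x extent
  of the mask — the amputation stump is the posterior-most tissue under
  the anterior-left convention.  The window is configurable because
  amputation planes are not always exactly vertical.
* **Distance.** Geodesic *within the embryo mask*, not straight-line,
  so a concave fin fold cannot short-cut the path from wound to trunk.
  Distances come from a 5×5-neighbourhood chamfer propagation (step
  weights 1, √2, √5) iterated to convergence.  The chamfer metric never
  underestimates the true geodesic distance and overestimates by at
  most about 2%; it is exact along axis-aligned directions, which is
  also how the rectangle-embryo oracle fixtures are laid out.  Knight
  moves require an intermediate in-mask pixel and diagonal moves an
  adjacent orthogonal one, so paths cannot tunnel through one-pixel
  walls.
* **Trunk reference.** The assay fixes the offset (1 mm distal) but not
  the size or shape of the reference area.  A 100 µm-deep geodesic band
  is used by default; the median is robust to the exact depth, and the
  depth is a parameter (`trunk_band_um`).

## Membrane curvature

Notochord cell membranes bow anteriorly, then posteriorly, within
minutes of excision.  Bowing is scored by the signed Menger curvature of
a three-point "membrane triple": the two sheath contacts and the apex
(the membrane point furthest from the chord between the contacts).  The
magnitude is the inverse circumradius,

$$ |\kappa| = \frac{4A}{abc}, $$

with $A$ the triangle area and $a, b, c$ the side lengths in µm.  The
sign is positive for a posterior bow and negative for an anterior bow.
Numerical decisions:

* **Sign from apex laterality, not circumcentre position.**  The two
  rules agree for any circle, but the circumcentre runs off to infinity
  as the membrane straightens, while the apex's side of the chord stays
  perfectly well-conditioned.
* **Collinearity tolerance.**  The straight-membrane case must be
  reachable in floating point: when the sine of the apex angle
  ($2A/(|AP||BP|)$) falls below 1e-9 the curvature is exactly 0 with
  sign 0 and infinite radius.
* **Degenerate chord.**  For a chord lying exactly parallel to the body
  axis there is no anterior/posterior side; the magnitude is reported
  with positive sign.  This cannot occur for real membrane triples,
  whose chords run across the notochord.
* **Cell selection** (`select_measurement_cell()`) mirrors the manual
  rule: among traces spanning the notochord width and not bent by
  contact with a neighbour, take the one nearest the 600 µm line
  anterior of the stump; the apex is the chain point furthest from the
  chord, ties broken by smallest y (dorsal-most), a tie-break fixed
  here because the original procedure does not record one.

## Morphometry

Tail length (anus to caudal end of the fin fold), regrowth (end of the
notochord to the fin fold tip) and trunk spans are all axial
projections: `measure_axial_length()` projects the landmark difference
onto the body-axis direction, so displacement perpendicular to the axis
does not perturb the measurement — the programmatic equivalent of the
rectangle-parallel-to-the-body measuring convention.
`measure_contraction()` takes the span between one named landmark pair
(somite boundaries roughly eight somites apart) before and two hours
after excision and reports $100 (L_{pre} - L_{post}) / L_{pre}$ percent.
The assay measures a single distance across ~eight somites rather than
per-somite distances, so the operation takes one landmark pair; the
generator still lays down eight somite-boundary proxies so synthetic
spans have realistic structure.  Which landmark types bounded the span
originally (somite boundaries or pigment cells) is not recorded, so any
named pair is accepted.  Bead area is the shoelace area of a traced
polygon, pixel-centre rasterisation follows the even-odd rule, and
degenerate polygons return zero area with a warning.

## Mitotic-figure counting

Phospho-histone-H3 maximum-intensity projections (`max_project()`) are
thresholded (Otsu, or an absolute intensity), components are labelled
with 8-connectivity, and a spot counts iff its area *strictly exceeds*
50 µm² and its centroid lies *within (inclusive)* 500 µm of the caudal
reference point.  "Greater than" is read literally as strict and
"within" as inclusive; both live in `spot_filter_params()` so the
reading is auditable and adjustable.  Distance is measured from the
spot centroid to a caudal *point* landmark; a distance-to-amputation-
plane variant was considered and deliberately left out.  The original
counts were produced in a commercial package; this module is an open,
parameterised replacement for that step.

## What the synthetic fixtures do and do not show

Every stage has a seeded generator with a machine-readable manifest
(`gen_wound_embryo()`, `gen_stain_image()`, `gen_membrane_triples()`,
`gen_contraction_pair()`, `gen_spot_image()`).  Two conventions make
the manifests exact oracles:

* Disks and silhouettes are rasterised by pixel-centre inclusion and
  the manifest records the *rasterised* pixel count, not the analytic
  area, so noiseless area assertions are exact (`gen_spot_image()`
  additionally trims/extends the disk boundary to hit the requested
  pixel count exactly — this is how a spot of exactly 50 µm² is
  constructible).
* Noise is additive Gaussian, rounded and clipped to the intensity
  range, with σ = 0 default for unit tests; the same seed reproduces
  pixels bit-identically, and generators restore the caller's RNG
  state.

Default fixture calibration is 1 µm/px so physical and pixel units
coincide; original acquisition pixel sizes are not recorded anywhere we
could use, and all thresholds are expressed in physical units so the
choice is free.  The contraction generator's ground-truth presets
(`contraction_presets()`: untreated 4.4%, DPI 1.7%, PP2 1.2%) are the
group means the study conditions define; landmark jitter of σ = 2 µm on
an 800 µm span gives recovered-contraction noise of about 0.35
percentage points per pair, so 30 pairs estimate the mean to well
within ±0.3.

The fixtures are deliberately not photorealistic: no optics or PSF
simulation, no autofluorescence gradients, no pigment texture, no
z-stacks (projections are taken as inputs), and embryo silhouettes are
truncated ellipses rather than traced larvae.  Passing the recovery
tests therefore shows that the *measurement arithmetic* is correct and
unbiased under the stated noise model — it does not validate embryo
outline detection against real brightfield variability, nor threshold
choices against real staining chemistry, which remain
operator-validated steps (hence the preview and provided-mask paths).

Problem sizes were chosen so the whole suite runs in well under a
minute of compute per module: the default wound scene is a
2200 × 360 µm frame (~0.8 Mpx), unit-test scenes 1600 × 240 µm, the
Monte-Carlo recoveries use 20-30 seeded replicates, and the curvature
equivalence check runs 1000 random triples against an exact
circumcircle solver.

## Known limitations

* The chamfer geodesic distance carries ≤ ~2% metric error off-axis;
  band memberships within that margin of the 50/1000/1100 µm cut-offs
  can differ from an exact Euclidean-geodesic implementation.
* TIFF calibration metadata round-trips through a single-precision
  resolution rational: calibrations are preserved to 7 significant
  digits.
* PNG carries no physical calibration and 16-bit PNG output is not
  supported; TIFF is the preferred interchange format.
* `polygon_roi()` does not verify simplicity; self-intersecting
  polygons follow even-odd semantics rather than erroring.
* Group-comparison statistics are out of scope by design: results are
  exported as tidy CSV for external statistical software.
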