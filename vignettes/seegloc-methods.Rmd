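---
title: "Models and methods behind seegloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seegloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seegloc)
```

seegloc implements the computational core of an SEEG
electrode-localization workflow: electrode placement, contact labeling,
resection quantification, cohort queries and group-level parcellation
quality control. This vignette explains the models, the parameters that
matter, the numerical choices, and what the synthetic fixtures do and do
not demonstrate.

## Coordinate conventions

All volumes are `volume3d` objects: a 3D array plus a 4×4 affine mapping
**0-based voxel indices** (voxel centers) to world millimetres, RAS
oriented — the NIfTI convention. Rigid world-to-world transforms are
validated to 1e-6 orthonormality and determinant +1; reflections are
rejected. Resampling is nearest-neighbour only: every volume the pipeline
consumes (atlas labels, tissue classes, binary masks) is categorical, and
interpolating categories is meaningless. Voxels that map outside the
source grid become 0, never an edge value, because 0 uniformly means
"background/unlabeled" across all volume kinds.

## Electrode model and placement

An electrode model is an ordered list of segments
`(n_contacts, contact_length_mm, gap_after_mm)` plus a shaft diameter and
an optional `tip_offset_mm` (default 0). Within a segment, consecutive
contact centers are `contact_length + gap_after` apart; the segment's
`gap_after` also separates it from the next segment, so grouped layouts
(e.g. three groups of five) are encoded by giving the last contact of a
group its own single-contact segment carrying the larger inter-group gap.
Placement from a trajectory (tip point plus any shaft point) is pure
arithmetic along the unit vector, so it is exactly equivariant under rigid
transforms; the suite checks this to 1e-9 mm. Contact 1 starts at the tip
— manufacturers differ in the tip-to-first-contact distance, which is why
`tip_offset_mm` exists, but 0 is the default because no universal value
exists. The bundled JSON catalog is explicitly *illustrative*: real
manufacturer geometries must be supplied by the user.

## Sphere-vote labeling

A contact is labeled by the modal atlas label among voxels whose centers
lie within `label_radius_mm` (default 3 mm) of the contact center.
Membership is decided on voxel centers, not partial volumes, which keeps
an exhaustive lattice count an exact oracle (123 voxels at radius 3 on a
1 mm grid). For atlases flagged *cortical* in their lookup table, only
gray-matter voxels with a nonzero label vote. This is deliberate: a
contact at the gray–white interface whose sphere is mostly white matter
should still be attributed to the adjacent cortical parcel. The flag is
per-atlas metadata rather than hard-coded, because whole-brain atlases
(e.g. maximum-probability maps) should not be gray-matter-restricted.

Two defaults coexist on purpose: 3 mm **radius** for atlas/tissue labels
and 1.5 mm radius (3 mm **diameter**) for statistical-map means. Both are
arguments, not constants.

Determinism demands explicit tie-breaks: smallest label id for atlas
votes, fixed priority GM > WM > CSF for tissue votes. Resection
membership uses the single containing voxel rather than a sphere vote —
it is a binary in/out question and the cheapest deterministic reading.

## Resection pipeline

`compute_resection` = resample post-op mask → logical difference →
morphological opening → 26-connected components → keep the seeded
component. The opening uses the smallest reasonable structuring element (a
6-connected cross, radius 1 voxel, one iteration): it removes the
1-voxel misregistration fringe the difference image inevitably carries
while preserving small resections; element iterations and component
connectivity (6/18/26) are exposed as arguments. Connectivity 26 is the
default because resection cavities with diagonal-touching voxels should
not split. The morphology is implemented in-package with array shifts and
is verified against an explicit-loop oracle: the canonical check is a 5³
block whose opening is 81 voxels (the 3³ erosion core dilated into six
3×3 face extrusions).

Overlap percentages (`100 × |parcel ∩ mask| / |parcel|`) are reported
with `brain_shift_unreliable = TRUE`: the pipeline ignores post-surgical
brain deformation, so percentages are indicative, not quantitative.

## Cohort store

The store persists complete patient records as a single JSON document
file. JSON was chosen over an embedded relational database so that the
store is portable, diffable and dependency-free; serialization is
deterministic (patients sorted by id, full numeric precision), making
save→load→save byte-identical — a property the suite asserts and that
makes cohort files usable in version control. Stimulation semantics use
closed vocabularies (frequencies 1/50 Hz; response categories
not_stimulated / no_response / response_non_epileptic / seizure_like;
semiology classifications motor, sensitive, sensory, vegetative,
emotional, experiential, superior_function) in explicit CSV columns. On
clinical stimulation sheets these are traditionally encoded as colors
(gray = not stimulated, black = no response; red motor, blue sensitive,
green sensory, yellow vegetative, purple emotional, pink experiential,
brown superior function); colors are presentation, not data, so the
import format makes the categories explicit.

`query()` is a conjunction of optional criteria with brute-force-filter
semantics. "Parcel at least partially resected" means overlap percent
strictly greater than 0 by default (`min_percent` overridable). A bipole
"is in" a parcel if either of its two contacts is labeled with it
(`both_contacts = TRUE` tightens this).

## Group QC statistics

For each parcel the MNI positions of all contacts labeled with it are
pooled across patients.

**4×MAD rule.** With `d_i` the Euclidean distance of point *i* to the
component-wise median position, the robust scale is
`MAD = median(|X_i − median(X)|) = median(d)`, and a contact is flagged
when it lies *further than four times the MAD* from the median:
`d_i > 4·MAD`. Distances (rather than per-axis coordinates) make the rule
rotation invariant; a per-axis variant is available. For a tight 3D
Gaussian cluster the threshold sits near 6 sigma, so false flags on clean
data are vanishingly rare, while a 40 mm mis-normalization exceeds it by
an order of magnitude.

**Chauvenet criterion.** Per axis, flag when
`n · erfc(|x_i − mean| / std) < 0.5`, with the *population* standard
deviation (stated explicitly because the choice changes flags at small
n). The residual is deliberately **not** divided by √2: the criterion is
applied exactly in this printed form, which is markedly more aggressive
than the textbook Chauvenet test; `classic = TRUE` restores the √2. Two
consequences are worth knowing. First, the criterion is scale invariant,
and on *clean* Gaussian data it rejects on the order of a quarter point
per axis by construction — an uncontaminated parcel cloud can therefore
produce occasional flags no matter how tight it is. Second, when genuine
outliers contaminate the cloud they inflate the standard deviation, which
paradoxically *protects* the clean points; in the planted-outlier
scenarios this makes the criterion exact. Both detectors require n ≥ 3;
smaller parcels are reported as "insufficient data", never silently
flagged.

The QC report emits one row per flagged contact per method ("each patient
having a [flagged] contact should be considered suspicious"), so
patient-level aggregation is a trivial `unique()` on the patient column.

## Synthetic fixtures: what they emulate

The generators produce, deterministically per seed:

* a **head** of nested ellipsoids — WM core (normalized radius ≤ 0.45),
  GM shell (0.45–0.85), CSF rim (0.85–1) — in a 64³ grid at 1 mm
  (defaults), world origin at the brain center;
* an **atlas** partitioning the GM shell into 16 parcels (8 per
  hemisphere: 4 angular sectors × 2 depth bands). This granularity was
  chosen so parcel extent (~10–20 mm) matches real cortical
  parcellations; coarser wedges produce multi-modal per-parcel contact
  clouds unlike anything a real atlas yields;
* **implantations** of 12 electrodes × 15 contacts (≈180 contacts, the
  scale of a typical exploration), straight chords through the brain with
  a minimum 18° angular separation, each patient drawing its own
  trajectories — brains are sampled differently between patients, and
  per-parcel clouds consequently fill the parcel volume;
* **post-op masks** with an axis-aligned carved block and its exact
  ground-truth mask;
* **cohorts** (default 20 patients) with randomized center/year/Engel
  metadata, vocabulary-conformant stimulation events, MNI coordinates
  equal to contact positions plus a *per-patient* Gaussian normalization
  offset (σ = 2 mm — normalization error displaces a whole patient, not
  individual contacts), and `ceiling(0.1 · n)` planted outlier patients
  whose MNI coordinates are shifted +40 mm on every axis. One designated
  patient uniquely combines a contact in the cohort's most-implanted
  parcel with a resection of that same parcel, giving the combined
  contact-and-resection query a known single-patient answer.

Ground truth for labeling is recorded only for contacts whose 3 mm sphere
lies entirely within one parcel ("pure" contacts); boundary contacts are
"mixed" and excluded from agreement scoring, because their label
legitimately depends on the vote.

What the fixtures do **not** emulate: MRI intensities and segmentation
error, non-linear MNI normalization (the fixture frame doubles as
standard space through an identity mapping), brain shift, curved
electrodes, and anatomically shaped parcels. Passing tests therefore
demonstrate the correctness of the *computations* — vote counting,
morphology, statistics, query semantics — not the accuracy of upstream
segmentation or registration on clinical images.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on the sizes above:
64³ volumes, 180-contact implantations, 20–50-patient cohorts, 100–1000
randomized oracle comparisons per operation — a few minutes end to end on
one CPU. Every random draw is seeded; per-patient sub-seeds are derived
as `seed + 7919·i` (kept well below 2³¹). Reruns with the same seed are
byte-identical down to the gzipped NIfTI outputs.

## Known limitations

* Only rigid electrode models and straight trajectories; grids, strips
  and bent electrodes are out of scope.
* Transforms are inputs; no registration is estimated.
* Overlap percentages ignore post-surgical deformation (flagged in the
  report).
* The literal Chauvenet criterion flags ~0.25 points per axis on clean
  clouds by construction; treat its output as a screening list, not a
  verdict — which is also how the flagged-contact CSV is meant to be
  used clinically.
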