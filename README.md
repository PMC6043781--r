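# seegloc

Headless R toolkit for stereoelectroencephalography (SEEG) implantation
analysis: it localizes and anatomically labels depth-electrode contacts in
volumetric head images, quantifies surgical resections, stores implanted
patients in a queryable cohort database, and screens group-level
parcellations for suspicious contacts with robust outlier statistics.

It is aimed at epilepsy-surgery research groups who need the *computation*
behind electrode-localization GUIs — reproducible, scriptable, and testable
without any clinical data (a deterministic synthetic-fixture generator
builds heads, atlases, implantations and whole cohorts).

## What it computes

**Contact placement.** A depth electrode is a parametric model (ordered
segments of contacts of length *L* separated by insulating gaps *g*).
Given the tip point **t** and any shaft point **s** marked on the
post-implantation image, contact *i*'s center is

    c_i = t + u * (offset_i + L_i / 2),     u = (s - t) / ||s - t||

with `offset_i` the cumulative length of preceding contacts and gaps
(contact 1 starts at the tip; contacts are numbered tip-first, the clinical
convention).

**Contact labeling.** Each contact is labeled by a majority vote over the
voxels whose centers lie within a 3 mm-radius sphere around the contact
center. For cortical atlases only gray-matter voxels with a nonzero parcel
label vote — so a contact whose sphere is mostly white matter still
receives a cortical label if some parcel voxels are inside. Ties break
toward the smallest label id. The same sphere machinery yields the tissue
class (GM/WM/CSF majority, GM > WM > CSF on ties), statistical-map means
(default 1.5 mm radius), and resection membership (the containing voxel).

**Resection mask.** From pre- and post-operative brain masks:
resample the post-op mask onto the pre-implantation grid (rigid transform,
nearest neighbour), keep voxels present before but not after, apply one
morphological opening (6-connected cross, radius 1), label 26-connected
components, and keep the component containing a user seed point. Volume and
per-parcel overlap (percent of each parcel removed) follow directly; the
percentages ignore post-surgical brain shift and are flagged accordingly.

**Cohort store and queries.** Patient records (metadata, electrodes,
labels, overlap report, stimulation events with a closed response/semiology
vocabulary, MNI contact coordinates) persist in a single deterministic JSON
store. `query()` is a conjunction of criteria — center, year range, Engel
class, contact-in-parcel, parcel-at-least-partially-resected,
stimulated-parcel — with brute-force-filter semantics.

**Group QC.** For every parcel, the MNI positions of all contacts labeled
with it are pooled across patients and screened two ways:

* **4×MAD rule** — with `d_i` the distance of contact *i* to the
  component-wise median position and `MAD = median(d)`, flag contact *i*
  when `d_i > 4 × MAD`;
* **Chauvenet criterion** — per axis, flag when
  `n · erfc(|x_i − mean(x)| / std(x)) < 0.5` (population std; the residual
  is deliberately *not* divided by √2 — `classic = TRUE` restores the
  textbook form).

Flagged contacts suggest a wrong parcellation or MNI normalization for that
patient.

## Worked example

Everything below runs on synthetic data generated in-process:

```r
library(seegloc)

spec <- fixture_spec(seed = 1)              # 64 mm synthetic head, 1 mm iso
head3 <- make_head(spec)                    # tissue classes + brain mask
atl   <- make_atlas(head3$tissue, spec$n_parcels)
imp   <- make_implantation(atl$atlas, atl$lookup, seed = 1)   # 12 x 15 contacts

labels <- label_all(imp$electrodes,
                    atlases = list(synthatlas = list(volume = atl$atlas,
                                                     lookup = atl$lookup)),
                    tissue = head3$tissue)
head(labels[, c("electrode", "contact", "x", "y", "z",
                "synthatlas_name", "tissue")], 5)
#>   electrode contact     x      y      z synthatlas_name tissue
#> 1       E01       1 17.66 -3.431 17.099           P08_R    CSF
#> 2       E01       2 15.59 -2.825 14.341           P08_R     GM
#> 3       E01       3 13.52 -2.219 11.583           P08_R     GM
#> 4       E01       4 11.45 -1.613  8.825           P04_R     GM
#> 5       E01       5  9.39 -1.007  6.067           P04_R     WM
```

The deepest contacts sit in the white-matter core (`unlabeled` by the
cortical atlas), shallower ones traverse the gray-matter shell and pick up
parcel labels, and the most superficial reach CSF — the expected profile of
a depth trajectory.

```r
po <- make_postop(head3$mask, spec$resection_corner, spec$resection_size)
r  <- compute_resection(head3$mask, po$post,
                        seed = voxel_to_world(spec$resection_corner + 2, head3$mask))
parcel_overlap(r, atl$atlas, atl$lookup)
#> <overlap_report: 81.0 mm^3 resected, 4 parcel(s) affected; caveat: sensitive to post-surgical brain shift>
#>        atlas label  name parcel_voxels resected_voxels   percent
#> 1 synthatlas    10 P05_R          2477              11 0.4440856
#> 2 synthatlas    12 P06_R          2477              19 0.7670569
#> 3 synthatlas    14 P07_R          2477              32 1.2918853
#> 4 synthatlas    16 P08_R          2477              19 0.7670569
```

A 5×5×5 mm carved block survives the cross-element opening as 81 voxels
(3³ core plus six 3×3 face extrusions) and removes small fractions of four
right-hemisphere parcels.

```r
coh <- make_cohort(spec)                    # 20 patients, 2 planted outliers
qc  <- qc_report(coh$store, "synthatlas")
unique(qc$patient_id)
#> [1] "P006" "P015"
coh$truth$outlier_patients
#> [1] "P006" "P015"
```

Both planted mis-normalized patients (MNI coordinates shifted 40 mm) are
flagged by both detectors; no clean patient is flagged.

## Command line

The same workflow is exposed as the installed `seegloc` script
(`exec/seegloc`):

```sh
seegloc simulate --preset demo --seed 1 --out demo/
seegloc label --electrodes demo/electrodes.json \
    --atlas synthatlas=demo/atlas.nii.gz:demo/atlas.tsv \
    --tissue demo/tissue.nii.gz --out demo/labels.csv
seegloc resection --pre demo/brainmask.nii.gz --post demo/postop_mask.nii.gz \
    --transform demo/transform.txt --seed-point 18.5,0.5,0.5 \
    --atlas synthatlas=demo/atlas.nii.gz:demo/atlas.tsv \
    --out demo/resec.nii.gz --report demo/report.json
seegloc qc --db demo/cohort.json --atlas synthatlas --out demo/suspicious.csv
seegloc query --db demo/cohort.json --contact-in synthatlas:P04_R \
    --resected synthatlas:P04_R
```

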