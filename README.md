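# ieegloc — anatomical localization of implanted intracranial EEG electrodes

Patients evaluated for epilepsy surgery (and, increasingly, participants in
basic and translational neuroscience) are implanted with intracranial
electrodes: sEEG depth electrodes with 4–16 contacts along a thin shaft
(inter-contact spacing 4–10 mm, median 5 mm), and ECoG grids/strips lying on
the cortical surface. Interpreting anything those electrodes record requires
knowing, per contact, *which brain structure it is in* — in the patient's
own (native) space, relative to a parcellation and to the reconstructed
pial and white-matter surfaces.

`ieegloc` implements the computational stages of that localization workflow
for users who already have (a) a labelled parcellation volume (the
`aparc+aseg`-style output of a surface reconstruction with a DKT-style
cortical atlas plus subcortical segmentation), (b) pial/white triangle
meshes, (c) a color-LUT label table, and (d) manually picked contact
coordinates in RAS millimetres. Each stage is an independent function (and
CLI subcommand), so 2-D-only, basic and advanced outputs are compositions
of stages:

* **ELA (electrode labelling algorithm)** — probabilistic region
  assignment. An expanding cylinder is sampled around each contact (or
  bipolar pair): with radius schedule `r_k = k·r_max/K`, the probability of
  region `L` is the mean, over `k`, of the fraction of sample points inside
  radius `r_k` whose parcellation label is `L`:

  `P(L) = (1/K) Σ_k f_L(r_k)`,  `Σ_L P(L) = 1`.

  The reported region is the argmax over grey-matter (cortical or
  subcortical) labels; a contact whose grey probabilities are all zero is
  reported as white/outside with a fallback flag, and contacts near several
  structures carry multiple nonzero probabilities.
* **EVL (electrode volume labelling)** — volumetric five-way tissue
  classification. Watertight enclosing volumes are built per label
  (exact voxel-union boundary by default, lattice alpha complex as the
  alternative); each contact is classified by membership precedence
  subcortical → cortical grey → white → pial hull (surface contacts in
  sulci) → outside brain.
* **Brain-shift correction** — grids/strips are snapped onto the
  Taubin-smoothed pial surface by deterministically minimizing
  `E(x) = Σ_i ‖x_i − x_i⁰‖² + λ Σ_(i,j) (‖x_i − x_j‖ − d_ij⁰)²`
  subject to all contacts lying on the surface (projected Gauss–Seidel
  descent started from the naive projection; the energy trace is
  non-increasing and never worse than naive projection).
* **Measurements** — bipolar midpoints, nearest-vertex distances to the
  pial and white surfaces, recomputed inter-contact distances, shaft angle
  to the local cortical axis (area-weighted vertex normal), and
  per-trajectory tissue-class counts.
* **Reports and export** — per-contact multi-panel pages (three orthogonal
  MRI views plus an oblique reslice along the shaft) collated into a
  shareable PDF, per-label STL export, and iEEG-BIDS
  `electrodes.tsv` + `coordsystem.json`.
* **Synthetic phantom** — a labelled spherical head (pial/white spheres,
  azimuthal cortical wedges, subcortical blobs) with an analytic
  ground-truth function, so every stage above is testable end to end with
  known truth and no clinical data.

All coordinates live in one working frame (scanner RAS mm of the
pre-operative volume); FreeSurfer's surface-RAS offset is applied at read
time when a companion volume is supplied, and every container carries a
frame tag so accidental mixing is detectable.

## Worked example

```r
library(ieegloc)
head <- make_head()   # 60/50 mm spheres, 8 wedges, 2 blobs, 1 mm voxels
ra <- make_depth_electrode(head, entry = c(75, 35, 10), target = c(15, 7, 2),
                           n_contacts = 8, spacing_mm = 5, name = "RA")
probs <- ela_label_contacts(ra, head$parcellation, head$labels)
cls   <- classify_contacts(ra, head$parcellation, head$labels, head$pial)
data.frame(contact = probs$contact, ela = probs$assigned$name,
           p = round(probs$assigned$probability, 3),
           evl = cls$class)
```

```
 contact                   ela     p           evl
       1    Subcortical-blob-2 0.146         white
       2    Subcortical-blob-2 0.070         white
       3 Cerebral-White-Matter 1.000         white
       4 Cerebral-White-Matter 1.000         white
       5 Cerebral-White-Matter 1.000         white
       6 Cerebral-White-Matter 1.000         white
       7 Cerebral-White-Matter 1.000         white
       8           ctx-wedge-5 0.852 cortical_grey
```

The deepest contacts (1–2) sit in white matter a few millimetres from a
subcortical blob: the probabilistic route reports the *nearest grey*
structure with a small probability (0.146) while the volumetric route calls
them white — exactly the kind of white/grey disagreement expected between a
proximity-based and a membership-based labelling. Mid-shaft contacts are
unambiguous white (fallback flagged, p = 1), and the most superficial
contact lands in cortical wedge 5 with p = 0.852 by both routes.

```r
trajectory_summary(cls)
#  electrode cortical_grey subcortical white pial_surface outside total
#         RA             1           0     7            0       0     8
#      (all)             1           0     7            0       0     8
```

The command-line entry point (`inst/cli/ieegloc`) exposes the same stages:

```sh
ieegloc synth     --out work --seed 1
ieegloc label-ela --parcellation work/parcellation.nii.gz \
                  --lut work/labels.lut --contacts work/contacts.csv \
                  --out work/ela.csv
ieegloc bids      --contacts work/contacts.csv --out work/bids
```

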