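---
title: "petstage: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petstage: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whole-body PET/CT in prostate cancer shows many sites of elevated tracer
uptake, most of them physiological (bladder, kidneys, liver, salivary
glands for PSMA-ligand tracers; brain and myocardium for FDG). Reading a
scan means finding every elevated-uptake region, deciding whether it is
suspicious for cancer, naming its anatomical location, and summarising the
suspicious locations as a PROMISE miTNM stage: the miN category counts
regional (pelvic) lymph-node lesions, the miM category grades distant
disease (extrapelvic nodes, bone lesions by focality, other organs).
`petstage` implements this pipeline end to end: candidate segmentation,
multiplanar-reformation (MPR) feature extraction, a multi-task
convolutional classifier with dual-tracer training strategies, rule-based
miTNM staging, the full evaluation statistics, and a synthetic phantom
generator so that every component is testable without patient data.

## Volumes and geometry

A `PetCtVolume` holds co-registered PET (SUV) and CT (HU) grids. The
package convention is: grid axis 1 runs left-right, axis 2
anterior-posterior, axis 3 inferior-superior; world coordinates are in mm;
voxel indices are 1-based (the natural R convention, used consistently for
every mask, seed and SUVmax position). NIfTI input is reoriented to this
convention from its affine at load time, the CT is resampled onto the PET
grid when geometries differ, and negative PET values — reconstruction noise
— are clamped to 0 SUV because every downstream threshold assumes
non-negative uptake.

All analysis runs at 3 mm isotropic resolution; `resampleIsotropic()`
uses trilinear interpolation for both channels (the interpolation scheme
for intensity grids; masks, when resampled, use nearest-neighbour). Trilinear is
the field's default for intensity grids, and the operation is validated
against an independent interpolation implementation in the tests.

## Candidate segmentation

Candidate uptake regions come from a deterministic incremental
connected-component procedure: while any unassigned voxel exceeds the SUV
floor, the unassigned voxel of globally maximal SUV is taken as a peak
(ties broken by lowest linear index), a per-region threshold is set at 45%
of that peak, the 26-connected component of unassigned voxels at or above
the threshold is extracted and emitted, and its voxels are marked
assigned. This gives each region its own 45%-of-SUVmax threshold and makes
the output independent of any traversal order. Consequences worth knowing:

* The peeling continues into the *shoulders* of bright structures — voxels
  between the floor and a region's threshold become later, fainter
  candidates ("shell" findings). This is by construction: at test time the
  classifier, not the segmenter, decides what is suspicious.
* With no region cap every voxel above the floor belongs to exactly one
  finding; masks are pairwise disjoint. Both properties are asserted
  against a brute-force flood-fill oracle in the tests.

Three scheme variants mirror the annotation workflows the package
supports: `segmentGroupA()` (seed clicks, hill-climbing to the local
maximum, then 45% growth — one plausible reading of a semi-automatic
scheme), `segmentGroupB()` (floor set to the mean SUV of a PERCIST-style
liver reference region, then truncation to the 100 highest-SUVmax
findings), and `generateAutoNonsuspicious()` (floor 1.0 SUV, candidates
not touching any expert-suspicious mask are labelled nonsuspicious; only
applied where the expert annotation is known to be complete — group A, or
group B with at most nine suspicious findings). The group-B truncation
counts suspicious and nonsuspicious sites jointly; the exclusion rule for
auto-nonsuspicious regions is deliberately conservative (SUVmax-voxel
containment *or* any voxel overlap) to avoid mislabelling lesion voxels as
physiological.

## MPR feature extraction

Each finding is represented by thirteen coronal planes, 192 mm x 192 mm at
3 mm (64 x 64 samples), centred on the finding's SUVmax voxel, at fixed
anterior-posterior offsets (-144, -96, -48, -24, -12, -6, 0, +6, +12, +24,
+48, +96, +144 mm): a pyramid of context that is dense near the lesion and
sparse far from it. PET is windowed to [0, 15] SUV, CT to [-300, 300] HU,
and both are normalised to [0, 1] (feeding normalised rather than raw
clamped values is a package choice, exposed in the code). Samples outside
the volume take the window minimum. The centre voxel lands exactly on
sample (32, 32), so integer-grid extraction is an exact gather.

Training-time augmentation draws an isotropic scale in [0.8, 1.2] and
three rotations in [-17.2, 17.2] degrees about the patient axes from a
seeded generator and applies them about the centre position before
sampling. Rotation order is extrinsic x, then y, then z — an arbitrary
but frozen convention; with the ranges collapsed to the identity the
augmented stack equals the plain one bit for bit (asserted in tests).

## The classifier

The network is a shared convolutional trunk over the 26-channel 64 x 64
input (13 planes x PET/CT), built from 3x3 convolution + ReLU + 2x2
max-pool blocks, followed by adaptive average pooling and two fully
connected heads: a sigmoid *suspicious* head and a softmax *anatomical
location* head. In the dual-tracer variant a binary tracer input is
concatenated to the first fully connected layer of the suspicious head
only — the location head never sees it, so the location task is
tracer-invariant by architecture (the gradient of the location loss with
respect to the tracer weights is identically zero; a test asserts this).

Exact filter counts are configuration, not contract: the testable
architectural claims are the multi-task split and the tracer-bit
placement. The loss is binary cross-entropy plus categorical
cross-entropy, summed 1:1 by default, with the location term masked to
zero for findings without an anatomical label (auto-generated
nonsuspicious regions). Because labelled suspicious findings are a small
minority among candidates, the binary term supports an optional
positive-class weight (`posWeight`); the packaged toy configuration uses
it. The forward/backward passes and the Adam optimiser are implemented
in-package (base matrix operations with small C++ kernels for the im2col
gathers and trilinear sampling); the backward pass is verified against
finite differences on every weight tensor in the tests.

## Training strategies

Six strategies are implemented, differing in sampling, augmentation and
data composition:

* **I** — sequential: every labelled finding once per epoch.
* **II** — balanced: per subject and epoch, up to 32 nonsuspicious and up
  to 32 suspicious findings for the binary task and up to 4 findings per
  anatomical class for the location task; the union of the two draws forms
  the epoch set. (The two caps are interpreted as one joint epoch set,
  maximising label coverage; the alternative — independent draws per head —
  would process some findings twice.)
* **III** — II plus affine augmentation of every drawn example.
* **IV** — III on FDG data with a single 90/10 subject-level split.
* **V** — transfer learning: all weights of a IV checkpoint fine-tuned on
  PSMA data with III (no layer freezing — fine-tuning updates the whole
  network).
* **VI** — III on the union of both tracers with the dual-tracer model,
  the tracer bit set from each subject's tracer.

Optimiser defaults (Adam, learning rate 1e-3, batch 32, 50 epochs) are
package choices exposed in `trainConfig()`, including an optional
late-training learning-rate decay. Cross-validation is subject-level and
stratified (on the true stage when supplied, else on the presence of
suspicious findings).

## Staging rules

`assignStage()` maps the anatomical classes of suspicious-classified
findings to roles via a configurable taxonomy and applies: miN = N0/N1/N2
for zero, one, or multiple regional-node lesions; bone pattern M1b_u
(single), M1b_o (two or three), M1b_d (four or more); reported miM is the
most advanced applicable category with precedence M1c > M1b > M1a > M0.
The precedence when bone and visceral lesions coexist is a package
decision (most-advanced-site convention, matching one-category-per-subject
reporting). The diffuse bone-marrow pattern is not modelled. The rules are
verified against exhaustive enumeration of all role-count combinations in
0..5 (1296 cases).

## Evaluation statistics

`averagePrecision()` integrates the precision-recall curve step-wise over
descending-score thresholds with tied scores grouped (validated against an
exhaustive-threshold oracle). Detection counting matches suspicious
candidates to expert-suspicious masks by SUVmax-voxel containment by
default (any-voxel overlap is the configurable alternative); unmatched
suspicious candidates are false positives and unmatched expert findings
false negatives. Per-subject recall is undefined for subjects without
expert positives and such subjects are excluded from the per-subject
recall summary, except that zero predictions on zero positives count as
recall 100. Confidence intervals are percentile bootstrap over 2000
subject-level resamples; replicates on which a metric is undefined are
redrawn (and counted). Method comparisons use a two-sided paired z-test on
the bootstrap replicates — z = mean(d)/sd(d) over the paired differences —
with Bonferroni correction. Stage agreement is 100 x trace/total of the
confusion matrix, with optional category merging (e.g. N1+N2, the three
M1b patterns, or all M1 categories) and integer rounding for reporting.

## The phantom generator

The phantom emulates the study conditions at desk scale: a 64 x 64 x 160
grid at 3 mm (a ~19 x 19 x 48 cm body), tracer-specific physiological
organs painted as ellipsoids (PSMA-like: liver, spleen, kidneys, bladder,
salivary; FDG-like: brain, myocardium, liver, bladder), lesions as spheres
of 6-9 mm radius and SUVmax 4-15 placed in class-consistent zones
(regional nodes anterior pelvis, extrapelvic nodes retroperitoneum, bone
lesions inside the high-HU spine, other-organ lesions in lung), Gaussian
PSF blur of 6 mm FWHM, and voxelwise Gaussian noise with standard
deviation 5% of local SUV over a 0.3 SUV soft-tissue background. Organ
SUVs (e.g. bladder 12, kidneys 6, liver 2.5 for the PSMA-like tracer;
brain 8 for the FDG-like tracer) are chosen for class separability, not as
physiological claims; everything is configurable. Expert annotation is
emulated with the group-A geometry (45%-of-peak regions around each true
structure), so training labels have the same shape as candidate masks.
Anatomical class is encoded by spatial zone and CT context — bone lesions
sit in high-HU structures — which makes the location task learnable
largely from the CT channel.

What the phantom deliberately does *not* model: anatomical realism
(XCAT-class phantoms), scanner-specific noise, attenuation artefacts,
contrast-enhanced CT variability, or ambiguous uptake patterns (ureters,
ganglia) that make the clinical problem hard. Passing the phantom
benchmark therefore demonstrates that the pipeline's machinery —
segmentation, feature extraction, learning, staging, evaluation — is
correct and learnable, not that clinical performance would match.

A cohort generator draws per-subject target stages from a configurable
stage mix (defaults span all N and M categories with lesion-free subjects
most common), derives a lesion specification achieving each stage, and
emits per-subject ground truth for stratified splitting. Ground-truth
stages equal `assignStage()` on the true lesion classes by construction.

## Problem sizes and numerical choices

The package's own benchmark — used by its acceptance tests — trains the
packaged toy configuration (one 8-filter conv block, 32-wide heads,
positive-class weight 8) with strategy III on 60 phantom subjects and
evaluates on 20 held-out subjects. The pooled benchmark metrics are
computed over the *expert-annotated* findings of the validation subjects
(lesions and labelled physiological organs): the auto-generated
nonsuspicious regions — including the faint blur-shoulder "shell"
candidates the peeling produces — are a training device and are not part
of the pooled AP, mirroring how expert-annotated findings are pooled for
the clinical metric. The segmentation oracle runs on 32^3
grids, the AP oracle on 1000 datasets of up to 12 points, bootstrap
coverage on 30 subjects with 400 replicates. These sizes were chosen so
the whole suite runs on a single CPU in well under half an hour while
leaving each statistical check enough resolution to fail loudly if its
implementation drifts.

Numerical conventions that are frozen because determinism requires it:
ties in the segmentation peak search break toward the lowest linear
index; ties in the location argmax toward the first class; the
augmentation rotation order is x, y, z; bootstrap and every training draw
derive from explicit integer seeds (32-bit safe). Interpolation at exact
integer coordinates returns the stored value exactly, which is what makes
identity augmentation bit-identical to plain extraction.

## Known limitations

* The CNN engine is compact by design; it is not a GPU-scale training
  framework and the default architecture is far smaller than a clinical
  model would be.
* Automatic liver localisation for the group-B reference region is out of
  scope; the reference is a user-supplied mask or sphere.
* miT (local tumour) staging and diffuse bone-marrow involvement are not
  modelled.
* DICOM ingestion and SUV calibration are upstream of this package; only
  NIfTI is read.
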