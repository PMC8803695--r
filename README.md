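# petstage

Whole-body PET/CT uptake classification and automated PROMISE miTNM
staging for prostate cancer imaging, with a synthetic phantom generator
that makes the entire pipeline testable without patient data.

## The problem

A whole-body PSMA-ligand or FDG PET/CT scan contains dozens of
elevated-uptake regions, most of them physiological. Staging a prostate
cancer patient from such a scan means: find every candidate uptake region,
classify each as suspicious or nonsuspicious for cancer, assign each an
anatomical location, and summarise the suspicious locations as a PROMISE
miTNM stage — miN0/miN1/miN2 for zero, one, or multiple regional
lymph-node lesions, and miM0/miM1a/miM1b(u/o/d)/miM1c for distant disease
(extrapelvic nodes; bone lesions — unifocal, oligometastatic with up to
three lesions, or disseminated with four or more; other organs).

`petstage` implements this pipeline end to end:

* **Segmentation** — deterministic incremental connected components:
  repeatedly take the brightest unassigned voxel above an SUV floor and
  peel off the connected region above 45% of that peak, so every region
  gets its own threshold `t = 0.45 · SUVmax`.
* **Features** — each finding is represented as thirteen coronal
  multiplanar reformations (192 × 192 mm at 3 mm; PET windowed to
  [0, 15] SUV, CT to [−300, 300] HU) at fixed anterior-posterior offsets
  (−144 … +144 mm) from the finding's SUVmax position.
* **Classifier** — a compact multi-task CNN (shared conv trunk, a sigmoid
  suspicious head and a softmax location head) with six training
  strategies: sequential sampling, balanced per-subject sampling (caps
  32/32 findings and 4 per location class), affine augmentation (scale
  0.8–1.2, rotations ±17.2°), FDG pre-training, transfer learning, and
  combined dual-tracer training in which a binary tracer input feeds the
  suspicious head only.
* **Staging** — rules over the suspicious findings' location roles:
  N stage from the regional-node count; M stage as the most advanced of
  M1c (other organ) > M1b_u/o/d (1 / 2–3 / ≥4 bone lesions) > M1a
  (extrapelvic node) > M0.
* **Evaluation** — average precision (area under the precision-recall
  curve), recall/PPV with per-subject summaries, 2000-resample
  subject-level bootstrap confidence intervals, paired z-tests with
  Bonferroni correction, confusion matrices and percent agreement.
* **Phantom** — a seeded generator of dual-tracer synthetic subjects with
  ground-truth findings and stages, used by the test suite and the
  acceptance script.

See `vignettes/petstage-methods.Rmd` for the model, its assumptions, the
tunable parameters and the design decisions.

## A worked example

Stage-agreement statistics from a confusion matrix (rows = annotation,
columns = prediction), using the packaged reference tables:

```r
library(petstage)
cmN <- as.matrix(read.csv(system.file("extdata", "example_n_confusion.csv",
  package = "petstage"), row.names = 1))
colnames(cmN) <- rownames(cmN)
stageAgreement(cmN)$percentRounded
#> [1] 67
stageAgreement(cmN, merge = list("N+" = c("N1", "N2")))$percentRounded
#> [1] 81
detectionRates(tp = 159, fp = 79, fn = 37)[c("recallRounded", "ppvRounded")]
#> $recallRounded
#> [1] 81.1
#> $ppvRounded
#> [1] 66.8
```

So 67% of subjects receive the identical N category, 81% agree on the
presence of any nodal involvement, and the pooled detection counts give a
sensitivity of 81.1% at a positive predictive value of 66.8%.

A miniature end-to-end run on synthetic data:

```r
gs <- generateSubject(phantomConfig(lesionSpec = c(regional_node = 1, bone = 2),
                                    seed = 5))
print(gs$groundTruth$stage)
#> miTNM stage: N1 M1b_o (counts: regional_node=1, extrapelvic_node=0, bone=2, other_organ=0)
cands <- incrementalConnectedComponents(petGrid(gs$subject@volume),
                                        segmentationConfig(suvFloor = 1.0))
length(cands)   # candidate uptake regions, lesions and physiology alike
#> [1] 28
```

The packaged command-line front-end
(`inst/scripts/petstage.R`) exposes the same pipeline as `petstage
phantom | segment | stage | evaluate` subcommands with YAML configuration,
`--seed` everywhere, and a JSON run manifest beside every output.

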