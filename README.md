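# oiearr

Quantification and grading of **orthodontically induced external apical root
resorption (OIEARR)** of the maxillary incisors from annotations of paired
pre/post-treatment panoramic radiographs — for orthodontic researchers and
developers of automated annotation pipelines who need a tested, reproducible
measurement and evaluation stack downstream of their landmark or
bounding-box detector.

## What it computes

Each maxillary incisor (FDI 12, 11, 21, 22) is annotated at two timepoints,
either with three anatomical keypoints (incisal edge, cervical margin, root
apex; "pose" mode) or with crown and root bounding boxes ("detect" mode).
Crown length is the incisal–cervical distance (box height in detect mode),
root length the cervical–apex distance (root-box height). Because the two
radiographs differ in magnification and projection, the post-treatment root
length is corrected by the crown-length ratio before comparison — resorption
never shortens the crown, so the crown is an internal scale reference:

    CF = crown_pre / crown_post
    root_post_corrected = root_post × CF
    resorption % = (root_pre − root_post_corrected) / root_pre × 100

A uniform magnification of the post image cancels exactly in the corrected
length. The percentage is then graded 0–3 (0 none, 1 slight apical blunting,
2 up to one-third of the root, 3 exceeding one-third) with configurable
thresholds.

The package also ships:

* a YOLO-format label parser/writer for both dialects, with a 1e-6
  round-trip guarantee on normalized coordinates;
* a seeded synthetic cohort generator with known ground-truth geometry,
  resorption and grade, emulating grade-conditional apical shortening,
  patient-level magnification/translation between timepoints, and separate
  keypoint vs box-edge noise regimes;
* an evaluation suite: 4-class confusion matrix, one-vs-rest per-grade
  metrics and ROC-AUC (single-operating-point construction for label-only
  classifiers, plus an ordinal Mann–Whitney mode), Grade-0-referenced
  measurement error, ICC(2,1) for repeated gradings, and exact binomial
  power analysis for sample-size planning.

## Worked example

```r
library(oiearr)

cohort <- generate_cohort(synthetic_config(n_patients = 32, seed = 7))
graded <- grade_cohort(measure_cohort(cohort, "pose"))
head(graded[, c("patient_id", "tooth", "pre_root", "correction_factor",
                "resorption_percent", "grade")], 4)
#>   patient_id tooth pre_root correction_factor resorption_percent grade
#> 1 patient001    12    125.4             1.094              29.75     2
#> 2 patient001    11    118.6             1.197              10.75     1
#> 3 patient001    21    122.7             1.117              25.63     2
#> 4 patient001    22    128.6             1.038              48.04     3
```

Each row is one tooth: the pre-treatment root length in pixels, the
crown-ratio correction factor absorbing that patient's magnification change,
the corrected percentage of root lost, and its clinical grade. Scoring the
predicted grades against the generator's ground truth:

```r
report <- run_evaluate(cohort$ground_truth, graded)
report$confusion
#>      pred
#> truth  0  1  2  3
#>     0 17  7  0  0
#>     1  3 15  8  0
#>     2  0  4 31  3
#>     3  0  0  3 37
report$per_class[, c("grade", "support", "precision", "recall", "auc_hard")]
#>   grade support precision recall auc_hard
#> 1     0      24     0.850  0.708    0.840
#> 2     1      26     0.577  0.577    0.735
#> 3     2      38     0.738  0.816    0.847
#> 4     3      40     0.925  0.925    0.945
```

At the default 2 px keypoint noise, most confusion is between adjacent
grades; the overall accuracy is 0.781 and the Grade-0 reference teeth (true
resorption 0%) show a mean absolute measurement error of 4.37% (SD of the
signed errors 4.90%, n = 24). Sample-size planning for showing a 5-point
improvement over the 25% chance level of the 4-grade task:

```r
plan <- sample_size_exact_binomial(p0 = 0.25, g = 0.05,
                                   alpha = 0.05, target_power = 0.80)
plan$n                       # 494
total_with_split(plan$n, 0.8) # 618 once an 80% training share is added
```

A thin command-line wrapper over the same functions is in
`inst/cli/oiearr.R` (subcommands `simulate`, `measure-grade`, `evaluate`,
`power`, `icc`). The methods vignette
(`vignettes/oiearr-methods.Rmd`) documents the measurement model, the
generator's assumptions and the evaluation conventions in detail.

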