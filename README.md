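# eegdx

Deterministic pipeline for testing whether a convolutional neural network
can recover depression status and severity from resting-state scalp EEG —
validated end to end on synthetic cohorts with known ground truth.

## The scientific problem

Depression alters resting EEG, most reproducibly as a *frontal alpha
asymmetry*: relatively more left-frontal alpha (8–13 Hz) power with
increasing severity. A screening pipeline built on this signal looks like:

1. record eyes-closed resting EEG on the 19-channel 10-20 montage;
2. clean it (0.5–50 Hz band-pass, 50 Hz notch, bad-channel
   interpolation, ICA blink removal, ±70 µV epoch rejection, >50%
   effective-segment screening);
3. render non-overlapping 10 s windows as grayscale channel × time
   images;
4. train a small CNN to emit an "AI score" in [0, 1] per image (sigmoid
   output; ≥ 0.5 ⇒ depression), under stratified 10-fold
   cross-validation with an 8:2 train/test split per fold;
5. aggregate image scores per subject and correlate with psychometric
   scales (SDS, SAS, SCL-90, EPQ).

Clinical EEG cannot be redistributed, so `eegdx` ships a seeded synthetic
cohort generator that plants the asymmetry with a configurable
`effect_size`: the F3/F4 alpha log-power ratio shifts by
`effect_size × latent_severity`, where the latent severity in [0, 1] also
drives the questionnaire scales. With `effect_size = 0` the EEG is exactly
independent of the labels — a built-in null control. The pipeline's
claims are therefore falsifiable: it must recover the planted effect
(AUC ≫ 0.5, positive AI-score/SDS correlation) and stay silent under the
null.

## The model

For an image `x` the network computes

```
conv 11×11/128 (stride 4) → ReLU → maxpool 2×2
conv 5×5/256            → ReLU → maxpool 2×2
conv 3×3/256            → ReLU
flatten → fc 128 → ReLU → dropout
        → fc 32  → ReLU → dropout
        → fc 1   → sigmoid  ⇒  AI score ∈ [0, 1]
```

trained with plain minibatch SGD on binary cross-entropy with L2 decay on
the fully connected weights (14 536 641 parameters at the default
400 × 400 input). The implementation is hand-written RcppArmadillo and
bit-deterministic given a seed. A pilot-scale configuration
(`cnn_config_reduced()`: 100 × 100 input, 8/16/16 filters, 11 377
parameters, seeded time-shift augmentation) runs a complete two-task,
10-fold experiment in minutes on one CPU.

## Worked example

```r
library(eegdx)

out <- tempfile("demo_")
summary <- run_pipeline(pipeline_config(
  out, seed = 42,
  generator = list(n_healthy = 6, n_nonmajor = 4, n_major = 4,
                   duration_s = 120, fs = 250, effect_size = 2),
  featuremap = list(size = 100),
  n_boot = 200))
```

```
[synth] 6/4/4 subjects, 120s @ 250 Hz
[preprocess] 14/14 recordings included
[featurize] 135 feature maps (100x100)
[evaluate:diagnosis] pooled AUC 0.963 accuracy 0.926
[evaluate:severity] pooled AUC 0.982 accuracy 0.929
[correlate] rho(AI score, SDS) = 0.690
```

```r
str(summary)
```

```
List of 13
 $ seed              : int 42
 $ n_subjects        : int 14
 $ n_included        : int 14
 $ n_images          : int 135
 $ diagnosis_auc     : num 0.963
 $ diagnosis_auc_ci  : num [1:2] 0.934 0.983
 $ diagnosis_accuracy: num 0.926
 $ diagnosis_f1      : num 0.933
 $ severity_auc      : num 0.982
 $ severity_auc_ci   : num [1:2] 0.959 0.997
 $ severity_accuracy : num 0.929
 $ severity_f1       : num 0.931
 $ rho_ai_sds        : num 0.69
```

The planted left-frontal alpha asymmetry is recovered (diagnosis
AUC 0.963 against a chance level of 0.5) and the subject-level AI score
tracks the SDS severity scale (Spearman rho 0.69). Rerunning the same
call reproduces these numbers exactly; rerunning with
`effect_size = 0` drives the AUC to chance.

Artifacts written to `out`: `roster.csv` (subjects, latent severities,
scales), `screening.csv` (per-recording epoch accounting),
`manifest.csv` (one row per feature-map image), per-task
`metrics_*_folds.csv`, `scores_*.csv`, `roc_*.csv`,
`subject_ai_scores.csv`, `correlations.csv`, `run.log` and
`summary.json`.

The same run from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "eegdx.R", package = "eegdx"))')
Rscript "$CLI" run-all --out /tmp/demo --seed 42          # pilot defaults
Rscript "$CLI" run-all --config my_run.yaml --out /tmp/demo2
```

(`synth`, `preprocess` and `featurize` subcommands run the stages
individually over EDF directories; see the header of `inst/cli/eegdx.R`.)

## Documentation

The methods vignette (`vignettes/eegdx-methods.Rmd`) documents the
synthetic signal model, every preprocessing stage and its oracles, the
CNN architecture and training protocol, the cross-validation design
(including how "10-fold" and "8:2" reconcile, and the image- vs
subject-level split caveat), and the generator's realism limits.
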