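# gloriafall

Automated fall detection from video for patient-safety and assisted-living
monitoring, without dense optical flow and without wearables.

For each pair of consecutive frames, the package reconstructs the six
amplitudes of the global linear non-homogeneous motion group directly from
the brightness-constancy constraint (the GLORIA approach): writing the flow
as `v = Σ_u A_u v^u` over the generators

    translation_x = (1,0)   translation_y = (0,1)   dilation = (x,y)
    rotation = (y,-x)       shear1 = (0,x)          shear2 = (y,0)

the least-squares solution of `dL_c/dt = -∇L_c · v` over all pixels and
spectral channels is the 6×6 normal system

    S[u,v] = Σ (G_u L_c)(G_v L_c),   H[u] = -Σ (dL_c/dt)(G_u L_c),   S A = H,

solved per frame pair in closed form (minimum-norm: the published generator
set is rank-5 — rotation equals shear2 − shear1 — see the methods vignette).
The per-pair 6-vectors are assembled into 6×150 motion windows and classified
fall / no-fall by a compact time-axis CNN, or by a hybrid variant that adds a
bidirectional LSTM pathway. Seeded synthetic generators (textured scenes
warped by known parameter schedules; labeled windows with abrupt fall
transients) make every stage testable offline. Evaluation provides the
standard confusion-matrix metrics and ROC/AUC.

Intended users: computer-vision and biomedical-engineering groups working on
camera-based activity monitoring who need a transparent, CPU-only, fully
reproducible reference implementation.

## Worked example

```r
library(gloriafall)

# a textured scene translated right by 0.5 px/frame
spec <- scene_spec(64, 64, texture_seed = 7,
                   schedule = list(motion_params(tx = 0.5)))
seq <- render_sequence(spec)
estimate_motion(seq$frames[[1]], seq$frames[[2]])
#> Global motion parameters (per frame):
#>         tx         ty   dilation   rotation     shear1     shear2
#>  5.052e-01 -3.357e-04  3.969e-04  1.030e-04  9.124e-05  1.942e-04
#>   cond(S) = 1.51e+16, residual RMS = 0.000369
```

The translation is recovered within ~1% and the other parameters stay near
zero; the astronomical `cond(S)` reflects the structural rank deficiency of the
published generator basis (handled by the minimum-norm solve), not a failure.

```r
# train the CNN on simulated windows and classify held-out ones
train <- simulate_motion_dataset(motion_dataset_spec(400, seed = 101))
test  <- simulate_motion_dataset(motion_dataset_spec(100, seed = 202))
w <- normalize_windows(train$windows, "per_channel_z")
cnn <- train_classifier(build_model(classifier_config("cnn", seed = 11)),
                        w, train$labels)
pred <- predict(cnn, test$windows)
evaluation_report(test$labels, pred$probabilities[, "fall"])
#> Evaluation at threshold 0.50 (n = 100):
#> accuracy     100.0%
#> sensitivity  100.0%
#> specificity  100.0%
#> precision    100.0%
#> f1           100.0%
#> AUC          1.000
```

Synthetic fall transients (bursts at 10x background on all six channels) are
separable by construction, so a perfect held-out score is the expected
outcome — it validates the pipeline plumbing, not real-world accuracy.

## Command line

```sh
gloriafall simulate --out windows.csv --n 200 --seed 1
gloriafall train    --data windows.csv --arch cnn --seed 1 --model-out model.rds
gloriafall extract  --video frames_dir/ --out motion.csv
gloriafall detect   --video frames_dir/ --model model.rds --threshold 0.5
gloriafall evaluate --pred pred.csv --truth truth.csv
```

Video input is a directory of PNG frames; decode containers externally.

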