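# jnposture

Image-based classification of standing postural control from skeleton
joint trajectories.

## The problem

Postural control — the ability to stand still — declines with age. A depth
camera can record the 2-D coordinates (x mediolateral, y vertical) of 15
body joints at 30 Hz while a person stands quietly for 40 s. Drawing every
sampled joint position into one fixed-size colour image, a **joint-node
plot (JNP)**, turns balance assessment into image classification: stable
subjects leave tight per-joint point clouds, subjects with poor postural
control leave smeared or multi-lobed traces, and the image preserves
*which* body segments sway or tremble.

`jnposture` implements the full analysis as a reproducible pipeline:

1. **Simulate** two-group quiet-stance cohorts (control/young vs
   experimental/elderly) with group-dependent sway magnitude and
   segment-specific tremor phenotypes — there is no public cohort of this
   kind, so the generator is a first-class, tested module;
2. **Render** each 1200-sample recording into a deterministic
   875 × 656 px, 24-bit JNP (one plotted frame per second);
3. **Extract features** with interchangeable backends: per-joint colour
   moments (105-d) or a small trainable CNN (64-d penultimate layer);
   the five large pretrained backbones are specification-complete but
   require user-supplied weights;
4. **Classify** with SVM / logistic regression / naive Bayes over a model
   grid (epochs 10/15/20, training fractions 60 %/70 %; 90 cells in the
   replication design, 24 in the offline desk design) using stratified
   non-overlapping train/test splits;
5. **Report** six confusion-matrix indices with the elderly group as the
   target class — accuracy, sensitivity, specificity, PPV, NPV and Cohen's
   kappa

   κ = (p_o − p_e) / (1 − p_e),  p_e = [(tp+fp)(tp+fn) + (fn+tn)(fp+tn)] / N²

   — ranked ascending by kappa, with radar-plot data exported alongside.

See `vignettes/jnp-methods.Rmd` for the generative model, parameter
defaults and design rationale.

## Worked example

```r
library(jnposture)

sim    <- simulate_dataset(n_control = 6, n_experimental = 6,
                           sessions = 3, seed = 42)
images <- lapply(sim$recordings, render_jnp)
names(images) <- names(sim$recordings)

grid <- enumerate_grid("desk", train_fractions = 0.6, epochs = 10)
fit  <- run_grid(sim$manifest, images, grid, seed = 42)
fit
#> <jnp_grid> 6/6 cells evaluated on 36 images (seed 42, image-level splits)
#>   best by kappa: D1 (moments + lr, 60% train) accuracy 1.000, kappa 1.000
```

Each grid cell is one (backend, classifier, training-fraction) model; the
held-out images (stratified 40 % here) are scored into a confusion matrix
and its six indices. On this synthetic cohort the 3 mm vs 8 mm sway
contrast is fully separable, so every cell reaches accuracy and kappa 1.00
— the expected outcome under the default study conditions (the
null-control cohort, where both groups share one identical profile, stays
at chance instead). Metrics come straight from the confusion matrix:

```r
metric_set(confusion_counts(tp = 59, fn = 1, fp = 2, tn = 46))
#> accuracy     0.9722
#> sensitivity  0.9833
#> specificity  0.9583
#> ppv          0.9672
#> npv          0.9787
#> kappa        0.9436
```

`summary(fit)` ranks cells ascending by kappa with the default report
filter (accuracy ≥ 0.95, kappa ≥ 0.88); `rank_models()`,
`export_report()` and `radar_data()` write the report tables.
`run_pipeline(default_run_config())` executes all stages into one run
directory with recordings, PNGs, results, report, log and a provenance
JSON; re-running the same configuration reproduces it byte for byte.

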