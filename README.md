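# rvtrack

Fully automated quantification of right-ventricular (RV) longitudinal
function from 2D echocardiography.

Conventional RV screening relies on tricuspid annular plane systolic
excursion (TAPSE) and tissue-Doppler S′, which need dedicated acquisitions
and careful cursor placement. `rvtrack` instead tracks the tricuspid annulus
automatically on ordinary apical four-chamber cine loops: a residual U-net
labels the lateral and septal annulus on every frame, each annulus is
reduced to the center of mass of its labelled pixels, the resulting
trajectory is median-smoothed, and two displacement indices are reported per
annulus:

- **LTAD** (linear tricuspid annular displacement):
  `max over frame pairs (s,t) of ‖p_s − p_t‖ × pixel spacing` — the maximum
  displacement between any two positions of the annulus, in cm;
- **CTAD** (circumferential tricuspid annular displacement):
  `Σ_t ‖p_{t+1} − p_t‖ × pixel spacing` — the total bidirectional path
  length traversed by the annulus, in cm.

The segmenter is trained with the class-weighted softmax cross-entropy

```
Loss(x, i) = −W[i] · ln( e^{x[i]} / Σ_j^C e^{x[j]} )
```

with weights `W = (0.2, 0.8, 0.8)` for (background, lateral, septal) to
offset the extreme class imbalance, optimised with RMSProp. Case-level
k-fold cross-validation (with a hard leakage guard), Bland–Altman limits of
agreement, ICC(2,1), ROC/AUC with DeLong intervals and sensitivity-
constrained operating points are included for evaluation, along with a
synthetic speckle phantom whose annular motion — and therefore ground-truth
LTAD/CTAD — is known by construction.

The network, its training loop and the statistics are implemented in the
package (R with Rcpp/RcppArmadillo convolution kernels); no external deep
learning framework is required. Inference is a single deterministic pass, so
repeated analyses of the same loop agree exactly.

## Worked example

```r
library(rvtrack)
library(dplyr)

# 1. Simulate a small cohort with known annular motion (8 of 24 dysfunctional)
cfg <- phantom_config(image_size = 64, pixel_spacing = 0.2,
                      n_frames = 12, label_radius = 3)
cohort <- generate_cohort(24, 1/3, config = cfg, seed = 9)
#> <phantom_cohort> 24 cases, 8 dysfunctional

# 2. Train the residual U-net segmenter
fit <- train_segmenter(cohort$cases,
                       net_config = network_config(n_classes = 3, depth = 4,
                                                   base_channels = 8,
                                                   input_size = 64),
                       epochs = 12, frames_per_case = 4, lr = 2e-3, seed = 1)
fit$net
#> <rvtrack_net> residual U-net: depth 4, base 8 channels, 3 classes,
#>   input 64x64, 127,075 parameters

# 3. Fully automated quantification: segmentation -> tracking -> indices
indices <- quantify_cohort(fit$net, cohort$cases)
indices %>% select(case_id, ltad_lateral, ctad_lateral, ltad_septal, ctad_septal)
#> # A tibble: 24 x 5
#>   case_id ltad_lateral ctad_lateral ltad_septal ctad_septal
#> 1 case01         0.830         1.56       0.476       0.899
#> 2 case02         0.707         1.38       0.419       0.771
#> 3 case03         0.849         1.61       0.535       1.03
#> ...

# 4. Recovered vs configured amplitude (relative error per case)
m <- inner_join(indices, cohort$truth, by = "case_id")
summary(abs(m$ltad_lateral - m$lateral_amplitude) / m$lateral_amplitude)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> 0.05881 0.07881 0.08839 0.08818 0.09536 0.13228

# 5. Diagnostic performance against the dysfunction reference
evaluate_diagnostics(m, m$dysfunction) %>%
  select(index, auc, cutoff, sensitivity, specificity, ppv, npv)
#>   index          auc cutoff sensitivity specificity   ppv   npv
#> 1 ltad_lateral     1  1.22            1           1     1     1
#> 2 ctad_lateral     1  2.27            1           1     1     1
#> 3 ltad_septal      1  0.692           1           1     1     1
#> 4 ctad_septal      1  1.29            1           1     1     1

# 6. Reproducibility: a second identical run agrees exactly
run2 <- quantify_cohort(fit$net, cohort$cases)
evaluate_agreement(indices, run2, index_cols = "ltad_lateral") %>%
  select(index, mean_diff, loa_low, loa_high, icc)
#>   index        mean_diff loa_low loa_high   icc
#> 1 ltad_lateral         0       0        0     1
```

What the numbers mean: per-case LTAD/CTAD are in cm (the phantom's
configured lateral amplitudes are 0.8–1.4 cm for dysfunctional cases and
1.6–2.4 cm for normals). On this small 64-px cohort the tracked lateral LTAD
recovers the configured excursion to ~9% median relative error, the indices
separate dysfunctional from normal cases perfectly (AUC 1.0 with
sensitivity = specificity = 1 at the sensitivity-constrained cutoff), and a
repeated run reproduces every index exactly (zero mean difference,
zero-width limits of agreement, ICC 1) — automated analysis has no observer
variability.

A command-line pipeline wrapping the same functions is installed at
`inst/cli/rvtrack.R` with subcommands
`simulate | train | crossval | track | quantify | evaluate`.

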