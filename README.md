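# msfaunet

Automatic segmentation of the thyroid gland — a small organ at risk — on
localized radiotherapy CT slices, with a multi-scale fusion attention
U-Net: a U-Net-style encoder–decoder whose encoder keeps HRNet-style
parallel branches at full, 1/2, 1/4, … resolution, fuses the branches
after every stage, and replaces plain convolution pairs with **attention
residual blocks** (two 3×3 convolutions + batch norm ending in a channel
squeeze-and-excitation gate, plus a 1×1 projection shortcut).
Downsampling uses stride-2 convolutions, upsampling stride-2 transposed
convolutions, and a dropout layer (0.2) follows each decoder skip
concatenation.

Training minimizes the smoothed soft Dice loss

    DL = 1 − (2·Σ pᵢtᵢ + ε) / (Σ pᵢ + Σ tᵢ + ε),   ε = 1,

which is robust to the extreme foreground/background imbalance of a small
gland, with Adam under a staircase exponential learning-rate schedule
(`lr(step) = lr₀ · rate^⌊step/decay_steps⌋`; reference operating point
batch 2, 120 epochs, 512×512, lr₀ = 2e-4, decay 0.96 / 300 steps).
Evaluation reports DSC, JSC, PPV, SE and the exact symmetric Hausdorff
distance per case, aggregated as mean ± sd with box-plot statistics.

Everything needed to run end to end without patient data is included: a
deterministic CT-like **phantom generator** (bilobed thyroid-like gland at
60–100 HU over 40 HU neck tissue, vessel-like confounders in an
overlapping HU range, Gaussian noise), CT preprocessing (HU conversion,
window/level, CLAHE), label-consistent augmentation (rotation, flip,
zoom, shear), minimal single-frame DICOM + PNG mask I/O, and a
patient-level 6:1:1 dataset split.  The CNN engine itself — convolutions,
transposed convolutions, batch normalization, backpropagation, Adam — is
implemented in the package (Rcpp/Armadillo kernels plus a small
reverse-mode tape) and gradient-checked against finite differences.

## Worked example

A desk-scale version of the full study — generate 80 phantoms, split
6:1:1 by case, train a small configuration, evaluate on the 10 held-out
phantoms:

```r
library(msfaunet)

dir <- tempfile("phantoms")
man <- generate_dataset(phantom_config(image_size = 64, seed = 11), 80, dir)
sp  <- split_dataset(man$case_id, c(6, 1, 1), seed = 11)
sp
#> dataset split: 60 train / 10 validation / 10 test
man <- msfaunet:::apply_split(man, sp)

fit <- msfa_train(man, train_config(
  batch_size = 2, epochs = 12, image_size = 64,
  initial_lr = 2e-3, decay_steps = 300, decay_rate = 0.96, seed = 11,
  model = model_config(num_levels = 3, base_channels = 8)))

test_rows <- man[man$split == "test", ]
preds <- predict(fit, test_rows)                      # binary masks
gts   <- lapply(test_rows$mask_path, read_mask_png)
rep   <- evaluate_masks(preds, gts, case_ids = test_rows$case_id)
rep
#> Segmentation metrics over 10 case(s) (mean ± sd):
#>   DSC  0.980 ± 0.012
#>   JSC  0.962 ± 0.022
#>   PPV  0.986 ± 0.013
#>   SE   0.975 ± 0.015
#>   HD   1.000 ± 0.000
```

DSC/JSC near 1 say the predicted gland overlaps the reference almost
perfectly; PPV/SE near 1 say almost no over- or under-segmentation; HD of
1 pixel says the worst boundary disagreement on any test phantom is a
single pixel.  `write_metric_report(rep, "report.csv")` writes the
per-case table and summary; `plot(fit)` shows the loss curves and
`plot(rep)` the per-metric box plots.

Individual pieces are exposed as ordinary functions: `generate_phantom()`,
`pixels_to_hu()`, `apply_window()`, `adaptive_hist_equalize()`,
`augment_pair()`, `build_model()`, `msfa_forward()`, `dice_loss()`,
`confusion_counts()`, `overlap_metrics()`, `hausdorff_distance()`,
`read_dicom_slice()`, `split_dataset()`, `save_checkpoint()`, …  A thin
CLI lives in `exec/msfa-seg` (`phantoms`, `split`, `train`, `predict`,
`eval` subcommands).

See `vignettes/msfaunet-methods.Rmd` for the model, the preprocessing
pipeline, the phantom design, and the reasoning behind every tunable
default.

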