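# scintiseg

Adversarial multi-scale segmentation of metastatic bone lesions in planar
nuclear-medicine bone scintigrams, for imaging researchers and method
developers working with low-resolution radiotracer count images.

Whole-body bone scans (^99m^Tc-MDP, gamma camera) store radiotracer
counts as 16-bit integer matrices. Metastatic lesions appear as hot
spots, but their size spans a few pixels to large confluent regions, and
benign structures — the spine band, arthritis, tracer pooling — are
equally hot. `scintiseg` implements a conditional adversarial
segmentation framework for this setting, together with a synthetic
phantom generator so that everything is runnable and testable without
clinical data.

## The model

A generator *G* and a critic *D* are trained jointly:

* *G* is a 5-level encoder–decoder. Level 1 is a cascade dilated
  convolution (CDC) block — six 3×3 conv–BN–ReLU units with dilation
  rates 1, 2, 4, 1, 2, 4, whose cumulative receptive fields
  `rf_i = ks + (ks−1)(d−1) + s·(rf_{i−1}−1)` are 3, 7, 15, 17, 21, 29
  pixels. Levels 2–5 are multi-scale feature-extraction (MSFE) blocks:
  a residual dilated cascade (CRAC) followed by an Inception-style
  receptive-field block (RFB, equivalent kernels 1/3/5 with trailing
  dilated convolutions at rates 1/3/5). The decoder replaces U-Net's
  double convolution with residual multi-scale (RMS) blocks (dilations
  1, 2, 4), takes image-pyramid inputs at levels 2–4, and emits four
  deeply supervised sigmoid heads `y_1..y_4` at full resolution.
* *D* maps an image⊙mask product through six strided convolutions and
  flattens every stage into a weighted, mean-normalized feature
  signature. The losses are

      L_seg(G) = 1/4 Σ_i (1 − Dice(y_i, gt))
      L_adv(G) = 1/4 Σ_i | D(y_i × image) − D(gt × image) |   (multi-scale L1)
      L(G)     = α L_seg + β L_adv          (α = β = 1)
      L(D)     = 1 − L_adv                  (detached outputs)

  so the two adversarial losses sum to one by construction.
* Evaluation: pixels of the final head ≥ 0.5 are foreground;
  DSC = 2·Precision·Recall/(Precision+Recall), Precision = TP/(TP+FP),
  Recall = TP/(TP+FN), macro-averaged per image and reported as
  mean ± sd over repeated seeded runs.

All network layers and their gradients are implemented natively
(RcppArmadillo, single-precision GEMM), so the package has no
deep-learning framework dependency.

## Worked example

Simulate a phantom cohort, train the miniature adversarial model, and
evaluate on the held-out patients:

```r
library(scintiseg)

dir <- tempfile()
man <- generate_dataset(phantom_config(image_size = 64, n_patients = 26,
                                       seed = 42), dir)
man <- split_by_patient(man, 20/26, seed = 42)   # 40 train / 12 test images

res <- fit(man,
           generator_config(base_channels = 8),
           critic_config(base_channels = 8),
           loss_weights(),                        # alpha = beta = 1, Dice
           train_config(lr = 1e-3, batch_size = 8, epochs = 60, n_runs = 1),
           out_dir = file.path(dir, "run"))
res$runs[[1]]$metrics
```

```
metrics over 12 images: DSC 0.7496  precision 0.7147  recall 0.7982
```

A DSC near 0.75 on held-out synthetic patients means the network
recovers about three quarters of the lesion–prediction overlap mass
despite Poisson noise, a hot spine band, and benign confounders sharing
the lesion intensity range; recall above precision indicates it errs
towards over-segmenting lesion borders. Predictions for new images come
from the saved checkpoint:

```r
model <- load_generator(file.path(dir, "run", "run_1", "generator.rds"))
pred  <- predict_mask(model, read_scintigram(man$image_path[1]))
```

The same workflow is scriptable from a shell via the bundled CLI:

```sh
Rscript inst/cli/scintiseg.R simulate --out data phantom.n_patients=26
Rscript inst/cli/scintiseg.R train --manifest data/manifest.csv --out run \
        generator.base_channels=8 critic.base_channels=8 train.epochs=60
Rscript inst/cli/scintiseg.R rf-table
```

`rf-table` prints the receptive-field growth of the dilated cascade:

```
layer  kernel  dilation  padding  receptive_field
    1   3x3          1        1       3 x 3
    2   3x3          2        2       7 x 7
    3   3x3          4        4      15 x 15
    4   3x3          1        1      17 x 17
    5   3x3          2        2      21 x 21
    6   3x3          4        4      29 x 29
```

## Package layout

* `R/data_io.R` — 16-bit TIFF/PNG scintigram and mask I/O, CSV manifests,
  patient-grouped splitting (anterior/posterior views never separated).
* `R/phantom.R` — synthetic scintigram generator (Poisson counts, spine
  band, multi-scale elliptical lesions, benign confounders).
* `R/blocks.R`, `R/generator.R`, `R/discriminator.R` — CDC/CRAC/RFB/MSFE/
  RMS blocks, receptive-field arithmetic, the generator and the critic.
* `R/objectives.R` — Dice/BCE segmentation losses, multi-scale L1
  adversarial losses, DSC/precision/recall evaluation.
* `R/training.R` — alternating Adam optimization, seeded repeats,
  checkpoints and metrics reports.
* `R/cli.R`, `inst/cli/scintiseg.R` — command-line interface.
* `vignettes/adversarial-scintigram-segmentation.Rmd` — models, phantom
  assumptions, numerical choices, limitations.
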