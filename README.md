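# domainsalvage

Unsupervised adversarial domain adaptation for image classifiers deployed
across sites, in R.

## The problem

A classifier trained on images from one site (hospital, scanner, data
collection) usually loses performance on another site's images: the pixel
distribution shifts even when the labels mean the same thing. Acquiring
labeled data at every deployment site is expensive, so `domainsalvage`
implements a purely computational remedy that uses **labeled source images
and unlabeled target images only**:

1. Train a baseline CNN classifier `F_S` on the source domain.
2. Train a single conditional generator `G(x, c)` and critic
   `D = (D_src, D_cls)` so that `G` translates images between domains:
   Wasserstein adversarial loss with gradient penalty (λ_gp = 10), a domain
   classification loss (λ_cls = 1), an L1 cycle-consistency loss
   (λ_cyc = 10), and a semantic-consistency loss that ties class content to
   the translation using source labels and target pseudo-labels. The critic
   takes five updates per generator update; Adam (β₁ = 0.5), learning rate
   1e-4 decaying linearly to zero over the second half of training.
3. Translate the labeled source training set into the target style and
   fine-tune `F_S` on it, producing the adapted classifier.

Efficacy is quantified by comparing three AUCs on the target test set and
reporting **salvage**, the share of the performance gap recovered:

```
salvage = 100 * (AUC_adapted - AUC_external) / (AUC_internal - AUC_external)
```

where *internal* is the source model's AUC on its own held-out test set and
*external* its AUC on the target's. The package also computes bootstrap
confidence intervals (1,000 replicates of size 1,000), relative/absolute
change, calibration curves, and **domain spread** — the inter-domain variance
of a single model's per-domain AUCs, an a priori fragility indicator for
pooled ("global") models.

Everything runs on plain CPU R: networks, the training loop, and a small
reverse-mode automatic-differentiation core (with exact second-order
gradients for the gradient penalty) are part of the package, with the
convolution lowering in C++.

Because real multi-site corpora cannot ship with a package, a synthetic
benchmark generator builds several "sites" that share one classification
task (10 glyph classes, or binary blob detection) and differ only by a
label-preserving pixel style: color washout, gamma, background texture,
noise. At full severity a source-trained baseline drops from ~99.9% internal
to ~91.7% external macro AUC — the same regime reported for real cross-site
digit benchmarks.

## Worked example

The `micro` preset (16x16 glyphs, 600/100/300 images per domain, 200
adaptation iterations) runs the whole pipeline — generate two domains, train
the baseline, adapt, translate + fine-tune, evaluate — in a few minutes on
one CPU core:

```r
library(domainsalvage)

res <- run_experiment(run_config("micro", seed = 11))
dplyr::glimpse(res$report)
#> Rows: 1
#> Columns: 14
#> $ pair         <chr> "0->1"
#> $ internal_auc <dbl> 99.98778
#> $ internal_lo  <dbl> 99.95691
#> $ internal_hi  <dbl> 100
#> $ external_auc <dbl> 85.6505
#> $ external_lo  <dbl> 83.48351
#> $ external_hi  <dbl> 87.71527
#> $ adapted_auc  <dbl> 87.13448
#> $ adapted_lo   <dbl> 84.86156
#> $ adapted_hi   <dbl> 88.94768
#> $ ceiling_auc  <dbl> 99.84801
#> $ abs_change   <dbl> 1.483977
#> $ rel_change   <dbl> 1.732596
#> $ salvage      <dbl> 10.35048
```

Reading the row: the baseline classifier scores 99.99% macro AUC on its own
domain (`internal_auc`) but only 85.65% on the shifted domain
(`external_auc`). After adaptation the same deployment test set scores
87.13% (`adapted_auc`), an absolute gain of 1.48 AUC points — 10.4% of the
gap toward the 99.85% ceiling a natively trained model would reach
(`salvage`). At this miniature scale the salvage is small but positive; it
grows with adaptation length and network width.

Useful follow-ups:

```r
tidy(res$adaptations[[1]])          # component losses per update
plot_loss_history(res$adaptations[[1]], smooth_window = 5)
autoplot(res$deployment)            # strategy x domain AUC matrix
plot_images(translate_set(res$adaptations[[1]], res$data[[1]]$test, 1L))
```

A thin command-line front end over the same functions is installed with the
package (`inst/cli/domainsalvage`): subcommands `synth`, `train-baseline`,
`adapt`, `finetune`, `eval`, `run`, `report`.

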