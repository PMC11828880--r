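# noisytools

Training robust multi-label surgical-tool classifiers when the labels are
wrong in structured ways.

Endoscopic recordings from robotic surgery are annotated once per clip
with the set of tools *installed* on the robot (typically three). Building
a frame-level classifier means extrapolating that clip label onto every
extracted frame — but surgeons move tools out of the field of view, so
many frames inherit labels for tools that are not visible in them. On top
of that, the device UI leaks the installed tool names into a banner region
of every frame (a shortcut that lets models "classify" without looking at
the scene), some frames are entirely black, and tool usage is heavily
long-tailed.

`noisytools` implements a complete methodology for this setting, for
anyone who needs to train classifiers from clip-annotated, noisy,
leak-prone video data:

* a **synthetic scene generator** that reproduces the pathologies —
  per-frame tool-visibility dropout at rate `p_out`, a banner that
  deterministically encodes the installed set, black frames, Zipf
  tool prevalence — with hidden per-frame ground truth for oracle use;
* **preprocessing**: label standardisation, 10 Hz keyframe extraction, a
  learned foreground segmenter + dynamic cropping that removes the
  leakage banner, black-frame relabelling to a `blank` class, and
  clip-to-frame label extrapolation;
* a **four-member classifier ensemble** with the weighted ensemble loss
  `alpha*L1 + beta*L2 + gamma*L3 + delta*L4`, max-probability aggregation
  (annotation phase), mean-logit sigmoid aggregation
  `sigma(mean_m z_m(x))` (teacher/student inference), and top-3 final
  decisions;
* **active-learning label cleaning**: rank pool records by the ensemble
  loss of their noisy labels (loss-based epistemic scoring), correct the
  50 worst against an annotation oracle, fine-tune the member heads,
  repeat to a budget `k` — manual effort falls batch over batch;
* **student–teacher self-training**: a teacher trained on the cleaned
  records pseudo-labels the rest of the pool (noisy labels discarded); a
  student trains on pseudo + clean data, optionally with label smoothing
  (mass `p` on the correct classes, `(1-p)/(T-1)` elsewhere) and
  weighted-data-loader fine-tuning, which resamples by the reciprocal-log
  weight `1/ln(1 + combination count)` to protect minority classes;
* an **evaluation harness**: macro mAP / mAR / mAA / mAF1 over classes,
  and method comparison via one-way ANOVA, tie-corrected Kruskal–Wallis
  and Tukey HSD with 95% family-wise intervals.

## Worked example

```r
library(noisytools)
vocab <- tool_vocabulary()
cfg   <- generator_config(n_clips = 60, p_out = 0.3, seed = 7)
ds    <- generate_dataset(vocab, cfg)
ds
#> Synthetic clip dataset: 60 clips x 20 frames (72x128 px), p_out=0.30, p_black=0.05

ds$clips[[1]]$label_set
#> "permanent cautery hook spatula" "needle driver" "monopolar curved scissor"
ds$manifest$raw_label_string[1]          # the dirty annotation dialect
#> "['Permanent_cautery_hook_spatula', 'Needle_driver', 'Monopolar_curved_scissor']"
banner_read_labels(ds$clips[[1]]$frames[[1]], vocab)   # the leakage channel
#> "needle driver" "monopolar curved scissor" "permanent cautery hook spatula"
ds$clips[[1]]$truths[[1]]$visible_tools  # what is actually in view
#> "needle driver" "monopolar curved scissor"
```

The banner reveals all three installed tools even though only two are
visible — and the extrapolated frame label will claim all three. Running
the full pipeline (preprocess → noisy baseline → annotation loop →
teacher → student → smoothing and weighted arms):

```r
pl <- run_pipeline(pipeline_config(generator = cfg, k = 150, seed = 7))
summary(pl)
#> Pipeline summary
#>   corrections per batch: 50 23 22  (Spearman trend -1.00)
#>   ensemble mAF1 [noisy baseline]: 0.2300
#>   ensemble mAF1 [teacher]: 0.2598
#>   ensemble mAF1 [student]: 0.2484
#>   ensemble mAF1 [label smoothing]: 0.2712
#>   ensemble mAF1 [weighted data loaders]: 0.2506
#>   student - baseline mAF1: +0.0184
```

Manual corrections halve after the first annotation batch as the
fine-tuned ensemble starts proposing correct labels, and every
self-training arm beats the noisy-trained baseline on the clean test
split. (Absolute mAF1 values at this toy scale are dominated by the
macro average over all 15 classes, many of which barely occur in the
29-record clean test split; orderings, not levels, are the meaningful
output.)

Method comparison from per-model metric tables uses the same machinery as
the bundled example:

```r
rep <- compare_methods(example_method_tables())
rep$anova
#>   metric         F            p
#> 1    mAP 14.865554 6.898749e-05
#> 2    mAR 12.176699 2.111498e-04
#> 3    mAA  5.531885 8.440321e-03
#> 4   mAF1  2.706456 7.995842e-02
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/noisytools", package="noisytools"))') \
    pipeline --clips 60 --p-out 0.3 --k 150 --seed 7 --out results/
```

Subcommands: `synth` (write a synthetic dataset as PNG + CSV), `pipeline`
(full run, writes metric tables and the correction curve) and `eval`
(ANOVA/Kruskal–Wallis/Tukey over method metric tables).
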