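# drgrade

Five-grade diabetic retinopathy (DR) severity classification from retinal
fundus images, as one tested, reusable R package. Diabetic retinopathy is
graded 0 (healthy) through 4 (proliferative); automated grading pipelines of
this family segment the visible retinal structures, summarize them with
hand-crafted descriptors, prune the descriptor set with a swarm-intelligence
wrapper, and classify with an ensemble of standard learners. `drgrade`
implements that whole chain, plus a synthetic fundus generator with
per-structure ground-truth masks so every stage can be exercised and tested
without any external dataset.

The package is aimed at researchers who want a transparent, fully
reproducible reference implementation of this pipeline family — to probe its
components, benchmark alternatives against it, or run it on their own
fundus images (PNG/JPEG with integer grade labels).

## The method

1. **Segmentation** — each image is min–max normalized and five structures
   are thresholded at fixed fractions of the intensity range, with a
   foreground polarity and disc-structuring-element morphology:

   | structure   | level | polarity | morphology       |
   |-------------|-------|----------|------------------|
   | optic disc  | 0.4   | bright   | —                |
   | macula      | 0.6   | bright   | —                |
   | vessels     | 0.5   | bright   | close(disc, 5)   |
   | exudates    | 0.3   | bright   | open(disc, 10)   |
   | hemorrhages | 0.7   | dark     | open(disc, 3)    |

2. **Features (DRFV)** — for six channels (whole image + five masked
   structures) the row-major pixel sequence p_n is passed through five
   descriptor families: raw intensities, the DFT
   `DFT_m = Σ_n p_n [cos(2πmn/N) − i sin(2πmn/N)]`, the orthonormal DCT-II,
   Gabor responses `exp(−(x′² + γ²y′²)/(2σ²)) cos(2πx′/λ)` at four
   orientations, and the Haar pair wavelet
   `W_a = (p_n + p_{n+1})/2`, `W_d = (p_n − p_{n+1})/2`. Each family is
   summarized by mean, standard deviation, energy and Shannon entropy:
   6 × 5 × 4 = 120 named descriptors per image (the Diabetic Retinopathy
   Feature Vector).

3. **Feature selection (two-phase moth flame wrapper)** — a population of
   NM moths each holds `round(LM·N)` feature indices. Per iteration every
   moth's fitness is computed, the threshold `f_th = mean(f)·LM` is formed,
   and sub-threshold moths are re-randomized. Phase 1 uses the variance
   fitness `sqrt(Σ(x_i − x̄)²/N)` (averaged over the moth's features);
   phase 2 re-selects from the phase-1 survivors under the inter-class
   fitness (sample standard deviation across classes of the within-class
   standard deviations). The result is the union of the final survivors.

4. **Ensemble** — naive Bayes, kNN, RBF SVM, multinomial logistic
   regression, an MLP and a random forest are trained on the selected
   columns; each model's class vote is one-hot encoded, scaled by its
   held-out validation accuracy `A(·)`, summed, and argmaxed
   (`C_out = Σ_model A(model)·onehot(C(model))`). Metrics: accuracy,
   per-class and macro precision/recall/F1 from the 5×5 confusion matrix,
   on a stratified 80:20 train/test split.

## Worked example

```r
library(drgrade)

cfg <- run_config(source = list(type = "synthetic", n_per_grade = 10L),
                  seed = 42L)
run <- run_pipeline(cfg)
print(run$report)
#> <dr_eval_report> accuracy 0.8000 | macro P 0.8000 R 0.8000 F1 0.8000
#>      predicted
#> truth 0 1 2 3 4
#>     0 1 1 0 0 0
#>     1 1 1 0 0 0
#>     2 0 0 2 0 0
#>     3 0 0 0 2 0
#>     4 0 0 0 0 2
```

Ten images per grade are generated, segmented and featurized; features are
z-scored with training-split statistics, the moth flame wrapper picks the
descriptor subset, the six learners vote, and the held-out 20% (2 images
per grade) is scored. Grades 2–4 separate cleanly through their lesion
descriptors; the residual confusion sits between grade 0 and grade 1,
whose only difference is a couple of microaneurysm-sized blobs. A rerun
with the same seed reproduces the report byte for byte.

The segmentation stage can be inspected directly:

```r
it <- generate_fundus_image(default_grade_profile(3), seed = 7)
ms <- segment_all(it$image)
dice(ms$od, it$masks$od)        # ~0.87
dice(ms$macula, it$masks$macula) # ~0.9 or higher
```

A command-line wrapper with `synth`, `segment`, `featurize`, `select`,
`train-eval` and `run` subcommands lives at
`system.file("cli", "drgrade.R", package = "drgrade")`.

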