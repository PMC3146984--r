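# icseg — iterative classification segmentation of dermoscopic skin lesions

Accurate delineation of a pigmented skin lesion's border is the first step of
any computer-aided melanoma workup, and the step on which every downstream
shape or color feature depends. `icseg` implements a fully automatic
segmenter for dermoscopic images — frames acquired through a dermatoscope,
showing a circular field of roughly 17.4 mm diameter with the lesion framed
near the center on lighter background skin.

## The method

Segmentation is cast as a binary pixel classification in CIE L\*u\*v\* space,
bootstrapped without any user input from two acquisition assumptions:

* **d₁ = {r ≤ 5 mm}** — the central disk contains at least part of the
  lesion;
* **d₂ = {5 mm < r ≤ ℓ}** — the peripheral annulus (ℓ ≈ 8.7 mm) contains
  patches of background skin, which is lighter than the lesion.

**Stage 1 — seeds.** Each quadrant of d₂ is scanned exhaustively for the
1 mm box with maximal mean luminance; of the four boxes the three most
mutually consistent are kept (the most deviant is dropped by a
leave-one-out test on mean L\*). The 1.5 mm box in d₁ whose mean luminance
is farthest from the skin seeds' mean — in absolute value, so inverse-contrast
lesions work too — becomes the lesion seed.

**Stage 2 — hybrid classification.** Seed pixels are split into spatially
disjoint halves. One half trains a linear discriminant (LDA, pooled
covariance), the other a quadratic discriminant (QDA, per-class
covariances). The working posterior is the convex combination

    p_k(y = Ω | x) = λ_k · p_QDA(y = Ω | x) + (1 − λ_k) · p_LDA(y = Ω | x)

with λ_k chosen per iteration from a 0.01 grid by maximizing the *minimum*
of the two per-class seed accuracies; ties pick the smallest λ_k,
deliberately privileging the simpler linear model.

**Stage 3 — iterative refresh.** All field pixels are classified; pixels
with posterior above τ = 0.98 are harvested as new training samples. Lesion
candidates are additionally restricted to the opened (1 mm disk) component
that best encloses the lesion seed box — a safeguard against hairs and
clutter that is *not* applied to the segmentation itself. Per class, at most
as many samples as the original seeds are redrawn each iteration, so half of
the training set is always the original seeds. The loop stops when the count
m_k of high-confidence lesion pixels stabilizes, |1 − m_{k+1}/m_k| < 0.01,
or after 30 iterations.

**Postprocessing.** The binary classification is eroded (0.12 mm disk),
dilated (0.3 mm), multiplied back into the classification, and
Gaussian-filtered (σ = 0.06 mm, threshold 0.1) to bridge fragments. Each
remaining component is scored by a 2-D Gaussian centered on the field
(σ = 2.5 mm) summed over its pixels; only the best-scoring component
survives, holes are filled, and its border is traced as a closed sub-pixel
contour.

**Evaluation.** `evaluate_masks()` computes the four border scores:
sensitivity, specificity, the Hausdorff distance d_H (in mm), and the
tolerance ratio e(τ) — the fraction of contour points of both curves within
τ = 0.5 mm of the other curve (e(τ) = 1 whenever τ ≥ d_H). A pixelwise
majority vote builds consensus references from multiple manual
segmentations, and an exact dynamic-programming 1-D clustering stratifies
lesions into low/intermediate/high contrast groups.

## Worked example

Every stage can be exercised offline: the package ships a synthetic
dermoscopic frame generator with pixel-accurate ground truth.

```r
library(icseg)

frame <- synth_image(synth_spec(image_side_px = 256, contrast_L = 35,
                                rng_seed = 7))
fit <- ics(frame$image, frame$geom)
summary(fit)
#> ICS fit: 2 iteration(s), converged; lesion found (41.2 mm^2)
#>
#> Iteration trace (lambda = QDA weight, m = high-confidence lesion px):
#>  k lambda    m n_train_skin n_train_lesion
#>  1      0 8418          675            484
#>  2      0 8479         1350            968
#>
#> Seed regions:
#>   label top left side_px   mean_L
#>    skin  48  197      15 76.89970
#>    skin 241  114      15 76.07763
#>    skin 204  141      15 75.85878
#>  lesion  75  133      22 38.05587

evaluate_masks(fit$mask, frame$mask, frame$geom)
#> sensitivity 1.000  specificity 0.988  Hausdorff 0.19 mm  e(0.5mm) 1.000
```

The trace reads: the seeds were linearly separable, so λ stayed 0 (pure
LDA); the count of high-confidence lesion pixels moved from 8418 to 8479
(0.7 % < 1 %), triggering convergence at iteration 2; the recovered border
lies within 0.19 mm of the true one everywhere. `plot(fit)` overlays the
seed boxes and the final border on the luminance channel.

`run_pipeline()` wraps the same fit for files on disk (mask PNG, contour
CSV in px and mm, per-iteration trace, JSON run summary), and
`inst/cli/icseg.R` exposes `segment`, `evaluate` and `simulate` commands
for shell use.

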