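---
title: "Multiple-kernel SVM nodule recognition with hybrid SA/PSO tuning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-kernel SVM nodule recognition with hybrid SA/PSO tuning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mklsvm)
```

## The problem and the model

Computer-aided diagnosis of lung CT scans produces candidate regions of
interest (ROIs) that must be classified as *nodule* versus *non-nodule*.
`mklsvm` implements the recognition stage of such a pipeline: a binary
soft-margin SVM whose kernel is the convex combination

$$K(x, x') = \lambda\,K_{poly}(x, x') + (1 - \lambda)\,K_{sigmoid}(x, x'),
\qquad K_{poly} = (\langle x, x'\rangle + 1)^d,\quad
K_{sigmoid} = \tanh(a\langle x, x'\rangle + r).$$

The polynomial kernel is a *global* kernel with good generalization; the
sigmoid kernel is a strong nonlinear fitter. Mixing them convexly (any
convex combination of kernels is again a kernel when the bases are valid
kernels) lets the data decide the balance. The general $N$-kernel form
$\sum_p \alpha_p K_p$, $\sum_p \alpha_p = 1$, is supported through
`kernel_spec(weights = ...)`; the two-kernel mix is the default and the one
the search tunes.

Four coupled hyperparameters remain: the mix weight $\lambda$, the box
constraint $C$, and the sigmoid parameters $a$ (regulation) and $r$
(displacement). They are tuned jointly by maximizing the pooled 5-fold
cross-validated **F-score**

$$F = \frac{2\,\cdot SEN \cdot ACC}{SEN + ACC},$$

the harmonic mean of overall accuracy and nodule sensitivity. Using this
index rather than plain accuracy protects the minority nodule class:
missing a nodule is clinically the expensive mistake. Note this is *not*
the precision–recall F1.

## The search: hybrid simulated annealing / particle swarm

`run_sapso()` searches the box $\lambda \in [0,1]$, $C \in [2^{-9}, 2^9]$,
$a \in [2^{-7}, 2^7]$, $r \in [-3, 3]$ with 20 particles for 200
iterations, acceleration factors $c_1 = 1.5$, $c_2 = 1.7$, and a
constriction factor $\varphi$ on the previous velocity:

$$V \leftarrow \varphi V + c_1 r_1 (P_{best} - X) + c_2 r_2 (G_{plus} - X),
\qquad X \leftarrow X + V,$$

with velocities clamped componentwise to $\pm 0.6$ times the range bound
and positions clipped to the box. The annealing layer starts at
$T_0 = f_{Gbest}/\ln 5$ and cools geometrically, $T_{k+1} = 0.95\,T_k$.
Each iteration, Boltzmann weights over the personal-best fitnesses feed a
roulette draw that picks the *surrogate global attractor* $G_{plus}$; the
true global best is still updated greedily, so the best-so-far history is
monotone.

Design choices worth spelling out:

* **Attractor orientation.** The Boltzmann weighting
  $w_i \propto e^{-(P(i) - f_{Gbest})/T}$ originates in annealing over an
  *energy* (a minimized quantity). Applied verbatim to a maximized fitness
  its mass concentrates, as $T \to 0$, on the particle with the *lowest*
  personal best, i.e. the annealing would run backwards: exploitation
  first, exploration forever after. `boltzmann_weights()` exposes the
  formula exactly as stated (and the package's tests pin its values), but
  `run_sapso()` applies it on the energy scale (energy $=-$fitness), so
  the roulette is near-uniform while hot and concentrates on the best
  personal best as the system cools. Measured on a 2-D Rastrigin
  surrogate this orientation matches plain PSO's median final fitness,
  whereas the verbatim orientation falls measurably below it.
* **Constriction factor.** No value is prescribed and the closed-form
  constriction expression is undefined at $c_1 + c_2 = 3.2 < 4$; the
  canonical $\varphi = 0.729$ is the default and is exposed in
  `swarm_config()`.
* **Cooling rate.** Not prescribed; default 0.95, exposed.
* **Velocity bounds.** Printed as intervals with positive lower ends for
  $C$ and $a$; velocities must be signed for search to work, so all
  clamps are symmetric $\pm 0.6 \times$ the range bound, consistent with
  the $\lambda$ row's explicit $[-0.6, 0.6]$.
* **Box handling.** Positions are clipped (not reflected) — the simplest
  deterministic rule.
* **Raw versus log scale.** The $C$ and $a$ ranges are powers of two,
  suggesting log-uniform intent, but nothing says so; the default searches
  the raw scale and `swarm_config(log2_components = ...)` switches
  selected components to a $\log_2$ parameterization.
* **Greedy personal bests.** The enumerated algorithm never accepts a
  deteriorating personal best (the Metropolis "accept worse" prose applies
  to the attractor draw, not to $P_{best}$), so updates are greedy;
  `gbest_mode = "greedy"` additionally disables the roulette attractor.

Two baselines ship alongside: `run_pso()` (classical PSO, inertia weight
decaying linearly 0.9 → 0.4 — standard practice, nothing else specified)
and `run_grid()` (exhaustive search, first-encountered tie-break in
row-major order).

Benchmark objectives (`objective_sphere()`, `objective_rastrigin()`) are
wrapped as $1/(1+f)$ so the fitness lies in $(0, 1]$: $T_0 = f/\ln 5$
needs a nonnegative fitness, and position-based convergence checks are
invariant under this monotone transform.

## The fitness evaluator

`fitness_evaluator()` freezes a stratified fold assignment (same seed ⇒
identical folds), learns z-score normalization per training fold, and
precomputes the fold-wise feature inner products; a fitness evaluation is
then an elementwise kernel assembly plus five SMO solves, which keeps a
full 20 × 200 search on a 270-sample table around a minute on one core.
Fold predictions are **pooled** into a single confusion table before the
F-score is taken (micro aggregation): pooling keeps sensitivity defined
even if a fold were to contain few nodules, and makes the fitness a single
well-defined number.

## The SVM solver

`fit_svm()` solves the standard C-SVC dual on a precomputed Gram matrix by
sequential minimal optimization with maximal-violating-pair selection
(first-order working set, analytic pairwise update, $O(n)$ gradient
maintenance, KKT tolerance $10^{-3}$ by default and exposed). The contract
is the KKT conditions, not the algorithm; the test suite cross-checks the
dual solution and decision values against an independent SMO
implementation (kernlab) and against analytically solvable instances.
Sigmoid and mix kernels can be indefinite for part of the $(a, r)$ range —
no principled restriction of that range exists, so nothing is rejected:
negative pairwise curvature is floored at $10^{-12}$ inside the solver (as
SMO implementations commonly do), user-facing fits warn once per fit when
the Gram matrix is indefinite, and `spectral_clip()` offers an optional
PSD repair (negative eigenvalues zeroed) that is disabled by default.
Ties at a decision value of exactly zero predict $+1$ — a fixed convention
that makes tests deterministic.

## The feature cascade

`preprocess_roi()` binarizes the grayscale ROI (Otsu's method by default;
a fixed threshold can be supplied) and keeps the largest foreground
component under 8-connectivity. The labeling is done in-package because
the available image stack labels 4-connected components only; diagonal
contact must merge regions here.

`handcrafted_features()` computes the fixed 13-dimensional block — 7
morphological (area; Cauchy–Crofton perimeter, i.e. $\pi/4$ times the
count of exposed pixel edges, unbiased for isotropic smooth boundaries;
circularity $4\pi A/P^2$; rectangularity; elongation from second-order
moments; convexity deficiency against the pixel-center hull, clamped at
zero; equivalent diameter), 2 grayscale (mean, SD inside the mask) and 4
texture features (co-occurrence energy, contrast, correlation and entropy;
16 gray levels quantized inside the mask bounding box, distance 1,
averaged over the four directions; entropy in bits; correlation defined as
0 for a constant region). The 13 descriptors are only *counted*, not
individually defined, by the source material; this concrete
morphology/intensity/GLCM set is the standard CAD choice and the extractor
is table-driven so the set can be swapped without touching callers.

The deep-feature block is a *pluggable embedding contract*: any
deterministic `function(image) -> numeric vector`. The built-in
`default_embedder()` is a fixed-seed random projection of the resized
image — it stands in for a pretrained CNN's first fully-connected input
(25088-dim at full scale) at test scale, and it is *not* a claim about
learned features. Embeddings are reduced by centered PCA (`fit_pca()`,
98 components by default, or a cumulative-variance target), then
concatenated after the handcrafted block: $13 + 98 = 111$ dimensions.
When training and evaluation sets are distinct, the PCA (like the z-score
normalizer) should be fitted on the training side only and applied to the
rest — `extract_cascade(pca = ...)` supports exactly that; fitting on a
single pooled set reproduces the simpler protocol.

## Synthetic data: what it emulates and what it does not

`gen_roi_images()` draws nodules as radial Gaussian blobs (radius 6–12 px,
peak 0.7–1.0) and non-nodules as elongated ridges (length 30–50 px, width
2–4 px) on 64 × 64 frames with background noise SD 0.05 — a blob rather
than a hard disk so Otsu thresholding is exercised nontrivially, and sizes
chosen so the whole pipeline runs in seconds. `gen_feature_table()` draws
two spherical Gaussian clouds whose per-feature mean shift $\Delta$
controls Bayes separability ($\Delta = 1$ by default, giving a realistic
~0.93–0.97 cross-validated F on 13 features); `gen_imbalanced_table()`
reproduces a candidate pool of 270 samples at the 80:190
nodule:non-nodule ratio typical of screening candidates.

These generators define the package's study conditions. What passing
tests show: the formulas, the optimizer dynamics, the feature geometry and
the end-to-end plumbing are correct, and the tuned mix-kernel SVM
separates what is separable. What they do not show: performance on real
CT appearance — Hounsfield calibration, partial-volume effects, vascular
ridges that mimic nodules, annotation noise — none of which the
generators model. Published dataset-level numbers are therefore not
reproduced here; only their internal formula consistencies are.

## Numerical choices and degenerate inputs

* Labels are canonically $\{-1, +1\}$ with $+1$ = nodule; `{1, 0}` and
  `{nodule, nonnodule}` dialects are mapped on input.
* Zero-denominator metrics (e.g. sensitivity with no positive truth)
  return `NA` markers, never silent zeros, so repeat summaries are not
  corrupted.
* ROC uses the convention score ≥ threshold ⇒ positive; the trapezoid
  AUC equals pair concordance with ties counted half.
* Zero-variance features pass through normalization unscaled, with a
  warning.
* A constant image has no Otsu threshold and raises an explicit error, as
  does an empty foreground or a degenerate (< 4 px) mask.
* `boltzmann_weights()` uses a max-shifted softmax so cooled temperatures
  cannot overflow; inside `run_sapso()` the temperature is floored at the
  machine epsilon for the draw.
* Full runs are bit-reproducible under a fixed `swarm_config(seed = )`.

## Problem sizes used by the tests and the acceptance script

Deliberate choices, stated once: optimizer benchmarks use 20 particles ×
200 iterations × 20 paired seeds (Rastrigin) and 10 seeds (sphere); the
search-versus-grid comparison uses the full 270-sample imbalanced table
with the complete 20 × 200 SAPSO budget against the coarse $4^4$ grid;
the end-to-end pipeline uses 120 images (60 per class), which bounds the
PCA rank at 119 — comfortably above the 98 components kept.

## Known limitations

* The SVM is strictly binary; no multiclass scheme or probability
  calibration.
* The handcrafted set is *a* standard 7+2+4 choice, not a canonical one;
  swapping definitions changes the feature block and any downstream
  numbers.
* The built-in embedder is a random projection: adequate for exercising
  the cascade and PCA plumbing, not a learned representation. A real CNN
  embedding can be injected through the embedder contract.
* Mercer validity of the sigmoid kernel across the searched $(a, r)$ box
  is not enforced anywhere — by design, since the training procedure
  tolerates indefiniteness — so individual fits may warn.
* Grid search cost grows as the product of grid sizes; the default
  4-points-per-component grid is a coarse oracle, not a competitive
  tuner.
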