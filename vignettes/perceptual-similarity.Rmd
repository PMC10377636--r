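---
title: "Scoring lesion visibility from perceptual color and texture similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring lesion visibility from perceptual color and texture similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(percsim)
library(dplyr)
```

## The measurement problem

Clinicians grade how *visible* a basal cell carcinoma (BCC) site or its
post-treatment scar is by comparing the target skin area with the
surrounding, perilesional skin, typically on an ordinal scale from 1
(indistinguishable) to 4 (strong deviation), separately for color and for
texture. Such visual grading is subjective; percsim implements an automated
counterpart built from clinical photographs alone.

The unit of analysis is a **patch triplet**: a target patch $S$ and two
perilesional reference patches $S_1$, $S_2$ cropped from the same
photograph. Every similarity measure $M$ in the package is aggregated the
same way,

$$\mathrm{similarity} = \frac{M(S, S_1) + M(S, S_2)}{2},$$

so the score always expresses the deviation of the lesion from *its own*
surrounding skin. Because both patches come from the same photograph, the
comparison is largely self-calibrating against camera, lighting and image
scale.

## Color similarity

Color deviation is measured between the *mean color vectors* of the
patches. Pixels are converted to the target space first and then averaged
(`mean_color()`, convert-then-average): under the nonlinear CIELAB mapping
this weights perceptual coordinates uniformly, whereas averaging sRGB first
would weight them by the local slope of the transform. The alternative
order is available via `order = "average_first"` for sensitivity analysis.

Three spaces and four metrics are provided:

* **RGB** — stored values, no transformation;
* **YIQ** — the NTSC/FCC linear transform of gamma-encoded sRGB, pinned to
  the matrix given in `?rgb_to_yiq` (several variants circulate; fixing one
  makes results bit-reproducible). Luminance Y separates from the
  blue–orange I and green–purple Q axes;
* **CIELAB** — full IEC 61966-2-1 sRGB companding, D65 white, 2° observer.
  The white point is derived from the sRGB→XYZ matrix itself so the gray
  axis maps to exactly zero chroma.

Distances: Euclidean (`euclidean_distance()`, equal to ΔE(1976) in LAB),
the Bray–Curtis distance (`bray_curtis_distance()`,
$\sum|c_{1i}-c_{2i}| / \sum (c_{1i}+c_{2i})$, bounded in $[0,1]$ and defined
for nonnegative coordinates — plausible skin colors are positive in YIQ and
LAB, and negative coordinates raise an error rather than being silently
absolved), and the CIE94 difference (`delta_e94()`) with graphic-arts
constants ($k_L=k_C=k_H=1$, $K_1=0.045$, $K_2=0.015$). CIE94 is asymmetric
through its reference chroma; percsim always takes the reference from the
first argument, which by convention is the target patch.

The bounded Bray–Curtis distance converts to a similarity as $1-\mathrm{BCD}$
(`to_similarity()`), the orientation used in cluster plots.

## Texture similarity

Texture deviation is measured between deep-network activations of the two
patches (`extract_activations()`): at a convolutional layer, the cosine of
the two channel vectors at each spatial position averaged over positions
(`cosine_similarity_spatial()`); at a fully connected embedding, the plain
vector cosine (`cosine_similarity_vector()`). Rectified variants are
distinct layers (`fc6` vs `relu6`); the rectified first fully connected
embedding `relu6` is the default texture layer. On rectified, sparse maps
a position where both channel vectors are zero contributes 1 (identical
absence of response) and a position where exactly one is zero contributes
0, which keeps the average free of NaNs.

Backbones are pluggable `backbone_spec()` objects: an ordered layer list
with weights plus a preprocessing recipe (bilinear resize to a fixed input
size and per-channel normalization — fully connected layers need a fixed
input size, so the resize applies to all layers). The classic VGG16 layer
naming (`conv1_1 … relu7`) is the reference vocabulary, and a pretrained
VGG16 can be supplied as a weights list through the same interface.

The bundled backbone is a **seeded stub**: two 3×3 convolution + ReLU +
max-pool blocks, global average pooling, and one fully connected embedding,
with weights drawn once from a seeded Gaussian. Three design choices make
it a usable texture instrument rather than a mere placeholder:

* convolution kernels are **mean-centered**, with edge-replicate padding, so
  activations are exactly invariant to constant color shifts — texture
  scores cannot leak mean-color information;
* **global average pooling** before the embedding makes the descriptor a
  function of channel response statistics (a texture signature), so patches
  with the same texture but independent noise realizations embed nearly
  identically;
* the **fc bias is nonzero** (scale 0.1, a few times the baseline skin
  response), anchoring the embedding so the cosine is *not* scale-invariant
  in the input: different texture amplitudes produce genuinely different
  embedding directions, as they do in trained networks.

Random convolutional features are a long-standing, effective texture
descriptor; the stub is deterministic, dependency-free, and every test in
the package runs on it. It is *not* a perceptual model of human vision —
conclusions about perceptual fidelity on real skin require a pretrained
backbone and real photographs.

## From similarity to the 1–4 scale

`fit_olreg()` fits the proportional-odds model
$P(Y \le j \mid x) = \mathrm{logistic}(\theta_j - \beta x)$ by maximum
likelihood: thresholds start at the empirical cumulative class logits,
$\beta$ at zero; BFGS iterations are polished by Newton steps until the
gradient ∞-norm falls below $10^{-8}$ (cap 200 iterations). Under perfect
separation the fit stops at the cap with a warning and keeps the last
iterate — predictions remain usable even though the parameters diverge.
Color metrics are distances (larger = more visible) and texture metrics are
similarities (larger = less visible); the `orientation` argument flips the
predictor's sign internally and records the flip, so both arrive in a
common "larger means more visible" frame. `predict_class()` takes the
class with maximal probability, breaking ties toward the lower (less
visible) class — the conservative choice for clinical use.

`validate_metric()` repeats the study design: each repetition draws a
class-balanced split (`balanced_split()`, 20 training items per class;
with 4 × 44 items that is the 80/96 train/validation design), fits the
model on the training similarities, and scores the validation items by
MSE, absolute accuracy, and adjacent accuracy (within one level).
Repetition $r$ uses seed $\text{master} + r$, so any single repetition is
reproducible in isolation and the whole report is bit-reproducible.
Means over repetitions carry normal-approximation 95% intervals
($\bar x \pm 1.96\, s/\sqrt{n}$); the estimator is simple, adequate at 100
repetitions, and stated explicitly so it can be replaced. Validation is
against the *rounded* mean gold score — the same labels the balanced
training uses; `gold_scores()` rounds half away from zero (a 2.5 boundary
item becomes 3) because banker's rounding would silently shift class
counts, and the rule is switchable.

`kmeans_cluster()` (base `stats::kmeans`, Lloyd iterations, 10 seeded
random restarts keeping the lowest inertia) summarizes items in the
$(1-\mathrm{BCD},\ \text{texture similarity})$ plane with $k = 4$ and
appends per-cluster mean perceptual scores; a coherent metric pair yields
clusters whose perceptual scores are monotone along the similarity axes.
Multi-start random seeding replaces k-means++ seeding; with $n$ in the
hundreds and 2 dimensions the restarts make the difference immaterial.

## Agreement machinery

To ask whether the automated scorer behaves like an expert, its predictions
join the human panel as an extra rater:

* `cronbach_alpha()` — internal consistency of the items × raters table,
  unbiased variances; `alpha_drop_one()` recomputes it with each rater
  removed;
* `cohen_kappa_quadratic()` — pairwise chance-corrected agreement with
  quadratic weights $w_{ij} = 1-(i-j)^2/(q-1)^2$; two constant, equal
  raters give $\kappa = 1$ by convention, constant-but-different raters
  give 0 with a warning;
* `gwet_ac2()` — multi-rater weighted agreement with the prevalence-robust
  chance term $p_e = \frac{T_w}{q(q-1)} \sum_k \pi_k(1-\pi_k)$; quadratic
  weights by default, linear by flag (the weighting scheme for ordinal
  panels is conventionally quadratic, matching the kappa);
* `compare_groups()` — all $\binom{k}{2}$ Human–Human kappas versus the $k$
  System–Human kappas, with a two-sided Wilcoxon rank-sum comparison. With
  at most 10 pairs per group the p-value is computed by exact enumeration
  over assignments (midranks for ties) — small kappa samples with ties sit
  outside the comfort zone of the normal approximation — otherwise the
  tie-corrected normal approximation is used.

Missing ratings are rejected rather than pairwise-deleted: the intended
panels are complete, and silent deletion changes what the coefficients
estimate.

## What the synthetic generator emulates — and what it does not

No photograph collection ships with the package, so `generate_dataset()`
fabricates study-shaped data: per item, a base skin color (sRGB
(0.80, 0.55, 0.45), small per-photo variation) plus low-amplitude smoothed
luminance noise for the perilesional patches, and for the target patch an
additional grade-controlled mean-color offset along an erythema-like
direction (green and blue fall faster than red) and grade-controlled
band-passed structural noise. The default grade map (offsets 0/0.04/0.09/
0.16 sRGB units; texture amplitudes 0/0.03/0.07/0.12; lognormal jitter,
SD 0.35 on the log scale, truncated at ±2 SD to stay in gamut) was chosen
once so that grades are ordinally separated but adjacent grades overlap:
absolute accuracy stays well below adjacent accuracy, the regime the
ordinal validation is designed for. Grade marginals default to 24/61/44/47
over 176 items, a realistic mix in which indistinguishable sites are the
smallest class. `simulate_raters()` models an expert as the true grade
plus latent Gaussian noise, rounded and clamped to 1–4; at noise SD 0.5 a
six-rater panel shows excellent consistency (α > 0.9) with moderate
pairwise kappa, the signature of a real expert panel.

The generator reproduces the *statistical* structure the pipeline needs —
graded, noisy, separable color and texture factors — and nothing else. It
does not attempt photorealism: no lesion shapes, no illumination gradients,
no specular highlights (shiny patches are a known failure mode of color
scoring on real photographs), no camera noise. Passing tests on synthetic
data therefore demonstrate that the machinery is correct and ordinally
coherent, not that the metrics match human perception of real skin.

## Numerical choices and degenerate inputs

* Patches below 8×8 px are rejected: mean colors become unstable and
  convolutional features degenerate.
* ROIs are 0-based, half-open, x along columns; images are consumed as
  stored sRGB with no ICC handling (heterogeneous clinic cameras, no
  calibration data).
* Bray–Curtis clamps numerical zeros (|value| ≤ 1e-9) but rejects true
  negative coordinates; an all-zero denominator is defined as distance 0.
* ΔH² in CIE94 is clamped at zero before the square root.
* A single validation repetition reports point values with a warning (no
  CI); degenerate k-means inputs (fewer distinct points than clusters)
  collapse to the feasible number of clusters with a warning.
* All randomness flows through explicit seeds (`withr::with_seed`), so no
  call disturbs the session RNG; derived seeds stay below 2³¹.

## Problem sizes

The shipped tests and the acceptance script use the full 176-item synthetic
study with 48×48 patches, the 32×32-input stub backbone, 100 validation
repetitions, and 1000-pair metric-axiom sweeps; this keeps a complete run
in the order of a minute or two on one CPU.

## Worked example

```{r example, eval = FALSE}
ds <- generate_dataset(master_seed = 1)          # 176 graded triplets
bb <- stub_backbone()

scores <- ds$truth |>
  mutate(
    distance = score_color(ds$triplets, space = "YIQ", metric = "bcd")$distance,
    tsim     = score_texture(ds$triplets, bb, layer = "relu6")$similarity
  )

glance(validate_metric(scores, distance, grade, n_reps = 100, seed = 2))
glance(validate_metric(scores, tsim, grade, n_reps = 100, seed = 2,
                       orientation = "similarity"))

panel <- simulate_raters(scores$grade, n_raters = 6, noise_sd = 0.5, seed = 3)
compare_groups(panel, gold_scores(panel)$rounded_score)
```

## Known limitations

The stub backbone measures structural-noise amplitude and scale, not
learned perceptual texture; CIE94 is the most perceptual color difference
implemented (no CIEDE2000); patches are assumed free of specular
highlights and tattoos (violations error loudly where detectable); and the
agreement module requires complete panels.
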