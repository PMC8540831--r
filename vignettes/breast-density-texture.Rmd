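---
title: "Texture descriptors for mammographic breast density: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture descriptors for mammographic breast density: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densitex)
```

## The problem

Breast density — the proportion of dense fibro-glandular tissue within the
breast area — is a risk factor for breast cancer and reduces mammographic
sensitivity through the masking effect. Clinically it is reported on the
four-category BI-RADS scale (I: 0–25% dense tissue, II: 26–50%,
III: 51–75%, IV: >75%), mostly by visual assessment, which suffers from
inter- and intra-reader variability. `densitex` implements an automated
pipeline that classifies a mammogram into those categories from texture
features of the breast region alone: multi-fractal alpha-histograms,
local binary pattern (LBP) histograms, and their fusion.

## Hölder exponents and alpha-images

For a pixel $p$, a local measure $\mu_w(p)$ is evaluated over square
windows of odd width $w$ centred at $p$. If the measure scales as
$\mu_w(p) = C\,w^{\alpha_p}$, the Hölder exponent $\alpha_p$ quantifies
the local singularity strength and is estimated as the slope of the
ordinary least-squares line of $\log \mu_w(p)$ against $\log w$. Four
measures are implemented:

* **maximum** $\mu_w(p) = \max_{(k,l)\in\Omega} g(k,l)$,
* **inverse-minimum** $\mu_w(p) = 1 - \min_{(k,l)\in\Omega} g(k,l)$,
* **summation** $\mu_w(p) = \sum_{(k,l)\in\Omega} g(k,l)$,
* **iso** $\mu_w(p) = \#\{(k,l)\in\Omega : |g(k,l) - g(p)| \le \tau\}$,

where $\Omega$ is the $w \times w$ window and $g$ the normalized
intensity. Replacing each pixel by $\alpha_p$ yields the alpha-image; the
range $[\alpha_{\min}, \alpha_{\max}]$ over ROI pixels is divided into 100
equal-width bins and bin heights are ROI-pixel *proportions*, so breasts
of different areas give comparable 100-bin feature vectors.

Analytic limits pin the implementation down: on a constant image the
maximum and inverse-minimum measures are flat in $w$ ($\alpha = 0$), while
iso and summation grow exactly as $w^2$ ($\alpha = 2$). These are asserted
to machine precision in the tests.

### Numerical choices

* Windows default to $w \in \{1, 3, 5\}$; $w = 1$ means
  $\Omega = \{p\}$. At least two windows are required for the regression.
* Intensities are min–max normalized to $[0,1]$ before any measure. The
  logarithm then amplifies subtle low-intensity structure for the
  maximum/inverse-minimum measures. A constant image normalizes to all
  zeros (the only degenerate case of the affine map; any constant works as
  the image carries no contrast).
* All four measures consume normalized intensities, keeping the log
  arguments scale-free; normalization is mandatory only for
  maximum/inverse-minimum, but using it uniformly makes the four feature
  blocks commensurable.
* The iso tolerance $\tau$ defaults to $1/255$ in normalized units,
  reproducing integer equality on 8-bit data; it is configurable for other
  bit depths.
* Measures are floored at $\varepsilon = 10^{-12}$ before the logarithm
  (the inverse-minimum measure reaches 0 exactly wherever a window touches
  a normalized maximum), keeping every $\alpha$ finite.
* Borders use symmetric (edge-repeating) reflection so $\alpha$ is defined
  at every pixel; ROI masking is applied only at histogram time. Pixels
  farther than $\max(w)/2$ from the ROI therefore cannot influence any
  histogram bin, a property the tests assert.
* The histogram range is per-image, as the proportion-normalized
  construction dictates. Bins are therefore not aligned across images; the
  descriptor captures the *shape* of each image's alpha distribution, and
  cross-image comparability rests on the shape, not on absolute alpha
  values. A fixed global range would be a reasonable alternative but would
  need a calibration corpus.

## LBP, elliptical and multi-resolution variants

The LBP code of a pixel compares its grey level $g_c$ with $P$ neighbours
$g_i$ sampled at angles $2\pi i/P$ (starting due east, counter-clockwise)
on a circle of radius $R$:
$\mathrm{LBP}_{P,R} = \sum_{i=0}^{P-1} s(g_i - g_c)\,2^i$ with
$s(x) = 1$ for $x \ge 0$ and $0$ otherwise. Neighbours at non-integer
positions are bilinearly interpolated with reflected borders. The
elliptical variant samples at $(R_2\cos\theta_i, R_1\sin\theta_i)$ with the
semi-major axis $R_2$ along image rows, capturing anisotropic structure; a
circle is the degenerate case $R_1 = R_2$. The multi-resolution descriptor
(MLBP) concatenates the 256-bin histograms of radii 2 and 4 at $P = 8$
into a 512-length vector, each half normalized to sum 1.

Design choices the encoding leaves open were fixed to the dominant
conventions so histograms are comparable with common references: bit $i$
carries weight $2^i$, sampling starts east and proceeds counter-clockwise,
and $s(0) = 1$. Working configurations are $R = 2$ for plain LBP,
$(R_1, R_2) = (1, 4)$ for ELBP — one ellipse with $P = 8$, giving a single
256-bin histogram — and radii $\{2, 4\}$ for MLBP. Raw 256-code histograms
are used throughout; uniform or rotation-invariant code folding is
deliberately not applied. Comparisons use a $10^{-12}$ tolerance so that
floating-point round-off in the interpolation cannot flip an exact tie
(the $s(0) = 1$ case), which otherwise occurs at reflected borders.

Because codes depend only on intensity *comparisons*, code maps are
invariant under shifts and under affine (and, away from interpolation
knife-edges, any monotone) intensity transforms — the property that makes
LBP robust to mammographic exposure differences.

## Fused descriptor and feature selection

The cascaded descriptor concatenates one 100-bin alpha-histogram with the
512-bin MLBP vector — multi-fractal block first — giving 612 features. The
two blocks are complementary: alpha-histograms summarise singularity
statistics, LBP histograms local sign patterns.

**PCA** follows the textbook construction: per-dimension means, sample
covariance with the $M-1$ denominator, symmetric eigendecomposition,
eigenvalues sorted descending, projection of the centred data onto the
leading $n$ eigenvectors. Eigenvector signs are fixed deterministically
(largest-magnitude entry positive) so runs are reproducible. The working
dimensionality for the fused descriptor is $n = 45$ of 612 — over 90% of
the feature space removed; `select_pca_n()` scans
$n \in \{5, 10, \dots, 70\}$ by cross-validated accuracy when a different
dataset calls for retuning.

**Autoencoder.** As an alternative selector, a symmetric fully connected
hourglass network reconstructs the (per-feature min–max scaled) descriptor
under binary cross-entropy; the bottleneck (code) layer provides the
reduced features. Hidden layers use ReLU, the output layer sigmoid.
Configurations scan 5–15 hidden layers and code widths
$\{16, 32, 64, 128\}$; the default is 11 hidden layers with code width 64.
Since published diagrams of such hourglasses rarely print intermediate
widths, widths interpolate geometrically between the input and code
dimensions, mirrored on the decoder side. Training uses Adam
(learning rate $10^{-3}$, batch 32, 200 epochs) with a fixed seed; the
implementation is a compact dense-network reference in base R matrix code,
adequate for tabular descriptors of this size. Within cross-validation the
autoencoder is retrained per fold on training data only, avoiding leakage
at the cost of fold-wise training time.

## Classification and evaluation

A multiclass SVM in one-against-all decomposition: one binary C-SVM per
class against the rest, prediction by the largest decision value.
Hyper-parameters are grid-searched over kernels RBF/polynomial/sigmoid,
$\gamma \in [10^{-4}, 10^3]$ and $C \in [10^{-3}, 10^4]$ at decade steps,
and polynomial degrees 1–6 (512 candidates), selected by inner 3-fold
accuracy on the training portion. Ties break toward smaller $C$, then
smaller $\gamma$, lower degree, and kernel order RBF < Poly < Sigmoid —
i.e. toward the smoother model.

Evaluation is stratified 5-fold cross-validation (stratification matters:
the extremely-dense class is rare in clinical datasets — 28 of 409 images
in INbreast — and plain k-fold could starve a fold). Everything fit to
data — standardization, PCA or autoencoder, grid search — uses the
training fold only; held-out predictions are pooled into one confusion
matrix. Reported metrics: accuracy (trace/total), Cohen's kappa from the
marginals, F1 both support-weighted and macro-averaged (the weighted
variant reconciles better with published summary tables computed from
pooled matrices; both are exposed), and macro one-vs-rest AUC from the
decision values, reported as mean ± SD across folds (the per-fold unit is
also what the paired t-tests use; with pooled matrices there is no
natural ± otherwise). Descriptors are compared by two-tailed paired
t-tests on fold-wise accuracies, with the degenerate cases fixed by
contract: identical fold accuracies give $p = 1$; a constant non-zero
difference gives $p = 0$.

A purely computational note: for folds with more features than samples the
feature block is replaced by an eigenfactor $Z$ of its Gram matrix
($ZZ^\top = XX^\top$). The RBF, polynomial and sigmoid kernels depend on
the data only through inner products, so every kernel value — and hence
every SVM solution — is unchanged (verified to $10^{-13}$ in tests), while
the libsvm kernel cost stops scaling with descriptor length.

## Synthetic phantoms

Clinical FFDM datasets are license-gated, so the package ships a phantom
generator that emulates exactly the properties the pipeline consumes:

* a half-elliptical bright breast region against a near-zero background,
  anchored on the left (chest-wall) edge;
* for MLO views, a bright pectoral triangle in the upper chest-wall corner
  (absent in CC views), disjoint from the breast mask;
* a smooth fractional-Brownian fatty base texture
  (spectral-synthesis fBm, Hurst 0.5, amplitude 0.06 over a 0.30 base);
* Gaussian dense-tissue blobs (SD `min(H,W)/32` px, amplitude ≈ 0.5,
  capped at 0.90) added inside the breast until the fraction of breast
  pixels above the fixed dense threshold 0.6 reaches a target drawn inside
  the BI-RADS band (targets keep a small margin from the band edges:
  0.06–0.20, 0.30–0.45, 0.55–0.70, 0.80–0.92 for classes I–IV);
* additive Gaussian noise (SD 0.01) last, then 16-bit quantization.

The dense threshold is a fixed generator constant: clinically, density is
an *area proportion*, not an intensity rule, so the generator defines
dense tissue by construction and records the realized fraction. Blob
centres keep a 2.5-SD margin from the pectoral edge so that dense tissue
and pectoral muscle remain separable components for the removal stage.
Everything is deterministic per seed (`withr::with_seed`), and identical
specs produce bitwise-identical images.

What the phantoms do *not* emulate: anatomic parenchymal patterns, skin
lines, nipple structure, lesions and calcifications, scanner artefacts, or
the heavy-tailed intensity statistics of real FFDM. Passing tests on
phantoms therefore validates the *mechanics* of the pipeline (geometry,
masking, feature definitions, fold hygiene, monotone relations between
density and features) — not clinical accuracy on real mammograms.

## Preprocessing design (where the design was open)

The published pipeline stage list (contrast enhancement, intensity
thresholding, morphological operations, K-means + polynomial fit for the
pectoral muscle, 3×3 median filter) leaves parameters unspecified, so this
package fixes them as follows:

* **Thresholding.** Otsu on the normalized image, with a tri-level
  refinement: dense breasts have three intensity modes (background, fatty,
  dense) and a single Otsu cut can land between fatty and dense tissue.
  When the sub-threshold population itself splits into two classes whose
  means differ by more than 0.1 normalized units, that lower cut is taken
  as the background/tissue boundary. When Otsu yields no foreground at
  all, the inverse-minimum alpha-image — which amplifies the
  background/tissue transition — is thresholded instead, implementing the
  multi-fractal contrast-enhancement stage.
* **Morphology.** Opening with a disc of radius 5 px at 512-px image
  width, scaled proportionally; hole filling; retention of the largest
  4-connected component.
* **Pectoral removal** (MLO only). 2-cluster K-means on intensities inside
  the mask with deterministic quantile-seeded centres (25th/95th
  percentiles); the bright cluster's 4-connected component touching the
  chest-wall upper corner is the pectoral candidate; its per-row outer
  boundary is smoothed by a degree-2 polynomial and everything on the
  chest-wall side of the curve (+2 px margin) is removed. If no bright
  component touches the corner the mask is returned unchanged, which also
  makes the operation idempotent. Images are oriented chest-wall-left
  first (laterality tag, else a column-sum heuristic).
* **Median filter.** 3×3 with reflected borders, as a vectorized
  median-of-9 selection network.

## Problem sizes used in the shipped experiments

The packaged experiments run at sizes a laptop handles comfortably:
phantoms at 256×256 (the texture operators are resolution-independent;
features are ROI proportions), 20 phantoms per class for the end-to-end
comparison, 40 phantoms at 128×128 for segmentation validation, and five
cross-validation seeds for the fusion-vs-individual comparison. The
acceptance script (`scripts/acceptance.R`) re-derives every reported
quantity from scratch at these sizes.

## Known limitations

* Phantom realism as discussed above; headline clinical accuracies from
  gated datasets are not reproducible here and are represented by their
  printed confusion matrices (shipped as reference data) instead.
* Per-image alpha-histogram ranges make bins non-aligned across images.
* DICOM reading is not included; convert to 16-bit PNG/TIFF first.
* The OAA decision-value comparison is un-calibrated across binary
  machines; Platt scaling is out of scope.
* The grid search is exhaustive by design (512 candidates × 3 inner
  folds × one binary machine per class); it dominates runtime for small
  feature sets.
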