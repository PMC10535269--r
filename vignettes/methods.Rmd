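---
title: "Methods: separability screening, random-forest mapping, CASA productivity and maximum-entropy suitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separability screening, random-forest mapping, CASA productivity and maximum-entropy suitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(carbonscape)
```

This vignette documents the models implemented in `carbonscape`, the
choices made where the methodology left room, and what the synthetic test
conditions do and do not demonstrate.

## The study design being emulated

The pipeline reproduces a common workflow in plantation-forestry remote
sensing: identify the acquisition window and band set in which a target
tree species separates best from its confusable neighbours, map it with a
random forest, estimate the mapped stand's annual carbon fixation with a
light-use-efficiency model, and delimit its climatically suitable area with
a presence–background niche model. The land-cover legend is five classes —
urban, waterbody, cropland, other forests, and the target plantation tree —
observed on three dates (May, June, September) by an 8-band sensor whose
distinguishing feature is a pair of red-edge bands (B5: 690–730 nm, B6:
730–770 nm) alongside blue, green, red, NIR, violet and yellow bands.

## Separability: Jeffries–Matusita distance

For univariate Gaussians the implemented Bhattacharyya distance is

$$B = \frac{(\mu_i-\mu_j)^2}{4(\sigma_i^2+\sigma_j^2)} +
      \frac12\ln\frac{\sigma_i^2+\sigma_j^2}{2\sigma_i\sigma_j},
\qquad J = 2(1-e^{-B}).$$

`jm_distance()` defaults to the full multivariate Gaussian form with pooled
covariance $(\Sigma_i+\Sigma_j)/2$, the standard choice when scoring 6–11
feature band sets; a `univariate-mean` mode (average per-feature $B$) is
retained as a diagnostic because published separability tables often do not
state which form they used. A relative ridge of $10^{-8}\cdot\mathrm{tr}/d$
is added to each covariance before inversion: with 28–53 samples per class
and up to 11 features, sample covariances can be near-singular. The ridge
breaks exact affine invariance at the $10^{-7}$ level; the unregularized
form (`reg = 0`) is exact and is what the invariance test checks.

The closed form is validated against direct numerical integration of
$2(1-\int\sqrt{p_ip_j})$ for random Gaussian pairs to $10^{-6}$, and
$B=\ln 2 \Rightarrow J=1$ exactly.

`select_optimal_window()` picks the date maximizing the hardest pair
(target vs other forests by default); ties go to the earliest date and are
flagged.

## The synthetic scene generator

`synth_truth()` fixes the study conditions. The label map is a seeded
Voronoi tessellation (60 sites over 120×120 px at 16 m) so classes form
contiguous patches and the 20 m sample-spacing rule is meaningful. Pixel
spectra are per-class Gaussians plus a shared per-pixel brightness factor
(`gain ~ N(1, γ²)` multiplying the whole spectrum), a rank-one inter-band
correlation that mimics within-class canopy and illumination variability.
This factor matters: it inflates the variance of each band along the
spectrum direction while cancelling exactly in normalized-difference
indices, which is why adding NDVI-family indices genuinely improves
empirical separability here, as it does in practice.

The target-vs-forest contrast is a red-edge *position shift* — the target
sits lower in B5 and higher in B6 than other forests, with modest NIR and
red offsets — scaled per date by (0.62, 0.45, 1.0) so September is the
best window by construction and June the worst. These magnitudes were set
once, from the closed-form configured J–M (`configured_jm()`), to place the
September all-band separability near 1.55 and the no-red-edge set near
0.6–0.9: large enough that red-edge models win the classification
comparison, small enough that the baseline model makes errors. `sd_scale`
scales all class noise; `sd_scale = 0.5` yields configured pairwise J–M
above 1.9 for every pair and is the condition under which full-raster
recovery above 95% is asserted. `red_edge_boost = 0` removes the red-edge
advantage entirely, for falsification tests.

Ground samples follow the survey design: 45/28/43/53/39 points for
urban/waterbody/cropland/other-forests/target, minimum pairwise spacing
20 m (greedy thinning over shuffled eligible pixels), stratified 3:1 split
with `train = floor(3n/4)` per class — so 39 target points give 29 train
and 10 test.

Climate is a monthly sinusoid per variable plus iid pixel noise
(temperature: mean 14 °C, amplitude 12, peak July, σ 0.5; precipitation:
60/55 mm, σ 8, floored at 0; solar radiation: 420/180 MJ m⁻² month⁻¹,
σ 15) — values typical of a humid warm-temperate hill county. Monthly NDVI
follows per-class phenology sinusoids (forests peaking near 0.8 in summer,
water slightly negative). Bioclim covariates BIO1–BIO19 are
Gaussian-filtered white noise (kernel σ = 6 px), standardized and mapped to
plausible units; occurrences are drawn with probability proportional to
`plogis(-10 + 8·z(BIO17))`, a deliberately sharp single-driver surface so
the true surface itself scores a held-out AUC above 0.9 — a weaker surface
would make that bar unreachable for any fitted model.

What passing these tests shows: the estimators recover the structure the
generator encodes, at realistic sample sizes. What they do not show:
robustness to mixed pixels, sensor noise, atmospheric effects, terrain
shadowing, spatially clustered sampling bias, or class spectra that are
non-Gaussian — none of which the generator simulates.

## Classification

The random-forest learner is `randomForest` (500 trees; `floor(sqrt(p))`
features per split, minimum 1); the package's own surface is schema
control, the shared-partition comparison harness, and raster application.
All eight registry models are scored on the *same* test set (the partition
is fixed before any model is fitted and its hash is reported); the winner
is the highest OA, with ties broken by target-class producer accuracy and
then lowest model id. Accuracy metrics come from the confusion-matrix
module: rows are the mapped class, columns the reference class, so row
totals give user's accuracy and column totals producer's accuracy; Cohen's
κ uses the marginal-product expected agreement. Area-weighted variants take
per-segment weights; unit weights reproduce plain counts exactly. One
caveat surfaced by testing: overall accuracy is invariant to *renaming*
classes but not to *reordering* factor levels, because tie-breaking inside
the forest depends on level order — the invariance test therefore permutes
names, not positions.

## CASA productivity

The light-use-efficiency chain is

$$\mathrm{NPP} = 0.5\,\mathrm{SOL}\cdot\mathrm{FPAR}\cdot
T_{\varepsilon1}T_{\varepsilon2}W_\varepsilon\,\varepsilon_{max}.$$

The stress formulations follow the widely used regional parameterization
behind county-scale CASA studies, implemented as pluggable functions:

* **FPAR**: mean of the NDVI linear stretch and the simple-ratio
  (`SR = (1+NDVI)/(1−NDVI)`) linear stretch, each mapping the
  vegetation-type range onto [0.001, 0.95], clamped. The per-type range is
  "automatically configured" as the 5th/95th percentile of that type's
  12-month NDVI series.
* **Temperature**: $T_{\varepsilon1} = 0.8+0.02T_{opt}-0.0005T_{opt}^2$;
  $T_{\varepsilon2} = 1.1814/[(1+e^{0.2(T_{opt}-10-T)})(1+e^{0.3(T-T_{opt}-10)})]$.
  $T_{opt}$ is the monthly mean temperature of each pixel's
  maximum-NDVI month. Note the asymmetric logistic shoulders put the true
  maximum of $T_{\varepsilon2}$ one to two degrees above $T_{opt}$; the
  tests assert near-maximality at $T_{opt}$ (within 2% of the scanned
  maximum) rather than exact argmax equality.
* **Water**: $W_\varepsilon = 0.5+0.5\,\mathrm{EET/PET}$ clamped to
  [0.5, 1], with EET from the Zhou–Zhang regional form, net radiation
  approximated from Thornthwaite potential evapotranspiration and
  precipitation, and $\mathrm{PET} = (\mathrm{EET}+\mathrm{PET}_0)/2$;
  zero-PET pixels take the dry floor and are counted.

$\varepsilon_{max}$ ships as a documented literature lookup per vegetation
type (0.389 g C MJ⁻¹ for non-forest, 0.542 cropland, 0.692 deciduous
broadleaf for both tree classes) — configuration, not ground truth. Annual
NPP is the exact sum of the 12 monthly grids, and every pixel respects the
analytic bound $0.5\,\mathrm{SOL}\times0.95\times T_{\varepsilon1}\times
1.1814\times\varepsilon_{max}$.

The carbon total over a class mask is
$\sum \mathrm{NPP}\cdot A_{px}\cdot 10^{-6}$ t C a⁻¹. Validation samples
30 random pixels and reports RMSE, $r$ and $r^2$; published usage labels
the correlation-coefficient formula "R²", so both are reported. Because no
independent productivity reference exists for a synthetic area, the
analysis validates against the model's own field plus known noise, which
verifies the statistic (RMSE recovers the injected σ within ±10% in
expectation at n = 30) rather than model skill.

## Natural breaks

`jenks_breaks()` is the exact Fisher dynamic program (O(k n²), prefix-sum
segment costs), verified against exhaustive enumeration of all partitions
for short arrays. Raster-scale inputs (beyond `max_n = 2000` values) are
first thinned to evenly spaced order statistics — the standard practice in
GIS implementations — which leaves four-class break positions on a 14 400
pixel NPP surface essentially unchanged while keeping the run sub-second.
Class assignment uses lower-bound-inclusive intervals, so the fixed
suitability thresholds 0.16/0.35/0.5 tile (0, 1) without gaps (published
bounds like "0.16–0.35" and "0.36–0.5" are treated as rounded renderings of
half-open intervals).

## Maximum-entropy suitability

The model is the Gibbs form $\pi(x)\propto e^{\lambda\cdot f(x)}$
normalized over the background sample, fitted by maximizing the mean
presence log-likelihood minus an L1 penalty
$\beta_j = \beta\,\max(s_j, 0.05)/\sqrt{m}$ ($s_j$: presence feature SD,
$m$: presence count). Features are linear, quadratic, and forward/reverse
hinges at three interior knots, all scaled to [0, 1] from the combined
presence+background range. Optimization is cyclic coordinate-wise penalized
Newton with soft-thresholding, a ±1 step clamp, and convergence when the
penalized-gain improvement per cycle drops below $10^{-5}$ (or 1000
cycles); typical fits converge in 20–60 cycles. The raw output sums to 1
over the training background after every fit — asserted in tests — and the
logistic output is $c\,r/(1+c\,r)$ with $c=e^H$, $H$ the entropy of the raw
background distribution, giving 0.5 under a featureless model.

Replicates: ten 75/25 presence resamples, each scored by held-out AUC
(rank-based, midrank ties) against the full background. Variable
importance: percent contribution accumulates each coordinate update's gain
increment on the owning variable (negatives floored, normalized to 100);
permutation importance is the drop in training AUC after shuffling one
variable across all points (floored, normalized to 100 — published
permutation columns are normalized differently by different tools, so only
rankings are comparable); jackknife refits with-only/without each variable
and reports training gains. Background size defaults to the whole grid up
to 10 000 cells in the pipeline configuration, 2000 in the analysis
scripts.

## Numerical and design choices

* Grids are plain matrices with origin/resolution metadata; pixel-centre
  coordinates, row 1 at the north edge. On-disk raster format is ESRI
  ASCII (`.asc`) with a JSON sidecar for multi-layer stacks — plain text,
  standard in the niche-modelling toolchain, and lossless at double
  precision.
* Index pixels with zero denominators become NA and are counted, never
  silently zeroed; out-of-raster sample points are reported in an
  exclusion list, never dropped.
* All stochastic steps take explicit integer seeds; stage seeds derive
  from one master seed but can be overridden per stage, and changing a
  later stage's seed leaves earlier artifacts bit-identical (tested via
  file hashes).
* Problem sizes in the tests and drivers — 120×120 px scenes, 208 samples,
  2000-cell backgrounds, 10 replicates — were chosen as the smallest sizes
  at which the statistical properties under test are stable.

## Known limitations

* The classification comparison uses a single fixed 3:1 split, not
  cross-validation; with ~54 test points, OA moves in ~1.9 % steps.
* The evapotranspiration submodel is one documented regional
  parameterization; other CASA lineages differ, which is why the stress
  terms are pluggable.
* Station-to-grid interpolation is inverse-distance weighting, not
  kriging; gridded climate is the primary path.
* The MaxEnt implementation targets the documented model family (linear /
  quadratic / hinge, L1, logistic output), not byte-level parity with any
  particular GUI tool; absolute importance percentages are
  implementation-specific.
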