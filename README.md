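# carbonscape

Mapping a plantation tree species from multi-date 8-band imagery and
assessing its carbon sequestration capacity and climatic suitability — as a
single tested R pipeline, exercisable end-to-end on synthetic data with
known ground truth.

The package is aimed at remote-sensing ecologists who want the full chain —
band screening, supervised classification, productivity modelling and niche
modelling — reproducible from one seed without any satellite, climate or
occurrence downloads.

## What it computes

**1. Separability screening.** For two classes with Gaussian feature
distributions, the Jeffries–Matusita distance is

    J = 2 (1 − e^−B),      B = ⅛ (μ₁−μ₂)ᵀ Σ̄⁻¹ (μ₁−μ₂) + ½ ln( |Σ̄| / √(|Σ₁||Σ₂|) )

with Σ̄ the pooled covariance; J ∈ [0, 2] and J ≥ 1.8 conventionally means
excellent separability. The screening compares three feature sets — the six
non-red-edge bands, all eight bands, and all bands plus NDVI, NDVI710 and
NDVI750 — across three acquisition dates, and selects the date maximizing
the hardest class pair (target tree vs other forests).

**2. Classification harness.** Eight band/index combinations ("models")
are each fitted with a 500-tree random forest (√p features per split) on a
shared 3:1 train/test split; OA, Cohen's κ and the target class's
producer/user accuracy decide the winner, which is applied to every pixel.

**3. CASA productivity.** Monthly net primary productivity follows the
light-use-efficiency form

    NPP(x,t) = APAR(x,t) × ε(x,t)
    APAR = 0.5 · SOL · FPAR(NDVI),    ε = Tε1 · Tε2 · Wε · εmax

with FPAR an NDVI/simple-ratio linear-stretch blend clamped to
[0.001, 0.95], two temperature-stress terms around a per-pixel optimal
temperature, and a water stress Wε = 0.5 + 0.5·EET/PET from a regional
evapotranspiration submodel. Annual NPP is graded into four natural-breaks
(Fisher–Jenks) classes and summed over the mapped species area into a
carbon total (t C a⁻¹); validation draws 30 random points against a
reference raster and reports RMSE and r².

**4. Maximum-entropy suitability.** A presence–background Gibbs model over
BIO1–BIO19 covariates (linear + quadratic + hinge features, L1-regularized,
coordinate-wise updates, ≤1000 cycles), evaluated by held-out AUC over ten
75/25 replicates, with percent-contribution / permutation / jackknife
variable importance. The logistic suitability raster is zoned into four
classes (natural breaks or the fixed thresholds 0.16 / 0.35 / 0.5) and
per-zone areas are pixel counts × resolution².

A seeded synthetic-data module generates all inputs — a Voronoi-patch
land-cover map, per-class Gaussian spectra with a configured red-edge
advantage for the target tree, seasonal climate and NDVI series, and
occurrences drawn from a known logistic suitability surface — so every
stage is testable against the generating truth.

## Worked example

The numbered drivers under `analysis/` run the four stages on the default
synthetic study area (120×120 px at 16 m, seed 1):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_separability.R
Rscript analysis/03_classify.R
Rscript analysis/04_casa.R
Rscript analysis/05_sdm.R
```

Stage 2 prints the screening table (target vs other forests):

```
       date jm.combination1 jm.combination2 jm.combination3
 2021-05-09       0.6738917       1.2707191        1.664904
 2021-06-28       0.3698355       0.9030755        1.504508
 2021-09-09       0.9032905       1.7375247        1.935864

selected window: 2021-09-09 (J-M = 1.936)
```

Adding the red-edge bands roughly doubles the J–M distance on every date,
the indices push it past the 1.8 "excellent" threshold, and the September
scene is the best window — the structure the generator was configured to
exhibit. Stage 3 then ranks the models on that scene; every red-edge model
beats the no-red-edge baseline (model 1, OA 83.3%), and the winner reaches
test-set OA 92.6% (κ 0.907, target PA 100%, UA 90.9%). Stage 4 reports a
mean annual NPP of 511.7 g C m⁻² a⁻¹, natural-break grade bounds at
340 / 452 / 586, a target-species carbon total of 518.5 t C a⁻¹ over 3120
pixels, and a 30-point validation RMSE of 46.0 with r² = 0.91 against a
noisy reference. Stage 5 recovers the generating driver: BIO17 tops the
contribution table at 73.1%, and the ten-replicate held-out AUC averages
0.922.

Equivalent programmatic entry points: `run_pipeline(pipeline_config(...))`
runs everything into one output directory with a hash manifest.

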