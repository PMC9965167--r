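---
title: "Methods: multimodal fusion and multi-task learning for maize phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal fusion and multi-task learning for maize phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`maizefuse` implements a complete plot-level maize phenotyping pipeline for
co-registered UAV data — a hyperspectral reflectance cube (VNIR, 400–1000 nm,
3 cm ground sampling distance), LiDAR-derived canopy height and intensity, and
a thermal raster — together with a synthetic field-trial generator that makes
every stage testable without field data. This vignette records the models, the
parameters that matter, the numerical choices, and what the synthetic
experiments do and do not demonstrate.

# The synthetic field trial

The generator emulates a nitrogen-response trial: single-row plots of
5.33 m × 0.76 m arranged in blocks that alternate between a no-supplemental-N
control ("low N") and a fertilized treatment ("high N"). Eight end-of-season
traits are produced per plot: dry stalk biomass, cob biomass, dry grain yield
(all kg/ha), harvest index, grain nitrogen utilization efficiency (NutE),
grain N and total plant N (kg/ha), and grain density.

Traits are not drawn directly. Per-plant latent measurements (stalk, cob and
grain biomass in g/plant, stalk N %, grain protein %) come from a
treatment-conditional multivariate normal with a shared correlation structure,
and the plot traits are then **derived** with the standard formulas: biomass
components scale to kg/ha via standing plants (28) and plot area
(4.05 × 10⁻⁴ ha); grain protein converts to grain N through the Jones factor
6.25; plant N is stalk N + grain N; harvest index is grain over total
above-ground biomass; NutE is grain biomass per unit plant N mass. This
guarantees the accounting identities (grain N ≤ plant N, harvest index in
(0, 1)) by construction. Treatment means are calibrated so a ~370-plot trial
shows the canonical shape: strongly bimodal yield and N traits (coefficients
of variation in the 45–55% range), correlated biomass components, and a
narrow, left-skewed grain density (cv ≈ 3–4%) sampled as a reflected gamma
**independently of everything else** — it is the pipeline's built-in
pure-noise benchmark trait, mirroring the common observation that grain
density is the hardest trait to predict from canopy reflectance.

## Rendering and the planted signal

The renderer draws a per-pixel class map (vegetation / soil / shadow; 25%
non-vegetation inside each plot polygon by default, placed as a border ring
plus random speckle), then synthesizes:

* **Hyperspectral**: vegetation follows a fixed visible-region template with
  a linear red-edge ramp (700–760 nm) into a NIR plateau whose level is
  `0.33 + 9e-4 × total plant N (kg/ha)` — a deliberately linear link so that
  parameter recovery is analyzable; soil is a bright sloped line, shadow an
  attenuated soil spectrum (0.5×). Noise is a per-pixel multiplicative
  brightness term (sd 0.04) plus per-pixel-per-band additive noise (sd 0.005).
  With both at zero the plot-mean NIR over the truth mask equals the planted
  linear function exactly, which the tests assert.
* **Canopy height**: `0.8 + 1.74e-4 × stalk biomass (kg/ha)` metres on
  vegetation pixels (≈ 1.5–3 m), zero elsewhere, Gaussian pixel noise 0.05 m.
* **Intensity / thermal**: class-conditional Gaussians; canopy returns are
  brighter than soil at the laser wavelength, and the thermal field is
  near-uniform with vegetation slightly cooler than soil — the trial assumes
  water is not limiting, so thermal carries essentially no trait signal.

The LiDAR simulator drops points uniformly at a requested density
(1600 pts/m² is the realistic airborne default; tests use sparser clouds),
returning canopy tops with probability 0.85 over vegetation and ground
otherwise, with 3 cm vertical noise. Terrain is flat at z = 0 by default; an
optional linear ramp exercises the terrain-model interpolation.

All randomness flows from one master seed through named sub-streams
(`substream_seed`), so regeneration is bit-identical and changing one stage's
draws cannot silently perturb another's.

**What passing on this generator does not show:** real canopies violate the
linear trait-to-signal links, mix pixels at boundaries, and carry structured
(non-Gaussian, spatially correlated) noise; segmentation and model accuracies
here are upper bounds, and the field-scale accuracies reported in the
literature are not reproducible from synthetic data.

# LiDAR surfaces

Outlier returns are removed by the classic statistical filter: a point is
dropped when its mean distance to its k = 8 nearest neighbours exceeds the
global mean by 3 sd (both parameters tunable; at most 10% of the cloud is
ever removed). The DSM takes the **maximum** z of non-ground points per 3 cm
cell; the DTM takes the **minimum** z of ground points per cell (the lowest
return best approximates bare earth — the gridding rule is a package choice),
fills voids by linear interpolation over the Delaunay triangulation of the
ground points (the TIN method, via the `interp` package) and fills cells
outside the convex hull with the nearest ground value so the terrain model is
complete. CHM = DSM − DTM, clipped at zero, nodata propagating. "Voxelization"
here is 2-D gridding in x–y at the imagery cell size; the grid origin snaps to
the imagery raster so modalities align without resampling. The intensity
surface records the intensity of the **highest** point per cell by default
(the per-cell maximum intensity is a configuration switch, since either
reading is defensible).

# Plot preparation

Chips are axis-aligned pixel windows covering the plot polygon plus a margin
(default 5 px); the polygon interior acts as an additional validity mask for
plot statistics. Vegetation segmentation clusters per-pixel feature vectors —
all spectral bands plus height, intensity and thermal, each z-scored across
the chip — with k-means (k = 2) under k-means++ seeding; five restarts are run
and the lowest within-cluster sum of squares wins, which removes the
occasional bad-initialization split. The cluster with the higher mean raw NIR
reflectance (750–1000 nm) is labelled vegetation, so the mask cannot depend on
cluster indexing. A chip whose pixels are all identical is labelled entirely
vegetation with a warning. On default synthetic chips the masks agree with the
generator's truth at ≥ 95% pixel accuracy (typically 100%).

The per-plot band-mean table (masked mean of every band, plus height,
intensity, thermal) feeds the screening and feature stages. Column-wise
z-scoring (`standardize`) always fits its parameters on an explicit training
subset and exposes the exact inverse; the tests include a perturbation check
that held-out rows can never influence the scaler.

# Extended NDSI screening

For band means $M_i, M_j$ the normalized difference spectral index is
$\mathrm{NDSI}_{i,j} = (M_i - M_j)/(M_i + M_j)$. The screen evaluates the
squared Pearson correlation between the per-plot NDSI and a trait for **every
unordered pair** over the spectral bands plus the three auxiliary bands
(height, intensity, thermal) — $\binom{s+3}{2}$ pairs, 36,856 at s = 269. Two
choices were genuinely open:

* The R² definition: squared Pearson correlation, identical to the R² of the
  simple regression of the trait on the NDSI (verified against `lm` in the
  tests). It is the only scale-free choice for a two-variable screen.
* Auxiliary bands are z-scored before entering the ratio (raw heights in
  metres or intensities in the hundreds would break the [−1, 1] range and the
  sign symmetry); a raw-scale mode remains available.

Ties in the argmax resolve to the lexicographically smallest pair (lower
first wavelength, then lower second). Pairs with a zero denominator on any
plot are flagged invalid rather than silently dropped.

# The 95-feature library

Per plot: 34 hyperspectral vegetation indices evaluated from the plot-mean
spectrum exactly as tabulated in the standard VI literature (including the
asymmetric SIPI variant, the three-band GNDVI variant, and
FCI = R²₆₈₃/(R₆₇₅·R₆₉₁)); 30 height and 30 intensity distribution metrics
from the vegetation-masked pixels; and one thermal index. Band lookup is
nearest-neighbour with ties to the lower wavelength and errors outside the
sensed range naming the offending index.

Conventions fixed where the literature leaves them open:

* Percentiles: linear interpolation between order statistics (type 7).
* Mode of a continuous sample: midpoint of the densest fixed-width histogram
  bin (0.05 m for height, 5 units for intensity).
* Skewness moment-based; kurtosis as **excess** kurtosis.
* Canopy-return densities: proportion of masked pixel values strictly above
  the plot's own 10/30/50/70/90th quantiles.
* Canopy-to-ground ratio: vegetation-mask pixel count over non-vegetation
  count in the raster domain (classification counts in point-cloud mode).
* Constant input: cv and relief ratio return 0 with a warning.
* The thermal index keeps the printed form (Tᵢ − Tmin)/(Tᵢ − Tmax) as the
  default for fidelity — note it is negative for plots between the field
  extremes — with the conventional (Tᵢ − Tmin)/(Tmax − Tmin) one flag away.
  Field extremes are taken over canopy **pixels**, so the plot means lie
  strictly inside them and the printed form is defined for every plot.

# Shallow baselines

SVR (`e1071`) and random-forest regression (`ranger`) run behind an
exhaustive grid search scored by 5-fold inner cross-validated R². Defaults:
SVR cost ∈ {0.1, 1, 10, 100}, kernels {radial, linear}, γ as {0.1, 1, 10} ×
the scale heuristic 1/(p · mean feature variance), ε-tube 0.1 on standardized
targets; RFR trees ∈ {100, 300, 500}, depth ∈ {unlimited, 10, 20}, minimum
leaf ∈ {1, 3, 5}, with all features offered at every split (the
regression-forest default of scikit-learn-style pipelines, which also makes
impurity importance concentrate on genuinely predictive features). Bootstrap
evaluation reshuffles a stratified 60/20/20 split (stratified by nitrogen
treatment so every split keeps the bimodal structure) five times; scaler and
search are refit inside each shuffle on the training split only. MDI feature
importances are impurity importances normalized to sum to one.

# The multimodal multi-task network

Three convolutional streams: the hyperspectral cube in a 3-D stream (kernels
3×3×7 — 3×3 spatial, 7 spectral), and two 2-D streams (3×3 kernels) for
LiDAR — height and intensity stacked as two channels of one stream — and
thermal. Every stream uses the 8→16→32→64 filter ladder, Glorot-uniform
weights, zero biases and ReLU, each convolution followed by max pooling
(2×2×6 in the 3-D stream, 2×2 in 2-D). Global average pooling reduces each
stream to 64 values; fusion is concatenation (192 values for three streams);
the head is a 32-unit ReLU layer, dropout (0.5, applied after the 32-unit
layer), and a linear output with one unit per trait.

Geometry: four 'valid' convolution/pooling rounds cannot all fit a
176 × 25-pixel window (the width reaches zero before the fourth layer), so
convolutions use 'same' zero padding and pooling uses ceiling mode (edge
windows are clipped rather than dropped). This keeps all four layers well
defined for any input of at least one pixel and is the only geometric
deviation from the narrowest reading of the architecture.

The convolution and pooling kernels are implemented in C++
(im2col + BLAS gemm via RcppArmadillo) with gradients verified against
numerical differentiation; the optimizer is Adam (β₁ = 0.9, β₂ = 0.999)
starting at 0.001 with exponential decay 0.9 every 5 epochs, minimizing the
**unweighted mean of per-trait Huber losses** (δ = 1) on targets standardized
on the training plots — standardization is what makes the equal weighting
across traits meaningful. Input channels are likewise normalized by per-channel
affine parameters fitted on the training plots' chips. Training runs with
batch size 16 and early stopping on validation loss.

Augmentation slides a 176 × 25 window (the true plot footprint at 3 cm) to 20
random offsets per training plot; the offsets are drawn once per plot and
applied identically to every modality, so the crops stay co-registered — the
tests assert exact offset equality across modalities, and plots are split
60/20/20 **before** augmentation so no plot's crops straddle splits.
Validation, test and inference use the deterministic center crop (a five-crop
average is available). The hyperspectral cube is averaged into 8 spectral
bins before entering the 3-D stream by default; binning is a config knob that
trades spectral resolution for single-CPU speed.

Open readings resolved as package choices: the original uncropped chip does
not join the 20 crops; dropout sits after the 32-unit layer; both the
three-modality and four-modality fusion variants are constructible
(`build_network` takes any modality subset, and `stack_lidar = FALSE` gives
height and intensity separate streams).

# Evaluation

`regression_metrics` reports R², RMSE and MAE. The RMSE default uses the
$\sqrt{\sum(\hat y - y)^2/(n-1)}$ form to match the convention printed in the
trait-phenotyping literature this package follows; the conventional $n$
denominator is a flag. `describe_traits` gives the count/mean/sd/cv%/quartile
summary with cv% = 100·sd/mean.

Global Moran's I uses row-standardized k = 8 nearest-neighbour weights
(inverse-distance is the alternative scheme) — the weights scheme is a
package choice, robust for a regular plot grid. Significance comes from a
two-sided permutation test (default 999 permutations; the resolvable p floor
is 2/(n_perm+1), so detecting p < 0.001 needs ≥ 3999 permutations). The
permutation null reproduces the analytic expectation −1/(n−1), and
`ape::Moran.I` serves as an independent oracle for the statistic in the test
suite. Prediction maps join measured, predicted and residual values onto the
plot polygons (GeoJSON plus a ggplot choropleth).

# Problem sizes used by the automated experiments

The package's own experiments are sized for a single CPU: the acceptance
experiment uses a 300-plot field at 48 spectral bands (binned to 8 for the
network), trains the multi-task network on 20 crops/plot with 60 batches per
epoch for up to 4 epochs against a 0-crop (center-crop) run of up to 20
epochs with the same split, and runs the forest baseline with the full
default grid; the unit-test scenes are smaller (8–40 plots, 12–40 bands).
These sizes are stated here as the package's reference experiment; they are
deliberate simulation-scale reductions of a field campaign, not statements
about real-data compute budgets.

# Known limitations

* No radiative-transfer realism, atmospheric effects, or sensor noise beyond
  additive/multiplicative Gaussians; no multi-date time series.
* The text-based interchange formats (CSV rasters, TSV point tables,
  GeoJSON polygons) favour portability and reviewability over the binary
  geospatial formats a production deployment would use.
* The network trains on CPU at simulation scale; it is an implementation for
  method study, not a GPU training framework.
* Thermal carries no planted signal in the generator (water non-limiting), so
  thermal-only models are expected to perform at chance on synthetic data.
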