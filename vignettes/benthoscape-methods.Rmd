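---
title: "Methods: rule-based habitat classification and predictive biotope mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based habitat classification and predictive biotope mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthoscape)
```

## The problem

Marine-strategy reporting for shelf seas such as the Baltic requires
full-coverage maps at three levels of description: **broad habitat types**
(BHT: zone x substrate, equivalent to EUNIS level 2), **other habitat
types** (OHT: separately assessed protected categories such as reefs,
sandbanks, seagrass meadows), and regional **biotopes** (HELCOM HUB codes
down to the dominant-taxon level). The raw materials are heterogeneous:
hydroacoustic sediment maps, boulder detections, grab samples with taxon
biomass tables, video and photo records with percent covers, and modelled
environmental rasters. benthoscape implements the full chain from those
inputs to the three map layers, with every rule explicit and testable.

## Sediment classification

Grain-size compositions are mass fractions of mud (< 63 µm), sand
(0.063-2 mm) and gravel (> 2 mm) summing to one.

* **Folk / BSH levels A-B.** The canonical Folk triangle with gravel tiers
  < 5 / 5-30 / 30-80 / > 80 % and sand:mud ratio boundaries 1:9, 1:1 and
  9:1. The national guideline behind the source maps uses a "simplified"
  Folk scheme without printing the tier boundaries, so the canonical
  triangle is adopted here. Peat and lag sediment are map classes, not
  granulometric ones, and are never returned by the classifier.
* **Figge / level C.** Sands subdivide by the subfraction holding at least
  50 % of the sand mass (fine 0.063-0.25 mm, medium 0.25-0.5 mm, coarse
  0.5-2 mm); no majority gives mixed sand. The 50 %-plurality rule and bin
  edges are this package's choice: they are the conventional sieve bins,
  and the source material does not state alternatives.
* **EUNIS substrate.** Muddy sediment at >= 20 % fines (inclusive); coarse
  sediment when gravel exceeds 30 % of the combined gravel+sand fraction
  (strict); sand when sand exceeds 70 % of that fraction (strict). Areal
  hard cover, when known, takes precedence: 10-90 % (inclusive) is mixed
  sediment, above 90 % rock and biogenic reef. Mass fractions and areal
  cover are never mixed arithmetically.

**The boundary sliver.** With fines below 20 %, a composition whose gravel
share is exactly 30 % (sand share exactly 70 %) satisfies *neither* strict
criterion. We return `mixed_sediment_hard` for this measure-zero sliver and
flag it (`attr(..., "residual")`). Any other choice silently absorbs the
boundary into coarse sediment or sand and thereby changes the effective
threshold by one integer percent.

**Numerical tolerance.** All threshold comparisons carry a 1e-9 tolerance:
a share that is mathematically equal to a boundary is never pushed across
it by double-precision rounding. The test oracles avoid the issue
altogether by comparing in exact integer-percent arithmetic.

## Hard bottom

Boulder detections are counted per 50 x 50 m cell (half-open cell
intervals, row-major from the north-west, so a point on a shared edge lands
in exactly one cell) and binned: class 1 = no boulders, class 2 = 1-5,
class 3 = more than 5. A cell is geogenic hard substrate iff it is class 3,
or class 2 on lag sediment — same cell only; a lag-sediment neighbour does
not count. Outside the surveyed footprint, hard substrate comes exclusively
from reef polygons (provenance is tracked per cell).

## Station labelling (HELCOM HUB)

* **Endobenthos** (grab samples): the dominant taxon needs a strictly
  greater than 50 % share of station wet-weight biomass; a 50/50 tie has no
  dominant. Zero biomass marks a no-macrocommunity candidate.
* **Epibenthos** (video/photo/diver): a taxon qualifies at >= 10 % cover of
  the total area, or >= 90 % cover when rescaled to the hard-substrate area
  of the field of view (cover / hard-cover fraction, both inclusive). Among
  qualifiers the largest cover wins; ties fall to a precedence list of
  structuring, long-lived taxa.
* **ACFOR** video estimates convert through fixed midpoints A = 75, C = 35,
  F = 15, O = 5, R = 1. The source analysis is semi-quantitative with no
  published mapping; any monotone mapping preserves dominance ordering, and
  midpoints keep the numbers interpretable.
* **Conventions** harmonise labels before modelling: mixed labels collapse
  to the structuring component; poorly separable dominants merge upward
  (Mya arenaria and Astarte spp. into the multiple-infaunal-bivalve
  community `3L9`; named polychaete dominants and level-5 endings into the
  level-4 infaunal-structures class `3`); Ophelia/Travisia dominants are
  removed (unpredictable); dominants at <= 1 % of all stations are removed
  as rare. The rare-share denominator is deliberately the *full* input
  station set and harmonisation runs before exclusion, which makes
  `apply_conventions()` idempotent — re-running the harmonisation on its
  own output is a no-op, so pipelines can apply it defensively.

HUB codes themselves are handled by a small grammar
(`parse_hub()`/`compose_hub_string()`) covering unions (`AA.G+AA.J1E1`),
unknown substrates (`AA.?3L9`) and uncertainty suffixes (`AA.I1E1?`);
`compose_hub()` completes a predicted community token with the zone (photic
AA / aphotic AB) and substrate letter of its cell.

## Predictive modelling

Community tokens (HUB levels 4-6) are predicted per cell from environmental
rasters sampled at cell centres, with sediment as a categorical predictor.
Slope, PAR and the photic flag enter the epibenthos model only, and the
epibenthos model is restricted to hard-substrate-dominant cells. The
labelled set splits 70/30; tree count ({250, 500, 1000}) and
predictors-per-split (floor(sqrt(p)) +- 1) are tuned to the lowest
out-of-bag error; imbalance corrections (down-/upsampling, balanced
bootstrap, SMOTE with k = 5, categorical columns by neighbour majority)
touch the training split only. Metrics follow the conventional
confusion-matrix definitions: overall accuracy with an exact binomial
(Clopper-Pearson) 95 % interval, Cohen's kappa with chance agreement from
the marginal products, and multiclass AUC as the Hand-Till mean of pairwise
AUCs computed from held-out class probabilities (the source reports a
single AUC without naming its multiclass extension; Hand-Till is the
standard choice). Per-cell prediction confidence is the winning-class vote
share; maps flag cells below 67 % as low-confidence.

The tree ensemble itself (bagged CART, Gini splits, mtry feature
subsampling, OOB votes, total-Gini-decrease importance) is implemented in
the package (C++), because no random-forest implementation is available in
the target environment; it is deterministic for a fixed seed via an
internal xorshift generator, independent of R's RNG state.

## Map composition

* **BHT**: zone from the photic polygon (photic = infralittoral), substrate
  as attributed; mussel-covered peat enters as rock and biogenic reef.
  Patches under 1 ha (4-connected; connectivity is this package's choice)
  are relabelled to the modal label of their boundary neighbours. Cell
  count is conserved and no new label can appear.
* **HUB**: community tokens completed with zone and substrate; *never*
  generalised.
* **OHT**: reef and sandbank polygons pass through untouched (exact
  shoelace areas, not gridded counts); seagrass/Fucus cells enter at >= 50 %
  modelled occurrence or >= 10 individuals/m2 mapped density; the Arctica
  category collects cells whose HUB code is `AB.H3L3`; species-rich
  gravel/coarse-sand/shell candidates need >= 3 qualifying indicator
  stations (single taxon >= 10 % biomass or combined >= 5 %) on an
  occurrence area, with the > 50 % gravel/coarse-sand/shell designation
  test reported separately. Where a reef polygon overlaps a species-rich
  candidate the reef wins and the species-rich area shrinks — the two
  cannot be designated simultaneously.

Majority rasterization breaks areal ties toward the harder substrate
(mud < sand < coarse < mixed < rock), consistent with the precautionary
treatment of hard bottoms. The grid is abstract planar (row/col, metres);
inputs are assumed co-registered, and no CRS handling is attempted.

## The synthetic seascape

Because no survey data ship with the package, every stage is exercised on
seeded synthetic seascapes with a *known* community-generating rule:

* Environmental layers are linear gradients plus spatially smoothed
  Gaussian noise. Default magnitudes are plausible for the south-western
  Baltic (salinity falling west to east from about 20 to 8, depths to about
  40 m) but are free parameters, not estimates of any surveyed area.
* Sediment patches come from a quantile-binned smooth latent field, so
  requested class weights are met up to cell rounding and patches are
  contiguous. Boulders follow a per-class Poisson process (lag sediment at
  6 expected boulders per cell).
* The default rule is deterministic: endobenthic communities are driven by
  sediment, salinity and depth; epibenthic communities by depth and
  salinity. Each community token has a signature dominant taxon whose
  biomass share (0.65 by default) exceeds the dominance threshold, so
  noise-free stations recover their labels exactly; biomass noise is
  Dirichlet around the target shares (concentration 200 by default) and
  cover noise is truncated normal on [0, 100].

A green end-to-end test therefore establishes that the *rules and the
model* recover a recoverable world — it says nothing about how well a real
seascape satisfies the rules' assumptions (stationary communities, crisp
class boundaries, noise-free predictors). Transitional communities, seasonal
dynamics and spatially autocorrelated label noise are explicitly not
emulated.

## Known limitations

* No spatial cross-validation: the 70/30 split ignores spatial
  autocorrelation and will flatter accuracy on clustered stations, as
  random splits always do.
* Polygon handling is minimal (simple outer rings, even-odd containment);
  holes and invalid geometries are out of scope.
* The species-rich occurrence areas are connected components of eligible
  sediment classes; the operational definition of an "occurrence area" in
  monitoring practice may differ.
* Labels at stations sharing a cell are kept as separate training rows
  rather than aggregated; with very dense sampling this overweights those
  cells.
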