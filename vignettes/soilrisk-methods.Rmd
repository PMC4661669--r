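---
title: "Methods: integrated soil-pollution risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated soil-pollution risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilrisk)
```

`soilrisk` assesses the soil environment of industrial and mining
gathering areas along two axes — the human health risk carried by measured
pollutant concentrations, and the inherent risk posed by the polluting
factories themselves — and joins them spatially into an integrated risk
map. This vignette documents the models, their assumptions, the tunable
parameters, the numerical conventions, and the limits of what the test
suite demonstrates.

## 1. Health-risk model

For a soil concentration $C$ (mg/kg) the chronic daily intake along each
exposure pathway is the standard three-pathway soil model used by risk
guidelines worldwide (US EPA RAGS; Chinese HJ 25.3):

$$D_{ing} = \frac{C \cdot IngR \cdot EF \cdot ED \cdot CF}{BW \cdot AT},
\qquad
D_{derm} = \frac{C \cdot SA \cdot AF \cdot ABS \cdot EF \cdot ED \cdot CF}{BW \cdot AT},
\qquad
D_{inh} = \frac{C \cdot InhR \cdot EF \cdot ED}{PEF \cdot BW \cdot AT},$$

with $AT = AT_{ca}$ (70-year lifetime, days) for carcinogenic averaging and
$AT_{nc} = 365 \cdot ED$ otherwise. Carcinogenic risk per pollutant and
pathway is $CR = D \cdot SF$; the hazard quotient is $HQ = D / RfD$. The
per-sample **total carcinogenic risk** $TCR$ sums $CR$ over every pollutant
and pathway with a slope factor; the **total hazard index** $THI$ sums $HQ$
over every pathway with a reference dose. Both sums are linear in the
concentration vector — a property the test suite checks directly
(homogeneity and additivity over registry partitions, agreement with an
independent nested-loop oracle to 1e-12 relative).

Assumptions worth stating explicitly:

* additive risk across pollutants and pathways (no interaction terms);
* a single adult receptor per land-use class — no age stratification, no
  probabilistic (Monte Carlo) exposure, no bioaccessibility correction;
* nondetects contribute zero dose by default. The alternative
  `nondetect_policy: lod2` substitutes half the configured detection limit,
  which matters only for $THI$ of the rarely detected analytes here.

Every exposure parameter (BW kg, EF d/yr, ED yr, IngR mg/d, SA cm²,
AF mg/(cm²·d), ABS –, InhR m³/d, PEF m³/kg, AT d, CF = 1e-6 kg/mg) lives in
the configuration, one scenario per land-use class; the scenario applied to
a sample is chosen from the land-use cell it falls in, with a residential
fallback where land use is unavailable. The shipped toxicity registry
(slope factors, reference doses, dermal absorption fractions for 18
analytes: As, Cd, Cr as Cr(VI), Co, Cu, Pb, Ni, V, Zn, Hg, and eight
organics) carries documented literature-order defaults. They are working
values chosen once for the default configuration, fully overridable, and
no analysis in this package depends on their exact magnitudes — the tests
exercise structure (linearity, additivity, classification), not specific
toxicity numbers.

$TCR$ is classified against three strictly increasing breaks, default
$(10^{-6}, 10^{-5}, 10^{-4})$: $10^{-6}$ is the conventional acceptability
line, $10^{-4}$ the conventional upper bound of tolerable risk. Four-class
TCR boundaries are a modelling choice, not a standard; they live in the
configuration precisely because defensible alternative readings exist
(e.g. treating $10^{-5}$ rather than $10^{-6}$ as the top of "low").

## 2. Factory comprehensive risk index (CRI)

The factory assessment is a three-criterion weighted index. Each of 22
indicators is scored on $[0, 3]$ by a rule (interval bins for quantities
like emissions and treatment rates, categorical lookups for plan/capacity
states, booleans for installed systems). Indicators aggregate within each
criterion — inherent sudden-risk level, cumulative risk level, supervision
level — and the criteria combine as

$$CRI = 0.30 \cdot S_{sudden} + 0.30 \cdot S_{cumulative} + 0.40 \cdot S_{supervision}.$$

**Weight normalization.** The printed indicator weights of the cumulative
criterion sum to 0.65, not 1. The default subscore is therefore the
weight-normalized mean $\sum w_i s_i / \sum w_i$, which preserves the
relative importance of indicators while keeping every criterion on the same
$[0,3]$ scale, so $CRI \in [0,3]$ holds by construction (the classification
table bounds CRI at 3). The alternative `weight_mode: raw` uses
$\sum w_i s_i$ verbatim, capping the cumulative contribution at
$3 \times 0.65$; both modes are tested. Normalization also makes subscores
invariant under rescaling one criterion's weights by a positive constant —
a property test.

CRI classes follow the published boundaries: low $[0,1]$, moderate
$(1,2]$, high $(2,2.5]$, extreme $(2.5,3]$. All class intervals in the
package (CRI, TCR, raster classification) share one convention:
lower-open/upper-closed above the lowest class, so a value exactly at a
break takes the *lower* class. Boundary behaviour is asserted at
$\pm 10^{-9}$ perturbations.

The shipped scoring rules are documented stand-ins on the published
indicator/weight skeleton: the original standardization tables are not
public, so the rules encode generic regulatory-style cut-points and are
replaceable wholesale through the configuration. Missing indicators are an
error by default; `worst` (score 3) and `renormalize` (drop and rescale)
policies are available.

## 3. IDW interpolation and validation

Point risk values are interpolated onto the analysis raster by inverse
distance weighting: the prediction at $x$ is
$\sum_i w_i v_i / \sum_i w_i$ with $w_i = d_i^{-p}$ over the $k$ nearest
samples. IDW is chosen over kriging/splines because it preserves local
maxima and minima — exactly the features that matter when the goal is to
identify polluted cells rather than estimate a smooth trend. Consequences
that double as test oracles: predictions are exact at data points (queries
within `snap_eps`, default 1e-9 m, return the sample value), bounded by the
range of the values used, and converge to the nearest neighbour's value as
$p$ grows.

Defaults $p = 2$, $k = 12$: the usual IDW power, and a neighbourhood large
enough to stabilize predictions between the 1 km infill grids without
smearing census-scale structure. Both are configuration/CLI parameters.
Numerical choices:

* weights are computed as $(d_i/d_{\min})^{-p}$ — identical mathematically,
  but immune to underflow at large powers (tests run $p = 64$);
* ties at the $k$-th neighbour distance include every co-distant point, so
  results are independent of input order;
* grid cells are evaluated at cell centers; the value matrix stores the
  northernmost row first, matching the ESRI ASCII file layout, and the
  origin is the lower-left corner (a row-order contract covered by tests).

Interpolation quality is measured by leave-one-out cross-validation RMSE,
$\sqrt{\tfrac1n \sum_i (v_i - \hat v_{-i}(x_i))^2}$, frozen in the tests
against a three-point hand computation ($\sqrt{76}$ for the collinear
fixture $0, 10, 0$).

**Aggregation order.** The pipeline interpolates the per-sample $TCR$
(sum first, interpolate second). An `tcr_mode = "per_pollutant"` flag
interpolates each pollutant's CR field and sums the rasters instead. Since
IDW weights depend only on geometry, and every CR field here is defined at
every sample (nondetects contribute zero), the two orders coincide exactly
— the suite asserts this commutation rather than a difference. They would
diverge only if per-pollutant fields used different point supports (e.g.
dropping nondetect points per analyte), which this package does not do.

## 4. Matrix overlay and the factory layer

Integrated risk is a pure 4×4 lookup of (health-risk class × land-use
class), monotone in health level within every land-use column: industrial
land tolerates a given health class best, conservation land least. The
default matrix is asserted cell-for-cell in the acceptance suite. A cell is
nodata in the overlay iff either input is nodata; grids must agree to 1e-6
relative in origin, cell size and dimensions.

The factory-CRI IDW surface is a *companion layer*: the integrated
classification is defined strictly on health risk × land use, and blending
factory scores into the matrix would invent a rule with no published
definition. An explicit extension (`factory_escalation: true`, off by
default) raises a cell one class where the CRI surface exceeds the top CRI
break, for users who want a conservative joint map.

## 5. The synthetic scene generator

The generator builds study areas with the structure of a coastal
industrial/mining district, with known ground truth:

* **Extent** 40 × 30 km (~1200 km²) on a 500 m analysis grid.
* **Sampling design**: census points by systematic random sampling — one
  point per 3 km grid cell, uniformly jittered up to 800 m (jitter 0 gives
  the exact grid, which the spacing test uses); 1 km "encrypted" infill
  grids inside three industrial/mining hotspot zones; no points in the
  reservoir rectangle, which is nodata throughout the pipeline. Point
  counts are emergent from the geometry (about 125 census + 80 infill
  under the defaults), not forced.
* **Concentrations**: each metal is log-normal (configured median and
  geometric sd) with plume terms added on the log scale,
  $\log C = \log C_{med} + \sum_j A_j e^{-d_j^2/2\ell_j^2} + \varepsilon$,
  so metals are strictly positive (100% detection) and background
  variability survives near plumes. Hg and the eight organics are detected
  with probability 0.08 (matching a below-10% detection structure);
  nondetects are `NA`.
* **Default plumes**: a dominant As plume (amplitude 3.0 log units, length
  scale 2500 m) centred in a residential pocket inside the oilfield
  hotspot — the configuration that makes end-to-end recovery meaningful —
  plus secondary Cd and Ni plumes in the other two zones.
* **Factories**: 150, each with a latent risk tier drawn from configured
  probabilities; the tier's class midpoint plus Gaussian noise (sd 0.4)
  sets per-indicator target scores, and raw attributes are obtained by
  inverting the scoring rules. Recovery of the tier ordering through the
  CRI is a Monte-Carlo test. A 20% scattered fraction places factories
  outside hotspot zones, echoing the disordered siting typical of such
  areas.
* **Land use**: rectangles painted over an agriculture background with
  priority conservation > residential > industrial > agriculture.

All generators are pure functions of (configuration, seed); the pipeline
writes byte-identical outputs on re-runs (numbers serialized with the
shortest representation that round-trips exactly).

What the scene does *not* emulate: real geography, geostatistically
calibrated concentration moments, spatially correlated background noise
(only plumes are spatial), seasonal or depth structure, or measurement
error. Passing recovery tests therefore demonstrates that the pipeline's
logic is correct and stable under realistic magnitudes — not that any
particular field study's numbers are reproduced.

## 6. Test design and problem sizes

The suite favours property-based checks against independent oracles:
direct-summation IDW on 200 random instances (≤30 points, 1e-10
absolute), a nested-loop dose/risk oracle on 100 random registries (1e-12
relative), exhaustive 4×4 matrix and ordering enumerations, boundary
straddles at ±1e-9, and bisection recovery of the CRI class boundaries.
The end-to-end check runs 50 seeded replicates of the default scene and
requires the plume-center cell to classify extreme-TCR and ≥ high
integrated in at least 95% of them; a 1000-point scene bounds the organic
detection rate below 10% and within 99% binomial bounds of the configured
0.08. These sizes keep the full suite under half a minute on one CPU while
leaving the statistical assertions sharp.

## 7. Known limitations

* Exposure and toxicity defaults are literature-order stand-ins; any
  regulatory use requires substituting jurisdictionally appropriate values
  in the configuration.
* The factory scoring rules are structural stand-ins on the published
  weight hierarchy; only the aggregation arithmetic is asserted, not the
  rule content.
* IDW has no uncertainty model: the LOO RMSE is a global quality summary
  and cannot bound local errors at unsampled extremes.
* Coordinates are planar meters by contract; no CRS handling or
  reprojection is provided.
* THI aggregation sums hazard quotients across endpoints, the conventional
  conservative screen, which can overstate non-carcinogenic risk when
  target organs differ.
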