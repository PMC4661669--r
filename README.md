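# soilrisk

Integrated soil-pollution risk assessment for industrial and mining
gathering areas.

Soil around dense industrial and mining activity carries two distinct kinds
of risk: the **human health risk** encoded in measured pollutant
concentrations, and the **inherent risk of the polluting factories**
themselves (what they store, emit, and how well they are supervised).
`soilrisk` implements a complete, reproducible pipeline that joins the two:

1. **Health risk per sampling point.** For each soil sample, chronic daily
   intakes are computed for three exposure pathways — soil ingestion,
   dermal contact, and inhalation of resuspended particulates — under a
   land-use-specific exposure scenario:

   dose_ing = C·IngR·EF·ED·CF / (BW·AT),
   dose_derm = C·SA·AF·ABS·EF·ED·CF / (BW·AT),
   dose_inh = C·InhR·EF·ED / (PEF·BW·AT).

   Carcinogenic risk is CR = dose × SF and the hazard quotient is
   HQ = dose / RfD; summing over pollutants and pathways gives the total
   carcinogenic risk (TCR) and total hazard index (THI). TCR is classified
   low/moderate/high/extreme against configurable breaks (default 1e-6,
   1e-5, 1e-4).
2. **Factory inherent risk (CRI).** Raw factory attributes are scored onto
   a [0, 3] scale by per-indicator rules, aggregated into three criterion
   subscores (sudden-risk inherent level, cumulative risk, supervision
   level) as weight-normalized means, and combined as
   CRI = 0.30·sudden + 0.30·cumulative + 0.40·supervision, then classified:
   low [0, 1], moderate (1, 2], high (2, 2.5], extreme (2.5, 3].
3. **Spatial regionalization.** Per-point TCR is interpolated onto a raster
   grid by inverse distance weighting (IDW, weights d^-p over the k nearest
   points; exact at data points, bounded by the data range, preserving
   local extrema), with leave-one-out cross-validation RMSE as the quality
   measure.
4. **Integrated risk.** The classified TCR raster is overlaid with a
   four-class land-use raster (industrial, agriculture, residential,
   conservation) through a 4×4 risk matrix — the same health risk weighs
   more heavily on residential and conservation land — and the factory-CRI
   IDW surface is reported as a companion layer.
5. **Synthetic scenes.** Because real census data of this kind are rarely
   public, a first-class generator builds complete synthetic study areas —
   systematic-random census sampling on a 3 km grid, 1 km infill in
   industrial/mining hotspots, a masked reservoir, log-normal metal
   backgrounds with plume-like hotspots, rarely-detected organics, and
   factories with known latent risk tiers — so the entire pipeline is
   testable end to end against known ground truth.

All parameters (toxicity values, exposure scenarios, scoring rules,
weights, breaks, the integration matrix, the scene) live in one validated
YAML configuration; a complete default ships with the package.

## Worked example

```r
library(soilrisk)

config <- load_config()                     # shipped defaults
scene  <- generate_scene(config, seed = 7)  # 40 x 30 km synthetic study area

nrow(scene$samples)
#> [1] 204                                  # 124 census + 80 infill points

health <- assess_samples(scene$samples, config, scene$landuse)
summary(health$tcr)
#>      Min.   1st Qu.    Median      Mean   3rd Qu.      Max.
#> 1.346e-06 1.328e-05 2.617e-05 4.116e-05 4.097e-05 4.186e-04
table(health$level)
#>  extreme     high moderate
#>       17      150       37

loo_rmse(cbind(health$x, health$y), health$tcr)
#> [1] 4.54e-05

cri <- assess_factories(scene$factories, config)
table(cri$level)
#>  extreme     high      low moderate
#>       20       42       12       76

tcr_map    <- map_health_risk(health, scene$spec, config, mask = scene$mask)
classes    <- classify_raster(tcr_map, config$thresholds$tcr_breaks)
integrated <- overlay(classes, scene$landuse, config$matrix)
class_area_summary(integrated)
#>      level cells   area_m2
#> 1      low    55  13750000
#> 2 moderate  3998 999500000
#> 3     high   249  62250000
#> 4  extreme   242  60500000
```

Reading the output: most sampled points carry a TCR in the 1e-5..1e-4 band
(high), driven by the arsenic plume the scene plants near the oilfield
residential zone; the leave-one-out RMSE is of the order of the TCR spread,
as expected for a strongly peaked field; the integrated map is moderate over
most of the area with high/extreme cells concentrated where elevated health
risk meets residential or conservation land. Reservoir cells are nodata
throughout.

The same run as a single call, writing `samples.csv`, `health.csv`,
`cri.csv`, `tcr.asc`, `integrated.asc`, `summary.json` and friends:

```r
run_pipeline(config, "out_dir", seed = 7)
```

Re-running with the same config and seed reproduces byte-identical outputs.

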