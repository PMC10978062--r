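# iceballast

Sea-ice ballasting of Arctic carbon export: backward ice-trajectory
tracking, ice-edge conditioning of sediment-trap fluxes, and settling
statistics, validated end to end on a synthetic Arctic scenario.

## The scientific problem

When Arctic sea ice forms over shallow shelves it entrains sediment, and
brines concentrated inside the ice precipitate cryogenic gypsum. Both are
dense minerals. When the ice melts — increasingly *before* it reaches the
deep basins — these minerals are released into the water column, attach to
sinking organic aggregates, and **ballast** them: the aggregates' excess
density rises, they sink faster, and a larger share of their particulate
organic carbon (POC) reaches depth before being respired.

A long moored sediment-trap record should therefore show two coupled
fingerprints of a shrinking, younger ice cover:

1. a **long-term decline of terrigenous marker fluxes** (land-derived
   sterols riding on ice-rafted sediment), as less shelf-sourced ice
   survives the transit to the trap; and
2. **higher POC fluxes in cups collected near the ice edge** than far from
   it, because melt happens at the edge and ballast shortens the particle
   transit.

Testing these requires a chain of methods: where and when did the exported
ice form (backward Lagrangian tracking through prioritized satellite drift
products)? How old and thick was it (freezing-degree-day model)? How far
was each trap cup from the ice edge (threshold edge detection)? Are the
trends and group differences real (seasonal Mann-Kendall, exact Wilcoxon,
Spearman)? And do gypsum crystals actually accelerate aggregates
(roller-tank tracks, two-way ANOVA on log velocities)?

`iceballast` implements that entire chain, plus a synthetic Arctic
generator with *known imposed effects* (an 80 % terrigenous decline, a
+30 % ballast coupling, a 10x large-crystal settling enhancement), so the
pipeline's power and calibration can be demonstrated rather than assumed.
See `vignettes/ice-ballast-methods.Rmd` for the model and all conventions.

## Worked example

Backtrack one exported ice floe from the export gate and reconstruct its
state, then run the trap-record statistics — all on the default 14-year
synthetic scenario (seed 1):

```r
library(iceballast)

dom   <- domain_config(seed = 1)     # 1400 x 600 km, 50 km cells, 2000-2013
sc    <- scenario_params()           # imposed decline 0.8, ballast 1.3
stack <- make_drift_stack(dom, sc)   # 3 drift products, product 1 gaps Jun-Jul
conc  <- make_concentration_field(dom, sc)
temp  <- make_airtemp_field(dom, sc)

tr <- backtrack(dom$gate_xy_km, as.Date("2004-04-01"), stack, conc,
                tracker_config(), airtemp = temp)
tr
#> <ice_trajectory> start 2004-04-01 at (400, 300) km; 168 samples; reason: formed
#>   final: 2003-10-17 at (1228.1, 295.8) km, concentration 21.1%

rec <- ice_export_records(list(tr), make_bathymetry(dom))
#> age 167 days, thickness 158.6 cm, shelf formation: TRUE
```

The floe exported in April 2004 formed the previous October at 21 %
concentration over the shallow shelf, 167 days and one winter of freezing
degree days earlier.

```r
cups <- cup_ice_conditions(cup_intervals(dom), conc, dom$mooring_xy_km)
cups <- classify_cups(make_flux_series(dom, sc, cups$distance_km))

seasonal_mann_kendall(monthly_series(cups, "terr_flux"))
#> Seasonal Mann-Kendall trend test: S = -768, var(S) = 4004.000, Z = -12.121,
#>   tau = -0.7033, two-sided P = 8.148e-34 (n = 168)

g <- flux_group_tests(cups)   # productive-season 0-40 km vs 40-80 km bins
g$wilcoxon
#> Wilcoxon rank-sum test (normal): W = 9830, two-sided P = 0.0001229 (n = 110, m = 49)
#> near-edge mean POC 11.7 vs far 10.4 mg m-2 d-1
#> Spearman rho(POC, terrigenous) = 0.45, P = 3.2e-11
```

Both imposed fingerprints are recovered: a strongly negative terrigenous
trend, and significantly higher near-edge POC flux with a positive
POC-terrigenous rank correlation.

The same analysis runs end to end, with file handoffs, manifest and
logging, via:

```r
run_scenario(run_config(out_dir = "run1", seed = 1))
```

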