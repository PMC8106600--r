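# riverpec

Spatially resolved, probabilistic exposure assessment of down-the-drain
chemicals (pharmaceuticals, contrast agents, hormones) in whole river
catchments.

Water managers and environmental chemists need to know *where* in a river
network a substance exceeds its environmental quality standard (EQS), not
just a basin average: exceedances concentrate in small, effluent-dominated
creeks. `riverpec` predicts a concentration distribution for every river
segment of a catchment and evaluates management scenarios (re-routing of
small treatment plants, treatment upgrades, consumption change) as
flow-length statistics against the EQS.

## Model core

Emissions follow the per-capita route: a basin total
`L = P · c · f_ex / 1000` g/d (population `P`, consumption `c` in
mg/(cap·d), excretion fraction `f_ex`) is split per wastewater treatment
plant by resident population, with an optional hospital sub-model routing
the on-site fraction

```
f_site = f_stat + (1 − f_stat) · f_window
```

through the hospitals' receiving plants. After category-specific
percentage removal, effluent loads are routed down the segment network in
topological order under steady state:

```
M_out = M_in · exp(−k · τ(Q)),    C = M_in / Q        (reported in ng/l)
k = k_deg + k_sed + k_vol         τ = L / (v_ref (Q/MQ)^b)
```

with complete mixing at nodes and effluent flow added to river flow.
River-flow variability is lognormal per segment (median `Q50`, mean `MQ`),
sampled with one shared quantile per Monte Carlo iteration so the whole
basin is wet or dry together; 10,000 realisations per run yield any
percentile of the per-segment concentration distribution. Simulated
P10–P90 bands can be confronted with monitoring series (band coverage,
Dixon Q outlier screening).

No real catchment database ships with the package; a synthetic-catchment
generator produces structurally faithful networks (dendritic topology,
segments ≤ 2000 m, accumulated flows with `MNQ ≤ Q50 ≤ MQ`, plants from
village to city scale) so the full pipeline runs out of the box.

## Worked example

```r
library(riverpec)

ct <- generate(synth_config(n_segments = 120, n_wwtps = 15, n_hospitals = 0,
                            seed = 42, outlet_mq = 20, small_fraction = 0.4))
ct
#> <catchment> 120 segments, 121 nodes, 15 WWTPs, 0 hospitals, 1 gauges, 3 monitoring sites
#>   total flow length: 119.1 km

sub <- substance(
  name = "amoxicillin-like", per_capita_consumption = 1.2,  # mg/(cap d)
  excretion_fraction = 0.25,
  removal = c(activated_sludge = 0.9, bio_filter = 0.8,
              constructed_wetland = 0.6, lagoon = 0.4),
  k_deg = 0.02,            # 1/h in-stream loss
  eqs = 78, loq = 10)      # ng/l

smry <- summarize(run_probabilistic(ct, sub, mc_config(10000, seed = 1)))
head(smry, 3)
#>   segment_id     mean      p10       p50      p90
#> 1      S0001 10.93254 3.545564  9.034861 20.87472
#> 2      S0002 10.36184 3.784080  8.819357 18.98953
#> 3      S0003 13.43824 3.471303 10.439181 27.53638

exceedance_length(smry, ct, sub$eqs)   # km of flow length above the EQS
#> [1] 3.870911
exceedance_length(smry, ct, sub$loq)   # km where monitoring could see it
#> [1] 36.62952
```

Each row is one river segment: the mean predicted concentration and the
10th/50th/90th percentiles over 10,000 flow realisations, in ng/l. Here
3.9 of 119.1 km exceed the 78 ng/l quality standard on the mean, and only
36.6 km carry concentrations a method with a 10 ng/l quantification limit
could measure at all.

A management scenario — abandoning plants under 1000 inhabitants and
piping their wastewater to the closest larger plant — is one call, and is
compared segment by segment (changes within ±5% count as insignificant):

```r
action_ct <- reroute_small_wwtps(ct, 1000)
act <- summarize(run_probabilistic(action_ct, sub, mc_config(10000, seed = 1)))
compare(smry, act, ct)
#> <scenario_comparison> improved 5.0 km, deteriorated 2.4 km, insignificant 111.7 km
threshold_crossings(smry, act, ct, threshold = sub$eqs)
#> newly_above_km newly_below_km  net_relief_km
#>              0              0              0
```

Re-routing improves 5.0 km of flow length and deteriorates 2.4 km (the
receiving waters of the target plants); in this basin no segment crosses
the EQS in either direction, so the net relief is zero.

Results export as CSV (`write_summary()`) and GeoJSON
(`export_geojson()`) for colour-coded maps in any GIS; a thin command-line
interface (`inst/cli/riverpec`, subcommands `synth`, `simulate`,
`scenario`, `compare`, `report`) wraps the same functions for shell use.

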