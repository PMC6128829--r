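# sealplume

Detecting and tracking subglacial discharge plumes at a tidewater glacier
from CTD dive profiles collected by instrumented seals.

Ringed seals carrying GPS-equipped conductivity-temperature-depth satellite
relay data loggers (GPS-CTD-SRDLs) forage at the edges of buoyant meltwater
plumes at glacier fronts and pass through the plume core as they surface.
Their ascent profiles therefore sample the upwelling region of the plume —
water that ship-based CTDs cannot reach. `sealplume` turns a season of such
dive profiles into three quantitative results:

1. **Where the seals dive.** Profiles are quality-controlled (Argo-style
   gross-range, spike, gradient and density-inversion tests; exclusion of
   profiles whose locations come from long interpolation runs or whose
   temperature/salinity values were interpolated), geolocated between
   bracketing GPS fixes, and classified by glacier region (within 500 m of
   either terminus, open fjord, outside).

2. **How much subglacial discharge the seals encountered.** Every sample
   (Θ, S_A) is decomposed into three endmembers — ambient fjord water
   (Θ_a, S_a), subglacial runoff (freshwater at the pressure melting point,
   Θ_r, 0) and submarine meltwater (the Gade effective endmember
   Θ_m = Θ_f − L/c_p − (c_i/c_p)(Θ_f − T_i), at S = 0) — by solving the
   exact 3×3 linear system of mass, heat and salt conservation:

   ```
   f_ambient + f_sg + f_melt              = 1
   f_ambient Θ_a + f_sg Θ_r + f_melt Θ_m  = Θ
   f_ambient S_a                          = S_A
   ```

   `f_sg` is the subglacial discharge fraction; low-salinity spikes
   (anomalies beyond 5σ_S below the ambient column) mark in-plume profiles.

3. **When the plume was active.** The dive locations in a 5-day moving
   window (stepped 1 day) are clustered with DBSCAN for 1000 random
   parameter draws (eps uniform on 25–200 m, minPts uniform on 4–10); the
   percentage of draws that find a cluster attributable to the terminus is
   the cluster-density statistic. Its peaks are paired with peaks of the
   surface-runoff series to test how quickly seals respond to discharge.

A synthetic-campaign generator (stratified fjord, entrainment-plume model,
runoff-driven seal behaviour, lossy 4-hour satellite transmission, GPS and
interpolated locations, instrument noise) makes the entire pipeline testable
closed-loop without field data, with a truth record for every dive.

## Worked example

```r
library(sealplume)

geometry <- synthetic_fjord_geometry()
sim <- simulate_campaign(synthetic_config(seed = 1), geometry = geometry)
fit <- plume_analysis(sim$profiles, geometry, sim$runoff,
                      plume_config(sweep = sweep_config(n_draws = 1000, seed = 2)))
fit
#> Seal-borne CTD plume analysis
#>   profiles kept: 1107 (32 rejected)
#>   regions: kronebreen_near 40%, kongsbreen_near 2%, fjord 57%, outside 0%
#>   max f_sg: 26.9% at 64 m (profile d00753)
#>   peak pairing: 3 runoff peak(s) matched to clustering peaks
```

The campaign keeps 1107 of 1139 transmitted profiles (the rest fail the
location-interpolation or interpolated-value rules). 40% of kept dives fall
within 500 m of the marine-terminating front, against a uniform-diving
expectation of

```r
round(uniform_expectation(geometry), 2)
#> kronebreen_near kongsbreen_near
#>            4.33            3.46
```

so the seals' preference for the terminus is roughly tenfold. The maximum
subglacial discharge fraction is 26.9% at 64 m depth — the generator's
configured core encounter is 27% at 64 m, recovered through the full QC →
conversion → endmember → decomposition chain (exactly, when noise is
switched off). All three runoff peaks (150, 220, 70 m³/s) are matched by
cluster-density peaks at zero lag:

```r
fit$peaks$pairing$pairs
#>   runoff_date clustering_date lag_days
#> 1  2012-08-08      2012-08-08        0
#> 2  2012-08-26      2012-08-26        0
#> 3  2012-09-12      2012-09-12        0
```

`summary(fit)` prints endmembers, peak tables and the in-plume timeline;
`plot(fit)` draws the runoff and cluster-density series with detected peaks.
Stage functions (`convert_teos10()`, `qc_samples()`, `filter_profiles()`,
`classify_region()`, `decompose_fractions()`, `windowed_sweep()`,
`detect_peaks()`, ...) are exported individually, and
`build_report()`/`write_report()` emit a machine-readable JSON summary.

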