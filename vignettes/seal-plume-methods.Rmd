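---
title: "Methods: seal-borne CTD analysis of subglacial discharge plumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seal-borne CTD analysis of subglacial discharge plumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealplume)
```

## The problem

Subglacial discharge emerges at the grounded front of a tidewater glacier as
a buoyant freshwater plume that upwells along the ice face, entraining and
melting as it rises. Ringed seals forage at the edge of such plumes and cross
the upwelling core while surfacing, so CTD loggers glued to their fur return
vertical profiles from a region no conventional instrument samples. This
package implements the full analysis of such a deployment: sample- and
profile-level quality control, geolocation and glacier-region statistics,
a three-endmember water-mass decomposition yielding the subglacial discharge
fraction `f_sg` per sample, a Monte-Carlo DBSCAN statistic that tracks how
densely dives cluster at the terminus through time, and the pairing of that
clustering series with a surface-runoff series.

The package is organised around one orchestrating fit, `plume_analysis()`,
which returns a classed object with `print`, `summary` and `plot` methods;
every stage is also exported on its own.

## Seawater thermodynamics

All analysis is done in conservative temperature Θ (°C) and absolute
salinity S_A (g kg⁻¹). The package computes these with compact, fully
published formulations rather than the full TEOS-10 library:

* S_A = S_P · 35.16504/35 (reference-composition scaling). The regional
  salinity anomaly this neglects is below 0.01 g kg⁻¹ on Arctic shelves —
  an order of magnitude under the 0.1 g kg⁻¹ accuracy of seal-borne CTDs.
* Θ is estimated by surface-referenced potential temperature from the
  UNESCO/Fofonoff adiabatic-lapse Runge-Kutta integration. At fjord
  pressures (< 200 dbar) and polar temperatures the Θ–θ difference is below
  0.05 °C, again under sensor accuracy; the inverse conversion is used by
  the synthetic generator so the closed loop is consistent by construction.
* Depth/pressure via the UNESCO formula with latitude-dependent gravity;
  freezing temperature via Millero's polynomial; σ₀ via the UNESCO
  one-atmosphere equation of state.

Published check values for each routine (e.g. potential temperature
36.89073 °C at S = 40, t = 40 °C, p = 10⁴ dbar; depth 9712.653 m at 10⁴ dbar
and 30° latitude; freezing point −2.588567 °C at S = 40, p = 500 dbar;
ρ(35, 5, 0) = 1027.67547 kg m⁻³) are frozen in the test suite as independent
oracles.

## Water-mass decomposition

Each sample is written as a mixture of ambient fjord water, subglacial
runoff and submarine meltwater under conservation of mass, heat and salt.
With three endmembers and three equations the system is square and solved
exactly; no least squares is involved, and `f_ambient + f_sg + f_melt = 1`
holds to machine precision by construction.

Endmember choices (all configurable):

* **Ambient** — mean (Θ, S_A) of fjord-region samples collected before a
  cutoff date (default 20 September, before which the upper water column is
  still summer-stratified), averaged over the deepest 20 m above the
  grounding-line pressure. The averaging band is the package's choice; the
  grounding line is where the plume source sits, so the water it entrains
  first is the natural reference.
* **Runoff** — freshwater at the pressure melting point at the
  grounding-line pressure (default 100 dbar): (Θ_f(0, p_ref), 0).
* **Meltwater** — the Gade construction
  Θ_m = Θ_f − L/c_p − (c_i/c_p)(Θ_f − T_i) with defaults
  L = 3.35×10⁵ J kg⁻¹, c_p = 3.98×10³ J kg⁻¹ K⁻¹, c_i = 2.1×10³ J kg⁻¹ K⁻¹,
  T_i = −10 °C, evaluated at the freezing point of the ambient salinity at
  the reference pressure. For Θ_f = −1.9 °C this gives Θ_m ≈ −90.3 °C.

Fractions are reported **unclamped** with a validity flag (all fractions in
[−ε, 1+ε], ε = 0.02 by default). Clamping would hide endmember
misspecification; the flag preserves it as a diagnostic. Samples from the
stratified upper layer decompose against the deep ambient endmember with
slightly negative `f_melt` and apparent `f_sg` up to ≈ 0.08 — exactly the
behaviour seen in real Θ–S_A diagrams, and the reason `max_fsg()` considers
only valid samples of spike-bearing ("in-plume") profiles.

Spike detection flags a sample when its S_A falls more than k·σ_S
(default 5 × 0.1 g kg⁻¹) below the ambient salinity at that depth, where the
ambient column is the depth-binned mean of fjord-region profiles.

## Quality control

The sample tests are the core Argo real-time suite with configurable
thresholds: gross range (defaults Θ ∈ [−2.5, 15] °C, S_A ∈ [0, 36] g kg⁻¹ —
open-ocean climatological ranges would reject valid inner-fjord water),
the Argo spike statistic |v₂ − (v₁+v₃)/2| − |v₃−v₁|/2, the gradient
statistic |v₂ − (v₁+v₃)/2|, and a density-inversion check (σ₀ decreasing
with depth beyond 0.03 kg m⁻³). Flags never modify values.

Profile-level exclusion drops (in order, one primary reason each):
locations from runs of more than three consecutive interpolated positions
(a run of exactly three passes — the boundary is read literally), profiles
with any interpolated temperature or salinity value, and profiles whose
flagged-sample fraction exceeds 20%. The 20% cap is this package's addition
(Argo QC is sample-level only). Density-inversion flags are *excluded* from
that cap by default: water inside an upwelling plume is genuinely statically
unstable, so counting inversion flags toward rejection would systematically
discard the very profiles the analysis targets. Filtering is idempotent and
partitions its input.

## Geolocation and regions

All distances are Euclidean in a single metric CRS (UTM; zone 33N for the
default geometry), implemented from the standard transverse-Mercator series
and verified against geodesic distances (agreement ≲ 0.05% at fjord scale,
where the projection error is far below GPS accuracy). Dive locations are
interpolated linearly in time between bracketing GPS fixes in projected
space — at fjord scale the great-circle correction is negligible.

A dive within the 500 m buffer of either front belongs to that front's
near-terminus region (ties go to the nearer front, then to the
marine-terminating front); otherwise `fjord` inside the study polygon, else
`outside` (added for robustness — real inputs are pre-clipped). The
uniform-diving expectation divides each near-terminus area by either the
fjord area alone or fjord plus buffers; the published wording is ambiguous,
both denominators are supported, and with areas 2.0/1.6/42.6 km² both land
in the printed 4–5% band. Dive densities are gridded in half-open
100 × 100 m bins.

## The cluster-density statistic

DBSCAN (compiled, with an O(n²) brute-force R oracle in the tests) uses the
standard semantics; the one genuinely ambiguous case — a border point
reachable from two clusters — is pinned to the first cluster that reaches it
in input order, for reproducibility. The Monte-Carlo sweep draws
(eps, minPts) uniformly from [25, 200] m × {4,…,10} (1000 draws) and runs
DBSCAN per draw on the dive locations of each 5-day window, stepped one day
and labelled by its centre day. One fixed draw set is reused across windows
(so the series is comparable through time; per-window redraw is available).
A cluster counts as a *plume cluster* when its centroid lies within the
terminus buffer — the centroid rule is robust to stragglers; a
membership-fraction rule is available.

Two series result: the percentage of draws finding a plume cluster
(`pct_tests`, the headline statistic) and the percentage of profiles that
are members of any cluster (`pct_profiles_in_clusters`). `pct_tests` is
bounded at 100% and saturates during dense clustering, so its maxima
localise poorly in time; the participation series is roughly linear in
clustering intensity. Peak *detection* therefore runs on the participation
series by default (configurable), while both series are reported.

## Peaks and pairing

Peaks are local maxima with the standard prominence definition (threshold:
20% of the series maximum; minimum separation 4 days — explicit knobs,
since the original identification of runoff and clustering peaks was
visual). Plateaus reduce to their centre day, and each accepted peak's date
is refined to the centre of mass of the series above half prominence
("centroid" refinement): for a noisy, flat-topped series this estimator is
much more stable than the raw argmax and is unbiased for symmetric peaks.
Pairing is greedy nearest-in-time within ±3 days — with at most a handful of
peaks per series, greedy matching equals optimal assignment in practice and
is symmetric under exchanging the series. Unmatched peaks on either side are
reported, not suppressed: clustering peaks without runoff peaks are a real
phenomenon (storage and delayed release in the subglacial system), which
this package reports but does not model.

## The synthetic campaign

The generator emulates the statistical structure the analysis assumes, with
a truth record so every test is closed-loop.

* **Runoff**: baseline plus Gaussian pulses, clipped at zero. Defaults: peaks
  of 150, 220 and 70 m³ s⁻¹ (8 and 26 August, 12 September 2012) with 2/3/2
  day widths — sharp, well-separated pulses like an observed late-summer
  melt season.
* **Plume**: the classical entrainment-plume equations dQ/dz = 2α√(πM),
  dM/dz = FQ/M (buoyancy flux F conserved; unstratified ambient), integrated
  by fixed-step RK4 at 0.5 m. Core dilution f_core(z) = Q₀/Q(z), Gaussian
  radial structure with scale b(z) = Q/√(πM). The source velocity defaults
  to the momentum-balanced value, for which b is non-decreasing from the
  source. Entrainment coefficient α = 0.1. The fraction of catchment runoff
  routed through the source is calibrated once per campaign so that core
  dilution at the configured depth equals the configured maximum f_sg
  (defaults 0.27 at 64 m).
* **Seals**: five seals, one potential dive per 4-hour block, of which a
  fraction `p_transmit = 0.25` is actually relayed (satellite delivery is
  lossy; this reproduces the few profiles per seal-day of real deployments).
  A transmitted dive goes to one of three destinations: tight to the plume
  source with probability base + gain·(Q/Q_max)^0.5 (the square root encodes
  a saturating response — real seals cluster almost as densely at modest as
  at peak discharge), diffusely into the near-terminus buffer with
  probability 0.25 (front affinity persists when the plume is off, without
  producing tight clusters), else uniformly in the fjord. By default the
  daily number of tight visits is the rounded expectation, assigned by
  per-dive uniform ranks (`visit_model = "quota"`); independent Bernoulli
  draws are available, but at these data rates they let the realised centre
  of a weak episode wander by more than a day, which is behavioural noise,
  not a property of the coupling under test.
* **Profiles**: ascent-sampled at 1 m resolution to the dive depth; samples
  are convex combinations of the runoff endmember and the ambient column
  (linear stratification above a 40 m pycnocline, uniform below — so
  spike-depth samples mix against exactly the ambient endmember and
  noise-free recovery is exact); converted to instrument variables (in-situ
  temperature, practical salinity, pressure) via the inverse seawater
  routines; Gaussian noise σ_T = 0.02 °C, σ_S = 0.1 added when enabled.
* **The core encounter**: on the day of maximum runoff one designated dive
  terminates at the target depth on the plume axis — seals forage at the
  plume edge and enter the core on ascent, so the deepest sample is the
  freshest. All other plume dives keep a per-day minimum approach radius
  such that their f_sg stays below 90% of the configured maximum; the
  campaign's true maximum is therefore exactly the configured value.
* **Locations**: GPS dives get bracketing fixes (±5–40 min) and ~10 m
  position error; 30% of dives are marked interpolated (~30 m error), with
  natural run lengths so some profiles violate the more-than-three rule; a
  small fraction of profiles (2%) carries an interpolated salinity value.
* **Determinism**: every dive draws from its own substream derived from the
  master seed, so campaigns are byte-identical under a fixed seed and the
  near-terminus share is exactly monotone in the behavioural gain.

What the generator does **not** emulate: stratified-ambient plume
detrainment and terminal-depth physics, turbulent plume fluctuations,
sediment/turbidity, subglacial storage-release (the cause of real
clustering peaks at low runoff), tag attrition through the season, and
Argos-class location errors of hundreds of metres. Passing closed-loop
tests therefore demonstrates the pipeline's correctness on data with the
assumed structure, not the validity of those assumptions for any real
deployment — in particular the 27%-at-64-m benchmark on archived field data
is known to be sensitive to endmember choices.

## Numerical choices and degenerate inputs

* Decomposition requires non-collinear endmembers (checked;
  |det| < 10⁻¹⁰ errors out) and is exact otherwise; the reported residual is
  a round-off diagnostic.
* `max_fsg()` on an empty valid set returns an empty result, not an error.
* Empty sweep windows score 0% with `n_profiles = 0`; windows below the
  smallest minPts cannot cluster and score 0%.
* Grid bins are half-open, `[x, x+100)`; a point exactly on an edge belongs
  to the higher bin.
* Region tie at exactly 500 m is inclusive (≤) and resolves to the nearer,
  then marine-terminating, front.
* The interpolation run-length boundary is strict: run length 4 rejects,
  3 passes.
* Pressure/depth and Θ/in-situ conversions round-trip to ≈10⁻⁹, so
  closed-loop "exact" recoveries are asserted at 10⁻³ absolute tolerance.

## Problem sizes in the tests

The default campaign (5 seals, August–December, ~1100 transmitted profiles,
~95 000 samples) runs the full pipeline in a few seconds; the acceptance
checks use two such campaigns (noise on and off) with 1000 sweep draws per
window, 10⁴ random mixtures for the inversion check, and 100 random DBSCAN
instances (n ≤ 200) against the brute-force oracle. Unit tests use a 2-seal,
two-month campaign. These sizes were chosen to exercise the full data volume
of a real deployment while keeping the whole suite under a minute.
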