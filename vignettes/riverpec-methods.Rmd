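---
title: "Modelling down-the-drain chemical exposure in river catchments with riverpec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling down-the-drain chemical exposure in river catchments with riverpec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverpec)
```

## The problem

Pharmaceuticals, personal-care products and contrast agents reach rivers
almost exclusively "down the drain": they are consumed by people, excreted
into the sewer, partly removed in wastewater treatment plants (WWTPs), and
the residual load is discharged into the receiving stream.  Regulators and
water managers need *spatially resolved* predicted environmental
concentrations (PECs) — a single basin-average number hides exactly the
small, effluent-dominated creeks where quality standards are exceeded.

`riverpec` implements a steady-state, mass-balance exposure model on a
dendritic river network, with Monte Carlo propagation of river-flow
variability, and scenario tooling (re-routing of small plants, treatment
upgrades, consumption change) evaluated as flow-length statistics against
an environmental quality standard (EQS).

## Model structure

### Network and hydrology

The river network is a directed tree of segments (edges at most 2000 m
long) draining to a single outlet; nodes sit at confluences and at every
point of interest (WWTP outfalls, gauges, monitoring sites).  Braided
channels and flow splits are rejected at validation: steady-state routing
assumes a unique downstream path, and the dendritic assumption matches the
drainage networks this model family is applied to.

Each segment carries three flow statistics: mean flow MQ, mean low flow
MNQ, and median flow Q50.  Flow variability is modelled as lognormal,
anchored by the median and the mean:

$$\mu = \ln Q_{50}, \qquad \sigma = \sqrt{2 \ln (MQ / Q_{50})},$$

the unique lognormal with median $Q_{50}$ and mean $MQ$.  The functional
form is a modelling choice: MQ/MNQ/Q50 are the statistics catchment
databases actually provide, and the lognormal is the standard
positively skewed flow model that those two anchors determine uniquely.
MNQ is kept as a plausibility bound rather than a third fitting target.

Sampling is *rank-correlated*: one shared quantile $u$ per Monte Carlo
iteration drives all segments ($Q = Q_{50} e^{\sigma z(u)}$), so the whole
basin is wet or dry together.  Independent per-segment draws would violate
mass coherence at confluences (a dry main stem meeting a flooding
tributary).  At $u = 0.5$ every segment carries exactly Q50, which the
tests assert bit-exactly.

Modelled flows are calibrated against gauges: every segment is scaled by
`observed/modelled` of its *nearest downstream* gauge, which makes the
calibrated flow exact at every gauge.  Segments downstream of the last
gauge inherit the factor of the nearest upstream gauge; where upstream
branches disagree, the branch with the larger modelled flow (the main
stem) wins.  The same factor is applied to MQ, MNQ and Q50 — the
alternative (calibrating only MQ/MNQ) would distort the fitted variability
distribution.

Velocity follows a hydraulic-geometry power law
$v = v_{ref} (Q/MQ)^{b}$ with a per-segment exponent $b$ (default 0.4, the
conventional mid-range value for natural channels); travel time is
$\tau = L / v$.

### Emissions

The basin-wide emission of a substance is
$L_{total} = P \cdot c \cdot f_{ex} / 1000$ g/d, with $P$ the connected
population, $c$ the per-capita consumption in mg/(cap·d) and $f_{ex}$ the
excretion fraction.  A fraction $f_{site}$ of the total is emitted at the
place of medical treatment and routed through the hospitals' receiving
plants (hospitals never discharge directly); the remaining
$1 - f_{site}$ follows the place-of-residence principle and is spread over
the resident population per plant.  Hospital patients are *not* added to
the population term — that would double-count them.

For substances administered during medical procedures the on-site fraction
combines stationary in-patients (emitted on site in full) with the part of
the out-patient dose excreted before leaving:

$$f_{site} = f_{stat} + (1 - f_{stat}) f_{window}.$$

With 50% stationary administration and 75% early excretion this gives
87.5%.  The hospital share is split across hospitals proportionally to
patients (or beds), or by custom weights when local knowledge — such as a
single radiology department handling most contrast-agent procedures —
justifies it; re-allocation never changes the basin total.

Treatment is percentage removal per category (lagoon, constructed wetland,
bio-filter, activated sludge).  Effluent (hydraulic) flow defaults to
0.2 m³ per inhabitant and day, the conventional design value, overridable
per plant.

### In-stream fate

Routing processes segments in topological order.  At a segment's head node
the upstream mass flows and local discharges mix completely; the reported
concentration is this after-mixing value at the segment *start*, so a
discharge segment shows its local maximum (the "hot-spot" convention).
Along the segment the mass decays by the lumped pseudo-first-order rate
$k = k_{deg} + k_{sed} + k_{vol}$ over the travel time at the segment's
current flow:

$$M_{out} = M_{in} \, e^{-k \tau(Q)}, \qquad
  C = \frac{M_{in}}{Q} \text{ (unit-converted to ng/l)}.$$

Effluent flow is added to river flow from the discharge node downstream —
in headwater creeks treated wastewater can dominate dilution, and ignoring
it would overestimate concentrations there.  Decay uses the flow at the
segment start; with segments capped at 2000 m, sub-segment discretisation
or mid-segment velocity would change results well below other model
uncertainties.

For a conservative substance ($k = 0$) the outlet mass flow equals the sum
of all loads to 1e-9 relative; the engine is linear and superposable in
the loads, and it is cross-checked in the tests against an independent
per-source path-enumeration oracle.

### Monte Carlo

A run draws, per iteration and from a single seeded RNG stream in a fixed
order (flow quantile, then consumption, then removal per category
alphabetically), one realisation of each varying parameter and routes it.
By default only flow varies: substance-parameter uncertainty
distributions are rarely available, and flow fluctuation dominates the
concentration variability in effluent-dominated networks.  When enabled,
consumption is lognormal (mean-preserving, given relative SD) and removal
is normal truncated to [0, 1].  The default 10,000 iterations make the
10th/90th percentiles stable to a few percent; the result object stores
the full sample matrix so any percentile can be computed afterwards
(linear interpolation between order statistics).

### Scenarios and basin statistics

Scenario operators modify a catchment or substance and are compared
against a reference run segment by segment:

* `reroute_small_wwtps()` removes every plant below a population threshold
  and transfers its population, hospitals and hydraulic load to the
  *geometrically closest* plant at or above the threshold (ties to the
  lower id).  Geometric distance stands in for sewer-construction cost;
  restricting targets to surviving plants avoids chained transfers.
* `upgrade_treatment()` stores a per-plant removal override.
* `change_consumption()` scales consumption; linearity propagates the
  factor exactly.

`compare()` classifies each segment by relative change of the mean PEC
(configurable to any percentile): *improved* below −5%, *deteriorated*
above +5%, otherwise *insignificant* — changes within ±5% are treated as
model noise.  `threshold_crossings()` sums the flow length newly above and
newly below a threshold; their difference is the *net relief*.
`exceedance_length()` reports the flow length above an EQS, or above a
limit of quantification (LOQ) to delimit where monitoring can see the
substance at all.  Segments at zero concentration in both runs are
insignificant (0/0 is defined as zero change).

### Confronting simulations with monitoring data

`band_coverage()` computes the fraction of observations inside the
simulated P10–P90 band; for observations that genuinely come from the
simulated distribution the expectation is 80%, which is also the
self-consistency test the synthetic generator enables.  Coverage can be
computed per site or pooled; pooled is the headline number.  Observations
below an LOQ are excluded by default (substitution at LOQ/2 is available,
since censoring conventions differ between agencies).

`dixon_q_test()` implements the classic r10 ratio for small samples
(3 ≤ n ≤ 30) with the two-tailed critical-value table of Rorabacher
(1991), flagging at most one extreme value per call at α = 0.05 or 0.01 —
the screening test traditionally used on sparse monitoring series before
band comparison.

## The synthetic catchment generator

No real catchment database ships with the package, so `generate()` builds
one: a random dendritic tree grown by recursive headwater
extension/bifurcation (acyclicity and a unique outlet hold by
construction), segment lengths uniform in (200, 2000] m, lognormal local
runoff accumulated downstream and rescaled so the outlet MQ matches the
configured scale exactly, Q50 and MNQ drawn below MQ segment-wise, plants
spanning village to city scale with an exact (not probabilistic) quota of
small plants so scenario tests are deterministic, hospitals, an outlet
gauge observing the modelled flow (calibration is the identity by
construction), and monitoring sites on the largest segments.

The generator aims at *structural plausibility, not geomorphological
realism*: no Horton laws, no floodplains, no correlated runoff fields.
Tests passing on synthetic catchments therefore demonstrate the
correctness of the arithmetic and the invariants (conservation, oracle
equivalence, coverage), not predictive skill on any real basin — that
requires a real, gauge-calibrated database and measured substance
parameters.

## Numerical choices and problem sizes

* Concentrations are ng/l everywhere; the g/d ↔ m³/s conversion constant
  is exact (`1e9 / 86 400 000`).
* Percentiles: `stats::quantile` type 7.
* Topological order breaks ties by segment id, so runs are reproducible
  across platforms; the Monte Carlo engine routes all iterations as one
  vectorised matrix pass per segment.
* Substance defaults in examples are placeholders to be overridden from a
  JSON parameter file; they are not measured properties of any real
  compound.
* The test suite exercises catchments up to 200 segments with 10,000
  iterations — a size chosen so the full suite runs in seconds while the
  percentile tests still operate at the iteration count used for
  production runs.

## Known limitations

* Steady state only: no storm events, no combined sewer overflows, no
  seasonal consumption signal.  Occasional monitoring outliers caused by
  such events are expected to fall outside the simulated band.
* No sediment compartment, no temperature dependence of loss rates, no
  metabolite tracking.
* Flow splits (braids, diversion weirs) are rejected rather than modelled.
* Agricultural or other non-point sources are out of scope; the emission
  model is strictly down-the-drain.
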