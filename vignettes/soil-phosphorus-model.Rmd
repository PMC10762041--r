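---
title: "A seven-pool model of phosphorus in agricultural topsoils: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A seven-pool model of phosphorus in agricultural topsoils: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilphos)
```

## The problem

Phosphorus availability limits crop production in large parts of the world,
while surplus fertilization elsewhere drives eutrophication. Unlike natural
soils, agricultural soils carry a long legacy of management: decades of
fertilizer and manure inputs, crop offtake, erosion and land conversion have
reshaped where soil P sits and in which chemical forms. `soilphos` simulates
that history for cropland and grassland topsoils (the 0-0.3 m plough layer):
it reconstructs annual P budgets from driver data, evolves seven functionally
distinct soil P pools with a daily process model, mixes pools across
land-use transitions, and propagates driver uncertainty through a Monte-Carlo
ensemble. Because the real driver stack is a collection of large gridded and
statistical datasets, the package ships a synthetic-world generator that
emulates every input, so the whole chain is testable offline.

## Pools and fluxes

Seven pools per land cover and grid cell, aligned with operationally defined
(Hedley-type) soil P fractions:

| pool | meaning |
|------|---------|
| `i_sol` | inorganic P in soil solution |
| `i_lab` | labile inorganic P (resin/bicarbonate; the plant-available proxy) |
| `i_sec` | moderately labile inorganic P on secondary minerals (hydroxide) |
| `i_prim` | primary (apatite) mineral P |
| `o_lab` | labile organic P |
| `o_sta` | stable organic P |
| `x_occ` | occluded P (residual; inorganic + organic) |

Daily first-order exchanges connect them:

* occlusion/de-occlusion: `k_sec_to_occ * P_sec` and `k_occ_to_sec * P_occ`;
* Freundlich sorption from solution to the secondary pool,
  `k_sol_to_sec * (P_sol / W_abs)^b`, with desorption `k_sec_to_sol * P_sec`
  (`W_abs` is soil water in L per kg soil, so `P_sol / W_abs` is the solution
  concentration in mgP/L);
* weathering of apatite into labile P, modulated by a Q10 of 2.4 referenced
  to 15 degC and linearly by relative soil moisture;
* mineralization of both organic pools into labile P, modulated by a Q10 of
  2 referenced to 30 degC and by the moisture polynomial
  `-1.1 w^2 + 2.4 w - 0.29`.

Rather than integrating a fast sorption/desorption pair between solution and
labile P, the two pools are assumed at equilibrium at the end of each day:
the total `P_sol + P_lab` is redistributed by solving

```
k_sol_to_lab * P_sol^b + k_lab_to_sol * W^b * P_sol
    = k_lab_to_sol * W^b * (P_sol + P_lab)
```

for `P_sol`. The left side is strictly increasing in `P_sol`, so the root is
unique; a safeguarded Newton iteration inside a bisection bracket
(`[0, total]`) converges to near machine precision, and tests compare it
against an independent pure-R bisection oracle to 1e-8 over a thousand random
parameter draws.

## Parameterization

Exchange-rate parameters vary by cell and are constant in time and identical
for cropland and grassland. Four quantities come from regressions on
pedo-climatic predictors (re-fitted without oxalate so they can be applied
where oxalate data do not exist): the Freundlich exponent `b`, the
labile-to-solution rate, the solution-to-secondary rate, and the occlusion
rate. The predictors are the steady-state fractions of the four
inorganic-exchange pools (solution, labile, secondary, occluded), soil
texture, pH, soil carbon, and mean air temperature; the steady-state pools
are taken from the natural-soil (unmanaged) background of each cell, with the
solution pool reconstructed as `p_c_inf * mean(W_abs)`, where `p_c_inf` is
the steady-state solution concentration (0.1 mgP/L by default, configurable
because the simulation is sensitive to it in low-sorption soils). The three
reverse rates follow from steady-state ratio identities and therefore hold
exactly by construction — a property asserted to machine precision in the
test suite.

Fixed-rate processes: weathering at 2.7e-7 per day; organic mineralization
under two presets, `"v1.0"` (stable 2.7e-5, labile 2.7e-4 per day; residence
times 100 and 10 years) and the default `"v1.1"` (1.8e-4 and 1.4e-3 per day;
15 and 2 years), selected in `flux_config()`. The faster preset is the
default because with slow mineralization the organic pools impose a large
spurious drift over the first simulated decades.

Two numerical guards:

* the labile-to-solution regression is linear and can return non-positive
  rates; these are floored at 1e-6 per day (with a warning naming the cells)
  because a non-positive rate makes the equilibrium problem ill-posed;
* the moisture scalar for mineralization is clamped at 0 where the quadratic
  is negative (relative water content below about 0.13), since a negative
  scalar would reverse the flux direction.

`check_parameter_consistency()` reports where a rate is large enough that a
single day's gross flux would exceed its source pool (`k_sec_to_sol >= 1` per
day, or `k_sol_to_sec >= mean(W_abs) * p_c_inf^(1-b)`). Such values are
legitimate — the sorption rate typically exceeds its bound by orders of
magnitude — and are handled by flux clamping rather than by altering the
parameters.

## The daily step: order of operations and clamping

Each day: (1) gross fluxes are computed from start-of-day pools; (2) each
pool's outflows are scaled by a common per-pool factor wherever the summed
outflow would push the pool below zero given its start-of-day stock plus
gross inflows; (3) pools are updated; (4) the solution-labile equilibrium
redistributes `P_sol + P_lab`. The proportional per-pool scaling is this
package's resolution of an under-determined statement ("prevent a net flux
larger than the pool it leaves"): it is order-independent and conservative.
Because scaling one pool's outflow reduces another pool's inflow, the scale
factors are iterated to a fixed point (they can only decrease, so the
iteration terminates); no pool can go negative even through the
secondary-occluded and secondary-solution flux cycles.

The three one-way decays (weathering, both mineralizations) use the exact
exponential update `P * (1 - exp(-k*g*h))` instead of the forward-Euler flux
`k*g*h*P`. The two agree to second order in the (small) daily rate, and the
exponential form makes annual decay match the closed form `exp(-k*g*h*365)`
exactly and independently of sub-stepping — which is also how the tests pin
the organic-pool dynamics.

All daily fluxes are internal transfers, so the daily step conserves total P
exactly; the only P entering or leaving a land-cover column does so through
the annual input/output and land-use mixing. That yields a machine-precision
annual mass balance, `delta(total P) = inputs - erosion - satisfied uptake`,
asserted at 1e-9 relative on randomized synthetic worlds.

## Annual inputs and outputs

On the first day of each year, the year's budget is applied: erosion removes
a mass fraction `loss / (bulk_density * (1 - coarse_frac) * 0.3 m * 1e4)` of
every pool except solution P (solution erosion is set to zero); chemical
fertilizer enters labile P; manure, residues and sludge are split
(inorganic-labile / organic-labile / organic-stable) with fixed composition
fractions (0.8/0.1/0.1 for manure and sludge, 0.4/0.4/0.2 for residues);
deposition enters labile and primary P (labile share 0.1 for dust, 0.5 for
all other components); and prescribed plant uptake is removed from labile P.
Solution P is deliberately never touched by the annual terms. If solution +
labile P cannot sustain the uptake, both are set to zero and the shortfall is
recorded as unsatisfied uptake (`fP_upns`) — a diagnostic, not an error,
since the uptake is prescribed by driver data rather than simulated plant
growth. Erosion is applied on day 1 together with the other annual terms,
using start-of-year pools.

The year is 365 days; no leap years. Forcing is annual, so calendar detail
is immaterial.

## Drivers

Each annual flux is constructed from driver inputs the way a global
reconstruction would:

* **manure**: gridded N-in-manure times a constant P:N ratio of 0.20
  (estimate 1), and the same field rescaled per country so its 1950-2017 mean
  (cropland + grassland pooled) matches a country-scale production table
  (estimate 2); the mean run uses the average of the two;
* **chemical fertilizer**: grassland N fertilizer times P:N = 0.22; the
  total-P field (which attributes everything to cropland) is corrected by
  subtracting the grassland share, floored at zero;
* **grassland uptake**: NPP-based stoichiometric conversion with carbon
  content 0.45 kgC/kgDM, dry fraction 0.20 kgDM/kgFM, aboveground P
  concentration 8.8e-2 gP/100gFM (bounds 2.5e-2 and 1.5e-1; belowground is
  half), organ lifespans 0.8/0.7 yr over a 1-yr season, and a belowground NPP
  share of 0.54; residues are `(1 - GI)` of the uptake, `GI` the grazing
  intensity. Two NPP estimates are carried (the gridded field and the same
  field scaled by 979/460, the ratio of two published global means);
* **cropland uptake/residues**: per-crop from fresh-matter yield, organ P
  concentrations, harvest index and root:shoot ratio (`RSR = 1/frac_above -
  1`), with root P at 0.75 of aboveground-residue P, equal dry-matter shares
  across organs, and a residue fraction of 0.5 (0 for forage crops);
  aggregated over crops with harvested-area weights. Yield and area series
  anchor a reference-year (2000) map to country time series; before 1961,
  yields scale with population and areas hold their 1961 value. For root
  crops the roles of the root and aboveground terms are swapped (harvested
  organ belowground, residue fraction applied to aboveground biomass) — a
  simplified symmetric variant adopted here as a design choice;
* **deposition**: five source components; non-anthropogenic parts static,
  the anthropogenic-combustion part scaled by a normalized emission series
  with a single multiplicative splice equalizing the overlap-period mean;
* **sludge**: country-scale human excretion routed through three treatment
  types with removal efficiencies 0.10/0.45/0.90, spread uniformly over the
  country's cropland; rates interpolated linearly 1970-2010 and held
  constant outside;
* **erosion**: gross soil loss divided by topsoil mass, capped at 1/yr.

## Land-use change

Four covers: cropland, grassland, non-agricultural, urban (aggregated from
twelve raw classes). Pools are mixed annually by area-weighted bookkeeping:
the stock a cover retains plus the stock incoming conversions import, divided
by the new fraction. Non-agricultural land always carries the natural-soil
background (with the derived solution pool) — conversion to agriculture
therefore imports natural pools; urban land carries zero P. A cover whose
fraction reaches zero stores zeroed pools (their weight is zero, so the
convention is observationally neutral). Mixing precedes the annual
input/output, which precedes the daily dynamics. Transitions between the two
agricultural covers conserve fraction-weighted P exactly (asserted to
1e-12). Land-use driver uncertainty is not sampled, because perturbing
fractions and transitions independently would break their consistency
identity.

Both agricultural covers start from the natural background (initial
conditions), which doubles as the steady state used in the parameterization.

## Uncertainty propagation

Ensembles redraw uncertain driver variables per member; all cells and years
are independent. Three families:

* `normal_4sigma`: where two estimates E1, E2 exist — normal with mean
  `(E1+E2)/2` and SD `(E2-E1)/4`, so about 95.4% of draws fall between the
  estimates;
* `uniform(E1, E2)`: for the most uncertain variables (manure, residue
  composition), where neither estimate is preferred;
* `relative_normal`: single-estimate variables — SD of 15% or 25% of the
  mean (`x` = 0.30 or 0.50).

Input/output samples are truncated below at zero; background, climate and
soil-property samples at the spatial min/max of their mean field. Truncation
re-draws rather than clips (no probability mass piles up at the bounds; after
100 re-draws stragglers are clipped with a warning). The per-variable family
assignment is not fully specified by the source material, so it lives in an
editable table (`uncertainty_spec()`) with these defaults: uniform for
manure and residue composition; `normal_4sigma` for NPP and the grass P
concentration; `relative_normal` x = 0.30 for fertilizer, crop uptake and
residues, deposition, erosion, background, climate and soil properties, and
x = 0.50 for sludge. Sampled texture triples are renormalized to sum to 100.

The uncertainty metric is the coefficient of variation across members
(population SD over mean, fixed for reproducibility; CV rather than SD
because members that bottom out at zero pools would otherwise bias the
spread), masked where the mean is non-positive. Freezing all drivers
reproduces the mean run bit-exactly; ensembles are bit-reproducible under a
fixed seed.

## The synthetic world

`make_world()` generates the complete input bundle: a grid (default 10 x 10
cells) with contiguous equal-area countries (default 4), soil properties in
ordinary agronomic ranges (texture summing to 100, pH 4.5-8.2, carbon 5-30
gC/kg, bulk density 1100-1500 kg/m3), natural-soil pools totalling 100-3000
kgP/ha spread over Hedley-type shares, near-constant climate with small
interannual noise, a land-use series built forward from random transitions
(so the consistency identity holds by construction), and every driver with
plausible magnitudes (chemical fertilizer ramping to at most ~40 kgP/ha/yr,
manure, NPP 2000-8000 kgC/ha/yr, three crops including one forage and one
root crop, deposition of order 0.1 kgP/ha/yr, erosion up to 5000 kg
soil/ha/yr on cropland). The default period is 1950-2018 to keep
full-pipeline runs fast; a 1900 start is available via `years`.
`make_steady_world()` zeroes all inputs/outputs and transitions for
conservation and closed-form decay harnesses.

What the generator does *not* emulate: spatial covariance of real soil and
climate fields, realistic country-size distributions, the full 172-crop
catalogue, or temporally changing country boundaries. Passing tests
demonstrate correctness of the machinery — budget construction, pool
dynamics, mixing, sampling — not agreement with any real-world map; the
headline statistics of a real reconstruction depend on the real driver
stack, which is out of scope here.

## Problem sizes used by the tests

The test suite runs the full pipeline on 10 x 10-cell worlds over 30
simulated years (20 seeds) for the mass-balance property, a
100-member ensemble on the default 100-cell, 69-year world for the
end-to-end check, 1e6 draws for the sampling-coverage check, and 1000 random
draws for the equilibrium-solver oracle. These sizes were chosen as the
smallest that exercise every code path with meaningful statistics.

## Known limitations

* Organic P dynamics are first-order decay only: no biochemical
  mineralization, no coupling to carbon or microbial pools.
* Uptake is prescribed, not coupled to solution P through plant growth;
  unsatisfied uptake is recorded (`fP_upns`) rather than fed back.
* The daily step with clamping understates the solution-to-secondary
  transfer where the sorption rate exceeds its daily-step bound; refining
  the step (`steps_per_day`) moves input-year mass from labile to secondary,
  and the package exposes this as a sensitivity rather than defaulting to an
  expensive sub-daily step.
* Parameters are identical for cropland and grassland and constant in time.
* Outputs are serialized as plain CSV with a units sidecar; the arrays are
  small enough at these problem sizes that a binary gridded format is
  unnecessary.
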