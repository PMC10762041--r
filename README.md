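# soilphos

Process-based reconstruction of phosphorus (P) pools in cropland and
grassland topsoils (0–0.3 m).

Soil P availability limits crop yields in much of the world while surplus P
drives eutrophication elsewhere, and decades of fertilization, harvest,
erosion and land conversion have left agricultural soils far from the state
that soil properties alone would predict. `soilphos` is for biogeochemical
modellers and agronomists who want a transparent, testable implementation of
the standard reconstruction chain: build annual P budgets from driver data,
evolve the soil P pools with a daily process model, mix pools across
land-use transitions, and put uncertainty bounds on the result with a
Monte-Carlo ensemble.

## The model

Seven pools per grid cell and land cover, aligned with Hedley-type
fractions: solution P (`P_i-sol`), labile inorganic P (`P_i-lab`, the
plant-available proxy), secondary mineral P (`P_i-sec`), primary apatite P
(`P_i-prim`), labile and stable organic P (`P_o-lab`, `P_o-sta`), and
occluded P (`P_x-occ`). Daily exchanges:

    occlusion:      k_so · P_i-sec          de-occlusion:  k_os · P_x-occ
    sorption:       k_ss · (P_i-sol/W)^b    desorption:    k_se · P_i-sec
    weathering:     k_w  · g1(T) g2(w) · P_i-prim
    mineralization: k_m  · h1(T) h2(w) · P_o-lab , P_o-sta

with Freundlich exponent `b`, soil water `W` (L/kg), Q10 temperature scalars
`g1` (2.4, ref 15 °C) and `h1` (2, ref 30 °C), and moisture scalars `g2 = w`
and `h2 = −1.1w² + 2.4w − 0.29` (clamped at 0). Solution and labile P are
held at a daily Freundlich equilibrium solved by safeguarded Newton
iteration. Rate parameters come from pedotransfer regressions on soil
texture, pH, carbon, air temperature and the steady-state pool fractions of
the natural-soil background; reverse rates follow from steady-state ratio
identities that hold exactly by construction. Annual inputs (fertilizer,
manure, residues, sludge, deposition), uptake and erosion are applied on day
1 of each year; land-use transitions mix cropland/grassland pools by
area-weighted bookkeeping, importing natural-soil pools when agriculture
expands. Driver uncertainty is propagated by re-sampling each uncertain
driver per ensemble member (normal with 4σ between paired estimates, uniform
for the most uncertain, relative normal otherwise) and summarized as
per-cell coefficients of variation.

A synthetic-world generator emulates every driver input on a small grid with
invented countries, so the full pipeline runs and is tested without any
external data. See the methods vignette
(`vignettes/soil-phosphorus-model.Rmd`) for assumptions, numerical choices
and limitations.

## Worked example

```r
library(soilphos)

world <- make_world(seed = 1)            # 100 cells, 4 countries, 1950-2018
sim   <- run_simulation(world)           # mean-driver run

round(apply(sim$pools[, , , "2018"], c(2, 3), mean), 1)
#>       i_sol i_lab i_sec i_prim o_lab o_sta x_occ
#> crop    1.7 409.6 613.3  341.1  34.4 154.9 368.0
#> grass   0.3 166.3 237.9  353.2 120.8 352.3 208.5

sim$consistency$n_flagged_sol_to_sec
#> [1] 100

ens <- run_ensemble(world, n = 20, seed = 1)
cv  <- coefficient_of_variation(ens)
round(c(crop  = median(cv[, "crop",  "i_lab"]),
        grass = median(cv[, "grass", "i_lab"])), 2)
#>  crop grass
#>  0.13  0.51
```

The pool table is the 2018 mean over cells in kgP/ha for the synthetic
world: cropland accumulates labile P under its larger fertilizer and manure
inputs, grassland stays leaner, and solution P is a tiny sliver of labile P.
The consistency count says every cell's Freundlich sorption rate exceeds
what a daily step can represent without clamping — expected for this
parameterization, and the reason the integrator clamps per-pool outflows
(`steps_per_day` refines the step where that matters). The ensemble CVs show
labile P far more uncertain on grassland than cropland, driven by the NPP
and grass-stoichiometry uncertainty in the uptake driver.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/soilphos.R run      --config cfg.txt --out out/
Rscript inst/cli/soilphos.R ensemble --config cfg.txt --out out/ --n 100
```

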