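# woodsim

Spatially explicit simulation of woody encroachment on temperate
semi-natural grasslands.

After grassland management stops, succession may run to forest within
decades or stall as a tall-grass fallow for half a century — the outcome
hinges on seed sources in the neighbourhood, the state of the herbaceous
layer, soil disturbance, and browsing pressure. `woodsim` is an
individual-based, raster-based simulator of exactly this transition, built
for landscape managers and succession ecologists who want process-level
what-if scenarios (mowing regimes, red-deer densities, initial shrub
cover) rather than statistical extrapolation.

## The model in brief

The landscape is a grid of 100 m² cells. Two coupled layers live on it:

* **Bushes and trees** (birch, broom, beech, spruce, oak) are explicit
  individuals with state (height *H*, age *A*, crown diameter *D*, cover
  *C*). Annual processes:
  - height growth by the yearly integral of the Bertalanffy law,
    ΔH = (H_max − H)(1 − e^(−g)), with g ~ N(G, s_G) drawn per
    individual and year;
  - crown allometry D = a·H^b and cover C = π(D/2)², capped at the cell
    area;
  - seed production with mast-year variability (a year is, with equal
    probability, seedless or yields 10–40%, 40–70%, 70–100% of
    `Seed_max`);
  - dispersal by a double-exponential kernel fixed by the effective
    seeding distance ED (containing the fraction p_ED of seeds) and the
    maximum distance MD; acorns and beechnuts travel beyond ED only into
    cells that already hold woody plants and are not forest (jay
    caching);
  - a per-cell seed bank with predator loss (80%), grass inhibition,
    exponential decay (λ), and annual germination capped at 35 tree + 35
    broom recruits per cell (the surplus feeds the browsing budget);
  - self-thinning: when summed crown areas exceed the cell, the smallest
    individual dies (broom first, and against trees, bramble and
    blackthorn); senescence at an individual maximum age within ±10% of
    the species maximum; mowing kills the 0.1–1 m size class.
* **The herbaceous layer** is cover-based: grasses, tufted plants, and the
  vegetatively spreading thorny shrubs bramble and blackthorn, iterated in
  daily increments. Grass cover inhibits the seed-bank input through a
  summed sigmoid with half-inhibition at I50 per species; the inhibition
  total is 30% lower in mown or grazed cells.

Wildlife couples in twice. Wild boar annually disturb 10% of managed
grassland, 3% of shrub and 1% of fallow cells, removing 45% of the herb
layer. Red deer browse by a supply–demand budget: a "standard deer" (the
mean individual of a 5♂/10♀/20-juvenile reference herd, 59.2857 kg)
demands

    D = (dsd·sdays + dwd·wdays) · (sdeer/100) · frw  =  157.46 kg dw a⁻¹

of woody browse; demand is spread evenly over cells, reduced by a
nurse-shrub factor where blackthorn/bramble shelter saplings, and met from
surplus seedlings and standing saplings in preference order (oak, birch,
beech, spruce; broom is never touched). Browsed saplings stop growing for
the year, die immediately below 0.2 m, and face a species-specific
mortality up to 1.7 m.

## Worked example

The canonical experiment: one mature birch in the middle of a bare
1-ha grassland, no deer, no grass inhibition.

```r
library(woodsim)
sc  <- make_single_parent_scenario("birch", inhibition = "off",
                                   deer_density = 0, years = 15)
sim <- run_simulation(sc$config, seed = 42)
print(sim)
#> woods_sim: 15 years on 10 x 10 cells (0 deer/100 ha)
#>   birch      9712.7 m2 cover ( 97.1%), 327 agents
#>   broom         0.0 m2 cover (  0.0%), 0 agents
#>   beech         0.0 m2 cover (  0.0%), 0 agents
#>   spruce        0.0 m2 cover (  0.0%), 0 agents
#>   oak           0.0 m2 cover (  0.0%), 0 agents
#>   vegetation: forest 100

encroachment_stats(sim, "birch", full_frac = 0.95)$year_full
#> [1] 3
```

The wind-dispersed parent floods the hectare with seeds; all 100 cells
carry a closed birch canopy within a few years and classify as forest.
Swap in `"beech"` and the spread halts at the 30 m effective seeding
distance — the 29 cells within it saturate at 29% of the area, because
without established woody cells the jay-borne tail of the kernel has
nowhere to deliver. With `inhibition = "on"` the grass-saturated fallow
blocks the seed rain entirely, and with `deer_density = 22` browsing pins
recruitment to the cells where the seedling flood saturates deer demand.
The demand side itself:

```r
p <- browser_params()
standard_deer_weight(p$herd)   # 59.2857 kg
annual_demand_per_deer(p)      # 157.46 kg dw per deer and year
```

`plot(sim)` draws the cover trajectories; `summary(sim)` tabulates percent
cover by year. Landscapes can also be initialized from Esri ASCII region
rasters plus an attribute table (`init_from_rasters()`, with the clumping
rules for scattered trees and bushes), and a thin CLI lives at
`inst/cli/woodsim.R`.

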