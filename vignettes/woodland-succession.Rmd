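---
title: "Simulating woody encroachment on semi-natural grasslands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating woody encroachment on semi-natural grasslands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodsim)
```

## Purpose and scope

`woodsim` simulates the encroachment of bushes and trees on temperate
semi-natural grassland after management changes. It is a multimodel: woody
species are explicit individuals on a raster of 100 m² cells, the
herbaceous layer is a cover-based difference-equation substrate, and the
two interact through space competition, seed-rain inhibition, and the
wildlife submodels (wild-boar soil disturbance, red-deer browsing).
Succession *within* closed forests (e.g. birch giving way to beech) is
deliberately out of scope, as is red-deer population dynamics: deer
density is a constant scenario parameter.

## The woody individual

Each bush or tree carries height $H$, age $A$, crown diameter $D$, cover
$C$ and a browsed flag.

**Growth.** The annual step is the exact one-year integral of the
Bertalanffy law $dH/dt = g(H_{max} - H)$:
$$\Delta H = (H_{max} - H)\,(1 - e^{-g}), \qquad
  g \sim \mathcal{N}(G, s_G)\ \text{truncated at } 0,$$
drawn anew per individual and year. Truncation prevents shrinkage; heights
approach $H_{max}$ asymptotically and never reach it. Browsed individuals
whose leader shoot is within deer reach ($H \le 1.7$ m) skip the year's
increment.

**Allometry.** $D = a_{cd} H^{b_{cd}}$ and $C = \pi (D/2)^2$, with $C$
capped at the cell area: a single dominant crown saturates its cell rather
than exceeding it, which also keeps the self-thinning rule from removing a
lone mature tree whose allometric crown outgrows 100 m².

**Self-thinning.** After growth, if the summed covers in a cell exceed
the cell area, the smallest individual (by height; ties remove the
younger) dies, one at a time, until the covers fit. Broom is thinned
first and against the widest competitor set (trees, conspecifics,
bramble, blackthorn); trees are then thinned against trees only. Space is
the single contested resource — there is no vertical light model.

**Senescence and mowing.** Each individual draws a maximum age uniformly
within ±10% of the species maximum at germination and dies on reaching
it. Mowing kills the $[0.1, 1]$ m size class (closed interval — the
boundary convention is a package decision).

## Seeds

**Production.** Mature individuals ($A \ge A_{mat}$) produce
$Seed_{max} \cdot m$ seeds, where the mast fraction $m$ is drawn once per
species and year: one of four categories (no seeds, 10–40%, 40–70%,
70–100%), then uniform within the range. The category probabilities are
not stated in the source material; the default is uniform $1/4$ and is
configurable. Drawing per species (not per individual) reflects the
regional synchrony of masting.

**Dispersal kernel.** The distance law is double-exponential,
characterized by the effective seeding distance $ED$ (containing the
fraction $p_{ED}$ of seeds) and the maximum distance $MD$ (containing the
rest; nothing travels farther). The exact published coefficients are not
recoverable, so the quantile constraints are treated as the definition:
mass $p_{ED}$ on $[0, ED]$ as a truncated exponential, mass $1 - p_{ED}$
on $(ED, MD]$ as a shifted truncated exponential, each component's scale
set so the untruncated law would hold 95% of its own mass inside its
segment. Discretization onto cell offsets converts the radial density to
an areal one (division by the annulus circumference $2\pi d$; the source
cell takes the mass of the central disc of one cell radius) and
renormalizes to sum one over all sink cells. This construction keeps the
two properties the tests enforce: weights are non-increasing with
distance, and the summed weight within $ED$ matches $p_{ED}$ to within
discretization error (checked against numeric integration of the
continuous law). Mass aimed beyond the grid edge is lost.

**Zoochory gating.** For beech and oak the tail beyond $ED$ represents
jay and mammal transport; it is delivered only into cells that hold at
least one bush or tree and are not forest. Gated mass aimed at ineligible
cells is discarded, not redistributed — the conservative reading. Broom's
tail is zoochorous too but ungated.

**Seed bank.** Incoming seeds lose the predator fraction $P_{loss}$
(80%), then the grass-inhibited fraction $T$:
$N_{sb} = N_{in}(1 - P_{loss})(1 - T)$. Banks are real-valued expected
counts (dispersal produces fractional per-cell amounts); they decay as
$N \leftarrow N e^{-\lambda}$ per year.

**Inhibition.** Per grass species $i$ with cover $c_i$,
$$s_i = \frac{1}{1 + (c_i / I_{50})^{S}}, \qquad S = -10,$$
so $s_i(0) = 0$, $s_i(I_{50}) = 1/2$, increasing toward 1 as the sward
closes. The species factors are summed and clamped at 1; in mown or
grazed cells the total is multiplied by 0.7 (the sward is weaker where
biomass is removed). The sigmoid's concrete form is a package decision
forced by the anchor points; only $I_{50}$ and $S$ are source values.

**Germination.** Candidates are $\lfloor N \cdot Germ \rfloor$ per
species and cell; the bank loses $candidates / Germ$ seeds (failed
germinants die with the successful). Germination requires free space:
tree seeds need space free of trees, broom seeds space free of trees and
all bushes; with none, nothing is attempted (no consumption, no surplus).
Realized recruitment is capped at 35 tree plus 35 broom seedlings per
cell and year; the tree cap is shared across species by largest-remainder
allocation (ties to the earlier species in the table). The surplus enters
the browsing budget as immediately consumable forage. The stored birch
germination rate (0.1) is already halved relative to its source model,
compensating for the absent density-dependent seedling mortality.

## The herbaceous layer

The full grassland community model this layer stands in for is outside
the package's scope; the stand-in honours exactly the contract the woody
model needs: (i) grass covers feeding the inhibition term, (ii)
bramble/blackthorn covers feeding the nurse factor and broom space
competition, (iii) decades-scale fallow dynamics. Per species and daily
increment (365 per year, no seasonality),
$$\Delta c = \frac{g_{max}}{365} \cdot c \cdot \frac{\text{free}}{F_S}
  \cdot (1 - s) \; - \; c \cdot \frac{s}{365},$$
where *free* is the space a species can still claim — thorny shrubs may
displace grasses and are limited only by woody crown cover, everything
else only grows into genuinely free space — and
$s = \min(1, \sum_j (I_j/100)(9 - U_j)/8)$ crosses the management
intensities with the utilization values (a $U = 9$ species is immune). A
configurable fraction (default 0.1) of growth a saturated cell cannot
realize spills to the four orthogonal neighbours. After woody growth,
herb covers are scaled down proportionally to the remaining herbaceous
space (`reclaim_space()`).

The published shrub table prints $g_{max} = 4.7$ with unit d⁻¹, which
would close a fallow within months; the package default reads it as a
per-year rate spread over the daily increments (`gmax_unit`, both
selectable). Under the default, bramble starting small in a
grass-saturated cell needs well over 20 years to claim half the cell —
the decades timescale the coupling contract requires — while cells
initialized at 25% bush cover (the raster-import rule) reach dominance on
the several-decades scale. The grass rows of the default table are
package calibrations (swards close within a few years; they are not
source values) and are documented as replaceable.

## Wildlife

**Wild boar** disturb, once a year, independent Bernoulli draws per cell:
10% of managed grassland, 3% of shrub, 1% of fallow cells (never forest),
removing 45% of the herb layer — which lowers the grass inhibition and
opens recruitment windows.

**Red deer.** Demand per standard deer is
$D = (dsd \cdot sdays + dwd \cdot wdays)(sdeer/100) frw$ with the
reference herd mean $sdeer = 59.2857$ kg, giving 157.46 kg dw a⁻¹. Note
the season lengths sum to 366 days — that is what the demand table
prints, and the budget only reproduces with it, so the validator does not
force a 365-day year. Demand is uniform over cells
($density \cdot A_{cell}/100\,\text{ha} \cdot D$), multiplied by the
nurse factor
$$F = \frac{1}{1 + (C_P/25)^4} \cdot \frac{1}{1 + (C_R/50)^4},$$
a product of Hill sigmoids in blackthorn ($C_P$) and bramble ($C_R$)
cover. Blackthorn's lower half-protection cover encodes its stronger
shelter effect; the half-covers and slope are package defaults, not
literature values, and are exposed in `browser_params()`.

The budget is met first from surplus seedlings (one bite each at seedling
size — recruits that would be eaten first), then from standing
individuals in preference order oak, birch, beech, spruce (broom is never
browsed), smallest first within a species. Only individuals up to 5 m
provide forage; the supply equation mapping height to browsable biomass
is not published, so the default is a height-stratum proxy — bite events
proportional to the crown circumference of the stratum below
$\min(H, 1.7)$ m, at least one, each removing
$B = a_{biom} L^{b_{biom}}$ kg for bite length $L = 0.1$ m — and the
whole function is injectable (`browse_fn`) for anyone holding a
literature form. Per cell and year, consumed biomass never exceeds
demand (a ledger identity the tests assert). Browsed individuals below
0.2 m die at once; flagged individuals with $H \le 1.7$ m die at year
end with probability `Brow_mort`.

## Scheduling and reproducibility

The year runs in a fixed order: boar — daily herb loop — seed production
and dispersal — inhibition-filtered bank input — bank decay — germination
— browsing — growth and allometry — mowing kill — self-thinning —
browsing mortality, then senescence — space reclamation and vegetation
classification — observers. The published flow chart is not available, so
the order is a package decision; it places browsing before growth so a
browsed sapling demonstrably loses the year's increment, and it is
centralized in `run_year()` so alternatives can be tested. Browsing
mortality sits in the mortality phase ("at the end of the year").

All stochastic processes draw from the single global R stream;
`run_simulation()` seeds it and rebuilds the initial landscape under that
seed, so runs are bit-reproducible (asserted in the tests) and replicate
ensembles differ only by seed.

Vegetation types are classified per cell, in precedence order: forest
(tree cover ≥ 50%), shrub (broom + bramble + blackthorn ≥ 10%),
grassland (mown or grazed), disturbed ground (unmanaged, herb cover below
5%), else fallow grassland. The full source typology lives in the
grassland reference model; the thresholds here are configuration-level
stand-ins driven by management flags and covers.

## Synthetic scenarios and what the tests show

`make_single_parent_scenario()` builds the canonical 1-ha experiment
(10 × 10 cells, one parent at age $A_{mat}$ with its deterministic
growth-curve height, bare or grass-saturated herb layer) and
`init_from_rasters()` the clumped landscape import: per region, a cell
share equal to the mapped percentage is fully covered with trees of the
stated age class (1 or 5 years), and bush entries assign 25% cover to
four times their percentage share (broom as aged individuals at 2, 7 or
10 years; bramble/blackthorn as herb cover), rounding half up.

These generators emulate the study conditions, not real data: uniform
soil and climate, sharp management boundaries, a single aggregate
tall-grass sward in fallows. Passing tests therefore demonstrate the
process mechanics — kernel mass accounting, budget identities,
competition bounds, the qualitative patterns (beech halting at its
effective seeding distance; broom populations oscillating on their
12-year lifespan; grass-saturated fallows staying unwooded for 40 years;
forest formation non-increasing in deer density) — but not predictive
skill on any real landscape, which would require a mapped initialization.

"Full-area cover" of a species is measured as total cover reaching 95%
of the simulated area: discrete self-thinning keeps saturated cells
marginally below the cell area, so exactly 100% never occurs.

Problem sizes are chosen for desk-scale runs: the test suite and the
acceptance script use the 1-ha grid (≤ 50 years, ≤ 20 replicate seeds)
and a 10,000-cell single-step landscape for the boar-disturbance rate;
the engine itself has no size limit beyond memory.

## Known limitations

* The herb layer is a minimal stand-in; its management response and
  grass parameters are package calibrations.
* The browse-supply equation and nurse-factor parameters are package
  defaults (both injectable); treat absolute browsing-mortality levels
  with care.
* Recruitment is extremely seed-rich near mature wind-dispersers: a
  single parent floods a hectare within a few years under the published
  seed numbers, so encroachment timing there is governed by growth and
  the recruitment cap rather than seed limitation.
* No vertical light competition, no within-forest succession, no
  seasonality, no deer population dynamics, no pre-existing seed banks at
  initialization.
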