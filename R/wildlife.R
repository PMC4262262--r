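#' Nurse-shrub protection factor
#'
#' Thorny shrubs shelter saplings from browsing: the per-cell deer demand is
#' multiplied by a factor F that decreases sigmoidally with blackthorn and
#' bramble cover, `F = 1/(1 + (Cp/P50)^h) * 1/(1 + (Cr/R50)^h)`. Blackthorn
#' protects more strongly than bramble (its half-protection cover is lower).
#' The sigmoid parameters are package defaults, exposed in
#' [browser_params()]; they are not literature values.
#'
#' @param blackthorn,bramble covers (m2), vectorized.
#' @param params a [browser_params()] object (P50/R50 and Hill slope).
#' @return Factor in \[0, 1\]; 1 with no shrubs, 0 as covers grow large.
#' @export
nurse_factor <- function(blackthorn, bramble, params = browser_params()) {
  h <- params$nurse_slope
  1 / (1 + (blackthorn / params$nurse_P50)^h) /
    (1 + (bramble / params$nurse_R50)^h)
}

#' Twig biomass of one browsing event
#'
#' A bite removes a branch length `L`, converted to dry-weight biomass with
#' the species' twig allometry `B = A_biom_const * L^A_biom_coeff`.
#' @param L branch length (m), vectorized.
#' @param species one row of the woody parameter table.
#' @return Biomass (kg dw); `NA` for species without a twig allometry.
#' @export
twig_biomass <- function(L, species) {
  species$A_biom_const * L^species$A_biom_coeff
}

#' Available browse of an individual
#'
#' Only trees up to `max_forage_height` (5 m) provide forage, and only the
#' stratum up to `max_browse_height` (1.7 m) is reachable. The equation
#' mapping height to forage biomass is injectable (`fn`); the default is a
#' height-stratum proxy: the number of available bite events is the crown
#' circumference of the browsable stratum divided by the bite length
#' (at least one event), and the available browse is that number of bites
#' at bite biomass, with bite branch length never exceeding the plant
#' height.
#'
#' @param H heights (m), vectorized.
#' @param species one row of the woody parameter table.
#' @param params a [browser_params()] object.
#' @param fn optional replacement function `(H, species, params) -> kg dw`
#'   for heights within forage reach.
#' @return Available browse per individual (kg dw).
#' @export
available_browse <- function(H, species, params = browser_params(),
                             fn = NULL) {
  out <- numeric(length(H))
  reach <- H > 0 & H <= params$max_forage_height
  if (!any(reach)) return(out)
  if (!is.null(fn)) {
    out[reach] <- fn(H[reach], species, params)
    return(out)
  }
  if (is.na(species$A_biom_const)) return(out)
  hb <- pmin(H[reach], params$max_browse_height)
  circ <- pi * species$A_cd_const * hb^species$A_cd_coeff
  n_bites <- pmax(1, floor(circ / params$bite_length))
  bite <- twig_biomass(pmin(params$bite_length, H[reach]), species)
  out[reach] <- n_bites * bite
  out
}

#' Annual red-deer browsing over the landscape
#'
#' Deer are distributed evenly: each cell owes
#' `demand = density * cell_area/100 ha * annual demand per standard deer`,
#' reduced by the nurse factor of its thorny-shrub cover. The demand is met
#' first from the surplus of germinating seedlings (recruits beyond the
#' per-cell cap, each worth one bite at seedling size), then by browsing
#' standing individuals in preference order (oak, birch, beech, spruce;
#' broom is never browsed), smallest first within a species. An
#' individual's annual contribution is capped by its available browse;
#' browsing stops when the demand is met. Browsed individuals are flagged
#' (their growth is zeroed if their leader is in reach) and individuals
#' smaller than `instant_death_height` die immediately.
#'
#' @param grid a `woods_grid`.
#' @param params a [browser_params()] object.
#' @param browse_fn optional available-browse replacement (see
#'   [available_browse()]).
#' @return A list: `grid` (flags set, instant deaths removed) and `ledger`
#'   (data.frame per cell with demand > 0: `cell`, `demand`,
#'   `consumed_surplus`, `consumed_agents`, `deaths_immediate`).
#' @export
browse_year <- function(grid, params = browser_params(), browse_fn = NULL) {
  empty_ledger <- data.frame(cell = integer(), demand = numeric(),
                             consumed_surplus = numeric(),
                             consumed_agents = numeric(),
                             deaths_immediate = integer())
  if (params$density <= 0)
    return(list(grid = grid, ledger = empty_ledger))
  wd <- grid$woody
  hp <- grid$herbsp
  pcov <- if ("blackthorn" %in% hp$name) grid$herb[, "blackthorn"] else 0
  rcov <- if ("bramble" %in% hp$name) grid$herb[, "bramble"] else 0
  F_ <- nurse_factor(pcov, rcov, params)
  demand <- params$density * (grid$A / 1e6) * annual_demand_per_deer(params) * F_

  # surplus seedlings first: one bite each at seedling size
  tree_sp <- which(!wd$is_broom & !is.na(wd$A_biom_const))
  surplus_biom <- numeric(grid$n_cells)
  sur_bite <- vapply(tree_sp, function(s)
    twig_biomass(pmin(params$bite_length, wd$H_ini[s]), wd[s, ]), 0)
  if (length(tree_sp))
    surplus_biom <- as.numeric(grid$surplus[, tree_sp, drop = FALSE] %*%
                                 sur_bite)
  consumed_surplus <- pmin(surplus_biom, demand)
  remaining <- demand - consumed_surplus

  ag <- grid$agents
  consumed_agents <- numeric(grid$n_cells)
  kill <- integer()
  if (nrow(ag)) {
    cand <- which(!wd$is_broom[ag$sp] & !is.na(wd$browse_rank[ag$sp]) &
                    ag$H <= params$max_forage_height &
                    remaining[ag$cell] > 0)
    if (length(cand)) {
      aB <- numeric(length(cand))
      for (s in unique(ag$sp[cand])) {
        sel <- ag$sp[cand] == s
        aB[sel] <- available_browse(ag$H[cand][sel], wd[s, ], params,
                                    fn = browse_fn)
      }
      ord <- order(ag$cell[cand], wd$browse_rank[ag$sp[cand]],
                   ag$H[cand], ag$age[cand])
      cand <- cand[ord]; aB <- aB[ord]
      cells <- ag$cell[cand]
      # per-cell sequential consumption via cumulative supply
      cum <- stats::ave(aB, cells, FUN = cumsum)
      before <- cum - aB
      take <- pmin(aB, pmax(0, remaining[cells] - before))
      eaten <- take > 0
      ag$browsed[cand[eaten]] <- TRUE
      tot <- rowsum(take, cells)
      consumed_agents[as.integer(rownames(tot))] <- tot
      kill <- cand[eaten & ag$H[cand] < params$instant_death_height]
    }
  }
  deaths <- integer(grid$n_cells)
  if (length(kill)) {
    dk <- table(ag$cell[kill])
    deaths[as.integer(names(dk))] <- as.integer(dk)
    ag <- ag[-kill, , drop = FALSE]
  }
  grid$agents <- ag
  act <- which(demand > 0)
  ledger <- data.frame(cell = act, demand = demand[act],
                       consumed_surplus = consumed_surplus[act],
                       consumed_agents = consumed_agents[act],
                       deaths_immediate = deaths[act])
  list(grid = grid, ledger = ledger)
}

#' End-of-year browsing mortality
#'
#' Individuals browsed during the year whose leader shoot was in reach
#' (height at or below `max_browse_height`) die with their species'
#' browsing-induced mortality probability. All browsed flags are cleared
#' afterwards.
#' @param grid a `woods_grid`.
#' @param params a [browser_params()] object.
#' @return A list: `grid` and `removed` (agent rows that died).
#' @export
browse_mortality <- function(grid, params = browser_params()) {
  ag <- grid$agents
  removed <- empty_agents()
  if (nrow(ag)) {
    at_risk <- which(ag$browsed & ag$H <= params$max_browse_height &
                       !is.na(grid$woody$Brow_mort[ag$sp]))
    if (length(at_risk)) {
      p <- grid$woody$Brow_mort[ag$sp[at_risk]]
      dies <- at_risk[stats::runif(length(at_risk)) < p]
      removed <- ag[dies, , drop = FALSE]
      if (length(dies)) ag <- ag[-dies, , drop = FALSE]
    }
    ag$browsed <- FALSE
    grid$agents <- ag
  }
  list(grid = grid, removed = removed)
}

#' Wild-boar soil disturbance
#'
#' Once a year, boar plough a random share of the open-land cells: by
#' default 10\% of managed grassland (hay meadows and pastures), 3\% of
#' shrub cells and 1\% of fallow grassland, each an independent Bernoulli
#' draw per cell. In a disturbed cell 45\% of the herbaceous layer is
#' removed, which lowers the grass inhibition. Forest cells are never
#' disturbed.
#'
#' @param grid a `woods_grid`.
#' @param rates named disturbance probabilities per vegetation type.
#' @param removal herb-cover fraction removed in disturbed cells.
#' @return A list: `grid` (updated) and `disturbed` (cell indices).
#' @export
boar_disturb <- function(grid,
                         rates = c(grassland = 0.10, shrub = 0.03,
                                   fallow_grassland = 0.01,
                                   disturbed_ground = 0, forest = 0),
                         removal = 0.45) {
  p <- rates[grid$veg]
  p[is.na(p)] <- 0
  p[grid$veg == "forest"] <- 0
  hit <- which(stats::runif(grid$n_cells) < p)
  if (length(hit)) grid <- remove_herb_cover(grid, hit, removal)
  list(grid = grid, disturbed = hit)
}
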