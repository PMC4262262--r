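#' Update crown diameter and cover from height
#'
#' Crown diameter is an allometric power law of height,
#' `D = A_cd_const * H^A_cd_coeff`, and cover is the crown circle,
#' `C = pi * (D/2)^2`, capped at the cell area: a crown cannot claim more
#' space than its cell holds, so a single dominant tree saturates its cell
#' rather than exceeding it.
#'
#' @param agents agent data.frame (columns `sp`, `H`, ...).
#' @param woody woody species parameter table.
#' @param A_cell cell area (m2), the cover cap.
#' @return The agents with `D` and `C` updated.
#' @export
update_allometry <- function(agents, woody, A_cell = 100) {
  if (!nrow(agents)) return(agents)
  agents$D <- woody$A_cd_const[agents$sp] *
    agents$H^woody$A_cd_coeff[agents$sp]
  agents$C <- pmin(pi * (agents$D / 2)^2, A_cell)
  agents
}

#' Annual height growth of all agents
#'
#' Growth follows the yearly integral of the Bertalanffy law
#' `dH/dt = g (H_max - H)`: each individual draws its growth rate
#' `g ~ Normal(G_mean, G_sd)` (truncated at zero) anew every year and grows
#' by `dH = (H_max - H)(1 - exp(-g))`. Individuals browsed this year whose
#' leader shoot is still within reach of red deer (height at or below
#' `browse_height`) do not grow. All agents age by one year.
#'
#' @param grid a `woods_grid`.
#' @param browse_height maximum browsing height (m); growth of browsed
#'   individuals at or below it is set to zero.
#' @return The updated grid (heights, ages, allometry).
#' @export
annual_growth <- function(grid, browse_height = 1.7) {
  ag <- grid$agents
  if (nrow(ag)) {
    wd <- grid$woody
    g <- pmax(0, stats::rnorm(nrow(ag), wd$G_mean[ag$sp], wd$G_sd[ag$sp]))
    dH <- (wd$H_max[ag$sp] - ag$H) * (1 - exp(-g))
    dH[ag$browsed & ag$H <= browse_height] <- 0
    ag$H <- ag$H + dH
    ag$age <- ag$age + 1
    grid$agents <- update_allometry(ag, wd, grid$A)
  }
  grid
}

#' Available space for a woody guild
#'
#' Trees compete only with trees: their available space is the cell area
#' minus all tree crown cover. Broom is inferior and additionally excluded
#' by the thorny shrubs: its available space is the cell area minus tree
#' cover, broom cover, and bramble/blackthorn cover. Both are floored at 0.
#'
#' @param grid a `woods_grid`.
#' @param guild `"tree"` or `"broom"`.
#' @return Numeric per-cell vector (m2).
#' @export
available_space <- function(grid, guild = c("tree", "broom")) {
  guild <- match.arg(guild)
  cov <- cover_summary(grid)
  if (guild == "tree") pmax(0, grid$A - cov$tree)
  else pmax(0, grid$A - cov$tree - cov$broom - cov$thorny)
}

# indices (into the agent table) to drop so the remaining covers fit:
# agents of one cell, ascending by (H, age); drop from the smallest until
# fixed_cover + sum(remaining) <= A
thin_one_cell <- function(idx, H, age, C, fixed, A) {
  ord <- idx[order(H[idx], age[idx])]
  tot <- fixed + sum(C[ord])
  drop <- integer()
  for (i in ord) {
    if (tot <= A + 1e-9) break
    tot <- tot - C[i]
    drop <- c(drop, i)
  }
  drop
}

#' Self-thinning by crown-area competition
#'
#' Space is the single contested resource. After growth, if the summed crown
#' areas in a cell exceed the cell area the smallest individual dies, one at
#' a time, until the covers fit. Broom is thinned first and against the
#' widest set of competitors (trees, conspecifics, bramble, blackthorn);
#' trees are then thinned against trees only. Ties on height remove the
#' younger individual.
#'
#' @param grid a `woods_grid`.
#' @return A list: `grid` (updated) and `removed` (the removed agent rows).
#' @export
self_thinning <- function(grid) {
  ag <- grid$agents
  if (!nrow(ag)) return(list(grid = grid, removed = empty_agents()))
  is_b <- grid$woody$is_broom[ag$sp]
  cov <- cover_summary(grid)
  drop <- integer()

  # broom pass: broom + trees + thorny shrubs must fit
  crowd <- cov$broom + cov$tree + cov$thorny
  for (cl in which(crowd > grid$A + 1e-9)) {
    idx <- which(ag$cell == cl & is_b)
    if (!length(idx)) next
    fixed <- cov$tree[cl] + cov$thorny[cl]
    drop <- c(drop, thin_one_cell(idx, ag$H, ag$age, ag$C, fixed, grid$A))
  }
  # tree pass: trees must fit among themselves
  for (cl in which(cov$tree > grid$A + 1e-9)) {
    idx <- which(ag$cell == cl & !is_b)
    drop <- c(drop, thin_one_cell(idx, ag$H, ag$age, ag$C, 0, grid$A))
  }
  removed <- ag[drop, , drop = FALSE]
  if (length(drop)) grid$agents <- ag[-drop, , drop = FALSE]
  list(grid = grid, removed = removed)
}

#' Senescence
#'
#' An individual dies when it reaches its individual maximum age, drawn at
#' germination uniformly within +/-10\% of the species maximum.
#' @param grid a `woods_grid`.
#' @return A list: `grid` (updated) and `removed` (agent rows that died).
#' @export
senescence <- function(grid) {
  ag <- grid$agents
  dead <- which(ag$age >= ag$age_max)
  removed <- ag[dead, , drop = FALSE]
  if (length(dead)) grid$agents <- ag[-dead, , drop = FALSE]
  list(grid = grid, removed = removed)
}

#' Mowing mortality
#'
#' In mown cells, individuals with heights in the closed interval
#' \[0.1 m, 1 m\] die (seedlings below the cutter bar and established trees
#' above it survive).
#' @param grid a `woods_grid`.
#' @return A list: `grid` (updated) and `removed` (agent rows killed).
#' @export
mow_kill <- function(grid) {
  ag <- grid$agents
  kill <- which(grid$mown[ag$cell] & ag$H >= 0.1 & ag$H <= 1)
  removed <- ag[kill, , drop = FALSE]
  if (length(kill)) grid$agents <- ag[-kill, , drop = FALSE]
  list(grid = grid, removed = removed)
}

#' Deterministic Bertalanffy height trajectory
#'
#' Closed form of the annual growth model with a fixed rate:
#' `H(t) = H_max - (H_max - H0) * exp(-G t)`.
#' @param t age in years (vectorized).
#' @param G growth rate (1/a).
#' @param H_max maximal height (m).
#' @param H0 initial height (m).
#' @return Heights (m).
#' @export
bertalanffy_height <- function(t, G, H_max, H0 = 0.05) {
  H_max - (H_max - H0) * exp(-G * t)
}
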