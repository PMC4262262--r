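#' One increment of herb-layer dynamics
#'
#' A deliberately minimal, cover-based stand-in for a full grassland
#' community model: it only has to (i) supply grass covers to the
#' grass-inhibition term, (ii) supply bramble/blackthorn covers to the nurse
#' factor and to broom space competition, and (iii) move on the decades
#' timescale typical of fallow succession. Per species and day,
#' potential growth is `g_max * c * free / F_S` where `free` is the space a
#' species can still claim: thorny shrubs (bramble, blackthorn) may displace
#' grasses and are limited only by woody crown cover, grasses and herbs only
#' grow into space free of everything. Management (cutting/grazing/trampling
#' intensities crossed with the utilization values U_C/U_G/U_T) suppresses
#' growth and removes cover of intolerant species. A fraction of the growth
#' that a saturated cell cannot realize spills to its four neighbours
#' (vegetative spread).
#'
#' @param grid a `woods_grid`.
#' @param dt_days time step length in days.
#' @param woody_cover optional precomputed per-cell woody (tree + broom
#'   agent) cover; pass it when looping over many increments within a year.
#' @param gmax_unit interpretation of the `g_max` column: `"per_year"`
#'   (default; the rate is spread over daily increments) or `"per_day"`.
#' @param spill_frac fraction of unrealizable growth that spills to the four
#'   orthogonal neighbours.
#' @param suppression scale of the management loss term (1/a at full
#'   intensity for a fully intolerant species).
#' @return The updated grid.
#' @export
herb_step <- function(grid, dt_days = 1, woody_cover = NULL,
                      gmax_unit = c("per_year", "per_day"),
                      spill_frac = 0.1, suppression = 1) {
  gmax_unit <- match.arg(gmax_unit)
  if (any(grid$herb < 0)) stop("negative herb cover: contract violation")
  hp <- grid$herbsp
  if (is.null(woody_cover)) {
    cov <- cover_summary(grid)
    woody_cover <- cov$tree + cov$broom
  }
  A <- grid$A
  herb <- grid$herb
  h_space <- pmax(0, A - woody_cover)          # space open to the herb layer
  thorny <- hp$is_thorny_shrub
  tot <- rowSums(herb)
  free_all <- pmax(0, h_space - tot)           # space free of everything

  g <- if (gmax_unit == "per_year") hp$g_max / 365 else hp$g_max
  rate <- herb * rep(g / hp$F_S, each = nrow(herb)) * dt_days
  pot <- rate * ifelse(rep(thorny, each = nrow(herb)), h_space, free_all)

  # management suppression: s in [0,1], scaled by tolerance (U = 9 immune)
  s <- outer(grid$I_C / 100, (9 - hp$U_C) / 8) +
       outer(grid$I_G / 100, (9 - hp$U_G) / 8) +
       outer(grid$I_T / 100, (9 - hp$U_T) / 8)
  s <- pmin(1, s)
  loss <- herb * s * suppression * dt_days / 365
  net <- pot * (1 - s) - loss
  prop <- pmax(herb + net, 0)    # args this way round: keep the dim attributes

  # enforce the space bound: grasses/herbs yield first, then thorny shrubs
  newtot <- rowSums(prop)
  over <- which(newtot > h_space + 1e-12)
  if (length(over)) {
    for (i in over) {
      th <- sum(prop[i, thorny])
      gr <- newtot[i] - th
      room <- max(0, h_space[i] - th)
      if (gr > room) prop[i, !thorny] <- prop[i, !thorny] *
          (if (gr > 0) room / gr else 0)
      if (th > h_space[i]) prop[i, thorny] <- prop[i, thorny] *
          (h_space[i] / th)
    }
  }

  # vegetative spill: unrealized positive growth leaks to the 4 neighbours
  if (spill_frac > 0) {
    unreal <- pmax((herb + pmax(net, 0)) - prop, 0)
    if (any(unreal > 0)) {
      spill <- unreal * spill_frac / 4
      nr <- grid$n_rows; nc <- grid$n_cols
      idx <- seq_len(grid$n_cells)
      col <- (idx - 1L) %% nc + 1L
      row <- (idx - 1L) %/% nc + 1L
      inc <- matrix(0, grid$n_cells, ncol(herb))
      for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        ok <- col + d[1] >= 1L & col + d[1] <= nc &
              row + d[2] >= 1L & row + d[2] <= nr
        tgt <- idx[ok] + d[1] + d[2] * nc
        inc[tgt, ] <- inc[tgt, ] + spill[ok, , drop = FALSE]
      }
      # receive only into genuinely free space
      room <- pmax(0, h_space - rowSums(prop))
      take <- pmin(1, ifelse(rowSums(inc) > 0, room / rowSums(inc), 0))
      prop <- prop + inc * take
    }
  }

  grid$herb <- prop
  grid
}

#' Run the daily herb-layer loop for one simulated year
#'
#' 365 increments of [herb_step()] with the woody cover held fixed (woody
#' processes are annual). No seasonality is imposed. Cells with an entirely
#' empty herb layer cost nothing: nothing can grow from zero cover.
#' @param grid a `woods_grid`.
#' @param ... passed to [herb_step()].
#' @return The updated grid.
#' @export
herb_year <- function(grid, ...) {
  if (all(grid$herb == 0)) return(grid)
  cov <- cover_summary(grid)
  wc <- cov$tree + cov$broom
  for (d in seq_len(365)) grid <- herb_step(grid, 1, woody_cover = wc, ...)
  grid
}

#' Remove a fraction of the herbaceous layer in given cells
#'
#' Every herb species' cover is scaled by `1 - fraction` (soil disturbance
#' by wild boar removes 45\%).
#' @param grid a `woods_grid`.
#' @param cells integer cell indices.
#' @param fraction fraction removed, in \[0, 1\].
#' @return The updated grid.
#' @export
remove_herb_cover <- function(grid, cells, fraction) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  grid$herb[cells, ] <- grid$herb[cells, , drop = FALSE] * (1 - fraction)
  grid
}

#' Reclaim space for the woody layer
#'
#' Space covered by trees and bushes is not available to grasses: after
#' woody growth, cells whose total herb cover exceeds the remaining
#' herbaceous space have all herb covers scaled down proportionally to
#' exactly fit.
#' @param grid a `woods_grid`.
#' @return The updated grid.
#' @export
reclaim_space <- function(grid) {
  cov <- cover_summary(grid)
  h_space <- pmax(0, grid$A - cov$tree - cov$broom)
  tot <- rowSums(grid$herb)
  over <- which(tot > h_space)
  if (length(over)) {
    f <- ifelse(tot[over] > 0, h_space[over] / tot[over], 0)
    grid$herb[over, ] <- grid$herb[over, , drop = FALSE] * f
  }
  grid
}
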