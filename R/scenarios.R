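#' Add a woody individual of a given age to a cell
#'
#' Height is taken from the deterministic growth curve at that age; the
#' individual maximum age is drawn within +/-10\% of the species maximum
#' (but at least the current age, so imported individuals do not die on
#' arrival).
#' @param grid a `woods_grid`.
#' @param species species name.
#' @param cell cell index.
#' @param age age in years.
#' @return The updated grid.
#' @export
add_agent <- function(grid, species, cell, age = 0) {
  s <- match(species, grid$woody$name)
  if (is.na(s)) stop("unknown species: ", species)
  wd <- grid$woody
  H <- bertalanffy_height(age, wd$G_mean[s], wd$H_max[s], wd$H_ini[s])
  amax <- max(age + 1, stats::runif(1, 0.9, 1.1) * wd$A_max[s])
  new <- data.frame(cell = as.integer(cell), sp = s, H = H, age = age,
                    age_max = amax, D = 0, C = 0, browsed = FALSE)
  grid$agents <- rbind(grid$agents, update_allometry(new, wd, grid$A))
  grid
}

#' Single-parent encroachment scenario
#'
#' The canonical 1-ha experiment: a 10 x 10 grid of 100 m2 cells, one
#' mature parent individual (age = age of maturity, height from the
#' deterministic growth curve), no management, no boar. With
#' `inhibition = "off"` the herb layer is bare and the inhibition term
#' disabled; with `"on"` every cell carries a tall-grass fallow sward near
#' saturation. Browsing is active only when `deer_density > 0`.
#'
#' @param species parent species name.
#' @param inhibition `"off"` or `"on"`.
#' @param deer_density red deer per 100 ha.
#' @param years simulated years.
#' @param n_cols,n_rows grid size.
#' @param position `"center"` or `"corner"` placement of the parent.
#' @param grass_frac initial tall-grass cover fraction when inhibition is on.
#' @param rng_seed seed stored in the config.
#' @param ... further arguments to [woods_config()].
#' @return A list: `config` (a [woods_config()]) and `grid` (one realized
#'   initial landscape; [run_simulation()] rebuilds its own from
#'   `config$init` under the run seed).
#' @export
make_single_parent_scenario <- function(species,
                                        inhibition = c("off", "on"),
                                        deer_density = 0, years = 25,
                                        n_cols = 10, n_rows = 10,
                                        position = c("center", "corner"),
                                        grass_frac = 0.9,
                                        rng_seed = 1L, ...) {
  inhibition <- match.arg(inhibition)
  position <- match.arg(position)
  woody <- woody_species_defaults()
  if (!species %in% woody$name) stop("unknown species: ", species)
  herbsp <- herb_species_defaults()
  cell <- if (position == "center")
    (ceiling(n_rows / 2) - 1L) * n_cols + ceiling(n_cols / 2)
  else 1L
  init <- function() {
    g <- woods_grid(n_cols, n_rows, 10, woody = woody, herbsp = herbsp)
    if (inhibition == "on")
      g$herb[, "tall_grass"] <- grass_frac * g$A
    g <- add_agent(g, species, cell, age = woody$A_mat[match(species,
                                                             woody$name)])
    g$veg <- classify_vegetation(g)
    g
  }
  config <- woods_config(n_cols = n_cols, n_rows = n_rows, years = years,
                         deer_density = deer_density,
                         woody = woody, herbsp = herbsp, init = init,
                         inhibition = inhibition == "on",
                         browsing = deer_density > 0, boar = FALSE,
                         herb_dynamics = inhibition == "on",
                         rng_seed = rng_seed, ...)
  list(config = config, grid = init())
}

round_half_up <- function(x) floor(x + 0.5)

#' Initialize a landscape from a region raster and attribute table
#'
#' Reproduces the clumping rules used when importing a vegetation map:
#' within each region, scattered young trees are clumped -- for each tree
#' age class, a share of cells equal to the mapped percentage cover is
#' picked at random and filled completely with trees of that age (up to 35
#' individuals), the rest stay empty. Bushes rarely fill whole cells, so
#' for each bush entry a share of cells equal to four times the mapped
#' percentage is assigned 25\% bush cover (broom as aged individuals,
#' bramble/blackthorn as herb-layer cover). Cells whose resulting tree
#' cover is at least 50\% classify as forest.
#'
#' @param region integer matrix of region labels (`n_rows` x `n_cols`, row
#'   1 = top), or the list returned by [read_esri_ascii()].
#' @param attrs data.frame with one row per region: `region`; optional
#'   `mown`, `grazed` (logical); `grass_frac` (initial tall-grass cover
#'   fraction); `tree_species`; `tree_pct_1`, `tree_pct_5` (percent cover
#'   of 1- and 5-year trees); `broom_pct_2`, `broom_pct_7`, `broom_pct_10`;
#'   `bramble_pct`, `blackthorn_pct`.
#' @param woody,herbsp species parameter tables.
#' @param cellsize cell edge length (m).
#' @return A `woods_grid`.
#' @export
init_from_rasters <- function(region, attrs,
                              woody = woody_species_defaults(),
                              herbsp = herb_species_defaults(),
                              cellsize = 10) {
  if (is.list(region) && !is.null(region$values)) {
    cellsize <- region$cellsize
    region <- region$values
  }
  pct_cols <- grep("_pct(_\\d+)?$", names(attrs), value = TRUE)
  for (cc in pct_cols)
    if (any(attrs[[cc]] < 0 | attrs[[cc]] > 100, na.rm = TRUE))
      stop("attribute percentages must lie in [0, 100]: ", cc)
  nr <- nrow(region); nc <- ncol(region)
  g <- woods_grid(nc, nr, cellsize, woody = woody, herbsp = herbsp)
  reg_cell <- as.integer(t(region))   # row-major cell order
  att <- function(row, name, default) {
    if (!name %in% names(attrs) || is.na(attrs[[name]][row])) default
    else attrs[[name]][row]
  }
  fill_woody <- function(g, sp_name, cells, age, target_cover) {
    s <- match(sp_name, g$woody$name)
    H <- bertalanffy_height(age, g$woody$G_mean[s], g$woody$H_max[s],
                            g$woody$H_ini[s])
    D <- g$woody$A_cd_const[s] * H^g$woody$A_cd_coeff[s]
    C1 <- min(pi * (D / 2)^2, g$A)
    n_per <- min(35, max(1, ceiling(target_cover / C1)))
    for (cl in cells)
      for (k in seq_len(n_per)) g <- add_agent(g, sp_name, cl, age)
    g
  }
  for (r in seq_len(nrow(attrs))) {
    cells <- which(reg_cell == attrs$region[r])
    if (!length(cells)) next
    g$mown[cells] <- isTRUE(att(r, "mown", FALSE))
    g$grazed[cells] <- isTRUE(att(r, "grazed", FALSE))
    g$I_C[cells] <- if (g$mown[cells][1]) 100 else 0
    g$I_G[cells] <- if (g$grazed[cells][1]) 100 else 0
    gf <- att(r, "grass_frac", 0)
    if (gf > 0) g$herb[cells, "tall_grass"] <- gf * g$A
    avail <- cells
    tsp <- att(r, "tree_species", "birch")
    for (age in c(1, 5)) {
      p <- att(r, paste0("tree_pct_", age), 0) / 100
      n_sel <- min(length(avail), round_half_up(p * length(cells)))
      if (n_sel > 0) {
        sel <- sample(avail, n_sel)
        avail <- setdiff(avail, sel)
        g <- fill_woody(g, tsp, sel, age, g$A)
      }
    }
    for (age in c(2, 7, 10)) {
      p <- att(r, paste0("broom_pct_", age), 0) / 100
      n_sel <- min(length(avail), round_half_up(4 * p * length(cells)))
      if (n_sel > 0) {
        sel <- sample(avail, n_sel)
        avail <- setdiff(avail, sel)
        g <- fill_woody(g, "broom", sel, age, 0.25 * g$A)
      }
    }
    for (shrub in c("bramble", "blackthorn")) {
      p <- att(r, paste0(shrub, "_pct"), 0) / 100
      n_sel <- min(length(cells), round_half_up(4 * p * length(cells)))
      if (n_sel > 0) {
        sel <- sample(cells, n_sel)
        g$herb[sel, shrub] <- g$herb[sel, shrub] + 0.25 * g$A
      }
    }
  }
  g <- reclaim_space(g)
  g$veg <- classify_vegetation(g)
  g
}

#' Encroachment summary statistics of a run
#'
#' Extracts, for one species, the cover trajectory as a percentage of the
#' simulated area, the first year the area counts as fully covered, and
#' the maximum cover with the year it is attained.
#' @param sim a `woods_sim`.
#' @param species species name.
#' @param full_frac cover fraction of the whole area that counts as full
#'   cover (self-thinning keeps saturated cells marginally below the cell
#'   area, so 1.0 is never reached exactly).
#' @return A list: `trajectory` (data.frame `year`, `pct`), `year_full`
#'   (`NA` if never), `max_pct`, `year_max`.
#' @export
encroachment_stats <- function(sim, species, full_frac = 0.99) {
  area <- sim$grid$n_cells * sim$grid$A
  tr <- sim$species[sim$species$species == species, c("year", "cover_m2")]
  tr$pct <- 100 * tr$cover_m2 / area
  full <- tr$year[tr$pct >= 100 * full_frac]
  list(trajectory = tr[c("year", "pct")],
       year_full = if (length(full)) min(full) else NA_integer_,
       max_pct = max(tr$pct), year_max = tr$year[which.max(tr$pct)])
}
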