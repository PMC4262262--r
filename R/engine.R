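#' Scenario configuration
#'
#' Bundles everything one run needs: grid geometry, duration, management,
#' deer density, species tables, process toggles, numerical settings and the
#' RNG seed. `init` is a zero-argument function building the initial
#' landscape; it is called (after seeding the RNG) by [run_simulation()], so
#' stochastic initialization is reproducible.
#'
#' @param n_cols,n_rows,cellsize grid geometry.
#' @param years simulated years (>= 1).
#' @param deer_density red deer per 100 ha (>= 0).
#' @param woody,herbsp species parameter tables.
#' @param browser a [browser_params()] object; its density is overridden by
#'   `deer_density`.
#' @param init function() -> `woods_grid`; default: empty fallow grid.
#' @param inhibition,browsing,boar,herb_dynamics process toggles.
#' @param tree_cap,broom_cap per-cell annual recruitment caps.
#' @param mast_probs mast category probabilities (see [mast_fraction()]).
#' @param gmax_unit,spill_frac,suppression herb-layer settings
#'   (see [herb_step()]).
#' @param boar_rates per-vegetation-type disturbance probabilities.
#' @param browse_fn optional available-browse replacement.
#' @param rng_seed integer seed, or `NULL` to leave the RNG alone.
#' @param out_dir optional output directory for annual rasters/CSV.
#' @param out_every write outputs every so many years.
#' @return A list of class `woods_config`.
#' @export
woods_config <- function(n_cols = 10, n_rows = 10, cellsize = 10,
                         years = 25, deer_density = 0,
                         woody = woody_species_defaults(),
                         herbsp = herb_species_defaults(),
                         browser = browser_params(density = deer_density),
                         init = NULL,
                         inhibition = TRUE, browsing = TRUE, boar = TRUE,
                         herb_dynamics = TRUE,
                         tree_cap = 35, broom_cap = 35,
                         mast_probs = rep(0.25, 4),
                         gmax_unit = "per_year", spill_frac = 0.1,
                         suppression = 1,
                         boar_rates = c(grassland = 0.10, shrub = 0.03,
                                        fallow_grassland = 0.01,
                                        disturbed_ground = 0, forest = 0),
                         browse_fn = NULL,
                         rng_seed = 1L, out_dir = NULL, out_every = 1) {
  stopifnot(years >= 1, deer_density >= 0)
  browser$density <- deer_density
  if (is.null(init)) {
    force(n_cols); force(n_rows); force(cellsize)
    force(woody); force(herbsp)
    init <- function() woods_grid(n_cols, n_rows, cellsize,
                                  woody = woody, herbsp = herbsp)
  }
  structure(list(n_cols = n_cols, n_rows = n_rows, cellsize = cellsize,
                 years = years, deer_density = deer_density,
                 woody = woody, herbsp = herbsp, browser = browser,
                 init = init, inhibition = inhibition, browsing = browsing,
                 boar = boar, herb_dynamics = herb_dynamics,
                 tree_cap = tree_cap, broom_cap = broom_cap,
                 mast_probs = mast_probs, gmax_unit = gmax_unit,
                 spill_frac = spill_frac, suppression = suppression,
                 boar_rates = boar_rates, browse_fn = browse_fn,
                 rng_seed = rng_seed, out_dir = out_dir,
                 out_every = out_every),
            class = "woods_config")
}

#' @export
print.woods_config <- function(x, ...) {
  cat(sprintf(paste0(
    "woods_config: %d x %d cells, %d years, %g deer/100 ha\n",
    "  toggles: inhibition %s, browsing %s, boar %s, herb dynamics %s\n",
    "  seed %s\n"),
    x$n_cols, x$n_rows, x$years, x$deer_density,
    x$inhibition, x$browsing, x$boar, x$herb_dynamics,
    if (is.null(x$rng_seed)) "none" else x$rng_seed))
  invisible(x)
}

# per-species kernels, built once per run
build_kernels <- function(woody, cellsize) {
  k <- lapply(seq_len(nrow(woody)), function(i)
    build_kernel(woody[i, ], cellsize))
  names(k) <- woody$name
  k
}

#' Advance the landscape by one year
#'
#' Executes the annual cycle in a fixed, documented order:
#' \enumerate{
#'   \item wild-boar disturbance;
#'   \item daily herb-layer loop (365 increments, management included);
#'   \item seed production by mature individuals (one mast draw per
#'     species and year) and dispersal;
#'   \item seed-bank input filtered by predator loss and grass inhibition;
#'   \item exponential seed-bank decay;
#'   \item germination under space limitation with recruitment caps and
#'     surplus bookkeeping;
#'   \item red-deer browsing budget per cell (flags, instant deaths);
#'   \item height growth (zeroed for browsed saplings) and allometry;
#'   \item mowing mortality;
#'   \item self-thinning (broom pass, then tree pass);
#'   \item end-of-year browsing mortality, then senescence;
#'   \item herb space reclamation and vegetation re-classification.
#' }
#' Browsing precedes growth so that a browsed sapling loses the year's
#' height increment.
#'
#' @param grid a `woods_grid`.
#' @param config a [woods_config()].
#' @param kernels optional precomputed kernel list (else built on the fly).
#' @return The updated grid; the year's browsing ledger and disturbed cells
#'   are attached as attributes `ledger` and `disturbed`.
#' @export
run_year <- function(grid, config = woods_config(), kernels = NULL) {
  wd <- grid$woody
  if (is.null(kernels)) kernels <- build_kernels(wd, grid$cellsize)
  disturbed <- integer()

  if (config$boar) {
    bd <- boar_disturb(grid, config$boar_rates)
    grid <- bd$grid; disturbed <- bd$disturbed
  }
  if (config$herb_dynamics)
    grid <- herb_year(grid, gmax_unit = config$gmax_unit,
                      spill_frac = config$spill_frac,
                      suppression = config$suppression)

  # seed production and dispersal (mast drawn for every species, every year)
  mast <- mast_fraction(nrow(wd), config$mast_probs)
  incoming <- matrix(0, grid$n_cells, nrow(wd))
  ag <- grid$agents
  elig <- if (any(wd$zoochory_gated)) zoochory_eligible(grid) else NULL
  for (s in seq_len(nrow(wd))) {
    if (mast[s] <= 0 || !nrow(ag)) next
    mature <- ag$sp == s & ag$age >= wd$A_mat[s]
    if (!any(mature)) next
    per_cell <- rowsum(rep(wd$Seed_max[s] * mast[s], sum(mature)),
                       ag$cell[mature])
    src <- as.integer(rownames(per_cell))
    for (i in seq_along(src))
      incoming[, s] <- incoming[, s] +
        disperse(grid, src[i], per_cell[i], kernels[[s]], eligible = elig)
  }

  # seed-bank input, decay, germination
  for (s in seq_len(nrow(wd))) {
    col <- incoming[, s]
    if (all(col == 0)) next
    T_ <- if (config$inhibition) grass_inhibition(grid, s) else 0
    grid$bank[, s] <- grid$bank[, s] +
      seedbank_input(col, wd$P_loss[s], T_)
  }
  grid <- seedbank_decay(grid)
  grid <- germinate(grid, config$tree_cap, config$broom_cap)

  ledger <- NULL
  if (config$browsing && config$deer_density > 0) {
    br <- browse_year(grid, config$browser, config$browse_fn)
    grid <- br$grid; ledger <- br$ledger
  }
  grid <- annual_growth(grid, config$browser$max_browse_height)
  grid <- mow_kill(grid)$grid
  grid <- self_thinning(grid)$grid
  if (config$browsing && config$deer_density > 0)
    grid <- browse_mortality(grid, config$browser)$grid
  grid <- senescence(grid)$grid
  grid$surplus[] <- 0
  grid <- reclaim_space(grid)
  grid$veg <- classify_vegetation(grid)
  grid$year <- grid$year + 1L

  attr(grid, "ledger") <- ledger
  attr(grid, "disturbed") <- disturbed
  grid
}

#' Observe the landscape state
#'
#' One summary row per woody and herb species (total cover over the whole
#' area, agent counts) plus vegetation-type cell counts. Optionally writes
#' the annual vegetation-type raster and appends the per-species series to
#' CSV in `out_dir`.
#'
#' @param grid a `woods_grid`.
#' @param year simulation year of the snapshot.
#' @param out_dir optional output directory.
#' @return A list: `species` (data.frame `year`, `species`, `cover_m2`,
#'   `agents`) and `veg` (data.frame `year`, `veg_type`, `cells`).
#' @export
observe <- function(grid, year = grid$year, out_dir = NULL) {
  wd <- grid$woody
  cover <- numeric(nrow(wd)); count <- integer(nrow(wd))
  if (nrow(grid$agents)) {
    cs <- rowsum(grid$agents$C, grid$agents$sp)
    cover[as.integer(rownames(cs))] <- cs
    count <- tabulate(grid$agents$sp, nrow(wd))
  }
  species <- data.frame(
    year = year,
    species = c(wd$name, grid$herbsp$name),
    cover_m2 = c(cover, colSums(grid$herb)),
    agents = c(count, rep(NA_integer_, nrow(grid$herbsp))))
  veg_levels <- c("grassland", "fallow_grassland", "shrub", "forest",
                  "disturbed_ground")
  veg <- data.frame(
    year = year, veg_type = veg_levels,
    cells = as.integer(table(factor(grid$veg, veg_levels))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    code <- match(grid$veg, veg_levels)
    write_esri_ascii(as_raster(grid, code),
                     file.path(out_dir, sprintf("veg_%04d.asc", year)),
                     cellsize = grid$cellsize)
    f <- file.path(out_dir, "species_series.csv")
    utils::write.table(species, f, sep = ",", row.names = FALSE,
                       col.names = !file.exists(f), append = file.exists(f))
  }
  list(species = species, veg = veg)
}

#' Run a full simulation
#'
#' Seeds the RNG, builds (or accepts) the initial landscape, iterates
#' [run_year()] and collects annual observations.
#'
#' @param config a [woods_config()].
#' @param grid optional pre-built initial `woods_grid`; default
#'   `config$init()`.
#' @param seed RNG seed; default `config$rng_seed`.
#' @return An object of class `woods_sim`: list with `config`, `grid`
#'   (final state), `species` (long data.frame of annual per-species total
#'   cover and agent counts, year 0 = initial state), `veg` (annual
#'   vegetation-type cell counts) and `ledger` (annual browsing totals).
#' @export
run_simulation <- function(config = woods_config(), grid = NULL,
                           seed = config$rng_seed) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid)) grid <- config$init()
  kernels <- build_kernels(grid$woody, grid$cellsize)
  obs0 <- observe(grid, 0, config$out_dir)
  species <- list(obs0$species); veg <- list(obs0$veg)
  ledger <- list()
  for (y in seq_len(config$years)) {
    grid <- run_year(grid, config, kernels)
    led <- attr(grid, "ledger")
    if (!is.null(led) && nrow(led))
      ledger[[length(ledger) + 1]] <- data.frame(
        year = y, demand = sum(led$demand),
        consumed = sum(led$consumed_surplus + led$consumed_agents),
        deaths_immediate = sum(led$deaths_immediate))
    if (y %% config$out_every == 0 || y == config$years) {
      ob <- observe(grid, y, config$out_dir)
      species[[length(species) + 1]] <- ob$species
      veg[[length(veg) + 1]] <- ob$veg
    }
  }
  structure(list(config = config, grid = grid,
                 species = do.call(rbind, species),
                 veg = do.call(rbind, veg),
                 ledger = if (length(ledger)) do.call(rbind, ledger)
                          else NULL),
            class = "woods_sim")
}

#' @export
print.woods_sim <- function(x, ...) {
  yrs <- max(x$species$year)
  cat(sprintf("woods_sim: %d years on %d x %d cells (%g deer/100 ha)\n",
              yrs, x$config$n_cols, x$config$n_rows, x$config$deer_density))
  fin <- x$species[x$species$year == yrs & x$species$species %in%
                     x$grid$woody$name, ]
  area <- x$grid$n_cells * x$grid$A
  for (i in seq_len(nrow(fin)))
    cat(sprintf("  %-8s %8.1f m2 cover (%5.1f%%), %s agents\n",
                fin$species[i], fin$cover_m2[i],
                100 * fin$cover_m2[i] / area,
                ifelse(is.na(fin$agents[i]), "-", fin$agents[i])))
  vf <- x$veg[x$veg$year == yrs & x$veg$cells > 0, ]
  cat("  vegetation: ",
      paste(sprintf("%s %d", vf$veg_type, vf$cells), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.woods_sim <- function(object, ...) {
  x <- object
  area <- x$grid$n_cells * x$grid$A
  wide <- stats::reshape(
    x$species[x$species$species %in% x$grid$woody$name,
              c("year", "species", "cover_m2")],
    idvar = "year", timevar = "species", direction = "wide")
  names(wide) <- sub("^cover_m2\\.", "", names(wide))
  wide[-1] <- 100 * wide[-1] / area
  structure(list(cover_pct = wide, veg = x$veg, ledger = x$ledger),
            class = "summary.woods_sim")
}

#' @export
print.summary.woods_sim <- function(x, ...) {
  cat("Percent cover of the simulated area by year:\n")
  print(x$cover_pct, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot encroachment trajectories
#'
#' Total cover of each woody species as a percentage of the simulated area
#' over time.
#' @param x a `woods_sim`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.woods_sim <- function(x, ...) {
  s <- summary(x)$cover_pct
  graphics::matplot(s$year, as.matrix(s[-1]), type = "l", lty = 1, lwd = 2,
                    xlab = "year", ylab = "cover [% of area]", ...)
  graphics::legend("topleft", legend = names(s)[-1], lty = 1, lwd = 2,
                   col = seq_len(ncol(s) - 1), bty = "n")
  invisible(x)
}
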