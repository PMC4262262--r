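test_that("the standard deer is the herd's mean individual", {
  herd <- data.frame(count = c(5, 10, 20), mass_kg = c(105, 70, 42.5))
  expect_equal(standard_deer_weight(herd), 2075 / 35)     # 59.2857 kg
  expect_equal(standard_deer_weight(data.frame(count = 1, mass_kg = 100)),
               100)
  expect_equal(standard_deer_weight(data.frame(count = c(1, 1),
                                               mass_kg = c(0, 100))), 50)
  expect_error(standard_deer_weight(data.frame()), "empty")
})

test_that("annual demand reproduces the published budget", {
  p <- browser_params()
  expect_equal(annual_demand_per_deer(p), 157.46, tolerance = 0.005 / 157.46)
  # no woody diet -> no demand
  p0 <- browser_params(frw = 1e-12)
  expect_lt(annual_demand_per_deer(p0), 1e-6)
  # linear in the standard-deer mass
  p2 <- browser_params(herd = data.frame(count = 1,
                                         mass_kg = 2 * 2075 / 35))
  expect_equal(annual_demand_per_deer(p2), 2 * annual_demand_per_deer(p),
               tolerance = 1e-12)
  # per-cell demand at the status quo density of 22 deer / 100 ha
  expect_equal(22 * annual_demand_per_deer(p) * 100 / 1e6, 0.3464,
               tolerance = 1e-4)
})

test_that("nurse factor: blackthorn shields more than bramble", {
  p <- browser_params()
  expect_equal(nurse_factor(0, 0, p), 1)
  expect_lt(nurse_factor(50, 0, p), nurse_factor(0, 50, p))
  expect_lt(nurse_factor(1e4, 1e4, p), 1e-6)
  # monotone non-increasing in each cover
  f <- nurse_factor(seq(0, 100, 10), 0, p)
  expect_true(all(diff(f) <= 0))
  f2 <- nurse_factor(0, seq(0, 100, 10), p)
  expect_true(all(diff(f2) <= 0))
})

test_that("bite biomass follows the twig allometry", {
  wd <- woody_species_defaults()
  oak <- wd[wd$name == "oak", ]
  expect_equal(twig_biomass(0.1, oak), 0.8172 * 0.1^3.746)
  expect_equal(twig_biomass(0.1, oak), 1.466e-4, tolerance = 1e-3)
  expect_true(is.na(twig_biomass(0.1, wd[wd$name == "broom", ])))
})

test_that("available browse: only below 5 m, non-decreasing up to 1.7 m", {
  wd <- woody_species_defaults()
  birch <- wd[wd$name == "birch", ]
  p <- browser_params()
  expect_equal(available_browse(6, birch, p), 0)
  expect_equal(available_browse(5.5, birch, p), 0)
  h <- c(0.05, 0.2, 0.5, 1.0, 1.7)
  ab <- available_browse(h, birch, p)
  expect_true(all(ab > 0))
  expect_true(all(diff(ab) >= 0))
  # above the browse height the supply plateaus (same browsable stratum)
  expect_equal(available_browse(1.7, birch, p),
               available_browse(3, birch, p))
  # broom provides no browse
  expect_equal(available_browse(1, wd[wd$name == "broom", ], p), 0)
  # an injected supply function replaces the default
  expect_equal(available_browse(1, birch, p, fn = function(H, s, p) H * 2),
               2)
})

test_that("browsing follows preference order and respects the budget", {
  g <- bare_grid(1, 1)
  g <- plant_agents(g, 1, sp_idx(g, "spruce"), H = 1, age = 3)
  g <- plant_agents(g, 1, sp_idx(g, "oak"), H = 1, age = 3)
  g <- plant_agents(g, 1, sp_idx(g, "broom"), H = 1, age = 3)
  p <- browser_params(density = 0.2)   # demand below one oak's supply
  res <- browse_year(g, p)
  br <- res$grid$agents$browsed
  nm <- g$woody$name[res$grid$agents$sp]
  expect_true(br[nm == "oak"])
  expect_false(br[nm == "spruce"])     # budget exhausted before spruce
  expect_false(br[nm == "broom"])      # broom never browsed
  # ledger identity: consumed never exceeds demand
  expect_true(all(res$ledger$consumed_surplus + res$ledger$consumed_agents <=
                    res$ledger$demand + 1e-9))
  # zero density: nothing happens
  res0 <- browse_year(g, browser_params(density = 0))
  expect_equal(nrow(res0$ledger), 0)
  expect_false(any(res0$grid$agents$browsed))
})

test_that("browsed seedlings below 0.2 m die immediately", {
  g <- bare_grid(1, 1)
  g <- plant_agents(g, 1, sp_idx(g, "oak"), H = c(0.05, 0.5), age = 1)
  res <- browse_year(g, browser_params(density = 22))
  expect_equal(nrow(res$grid$agents), 1)
  expect_equal(res$grid$agents$H, 0.5)
  expect_true(res$grid$agents$browsed)
  expect_equal(res$ledger$deaths_immediate, 1)
})

test_that("surplus seedlings are eaten before standing trees", {
  g <- bare_grid(1, 1)
  g <- plant_agents(g, 1, sp_idx(g, "birch"), H = 0.5, age = 2)
  # enough surplus to saturate the cell demand entirely
  g$surplus[1, sp_idx(g, "birch")] <- 1e6
  res <- browse_year(g, browser_params(density = 22))
  expect_false(any(res$grid$agents$browsed))
  expect_equal(res$ledger$consumed_agents, 0)
  expect_equal(res$ledger$consumed_surplus, res$ledger$demand)
})

test_that("nurse shrubs reduce consumption, never increase it", {
  make <- function(blackthorn) {
    g <- bare_grid(1, 1)
    g <- plant_agents(g, 1, sp_idx(g, "birch"), H = 0.5, age = 2)
    g$herb[1, "blackthorn"] <- blackthorn
    browse_year(g, browser_params(density = 22))
  }
  no_shield <- make(0); shield <- make(60)
  expect_lt(shield$ledger$demand, no_shield$ledger$demand)
  expect_lte(shield$ledger$consumed_agents,
             no_shield$ledger$consumed_agents + 1e-12)
})

test_that("end-of-year browsing mortality hits flagged saplings in reach", {
  wd <- one_species_table(Brow_mort = 1)   # certain death when browsed
  g <- woods_grid(1, 1, woody = wd)
  g <- plant_agents(g, 1, 1, H = c(0.5, 1.9), age = 2)
  g$agents$browsed <- TRUE
  set.seed(2)
  res <- browse_mortality(g, browser_params())
  expect_equal(res$grid$agents$H, 1.9)   # out of reach: survives
  expect_equal(res$removed$H, 0.5)
  expect_false(any(res$grid$agents$browsed))  # flags cleared
})

test_that("boar disturbance hits types at their rates and spares forest", {
  set.seed(12)
  g <- bare_grid(100, 100, mown = TRUE)
  g$herb[, "fescue"] <- 40
  g$veg <- classify_vegetation(g)
  expect_true(all(g$veg == "grassland"))
  res <- boar_disturb(g)
  frac <- length(res$disturbed) / g$n_cells
  expect_equal(frac, 0.10, tolerance = 0.1)      # ~binomial around 10%
  # disturbed cells lost exactly 45% of their herb layer
  expect_equal(unname(res$grid$herb[res$disturbed[1], "fescue"]), 22)
  expect_equal(unname(res$grid$herb[setdiff(1:100, res$disturbed)[1],
                                    "fescue"]), 40)
  # forest cells are never disturbed
  gf <- bare_grid(20, 20)
  gf$veg <- rep("forest", gf$n_cells)
  expect_equal(length(boar_disturb(gf)$disturbed), 0)
  # fallow rate is far lower than meadow rate
  set.seed(12)
  gl <- bare_grid(100, 100)
  gl$herb[, "tall_grass"] <- 60
  gl$veg <- classify_vegetation(gl)
  res2 <- boar_disturb(gl)
  expect_lt(length(res2$disturbed) / gl$n_cells, 0.03)
})
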