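test_that("mast fractions respect the category ranges and probabilities", {
  set.seed(101)
  x <- mast_fraction(1e5)
  expect_true(all(x == 0 | (x >= 0.10 & x <= 1.00)))
  # category frequencies ~ 1/4 each under the default
  f <- c(mean(x == 0), mean(x > 0 & x < 0.40), mean(x >= 0.40 & x < 0.70),
         mean(x >= 0.70))
  expect_true(all(abs(f - 0.25) < 0.01))
  # a no-seed year returns exactly 0
  expect_true(any(x == 0))
  # custom probabilities shift the mix
  y <- mast_fraction(1e4, probs = c(1, 0, 0, 0))
  expect_true(all(y == 0))
})

test_that("kernels are normalized with the stated mass inside ED", {
  wd <- woody_species_defaults()
  for (i in seq_len(nrow(wd))) {
    k <- build_kernel(wd[i, ])
    expect_equal(sum(k$offsets$w), 1, tolerance = 1e-9)
    # numeric-integration oracle on the continuous law
    num <- stats::integrate(woodsim:::kernel_density, 0, wd$ED[i],
                            ED = wd$ED[i], MD = wd$MD[i], p_ED = wd$p_ED[i],
                            rel.tol = 1e-10)$value
    expect_equal(num, wd$p_ED[i], tolerance = 1e-6)
    expect_equal(k$mass_ED, wd$p_ED[i], tolerance = 0.025)
    # weight non-increasing with centroid distance
    o <- k$offsets[order(k$offsets$dist), ]
    expect_true(all(diff(o$w) <= 1e-12))
  }
  # oak: nothing beyond MD = 200 m
  k_oak <- build_kernel(wd, name = "oak")
  expect_true(all(k_oak$offsets$dist <= 200))
  expect_error(build_kernel(transform(wd[1, ], ED = 300, MD = 200)), "ED")
})

test_that("dispersal delivers kernel mass, gated beyond ED for zoochory", {
  g <- bare_grid(41, 41)
  center <- cell_index(g, 21, 21)
  k_birch <- build_kernel(g$woody, name = "birch")
  expect_equal(sum(disperse(g, center, 0, k_birch)), 0)

  # ungated species on a grid wider than MD: all seeds land somewhere
  g2 <- bare_grid(9, 9)
  k_broom <- build_kernel(g2$woody, name = "broom")
  # broom MD=500 exceeds the grid: mass is lost at the edge
  inc <- disperse(g2, cell_index(g2, 5, 5), 1000, k_broom)
  expect_lt(sum(inc), 1000)
  expect_gt(sum(inc), 1000 * 0.9)   # ballistic near-mass stays inside
  # oak MD = 200 fits inside a 41x41 grid from its center
  k_oak <- build_kernel(g$woody, name = "oak")
  g_oak <- plant_agents(g, center, sp_idx(g, "oak"), H = 10, C = 50)
  elig <- rep(TRUE, g$n_cells)
  inc_oak <- disperse(g_oak, center, 1000, k_oak, eligible = elig)
  expect_equal(sum(inc_oak), 1000, tolerance = 1e-6)

  # beech far mass into an empty neighbourhood is discarded entirely
  k_beech <- build_kernel(g$woody, name = "beech")
  g_beech <- plant_agents(g, center, sp_idx(g, "beech"), H = 10, C = 50)
  inc_b <- disperse(g_beech, center, 1000, k_beech)
  cr <- cell_colrow(g, seq_len(g$n_cells))
  far_cells <- which(centroid_distance(cr$col, cr$row, 21, 21) > 30)
  expect_equal(sum(inc_b[far_cells]), 0)
  # the only agent-holding cell is the source itself (distance 0)
  expect_equal(sum(inc_b), 1000 * k_beech$mass_ED, tolerance = 1e-6)
})

test_that("grass inhibition is a clamped sigmoid sum with management relief", {
  g <- bare_grid(2, 1)
  s_broom <- sp_idx(g, "broom")
  expect_equal(grass_inhibition(g, s_broom), c(0, 0))
  # single grass at I50 -> 0.5 in a fallow cell
  g$herb[1, "tall_grass"] <- g$woody$I50[s_broom]     # 26.1 m2
  expect_equal(grass_inhibition(g, s_broom)[1], 0.5)
  # same cover, mown -> exactly 30% lower
  g$mown[1] <- TRUE
  expect_equal(grass_inhibition(g, s_broom)[1], 0.35)
  # monotone non-decreasing in every grass cover; clamped at 1
  g2 <- bare_grid(1, 1)
  prev <- -1
  for (cv in seq(0, 100, by = 5)) {
    g2$herb[1, "tall_grass"] <- cv
    g2$herb[1, "fescue"] <- cv / 2
    T_ <- grass_inhibition(g2, s_broom)
    expect_gte(T_ + 1e-12, prev)
    expect_lte(T_, 1)
    prev <- T_
  }
})

test_that("seed-bank input applies predator loss then inhibition", {
  expect_equal(seedbank_input(1000, 0.8, 0), 200)
  expect_equal(seedbank_input(1000, 0.8, 0.5), 100)
  expect_equal(seedbank_input(12345, 0.8, 1), 0)
})

test_that("seed banks decay exponentially and never go negative", {
  g <- bare_grid(1, 1)
  g$bank[1, ] <- 1000
  g2 <- seedbank_decay(g)
  expect_equal(unname(g2$bank[1, "oak"]), 1000 * exp(-0.81))     # ~444.9
  expect_equal(unname(g2$bank[1, "broom"]), 1000 * exp(-0.063))  # ~938.9
  expect_true(all(g2$bank >= 0))
  # lambda = 0 leaves the bank unchanged
  wd <- woody_species_defaults(); wd$lambda[] <- 0
  g3 <- woods_grid(1, 1, woody = wd)
  g3$bank[1, ] <- 500
  expect_equal(seedbank_decay(g3)$bank, g3$bank)
  # with production off, one year strictly shrinks every positive entry
  expect_true(all(g2$bank < g$bank))
})

test_that("germination caps recruitment and books the surplus", {
  g <- bare_grid(1, 1)
  set.seed(5)
  s <- sp_idx(g, "spruce")               # Germ = 0.75
  g$bank[1, s] <- 100
  g2 <- germinate(g)
  expect_equal(nrow(g2$agents), 35)      # 75 candidates, cap 35
  expect_equal(unname(g2$surplus[1, s]), 40)
  expect_equal(unname(g2$bank[1, s]), 0)         # 75/0.75 = 100 seeds consumed
  expect_true(all(g2$agents$H == 0.05))
  expect_true(all(g2$agents$age == 0))
  expect_true(all(g2$agents$age_max >= 0.9 * 500 &
                    g2$agents$age_max <= 1.1 * 500))
  # empty bank -> no candidates
  expect_equal(nrow(germinate(bare_grid(1, 1))$agents), 0)
})

test_that("tree cap is shared by largest remainder; broom capped separately", {
  g <- bare_grid(1, 1)
  set.seed(6)
  g$bank[1, sp_idx(g, "spruce")] <- 40 / 0.75   # 40 candidates
  g$bank[1, sp_idx(g, "oak")] <- 40 / 0.75      # 40 candidates
  g$bank[1, sp_idx(g, "broom")] <- 50 / 0.8     # 50 candidates
  g2 <- germinate(g)
  n_by_sp <- table(g2$woody$name[g2$agents$sp])
  expect_equal(sum(n_by_sp[c("spruce", "oak")]), 35)
  expect_equal(as.integer(n_by_sp["spruce"]), 18)  # tie -> earlier species
  expect_equal(as.integer(n_by_sp["oak"]), 17)
  expect_equal(as.integer(n_by_sp["broom"]), 35)
  expect_equal(unname(g2$surplus[1, sp_idx(g, "broom")]), 15)
})

test_that("germination needs available space for the guild", {
  g <- bare_grid(1, 1)
  g <- plant_agents(g, 1, sp_idx(g, "birch"), H = 15, C = 100)
  g$bank[1, sp_idx(g, "oak")] <- 1000
  g$bank[1, sp_idx(g, "broom")] <- 1000
  g2 <- germinate(g)
  expect_equal(nrow(g2$agents), 1)       # nothing germinated
  expect_equal(unname(g2$bank[1, sp_idx(g, "oak")]), 1000)   # nothing consumed
  expect_equal(sum(g2$surplus), 0)
  # broom also blocked by thorny shrubs alone
  g3 <- bare_grid(1, 1)
  g3$herb[1, "bramble"] <- 60
  g3$herb[1, "blackthorn"] <- 40
  g3$bank[1, sp_idx(g3, "broom")] <- 1000
  g3$bank[1, sp_idx(g3, "oak")] <- 10
  set.seed(7)
  g4 <- germinate(g3)
  expect_true(all(g4$woody$name[g4$agents$sp] == "oak"))
})
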