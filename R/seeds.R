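#' Draw annual mast fractions
#'
#' Each year is one of four seed-production categories: a full mast year
#' (70--100\% of the species' maximum seed output), an intermediate year
#' (40--70\%), a poor year (10--40\%), or a year without seeds. The category
#' is drawn with the given probabilities (uniform by default) and the
#' fraction uniformly within the category's range.
#'
#' @param n number of draws.
#' @param probs category probabilities (no seeds, poor, intermediate, mast).
#' @return Numeric vector in `{0} U [0.1, 1]`.
#' @export
mast_fraction <- function(n = 1, probs = rep(0.25, 4)) {
  stopifnot(length(probs) == 4, all(probs >= 0), sum(probs) > 0)
  lo <- c(0, 0.10, 0.40, 0.70)
  hi <- c(0, 0.40, 0.70, 1.00)
  cat_ <- sample.int(4, n, replace = TRUE, prob = probs)
  stats::runif(n, lo[cat_], hi[cat_])
}

## ---- dispersal kernel ----------------------------------------------------

# Continuous double-exponential distance law: mass p_ED within [0, ED] as a
# truncated exponential (scale b1), mass 1 - p_ED within (ED, MD] as a
# shifted truncated exponential (scale b2). Scales are set so that each
# untruncated component would hold 95% of its own mass inside its segment.
kernel_scales <- function(ED, MD, p_ED) {
  b1 <- -ED / log(0.05)
  b2 <- if (MD > ED) -(MD - ED) / log(0.05) else NA_real_
  list(b1 = b1, b2 = b2)
}

kernel_density <- function(x, ED, MD, p_ED) {
  sc <- kernel_scales(ED, MD, p_ED)
  near <- ifelse(x >= 0 & x <= ED,
                 exp(-x / sc$b1) / (sc$b1 * (1 - exp(-ED / sc$b1))), 0)
  far <- if (MD > ED)
    ifelse(x > ED & x <= MD,
           exp(-(x - ED) / sc$b2) /
             (sc$b2 * (1 - exp(-(MD - ED) / sc$b2))), 0)
  else 0
  p_ED * near + (1 - p_ED) * far
}

kernel_cdf <- function(x, ED, MD, p_ED) {
  sc <- kernel_scales(ED, MD, p_ED)
  near <- pmin(1, pmax(0, (1 - exp(-pmin(x, ED) / sc$b1)) /
                            (1 - exp(-ED / sc$b1))))
  far <- if (MD > ED)
    pmin(1, pmax(0, (1 - exp(-pmax(0, pmin(x, MD) - ED) / sc$b2)) /
                      (1 - exp(-(MD - ED) / sc$b2))))
  else as.numeric(x >= ED)
  p_ED * near + (1 - p_ED) * far
}

#' Build the discretized seed dispersal kernel of a species
#'
#' Seeds follow a double-exponential distance law characterized by the
#' effective seeding distance ED (holding the fraction `p_ED` of all seeds)
#' and the maximum seeding distance MD (holding the rest; nothing disperses
#' farther). The continuous law is discretized onto grid-cell offsets: the
#' source cell receives the mass of the disc of one cell-radius around the
#' origin, every other offset the radial density at its centroid distance
#' converted to an areal density (divided by the annulus circumference) and
#' scaled by the cell area; weights are renormalized so their sum over all
#' sink cells is one.
#'
#' @param species one row of the woody parameter table, or the full table
#'   plus `name` to pick a row.
#' @param cellsize grid cell edge length (m).
#' @param name optional species name when `species` is a full table.
#' @return An object of class `dispersal_kernel`: a list with `offsets`
#'   (data.frame `dcol`, `drow`, `dist`, `w`, `far`), the parameters, and
#'   the total weight within ED (`mass_ED`).
#' @export
build_kernel <- function(species, cellsize = 10, name = NULL) {
  if (!is.null(name)) species <- species[species$name == name, ]
  stopifnot(nrow(species) == 1)
  ED <- species$ED; MD <- species$MD; p_ED <- species$p_ED
  if (ED > MD) stop("ED must not exceed MD")
  r <- floor(MD / cellsize)
  off <- expand.grid(dcol = -r:r, drow = -r:r)
  off$dist <- cellsize * sqrt(off$dcol^2 + off$drow^2)
  off <- off[off$dist <= MD, ]
  w <- numeric(nrow(off))
  zero <- off$dist == 0
  w[zero] <- kernel_cdf(cellsize / 2, ED, MD, p_ED)
  d <- off$dist[!zero]
  w[!zero] <- kernel_density(d, ED, MD, p_ED) * cellsize^2 / (2 * pi * d)
  w <- w / sum(w)
  off$w <- w
  off$far <- off$dist > ED
  structure(list(species = species$name, offsets = off,
                 ED = ED, MD = MD, p_ED = p_ED, cellsize = cellsize,
                 zoochory_gated = isTRUE(species$zoochory_gated),
                 mass_ED = sum(w[!off$far])),
            class = "dispersal_kernel")
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat(sprintf(
    "dispersal_kernel (%s): ED %g m (mass %.3f, target %.2f), MD %g m, %d sink offsets%s\n",
    x$species, x$ED, x$mass_ED, x$p_ED, x$MD, nrow(x$offsets),
    if (x$zoochory_gated) ", zoochory-gated beyond ED" else ""))
  invisible(x)
}

#' Disperse seeds from one source cell
#'
#' Each sink cell within MD receives `n_seeds * weight`. For zoochory-gated
#' species (beech, oak) the weight mass beyond ED is delivered only to
#' eligible sink cells -- cells holding at least one bush or tree that are
#' not forest -- and the gated mass aimed at ineligible cells is discarded
#' (jays cache seeds only in structured, non-forest vegetation). Mass aimed
#' beyond the grid edge is lost.
#'
#' @param grid a `woods_grid`.
#' @param cell source cell index.
#' @param n_seeds number of seeds produced in the source cell.
#' @param kernel a [build_kernel()] object for the species.
#' @param eligible optional logical per-cell vector of zoochory-eligible
#'   sinks; computed from the current agents and vegetation types if `NULL`.
#' @return Numeric per-cell vector of incoming seed increments (a staging
#'   quantity: predator loss and grass inhibition are applied by
#'   [seedbank_input()] before anything reaches the seed bank).
#' @export
disperse <- function(grid, cell, n_seeds, kernel, eligible = NULL) {
  inc <- numeric(grid$n_cells)
  if (n_seeds <= 0) return(inc)
  cr <- cell_colrow(grid, cell)
  off <- kernel$offsets
  col <- cr$col + off$dcol
  row <- cr$row + off$drow
  ok <- col >= 1L & col <= grid$n_cols & row >= 1L & row <= grid$n_rows
  tgt <- (row[ok] - 1L) * grid$n_cols + col[ok]
  w <- off$w[ok]
  if (kernel$zoochory_gated) {
    if (is.null(eligible)) eligible <- zoochory_eligible(grid)
    far <- off$far[ok]
    w <- w * ifelse(far & !eligible[tgt], 0, 1)
  }
  inc_part <- rowsum(n_seeds * w, tgt)
  inc[as.integer(rownames(inc_part))] <- inc_part
  inc
}

#' Cells eligible to receive zoochorously dispersed seeds
#'
#' A sink cell beyond the effective seeding distance only receives gated
#' seeds (acorns, beechnuts) when it holds at least one bush or tree but is
#' not a forest cell.
#' @param grid a `woods_grid`.
#' @return Logical per-cell vector.
#' @export
zoochory_eligible <- function(grid) {
  has_agent <- logical(grid$n_cells)
  if (nrow(grid$agents)) has_agent[unique(grid$agents$cell)] <- TRUE
  has_agent & grid$veg != "forest"
}

## ---- inhibition and seed bank --------------------------------------------

#' Total grass inhibition of seed-bank input
#'
#' Per grass species i with cover c_i, a sigmoid factor
#' `s_i = 1 / (1 + (c_i / I50)^S)` (S negative, so `s_i(0) = 0`,
#' `s_i(I50) = 0.5`, increasing in cover). The single-species factors are
#' summed and clamped at 1; in mown or grazed cells the biomass removal
#' weakens the sward, so total inhibition is reduced by 30\%.
#'
#' @param grid a `woods_grid`.
#' @param species woody species name or row index (sets I50 and S).
#' @param cells cell indices (default all).
#' @param managed_factor multiplier applied in mown/grazed cells.
#' @return Numeric vector of total inhibition T in \[0, 1\] per cell.
#' @export
grass_inhibition <- function(grid, species, cells = NULL,
                             managed_factor = 0.7) {
  if (is.character(species))
    species <- match(species, grid$woody$name)
  I50 <- grid$woody$I50[species]
  S <- grid$woody$S[species]
  if (is.null(cells)) cells <- seq_len(grid$n_cells)
  gc <- grid$herb[cells, grid$herbsp$is_grass, drop = FALSE]
  s <- 1 / (1 + (gc / I50)^S)
  s[gc == 0] <- 0                      # 0^S with S < 0 is Inf; define s(0) = 0
  T_ <- pmin(1, rowSums(s))
  man <- grid$mown[cells] | grid$grazed[cells]
  T_[man] <- T_[man] * managed_factor
  T_
}

#' Seeds reaching the seed bank
#'
#' `Nsb = Nin * (1 - P_loss) * (1 - T)`: of the incoming seeds, a fraction
#' `P_loss` is taken by unspecific predators (mice) and a further fraction
#' `T` is held back by the grass sward.
#' @param n_in incoming seeds.
#' @param P_loss predator loss fraction.
#' @param inhibition total grass inhibition T in \[0, 1\].
#' @return Seeds added to the bank.
#' @export
seedbank_input <- function(n_in, P_loss, inhibition = 0) {
  stopifnot(all(n_in >= 0))
  n_in * (1 - P_loss) * (1 - inhibition)
}

#' Exponential seed-bank decay
#'
#' `dN/dt = -lambda * N`, integrated over `dt` years:
#' `N <- N * exp(-lambda * dt)`, per species.
#' @param grid a `woods_grid`.
#' @param dt time step in years.
#' @return The updated grid.
#' @export
seedbank_decay <- function(grid, dt = 1) {
  grid$bank <- grid$bank *
    rep(exp(-grid$woody$lambda * dt), each = nrow(grid$bank))
  grid
}

# largest-remainder allocation of `cap` seedlings over candidate counts
alloc_largest_remainder <- function(cand, cap) {
  tot <- sum(cand)
  if (tot <= cap) return(cand)
  quota <- cap * cand / tot
  base <- floor(quota)
  rem <- cap - sum(base)
  if (rem > 0) {
    ord <- order(-(quota - base), seq_along(cand))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Annual germination of the seed bank
#'
#' Once a year a species-specific fraction of each cell's seed bank
#' germinates: candidate seedlings are `floor(N * Germ)`, and the bank loses
#' `candidates / Germ` seeds (failed germinants die with the successful
#' ones). Germination needs free space: tree seeds only germinate while the
#' cell has space free of trees, broom seeds while it has space free of
#' trees and all bushes; with no space nothing is attempted. Realized
#' recruitment is capped at `tree_cap` tree seedlings (allocated over tree
#' species by largest remainder) plus `broom_cap` broom seedlings per cell;
#' the surplus of germinating seedlings is recorded per cell and enters the
#' browsing budget as immediately consumable forage.
#'
#' Seedlings start at the species' initial height with age 0; each draws an
#' individual maximum age uniformly within +/-10\% of the species maximum.
#'
#' @param grid a `woods_grid`.
#' @param tree_cap,broom_cap per-cell annual recruitment caps.
#' @return The updated grid (new agents appended, bank reduced, surplus
#'   matrix filled).
#' @export
germinate <- function(grid, tree_cap = 35, broom_cap = 35) {
  wd <- grid$woody
  cov <- cover_summary(grid)
  as_t <- pmax(0, grid$A - cov$tree)
  as_c <- pmax(0, grid$A - cov$tree - cov$broom - cov$thorny)
  germ <- rep(wd$Germ, each = nrow(grid$bank))
  cand <- floor(grid$bank * germ)
  # no space, no attempt
  cand[as_t <= 0, !wd$is_broom] <- 0
  cand[as_c <= 0, wd$is_broom] <- 0
  consume <- ifelse(germ > 0, cand / germ, 0)
  grid$bank <- pmax(grid$bank - pmin(grid$bank, consume), 0)

  real <- cand
  tree_cols <- which(!wd$is_broom)
  tree_tot <- rowSums(cand[, tree_cols, drop = FALSE])
  for (i in which(tree_tot > tree_cap))
    real[i, tree_cols] <- alloc_largest_remainder(cand[i, tree_cols],
                                                  tree_cap)
  broom_cols <- which(wd$is_broom)
  if (length(broom_cols))
    real[, broom_cols] <- pmin(real[, broom_cols, drop = FALSE], broom_cap)
  grid$surplus <- grid$surplus + (cand - real)

  n_new <- sum(real)
  if (n_new > 0) {
    idx <- which(real > 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    counts <- real[idx]
    cell <- rep(idx[, 1], counts)
    sp <- rep(idx[, 2], counts)
    age_max <- stats::runif(n_new, 0.9, 1.1) * wd$A_max[sp]
    new <- data.frame(cell = as.integer(cell), sp = as.integer(sp),
                      H = wd$H_ini[sp], age = 0, age_max = age_max,
                      D = 0, C = 0, browsed = FALSE)
    new <- update_allometry(new, wd, grid$A)
    grid$agents <- rbind(grid$agents, new)
  }
  grid
}
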