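# Small fixture builders shared across test files.

# a bare unmanaged grid
bare_grid <- function(n_cols = 10, n_rows = 10, ...) {
  woods_grid(n_cols, n_rows, 10, ...)
}

# place agents with explicit heights/covers, bypassing allometry, to set up
# exact competition scenarios
plant_agents <- function(grid, cell, sp, H, C = NULL, age = NULL) {
  n <- max(length(cell), length(sp), length(H), length(age), length(C))
  cell <- rep_len(cell, n); sp <- rep_len(sp, n); H <- rep_len(H, n)
  if (is.null(age)) age <- rep(1, n)
  new <- data.frame(cell = as.integer(cell), sp = as.integer(sp), H = H,
                    age = rep_len(age, n),
                    age_max = grid$woody$A_max[sp], D = 0, C = 0,
                    browsed = FALSE)
  new <- update_allometry(new, grid$woody, grid$A)
  if (!is.null(C)) new$C <- rep_len(C, n)
  grid$agents <- rbind(grid$agents, new)
  grid
}

sp_idx <- function(grid, name) match(name, grid$woody$name)

# a single-species woody table with controllable parameters, for closed-form
# growth checks
one_species_table <- function(G_mean = 0.03, G_sd = 0, H_max = 30,
                              Brow_mort = 0.1) {
  df <- woody_species_defaults()[1, ]
  df$G_mean <- G_mean; df$G_sd <- G_sd; df$H_max <- H_max
  df$Brow_mort <- Brow_mort
  df
}
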