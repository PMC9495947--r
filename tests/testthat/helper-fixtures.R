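# Shared fixtures built in code.

# A payoff matrix with every entry equal to `rho` (neutral competition),
# built by overwriting a shipped fixture's values.
neutral_payoffs <- function(rho = 0.5, crop = "cotton",
                            mode = "intra_plus_inter", bh = "BH_00RR") {
  pm <- load_payoff_fixture(crop, mode = mode)
  pm$entries$rho_num <- rho
  pm$entries$rho_s <- as.character(rho)
  expand_heterozygotes(pm, bh)
}

# A fitness table with equal Ro everywhere and configurable costs.
flat_fitness <- function(cost_RR = 0, cost_RS = 0) {
  ft <- default_fitness_table(cost_RR = cost_RR, cost_RS = cost_RS)
  ft$ro[] <- 1
  ft
}

# A small lattice with an explicitly specified grid of strain keys
# (character matrix with NA for empty cells).
lattice_from_matrix <- function(keys) {
  codes <- matrix(0L, nrow(keys), ncol(keys))
  occ <- !is.na(keys)
  codes[occ] <- match(keys[occ], names(refugeCA:::STRAIN_CODES))
  structure(list(grid = codes, width = ncol(keys), height = nrow(keys),
                 generation = 0L),
            class = "ca_lattice")
}

# Genotype counts vector helper
gc3 <- function(ss, rs, rr) c(SS = ss, RS = rs, RR = rr)
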