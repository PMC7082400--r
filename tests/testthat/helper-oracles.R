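# Independent oracles and small utilities shared across the test files.

# Element/charge vector computed straight from the registry table in plain
# doubles, independent of the package's rational machinery. The Other-SOI
# placeholder is expanded as tetrathionate at one sulfur atom per unit.
oracle_elem <- function(name) {
  reg <- species_registry()
  if (name == "S_OtherSOI") {
    row <- reg[reg$name == "S4O6^2-", ]
    return(c(row$n_S, row$n_O, row$n_H, row$charge) / row$n_S)
  }
  row <- reg[reg$name == name, ]
  c(row$n_S, row$n_O, row$n_H, row$charge)
}

# products-minus-reactants residual of a reaction, in doubles
oracle_residual <- function(rxn) {
  r <- c(0, 0, 0, 0)
  for (i in seq_along(rxn$reactants$species)) {
    r <- r - as.double(rxn$reactants$coef[i]) *
      oracle_elem(rxn$reactants$species[i])
  }
  for (i in seq_along(rxn$products$species)) {
    r <- r + as.double(rxn$products$coef[i]) *
      oracle_elem(rxn$products$species[i])
  }
  r
}

# Brute-force balance decision: enumerate signed rational grants for each
# free species with denominator in {1, 2} and magnitude <= 8, and ask
# whether any grant zeroes all four residuals.
oracle_balanced <- function(rxn, free_species = character(0)) {
  r <- oracle_residual(rxn)
  if (length(free_species) == 0) return(all(abs(r) < 1e-9))
  vals <- seq(-8, 8, by = 0.5)
  grids <- do.call(expand.grid, rep(list(vals), length(free_species)))
  cols <- vapply(free_species, oracle_elem, numeric(4))
  for (k in seq_len(nrow(grids))) {
    resid <- r + as.numeric(cols %*% t(grids[k, , drop = FALSE]))
    if (all(abs(resid) < 1e-9)) return(TRUE)
  }
  FALSE
}

# rational coefficient of one species in a reaction as a double (0 if absent)
coef_of <- function(rxn, species, side = c("reactants", "products")) {
  side <- match.arg(side)
  i <- match(species, rxn[[side]]$species)
  if (is.na(i)) 0 else as.double(rxn[[side]]$coef[i])
}

# multiplicative Gaussian perturbation of a delta vector (noise on the
# observed interval changes themselves)
perturb_delta <- function(delta, cv) {
  delta$d_species <- delta$d_species * (1 + cv * stats::rnorm(length(delta$d_species)))
  delta$d_other_soi <- delta$d_other_soi * (1 + cv * stats::rnorm(1))
  if (!is.na(delta$d_proton)) {
    delta$d_proton <- delta$d_proton * (1 + cv * stats::rnorm(1))
  }
  delta
}

# library subset helper preserving the class
lib_subset <- function(library, ids) {
  structure(library[ids], class = "reaction_library")
}
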