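#' Sulfur-cycle species registry
#'
#' Returns the registry of chemical species the package knows about. Each
#' species carries its elemental composition (S, O, H atom counts), formal
#' charge and a role annotation. Species are represented exactly as they
#' appear in the mass-balance reaction set (e.g. \code{SO3^2-} rather than
#' \code{H2SO3}, even though culture pH < 3), because the printed reactions
#' are the normative objects the balancer works with. Elemental sulfur is a
#' single S atom (ring structure ignored). \code{S_OtherSOI} is a placeholder
#' for the unresolved sulfur-oxidation-intermediate pool, counted in
#' single-sulfur units; balance checks expand it through a polythionate
#' proxy (see \code{\link{check_balance}}). The electron \code{e-} carries
#' charge only; it is the declared free species for respiratory
#' half-reactions whose electrons leave through the transport chain (the
#' biotic sulfite-to-sulfate oxidation), not a modelling of redox chains.
#'
#' @return A data.frame with columns \code{name}, \code{n_S}, \code{n_O},
#'   \code{n_H}, \code{charge}, \code{role} and \code{molar_mass} (g/mol,
#'   from atomic masses S 32.06, O 15.999, H 1.008).
#' @examples
#' species_registry()
#' @export
species_registry <- function() {
  df <- data.frame(
    name   = c("S0", "SO3^2-", "SO4^2-", "S2O3^2-", "S3O3^2-",
               "S3O6^2-", "S4O6^2-", "S5O6^2-", "S6O6^2-",
               "S^2-", "H+", "O2", "H2O", "e-", "S_OtherSOI"),
    n_S    = c(1, 1, 1, 2, 3, 3, 4, 5, 6, 1, 0, 0, 0, 0, 1),
    n_O    = c(0, 3, 4, 3, 3, 6, 6, 6, 6, 0, 0, 2, 1, 0, 0),
    n_H    = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 2, 0, 0),
    charge = c(0, -2, -2, -2, -2, -2, -2, -2, -2, -2, 1, 0, 0, -1, 0),
    role   = c("substrate", "SOI", "end_member", "SOI", "SOI",
               "SOI", "SOI", "SOI", "SOI",
               "substrate", "free_species", "free_species", "free_species",
               "free_species", "proxy"),
    stringsAsFactors = FALSE
  )
  df$molar_mass <- 32.06 * df$n_S + 15.999 * df$n_O + 1.008 * df$n_H
  df
}

# atomic mass of sulfur used for mg/L <-> mM-S conversions
S_MOLAR_MASS <- 32.06

# total-S limit of detection: 1 mg S / L expressed in mM-S
TOTAL_S_LOD_MM_S <- 1 / S_MOLAR_MASS

# dissolved pool used in the Other-SOI by-difference computation; particulate
# S0 (unfiltered measurement) is excluded because total aqueous S is the
# < 0.45 um fraction
DISSOLVED_POOL <- c("SO4^2-", "S^2-", "S2O3^2-", "SO3^2-", "S0")

species_row <- function(name, registry = species_registry()) {
  i <- match(name, registry$name)
  if (any(is.na(i))) {
    stop("unknown species token(s): ",
         paste(name[is.na(i)], collapse = ", "),
         " (not in the species registry)")
  }
  registry[i, , drop = FALSE]
}

# exact (rational) element-and-charge vector (S, O, H, charge) of one species;
# a placeholder ("proxy" role) species is expanded through `proxy`, a named
# character vector mapping placeholder name -> concrete species, with one
# placeholder unit equal to one sulfur atom of the proxy molecule
element_vector <- function(name, registry = species_registry(),
                           proxy = c(S_OtherSOI = "S4O6^2-")) {
  row <- species_row(name, registry)
  if (identical(row$role, "proxy")) {
    sub <- proxy[[name]]
    if (is.null(sub) || is.na(sub)) {
      stop("no proxy configured for placeholder species '", name, "'")
    }
    prow <- species_row(sub, registry)
    if (prow$n_S <= 0) stop("proxy species '", sub, "' has no sulfur")
    return(rq(c(prow$n_S, prow$n_O, prow$n_H, prow$charge)) / rq(prow$n_S))
  }
  rq(c(row$n_S, row$n_O, row$n_H, row$charge))
}
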