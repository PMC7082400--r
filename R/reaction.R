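#' Parse a reaction string
#'
#' Parses the reaction mini-grammar \code{"coef SPECIES + ... -> coef SPECIES
#' + ..."} into a canonical reaction object. Coefficients may be integers,
#' short decimals (\code{0.5}, \code{3.5}) or fractions (\code{1/2}); an
#' omitted coefficient is 1. Coefficient arithmetic is exact (rational).
#' Terms are separated by \code{" + "} (plus with surrounding whitespace, so
#' species tokens such as \code{"H+"} are unambiguous); the arrow is
#' \code{"->"} or \code{"<->"} for a reversible reaction. Canonicalisation
#' merges duplicate terms and cancels any species appearing on both sides,
#' so \code{"S0 -> S0"} parses to the empty reaction.
#'
#' @param text Reaction string.
#' @param id Identifier for the reaction (default \code{"user"}).
#' @param source Provenance tag: one of \code{"table3"}, \code{"fig1_derived"},
#'   \code{"net_observed"}, \code{"user"}.
#' @param catalysts Character vector of enzyme names annotated as catalysts.
#' @param abiotic_possible Logical; can the reaction proceed abiotically?
#' @param free_species Species granted free coefficients when this reaction
#'   is balance-checked (e.g. \code{"e-"} for respiratory half-reactions).
#' @param registry Species registry (see \code{\link{species_registry}}).
#' @return An object of class \code{sulfur_reaction}.
#' @examples
#' parse_reaction("2 S2O3^2- + 0.5 O2 + 2 H+ -> S4O6^2- + H2O")
#' @export
parse_reaction <- function(text, id = "user", source = "user",
                           catalysts = character(0), abiotic_possible = FALSE,
                           free_species = character(0),
                           registry = species_registry()) {
  p <- parse_reaction_terms(text, registry = registry, allow_unknowns = FALSE)
  new_reaction(id = id,
               species = p$species, coef = p$coef, side = p$side,
               reversible = p$reversible, source = source,
               catalysts = catalysts, abiotic_possible = abiotic_possible,
               free_species = free_species)
}

SOURCE_LEVELS <- c("table3", "fig1_derived", "net_observed", "user")

# shared term parser; with allow_unknowns, a single lowercase letter in
# coefficient position marks an unknown coefficient to be solved for
parse_reaction_terms <- function(text, registry, allow_unknowns = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  reversible <- grepl("<->", text, fixed = TRUE)
  sides <- if (reversible) strsplit(text, "<->", fixed = TRUE)[[1]]
           else strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) {
    stop("malformed reaction '", text, "': expected exactly one '->' or '<->' arrow")
  }
  species <- character(0); coef <- rq(); side <- integer(0)
  unknown_sym <- character(0); unknown_species <- character(0); unknown_side <- integer(0)
  for (s in 1:2) {
    txt <- trimws(sides[s])
    if (txt == "") stop("malformed reaction '", text, "': empty side ", s)
    terms <- strsplit(txt, "\\s+\\+\\s+")[[1]]
    for (k in seq_along(terms)) {
      term <- trimws(terms[k])
      if (term == "") {
        stop("parse error in '", text, "' at term ", k, " of side ", s,
             ": empty term")
      }
      parts <- strsplit(term, "\\s+")[[1]]
      if (length(parts) == 1) {
        cf <- rq(1); sp <- parts[1]
      } else if (length(parts) == 2) {
        if (allow_unknowns && grepl("^[a-z]$", parts[1])) {
          unknown_sym <- c(unknown_sym, parts[1])
          unknown_species <- c(unknown_species, parts[2])
          unknown_side <- c(unknown_side, s)
          species_row(parts[2], registry)
          next
        }
        cf <- tryCatch(as_rq(parts[1]),
                       error = function(e) stop("parse error in '", text,
                         "' at term ", k, " of side ", s, ": ",
                         conditionMessage(e), call. = FALSE))
        sp <- parts[2]
      } else {
        stop("parse error in '", text, "' at term ", k, " of side ", s,
             ": '", term, "'")
      }
      if (any(as.double(cf) <= 0)) {
        stop("parse error in '", text, "': coefficient of '", sp,
             "' must be positive")
      }
      species_row(sp, registry)  # errors on unknown token
      species <- c(species, sp); coef <- c_rq(coef, cf); side <- c(side, s)
    }
  }
  list(species = species, coef = coef, side = side, reversible = reversible,
       unknown = data.frame(symbol = unknown_sym, species = unknown_species,
                            side = unknown_side, stringsAsFactors = FALSE))
}

# build a canonical sulfur_reaction from (species, rq coef, side in {1,2})
new_reaction <- function(id, species, coef, side, reversible = FALSE,
                         source = "user", catalysts = character(0),
                         abiotic_possible = FALSE,
                         free_species = character(0)) {
  source <- match.arg(source, SOURCE_LEVELS)
  uniq <- unique(species)
  net <- rq(rep(0, length(uniq)))
  for (i in seq_along(species)) {
    j <- match(species[i], uniq)
    sgn <- if (side[i] == 2) rq(1) else rq(-1)
    net[j] <- net[j] + coef[i] * sgn
  }
  keep <- !rq_zero(net)
  uniq <- uniq[keep]; net <- net[keep]
  is_prod <- as.double(net) > 0
  structure(list(
    id = id,
    reactants = list(species = uniq[!is_prod], coef = rq_abs(net[!is_prod])),
    products  = list(species = uniq[is_prod],  coef = net[is_prod]),
    reversible = reversible,
    source = source,
    catalysts = catalysts,
    abiotic_possible = abiotic_possible,
    free_species = free_species
  ), class = "sulfur_reaction")
}

is_reaction <- function(x) inherits(x, "sulfur_reaction")

#' Net stoichiometric coefficients of a reaction
#'
#' Signed species coefficients (products positive, reactants negative) as an
#' exact rational vector.
#'
#' @param rxn A \code{sulfur_reaction}.
#' @return List with \code{species} (character) and \code{coef} (rational).
#' @keywords internal
net_coefficients <- function(rxn) {
  stopifnot(is_reaction(rxn))
  list(species = c(rxn$reactants$species, rxn$products$species),
       coef = c_rq(-rxn$reactants$coef, rxn$products$coef))
}

# numeric net coefficient of one species (0 if absent)
net_coef_of <- function(rxn, species) {
  nc <- net_coefficients(rxn)
  i <- match(species, nc$species)
  if (is.na(i)) 0 else as.double(nc$coef[i])
}

#' Format a reaction as its mini-grammar string
#'
#' @param rxn A \code{sulfur_reaction}.
#' @return A single string such as \code{"2 S2O3^2- + 1/2 O2 + 2 H+ ->
#'   S4O6^2- + H2O"}; the empty reaction renders as \code{"(empty)"}.
#' @export
reaction_string <- function(rxn) {
  stopifnot(is_reaction(rxn))
  fmt_side <- function(side) {
    if (length(side$species) == 0) return("")
    cf <- format(side$coef)
    paste(ifelse(cf == "1", side$species, paste(cf, side$species)),
          collapse = " + ")
  }
  lhs <- fmt_side(rxn$reactants); rhs <- fmt_side(rxn$products)
  if (lhs == "" && rhs == "") return("(empty)")
  arrow <- if (isTRUE(rxn$reversible)) "<->" else "->"
  paste(lhs, arrow, rhs)
}

#' @export
print.sulfur_reaction <- function(x, ...) {
  cat("<reaction ", x$id, "> ", reaction_string(x), "\n", sep = "")
  if (length(x$catalysts)) {
    cat("  catalysts: ", paste(x$catalysts, collapse = ", "), "\n", sep = "")
  }
  cat("  source: ", x$source,
      if (isTRUE(x$abiotic_possible)) " (abiotic possible)" else "",
      "\n", sep = "")
  invisible(x)
}

# is the reaction empty (no species on either side)?
reaction_is_empty <- function(rxn) {
  length(rxn$reactants$species) == 0 && length(rxn$products$species) == 0
}
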