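#' Check element and charge balance of a reaction
#'
#' Computes the exact residuals (products minus reactants) of sulfur, oxygen
#' and hydrogen atoms and of charge. Placeholder species are first expanded
#' through \code{proxy} (one placeholder unit = one sulfur atom of the proxy
#' molecule). Species listed in \code{free_species} are granted arbitrary
#' signed rational coefficients: the residual vector is reduced by its exact
#' rational least-squares projection onto the span of the free species'
#' element vectors, which zeroes every residual component the grants can
#' reach and leaves the rest untouched. The reaction is balanced when all
#' four remaining residuals are zero.
#'
#' @param rxn A \code{sulfur_reaction} (see \code{\link{parse_reaction}}).
#' @param free_species Character vector of species names granted free
#'   coefficients (typically a subset of \code{c("H+", "O2", "H2O")}).
#' @param proxy Named character vector mapping placeholder species to a
#'   concrete proxy, default \code{c(S_OtherSOI = "S4O6^2-")}. Any
#'   polythionate \code{SnO6^2-} (n = 3..6) in the registry may be used.
#' @param registry Species registry.
#' @return A \code{balance_report}: list with rational \code{residual_S},
#'   \code{residual_O}, \code{residual_H}, \code{residual_charge},
#'   \code{free_species_used} (named numeric) and logical \code{balanced}.
#' @examples
#' r <- parse_reaction("S4O6^2- + 3.5 O2 + 3 H2O -> 4 SO4^2- + 6 H+")
#' check_balance(r)$balanced
#' @export
check_balance <- function(rxn, free_species = character(0),
                          proxy = c(S_OtherSOI = "S4O6^2-"),
                          registry = species_registry()) {
  stopifnot(is_reaction(rxn))
  nc <- net_coefficients(rxn)
  r <- rq(rep(0, 4))
  for (i in seq_along(nc$species)) {
    ev <- element_vector(nc$species[i], registry, proxy)
    r <- r + ev * rep_rq(nc$coef[i], 4)
  }
  used <- stats::setNames(numeric(length(free_species)), free_species)
  if (length(free_species) > 0 && any(!rq_zero(r))) {
    cols <- lapply(free_species, element_vector, registry = registry, proxy = proxy)
    k <- length(cols)
    # exact normal equations: G x = -A' r, leftover = r + A x
    G <- vector("list", k)
    rhs <- rq(rep(0, k))
    for (i in seq_len(k)) {
      G[[i]] <- rq(rep(0, k))
      for (j in seq_len(k)) G[[i]][j] <- rq_dot(cols[[i]], cols[[j]])
      rhs[i] <- rq(0) - rq_dot(cols[[i]], r)
    }
    sol <- rq_solve(G, rhs)
    x <- sol$solution
    for (i in seq_len(k)) {
      r <- r + cols[[i]] * rep_rq(x[i], 4)
      used[i] <- as.double(x[i])
    }
  }
  structure(list(
    residual_S = r[1], residual_O = r[2], residual_H = r[3],
    residual_charge = r[4],
    free_species_used = used,
    balanced = all(rq_zero(r))
  ), class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance report> ", if (x$balanced) "balanced" else "NOT balanced", "\n",
      "  residuals (products - reactants): S=", format(x$residual_S),
      " O=", format(x$residual_O), " H=", format(x$residual_H),
      " charge=", format(x$residual_charge), "\n", sep = "")
  if (length(x$free_species_used) && any(x$free_species_used != 0)) {
    cat("  free species granted:",
        paste(names(x$free_species_used), format(x$free_species_used),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Complete a reaction skeleton by element-and-charge conservation
#'
#' Solves the exact linear system of S, O, H and charge conservation for
#' unknown coefficients written as single lowercase letters in the skeleton
#' string, e.g. \code{"S0 + x O2 + y H2O -> SO3^2- + z H+"}. Unknowns are
#' restricted to the free species \code{H+}, \code{O2} and \code{H2O}. A
#' negative solved coefficient moves that species to the opposite side of
#' the completed reaction.
#'
#' @param text Skeleton string with unknown coefficients, or a
#'   \code{sulfur_reaction} (returned unchanged, for the no-unknown case).
#' @param id,source,catalysts,abiotic_possible Passed to the completed
#'   reaction.
#' @param free_species Extra species (e.g. \code{"e-"}) granted a solved
#'   signed coefficient during completion, for half-reactions whose
#'   electrons leave through the respiratory chain.
#' @param proxy,registry As in \code{\link{check_balance}}.
#' @return The completed, exactly balanced \code{sulfur_reaction}.
#' @examples
#' complete_reaction("S0 + x O2 + y H2O -> SO3^2- + z H+")
#' @export
complete_reaction <- function(text, id = "completed", source = "user",
                              catalysts = character(0),
                              abiotic_possible = FALSE,
                              free_species = character(0),
                              proxy = c(S_OtherSOI = "S4O6^2-"),
                              registry = species_registry()) {
  if (is_reaction(text)) return(text)
  p <- parse_reaction_terms(text, registry = registry, allow_unknowns = TRUE)
  unk <- p$unknown
  if (length(free_species)) {
    unk <- rbind(unk, data.frame(symbol = free_species,
                                 species = free_species, side = 2L,
                                 stringsAsFactors = FALSE))
  }
  fixed <- new_reaction(id = id, species = p$species, coef = p$coef,
                        side = p$side, reversible = p$reversible,
                        source = source, catalysts = catalysts,
                        abiotic_possible = abiotic_possible)
  if (nrow(unk) == 0) return(fixed)
  allowed <- c("H+", "O2", "H2O", free_species)
  if (!all(unk$species %in% allowed)) {
    stop("unknown coefficients are restricted to H+, O2 and H2O; got: ",
         paste(setdiff(unk$species, allowed), collapse = ", "))
  }
  # residual of the fixed part
  nc <- net_coefficients(fixed)
  r <- rq(rep(0, 4))
  for (i in seq_along(nc$species)) {
    r <- r + element_vector(nc$species[i], registry, proxy) * rep_rq(nc$coef[i], 4)
  }
  # rows = S,O,H,charge; columns = unknowns; solve A u = -r
  k <- nrow(unk)
  cols <- lapply(seq_len(k), function(j) {
    sgn <- if (unk$side[j] == 2) rq(1) else rq(-1)
    element_vector(unk$species[j], registry, proxy) * rep_rq(sgn, 4)
  })
  A <- lapply(1:4, function(row) {
    v <- rq(rep(0, k))
    for (j in seq_len(k)) v[j] <- cols[[j]][row]
    v
  })
  sol <- rq_solve(A, rq(0) - r)
  if (!sol$consistent) {
    stop("skeleton '", text, "' has no balanced completion; ",
         "unremovable residuals: ",
         paste(format(sol$inconsistent_rhs), collapse = ", "))
  }
  if (sol$nullspace_dim > 0) {
    stop("skeleton '", text, "' is underdetermined: null-space dimension ",
         sol$nullspace_dim)
  }
  u <- sol$solution
  species <- p$species; coef <- p$coef; side <- p$side
  for (j in seq_len(k)) {
    uj <- u[j]
    if (rq_zero(uj)) next
    neg <- as.double(uj) < 0
    species <- c(species, unk$species[j])
    coef <- c_rq(coef, rq_abs(uj))
    # negative solution flips the species to the opposite side
    side <- c(side, if (neg) 3 - unk$side[j] else unk$side[j])
  }
  out <- new_reaction(id = id, species = species, coef = coef, side = side,
                      reversible = p$reversible, source = source,
                      catalysts = catalysts,
                      abiotic_possible = abiotic_possible,
                      free_species = free_species)
  rep <- check_balance(out, proxy = proxy, registry = registry)
  if (!rep$balanced) stop("internal error: completion of '", text,
                          "' did not balance")  # defensive; should not happen
  out
}

#' Compose reactions into a net reaction
#'
#' Species-wise linear combination of reactions with nonnegative
#' multipliers, in exact arithmetic. Species appearing on both sides of the
#' combination cancel. An empty term list yields the empty reaction.
#'
#' @param terms List of \code{list(reaction, mult)} pairs (or a named list
#'   with elements \code{reaction} and \code{mult}); multipliers may be
#'   numeric, strings like \code{"1/2"}, or rational.
#' @param id Identifier for the composed reaction.
#' @return The net \code{sulfur_reaction} (source \code{"user"}).
#' @examples
#' lib <- load_reaction_library()
#' net <- compose_reactions(list(
#'   list(lib[["T3.eq2"]], 4), list(lib[["T3.eq3"]], 2),
#'   list(lib[["T3.eq4f"]], 2), list(lib[["T3.eq5"]], 1)))
#' reaction_string(net)
#' @export
compose_reactions <- function(terms, id = "net") {
  species <- character(0); coef <- rq(); side <- integer(0)
  for (t in terms) {
    rxn <- t[[1]]; mult <- as_rq(t[[2]])
    stopifnot(is_reaction(rxn))
    if (as.double(mult) < 0) stop("composition multipliers must be nonnegative")
    if (rq_zero(mult)) next
    nc <- net_coefficients(rxn)
    for (i in seq_along(nc$species)) {
      v <- nc$coef[i] * mult
      species <- c(species, nc$species[i])
      coef <- c_rq(coef, rq_abs(v))
      side <- c(side, if (as.double(v) > 0) 2L else 1L)
    }
  }
  new_reaction(id = id, species = species, coef = coef, side = side,
               reversible = FALSE, source = "user")
}
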