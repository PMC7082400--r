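#' Stoichiometric matrix of a reaction library in observation space
#'
#' Builds the numeric matrix M whose columns are library reactions and whose
#' rows are the observable pools: each measured species in sulfur-atom units
#' (mM-S per mM of reaction turnover), one aggregate \code{OtherSOI} row
#' collecting the sulfur of every species that is not individually measured
#' (polythionates and the placeholder), and one \code{H+} row with the net
#' proton coefficient. O2 and H2O are treated as unlimited reservoirs and
#' excluded. With this convention the column sums over all sulfur rows are
#' zero for every sulfur-conserving reaction.
#'
#' @param library A \code{reaction_library}.
#' @param measured Character vector of measured species (default the
#'   dissolved pool).
#' @param registry Species registry.
#' @return Numeric matrix, rows \code{c(measured, "OtherSOI", "H+")}.
#' @export
stoich_matrix <- function(library, measured = DISSOLVED_POOL,
                          registry = species_registry()) {
  ids <- names(library)
  rows <- c(measured, "OtherSOI", "H+")
  M <- matrix(0, length(rows), length(ids), dimnames = list(rows, ids))
  for (j in seq_along(ids)) {
    nc <- net_coefficients(library[[j]])
    for (i in seq_along(nc$species)) {
      sp <- nc$species[i]
      v <- as.double(nc$coef[i])
      if (sp %in% measured) {
        M[sp, j] <- M[sp, j] + v * species_row(sp, registry)$n_S
      } else if (sp == "H+") {
        M["H+", j] <- M["H+", j] + v
      } else if (!(sp %in% c("O2", "H2O", "e-"))) {
        M["OtherSOI", j] <- M["OtherSOI", j] + v * species_row(sp, registry)$n_S
      }
    }
  }
  M
}

# nonnegative least squares with optional L1 penalty:
#   min ||W (M x - d)||^2 + l1 * sum(x)  s.t. x >= 0
# l1 = 0 delegates to the Lawson-Hanson solver; l1 > 0 uses projected
# coordinate descent started from the unpenalised solution.
nnls_fit <- function(M, d, w = NULL, l1 = 0, maxit = 20000, tol = 1e-12) {
  if (is.null(w)) w <- rep(1, nrow(M))
  WM <- M * w
  wd <- d * w
  x <- tryCatch(pracma::lsqnonneg(WM, wd)$x,
                error = function(e) stop("NNLS solver failed: ",
                                         conditionMessage(e),
                                         "; condition number of M: ",
                                         format(kappa(WM)), call. = FALSE))
  if (l1 > 0) {
    G <- crossprod(WM)
    b <- crossprod(WM, wd)
    nrm2 <- diag(G)
    for (it in seq_len(maxit)) {
      x_old <- x
      for (j in seq_along(x)) {
        if (nrm2[j] == 0) next
        g <- b[j] - sum(G[j, ] * x) + G[j, j] * x[j]
        x[j] <- max(0, (g - l1 / 2) / nrm2[j])
      }
      if (max(abs(x - x_old)) < tol * (1 + max(abs(x)))) break
    }
  }
  stats::setNames(as.numeric(x), colnames(M))
}

#' Fit nonnegative reaction extents to an observed change vector
#'
#' Solves \eqn{\min_x \|W(Mx - d)\|^2} subject to \eqn{x \ge 0}, where the
#' columns of M are the library reactions (sulfur-atom units) and d is the
#' observed interval change vector: measured species rows, the Other-SOI
#' row, and optionally the proton row. Extents are in mM of reaction
#' turnover. Rank-deficient libraries are reported, not silently resolved:
#' the fit carries the null-space dimension and a per-reaction
#' identifiability flag; an optional L1 penalty selects a sparse
#' representative solution.
#'
#' @param delta A \code{delta_vector}.
#' @param library A \code{reaction_library}.
#' @param weights Optional named row weights (e.g. \code{c("H+" = 0.5)} to
#'   down-weight the proton row); unnamed rows get weight 1.
#' @param include_proton Include the proton row (default \code{TRUE} when
#'   \code{delta$d_proton} is available).
#' @param l1 L1 penalty weight; 0 (default) for plain NNLS, \code{"auto"}
#'   for \code{1e-3 * ||d||}.
#' @param registry Species registry.
#' @return Object of class \code{extent_fit}: extents, residuals
#'   (\code{M x - d}), weighted squared objective, null-space dimension,
#'   identifiability flags, and the settings used.
#' @export
fit_extents <- function(delta, library, weights = NULL,
                        include_proton = !is.na(delta$d_proton), l1 = 0,
                        registry = species_registry()) {
  stopifnot(inherits(delta, "delta_vector"))
  if (length(library) == 0) stop("reaction library is empty")
  measured <- names(delta$d_species)
  M <- stoich_matrix(library, measured = measured, registry = registry)
  d <- c(delta$d_species, OtherSOI = delta$d_other_soi)
  if (include_proton) {
    if (is.na(delta$d_proton)) stop("delta has no proton observation")
    d <- c(d, "H+" = delta$d_proton)
  }
  M <- M[names(d), , drop = FALSE]
  w <- rep(1, length(d))
  names(w) <- names(d)
  if (!is.null(weights)) w[names(weights)] <- weights
  if (identical(l1, "auto")) l1 <- 1e-3 * sqrt(sum(d^2))
  x <- nnls_fit(M, d, w = w, l1 = l1)
  resid <- as.numeric(M %*% x - d)
  names(resid) <- names(d)
  rank <- qr(M)$rank
  ns_dim <- ncol(M) - rank
  identifiable <- rep(TRUE, ncol(M))
  names(identifiable) <- colnames(M)
  if (ns_dim > 0) {
    ns <- svd(M, nu = 0, nv = ncol(M))$v[, (rank + 1):ncol(M), drop = FALSE]
    identifiable <- apply(abs(ns) > 1e-8, 1, function(z) !any(z))
    names(identifiable) <- colnames(M)
  }
  structure(list(
    extents = x,
    residual = resid,
    objective = sum((w * resid)^2),
    nullspace_dim = ns_dim,
    identifiable = identifiable,
    settings = list(weights = w, l1 = l1, include_proton = include_proton,
                    measured = measured)
  ), class = "extent_fit")
}

#' @export
print.extent_fit <- function(x, ...) {
  cat("<extent fit> objective ", format(x$objective, digits = 4),
      ", null-space dim ", x$nullspace_dim, "\n", sep = "")
  act <- x$extents[x$extents > 1e-10]
  if (length(act)) {
    for (id in names(act)) {
      cat(sprintf("  %-9s %8.4f mM%s\n", id, act[[id]],
                  if (!x$identifiable[[id]]) "  (non-identifiable)" else ""))
    }
  } else cat("  (all extents zero)\n")
  invisible(x)
}

#' Predicted net proton change of a set of extents
#'
#' Sum over reactions of extent times net proton coefficient; positive
#' means acid produced.
#'
#' @param extents Named numeric vector of extents (mM), or an
#'   \code{extent_fit}.
#' @param library A \code{reaction_library}.
#' @return Net proton change in mM.
#' @examples
#' lib <- load_reaction_library()
#' predict_proton(c(T3.eq5 = 1), lib)  # -2: tetrathionate formation consumes acid
#' @export
predict_proton <- function(extents, library) {
  if (inherits(extents, "extent_fit")) extents <- extents$extents
  tot <- 0
  for (id in names(extents)) {
    if (!(id %in% names(library))) stop("extent for unknown reaction '", id, "'")
    tot <- tot + extents[[id]] * net_coef_of(library[[id]], "H+")
  }
  tot
}

#' Integer-normalised net reaction from an observed change vector
#'
#' Scales the consumed and produced sulfur pools of a change vector so the
#' produced sulfur totals \code{s_total_target} atoms, then rounds each
#' pool's molecule coefficient to the nearest integer with a
#' largest-remainder repair so the rounded produced sulfur still equals the
#' target. The proton change is scaled identically and rounded. In auto
#' mode the smallest target not exceeding \code{max_target} whose largest
#' produced-pool rounding residual is below \code{tol} is chosen; if none
#' qualifies the best candidate is reported in the error. The result is
#' scale-invariant in the input deltas.
#'
#' @param delta A \code{delta_vector} (the Other-SOI pool enters as the
#'   placeholder species \code{S_OtherSOI}, in single-sulfur units).
#' @param s_total_target Integer target of produced sulfur atoms, or
#'   \code{"auto"}.
#' @param tol Largest acceptable rounding residual in auto mode (default
#'   0.15).
#' @param max_target Largest target tried in auto mode (default 12).
#' @param registry Species registry.
#' @return Object of class \code{net_reaction}: the \code{sulfur_reaction}
#'   (source \code{"net_observed"}), the target, the per-pool rounding
#'   residuals, the proton coefficient (or NULL) and the scale factor.
#' @examples
#' d <- delta_vector(c(0, 5), d_species = c("SO4^2-" = 13.7, "S0" = -39),
#'                   d_other_soi = 25.3)
#' normalize_net_reaction(d, 6)
#' @export
normalize_net_reaction <- function(delta, s_total_target = "auto", tol = 0.15,
                                   max_target = 12,
                                   registry = species_registry()) {
  stopifnot(inherits(delta, "delta_vector"))
  pools <- c(delta$d_species,
             if (abs(delta$d_other_soi) > 0) c(S_OtherSOI = delta$d_other_soi))
  pools <- pools[pools != 0]
  prod <- pools[pools > 0]
  cons <- -pools[pools < 0]
  if (length(prod) == 0) stop("no produced sulfur pool in delta")
  s_prod_total <- sum(prod)
  build <- function(target) {
    lambda <- target / s_prod_total
    n_s <- vapply(names(pools), function(s) species_row(s, registry)$n_S,
                  numeric(1))
    # molecule-unit coefficients after scaling
    prod_mol <- lambda * prod / n_s[names(prod)]
    cons_mol <- lambda * cons / n_s[names(cons)]
    # largest-remainder rounding of produced pools, constrained so the
    # rounded sulfur total still equals the target
    pr <- floor(prod_mol)
    rem <- prod_mol - pr
    deficit <- target - sum(pr * n_s[names(prod)])
    ord <- order(rem, decreasing = TRUE)
    for (i in ord) {
      ns_i <- n_s[names(prod)][i]
      if (deficit >= ns_i) { pr[i] <- pr[i] + 1; deficit <- deficit - ns_i }
      if (deficit == 0) break
    }
    cr <- round(cons_mol)
    resid <- abs(c(prod_mol - pr, cons_mol - cr))
    proton_coef <- NULL
    if (!is.na(delta$d_proton)) proton_coef <- round(lambda * delta$d_proton)
    list(prod = pr, cons = cr, resid = resid, lambda = lambda,
         proton_scaled = if (!is.na(delta$d_proton)) lambda * delta$d_proton else NULL,
         proton_coef = proton_coef,
         max_resid = max(abs(prod_mol - pr)))
  }
  if (identical(s_total_target, "auto")) {
    best <- NULL; best_t <- NA
    for (t in seq_len(max_target)) {
      cand <- build(t)
      if (is.null(best) || cand$max_resid < best$max_resid) {
        best <- cand; best_t <- t
      }
      if (cand$max_resid < tol) { best <- cand; best_t <- t; break }
    }
    if (best$max_resid >= tol) {
      stop("auto mode found no target <= ", max_target,
           " with rounding residual < ", tol, "; best candidate: target ",
           best_t, " with max residual ", format(best$max_resid, digits = 3))
    }
    s_total_target <- best_t
    sol <- best
  } else {
    sol <- build(s_total_target)
  }
  # assemble the net_observed reaction, dropping zero-rounded pools
  species <- character(0); coef <- rq(); side <- integer(0)
  for (s in names(sol$cons)) {
    if (sol$cons[[s]] > 0) {
      species <- c(species, s); coef <- c_rq(coef, rq(sol$cons[[s]]))
      side <- c(side, 1L)
    }
  }
  for (s in names(sol$prod)) {
    if (sol$prod[[s]] > 0) {
      species <- c(species, s); coef <- c_rq(coef, rq(sol$prod[[s]]))
      side <- c(side, 2L)
    }
  }
  if (!is.null(sol$proton_coef) && sol$proton_coef != 0) {
    species <- c(species, "H+")
    coef <- c_rq(coef, rq(abs(sol$proton_coef)))
    side <- c(side, if (sol$proton_coef > 0) 2L else 1L)
  }
  rxn <- new_reaction(id = sprintf("net.d%g-d%g", delta$interval[1],
                                   delta$interval[2]),
                      species = species, coef = coef, side = side,
                      source = "net_observed")
  structure(list(reaction = rxn,
                 s_total_target = s_total_target,
                 rounding_residuals = sol$resid,
                 proton_coef = sol$proton_coef,
                 proton_scaled = sol$proton_scaled,
                 scale = sol$lambda),
            class = "net_reaction")
}

#' @export
print.net_reaction <- function(x, ...) {
  cat("<net reaction> (", x$s_total_target, " produced S atoms)\n  ",
      reaction_string(x$reaction), "\n", sep = "")
  cat("  max rounding residual: ",
      format(max(x$rounding_residuals), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Compare candidate reaction subsets against an observed change vector
#'
#' Fits each candidate subset of the library with \code{\link{fit_extents}}
#' and ranks by objective, breaking ties by subset size (parsimony). Also
#' reports whether the best subset containing the polythionate
#' disproportionation reactions improves on the best subset without them by
#' more than \code{dispro_factor}.
#'
#' @param delta A \code{delta_vector}.
#' @param candidate_subsets List of character vectors of reaction ids.
#' @param library A \code{reaction_library}.
#' @param dispro_ids Reaction ids counted as disproportionation (default
#'   \code{c("T3.eq10", "T3.eq11")}).
#' @param dispro_factor Improvement factor for the disproportionation call
#'   (default 10).
#' @param ... Passed to \code{\link{fit_extents}}.
#' @return Object of class \code{model_comparison}: a ranking data.frame,
#'   the fits, and the disproportionation verdict.
#' @export
compare_models <- function(delta, candidate_subsets, library,
                           dispro_ids = c("T3.eq10", "T3.eq11"),
                           dispro_factor = 10, ...) {
  if (length(candidate_subsets) == 0) stop("no candidate subsets given")
  fits <- lapply(candidate_subsets, function(ids) {
    miss <- setdiff(ids, names(library))
    if (length(miss)) stop("subset names unknown reactions: ",
                           paste(miss, collapse = ", "))
    sub <- structure(library[ids], class = "reaction_library")
    fit_extents(delta, sub, ...)
  })
  obj <- vapply(fits, `[[`, numeric(1), "objective")
  size <- lengths(candidate_subsets)
  # objectives equal up to solver tolerance count as ties; parsimony decides
  scale <- sum(delta$d_species^2) + delta$d_other_soi^2
  key <- obj
  key[obj < 1e-12 * max(1, scale)] <- 0
  ord <- order(key, size)
  has_dispro <- vapply(candidate_subsets,
                       function(ids) any(dispro_ids %in% ids), logical(1))
  dispro <- NULL
  if (any(has_dispro) && any(!has_dispro)) {
    best_with <- min(obj[has_dispro])
    best_without <- min(obj[!has_dispro])
    dispro <- list(best_with = best_with, best_without = best_without,
                   improvement = best_without / max(best_with, .Machine$double.eps),
                   supported = best_without > dispro_factor * best_with)
  }
  ranking <- data.frame(
    rank = seq_along(ord),
    subset = vapply(candidate_subsets[ord], paste, character(1), collapse = "+"),
    objective = obj[ord],
    n_reactions = size[ord],
    stringsAsFactors = FALSE
  )
  structure(list(ranking = ranking, fits = fits[ord],
                 subsets = candidate_subsets[ord],
                 disproportionation = dispro),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model comparison>\n")
  print(x$ranking, row.names = FALSE)
  if (!is.null(x$disproportionation)) {
    d <- x$disproportionation
    cat("  disproportionation reactions ",
        if (d$supported) "supported" else "not required",
        " (objective improvement factor ",
        format(d$improvement, digits = 3), ")\n", sep = "")
  }
  invisible(x)
}
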