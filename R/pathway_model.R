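#' Build a pathway model from an extent fit and expression support
#'
#' Integrates a reaction-extent fit with expression support into a
#' per-condition pathway model: unsupported biotic reactions are dropped,
#' extents are refit on the retained subset, the observed change vector is
#' normalised into a net reaction, and the stoichiometrically predicted
#' proton change is compared with the observed one. A discrepancy note is
#' attached when the predicted and observed proton changes differ by more
#' than 10\% of the observed value. Failures to fit or normalise are
#' reported as notes, never silently.
#'
#' @param fit An \code{extent_fit} over \code{library}.
#' @param support A \code{\link{reaction_support}} data.frame over the same
#'   library.
#' @param delta The \code{delta_vector} the fit explains.
#' @param library A \code{reaction_library}.
#' @param condition Condition label.
#' @param net_target Passed to \code{\link{normalize_net_reaction}}.
#' @param proton_tol Relative proton-discrepancy threshold (default 0.1).
#' @param fit_tol Residual-norm tolerance (relative to the observation
#'   norm) above which a failure note is attached (default 0.05).
#' @param map Gene-to-reaction map used for compartment annotation.
#' @param ... Passed to the refit \code{\link{fit_extents}} call.
#' @return Object of class \code{pathway_model}.
#' @export
build_model <- function(fit, support, delta, library,
                        condition = "", net_target = "auto",
                        proton_tol = 0.1, fit_tol = 0.05,
                        map = gene_reaction_map(), ...) {
  stopifnot(inherits(fit, "extent_fit"), is.data.frame(support),
            inherits(delta, "delta_vector"))
  if (!setequal(support$reaction_id, names(library))) {
    stop("support table and library cover different reactions")
  }
  notes <- character(0)
  keep <- support$reaction_id[support$supported]
  dropped <- setdiff(names(library), keep)
  if (length(dropped)) {
    notes <- c(notes, paste0("dropped unsupported reactions: ",
                             paste(dropped, collapse = ", ")))
  }
  if (length(keep) == 0) {
    notes <- c(notes, "no supported reactions; empty model")
    return(structure(list(condition = condition, reactions = list(),
                          fit = NULL, net_reaction = NULL,
                          proton_predicted = 0,
                          proton_observed = delta$d_proton, notes = notes),
                     class = "pathway_model"))
  }
  sub <- structure(library[keep], class = "reaction_library")
  refit <- fit_extents(delta, sub, ...)
  obs_norm <- sqrt(sum(c(delta$d_species, delta$d_other_soi)^2))
  if (sqrt(refit$objective) > fit_tol * max(obs_norm, 1e-12)) {
    notes <- c(notes, sprintf(
      "retained subset does not fit the observed changes (residual norm %.3g vs observation norm %.3g)",
      sqrt(refit$objective), obs_norm))
  }
  net <- tryCatch(normalize_net_reaction(delta, net_target),
                  error = function(e) {
                    notes <<- c(notes, paste0("net reaction unavailable: ",
                                              conditionMessage(e)))
                    NULL
                  })
  p_pred <- predict_proton(refit, sub)
  p_obs <- delta$d_proton
  if (!is.na(p_obs) && abs(p_pred - p_obs) > proton_tol * abs(p_obs)) {
    notes <- c(notes, sprintf(
      "proton discrepancy: model predicts %+.2f mM H+ but %+.2f mM observed",
      p_pred, p_obs))
  }
  sup_i <- match(keep, support$reaction_id)
  reactions <- lapply(seq_along(keep), function(k) {
    id <- keep[k]
    list(reaction = library[[id]],
         extent = unname(refit$extents[id]),
         support = as.character(support$support[sup_i[k]]),
         basis = support$basis[sup_i[k]],
         location = support$compartment[sup_i[k]])
  })
  names(reactions) <- keep
  structure(list(condition = condition, reactions = reactions, fit = refit,
                 net_reaction = net, proton_predicted = p_pred,
                 proton_observed = p_obs, notes = notes),
            class = "pathway_model")
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("<pathway model> ", x$condition, "\n", sep = "")
  if (!is.null(x$net_reaction)) {
    cat("  net: ", reaction_string(x$net_reaction$reaction), "\n", sep = "")
  }
  for (r in x$reactions) {
    cat(sprintf("  %-9s %8.4f mM  [%s%s]  %s\n", r$reaction$id, r$extent,
                if (is.na(r$support)) r$basis else r$support,
                if (!is.na(r$location)) paste0(", ", r$location) else "",
                reaction_string(r$reaction)))
  }
  cat(sprintf("  H+ predicted %+.2f mM, observed %s\n", x$proton_predicted,
              if (is.na(x$proton_observed)) "n/a"
              else sprintf("%+.2f mM", x$proton_observed)))
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

# plain-list form of a model for JSON serialisation (lossless round trip)
model_to_list <- function(model) {
  list(
    condition = model$condition,
    reactions = lapply(model$reactions, function(r) list(
      id = r$reaction$id,
      equation = reaction_string(r$reaction),
      extent_mM = r$extent,
      support = if (is.na(r$support)) NULL else r$support,
      basis = r$basis,
      location = if (is.na(r$location)) NULL else r$location)),
    net_reaction = if (is.null(model$net_reaction)) NULL else list(
      equation = reaction_string(model$net_reaction$reaction),
      s_total_target = model$net_reaction$s_total_target,
      proton_coef = model$net_reaction$proton_coef,
      max_rounding_residual = max(model$net_reaction$rounding_residuals)),
    proton_ledger = list(predicted_mM = model$proton_predicted,
                         observed_mM = if (is.na(model$proton_observed)) NULL
                                       else model$proton_observed),
    objective = if (is.null(model$fit)) NULL else model$fit$objective,
    nullspace_dim = if (is.null(model$fit)) NULL else model$fit$nullspace_dim,
    notes = as.list(model$notes)
  )
}

#' Render a pathway model as a deterministic report
#'
#' Produces either a plain-text report (net reaction, extent table,
#' support table, proton ledger, notes, optional regression summary) or
#' the equivalent JSON document. Output is byte-identical across runs for
#' identical inputs.
#'
#' @param model A \code{pathway_model}.
#' @param slope_stats Optional output of
#'   \code{\link{proton_species_regression}} to echo.
#' @param format \code{"text"} or \code{"json"}.
#' @return Character vector of report lines (\code{"text"}) or a JSON
#'   string (\code{"json"}).
#' @export
render_report <- function(model, slope_stats = NULL,
                          format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    out <- model_to_list(model)
    if (!is.null(slope_stats)) out$regression <- slope_stats
    return(as.character(jsonlite::toJSON(out, auto_unbox = TRUE,
                                         pretty = TRUE, digits = NA)))
  }
  L <- c(paste0("Pathway model: ", model$condition), "")
  if (!is.null(model$net_reaction)) {
    L <- c(L, "Net observed reaction:",
           paste0("  ", reaction_string(model$net_reaction$reaction)),
           sprintf("  (normalised to %d produced S atoms; max rounding residual %.3f)",
                   model$net_reaction$s_total_target,
                   max(model$net_reaction$rounding_residuals)), "")
  }
  L <- c(L, "Reactions (extent mM | support | location):")
  for (r in model$reactions) {
    L <- c(L, sprintf("  %-9s %10.4f | %-10s | %-10s | %s", r$reaction$id,
                      r$extent, if (is.na(r$support)) r$basis else r$support,
                      if (is.na(r$location)) "-" else r$location,
                      reaction_string(r$reaction)))
  }
  L <- c(L, "", "Proton ledger:")
  L <- c(L, sprintf("  predicted %+.3f mM", model$proton_predicted))
  if (!is.na(model$proton_observed)) {
    L <- c(L, sprintf("  observed  %+.3f mM", model$proton_observed))
  }
  if (!is.null(slope_stats)) {
    L <- c(L, "", "Regression of [H+] on species pools:")
    for (i in seq_len(nrow(slope_stats))) {
      L <- c(L, sprintf("  %-12s slope %8.4f  R2 %.3f", slope_stats$pool[i],
                        slope_stats$slope[i], slope_stats$r_squared[i]))
    }
  }
  if (length(model$notes)) {
    L <- c(L, "", "Notes:", paste0("  - ", model$notes))
  }
  L
}

#' Proton-versus-pool linear regression summary
#'
#' Reporting-grade ordinary least squares of proton concentration against
#' each sulfur pool across a speciation series (slope and R squared only).
#'
#' @param series A \code{speciation_ts}.
#' @param pools Pools to regress against: species column names and/or
#'   \code{"other_soi"}.
#' @return data.frame with columns \code{pool}, \code{slope},
#'   \code{r_squared}, \code{p_value}.
#' @export
proton_species_regression <- function(series,
                                      pools = c("SO4^2-", "other_soi")) {
  stopifnot(inherits(series, "speciation_ts"))
  df <- series$data
  h <- ph_to_proton(df$pH)
  out <- data.frame(pool = pools, slope = NA_real_, r_squared = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(pools)) {
    x <- if (pools[i] == "other_soi") other_soi(series) else df[[pools[i]]]
    if (is.null(x)) stop("pool '", pools[i], "' not in series")
    m <- stats::lm(h ~ x)
    s <- summary(m)
    out$slope[i] <- stats::coef(m)[2]
    out$r_squared[i] <- s$r.squared
    out$p_value[i] <- s$coefficients[2, 4]
  }
  out
}
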