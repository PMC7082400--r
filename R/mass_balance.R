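#' Convert a species concentration to sulfur-atom millimolar
#'
#' Concentrations of multi-sulfur species are expressed throughout the
#' package in sulfur-atom units (mM-S): 1 mM sulfate is 1 mM-S while 1 mM
#' thiosulfate is 2 mM-S.
#'
#' @param species Species name (must carry at least one sulfur atom).
#' @param conc Concentration in mM (molecules).
#' @param registry Species registry.
#' @return Concentration in mM-S (\code{conc * n_S}).
#' @examples
#' to_mm_s("S2O3^2-", 1)  # 2 mM-S
#' @export
to_mm_s <- function(species, conc, registry = species_registry()) {
  stopifnot(all(conc >= 0))
  row <- species_row(species, registry)
  if (any(row$n_S == 0)) {
    stop("species ", paste(species[row$n_S == 0], collapse = ", "),
         " carries no sulfur; mM-S undefined")
  }
  conc * row$n_S
}

#' Build a speciation time series
#'
#' Wraps a per-day table of pH, total dissolved sulfur and species
#' concentrations. Columns: \code{day}, \code{pH}, \code{total_s} (mM-S,
#' the < 0.45 um total-S measurement), one column per measured species in
#' mM (molecule units), and optionally \code{S0_particulate} (mM-S of
#' undissolved substrate, tracked outside the dissolved mass balance).
#'
#' @param data data.frame as above; days must be strictly increasing,
#'   concentrations nonnegative, pH in (0, 9).
#' @param treatment One of \code{"S0"}, \code{"thiosulfate"}, \code{"other"}.
#' @param below_lod Optional logical data.frame (same shape as the species
#'   columns) flagging censored values stored as 0.
#' @return Object of class \code{speciation_ts}.
#' @export
speciation_ts <- function(data, treatment = c("S0", "thiosulfate", "other"),
                          below_lod = NULL) {
  treatment <- match.arg(treatment)
  stopifnot(is.data.frame(data), all(c("day", "pH", "total_s") %in% names(data)))
  if (any(diff(data$day) <= 0)) stop("days must be strictly increasing")
  if (any(data$pH <= 0 | data$pH >= 9)) stop("pH out of range (0, 9)")
  if (any(data$total_s < 0)) stop("total_s must be nonnegative")
  sp <- setdiff(names(data), c("day", "pH", "total_s"))
  for (s in sp) if (any(data[[s]] < 0)) stop("negative concentration in ", s)
  structure(list(treatment = treatment, data = data, below_lod = below_lod),
            class = "speciation_ts")
}

#' @export
print.speciation_ts <- function(x, ...) {
  cat("<speciation time series> treatment=", x$treatment, ", ",
      nrow(x$data), " records (days ", x$data$day[1], "-",
      x$data$day[nrow(x$data)], ")\n", sep = "")
  print(x$data, ...)
  invisible(x)
}

#' Read / write speciation tables
#'
#' CSV dialect: columns \code{day}, \code{pH}, \code{total_s_mM_S} or
#' \code{total_s_mg_L} (mg S per litre, converted with the sulfur atomic
#' mass 32.06), then one column per species in mM. Values below the limit
#' of detection may be written as the token \code{"<LOD"}; they are read as
#' 0 and flagged.
#'
#' @param path File path.
#' @param treatment Treatment label for the series.
#' @return A \code{speciation_ts}.
#' @export
read_speciation_csv <- function(path, treatment = "other") {
  raw <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if ("total_s_mM_S" %in% names(raw)) {
    names(raw)[names(raw) == "total_s_mM_S"] <- "total_s"
  } else if ("total_s_mg_L" %in% names(raw)) {
    raw$total_s <- as.numeric(raw$total_s_mg_L) / S_MOLAR_MASS
    raw$total_s_mg_L <- NULL
  } else stop("speciation CSV needs a total_s_mM_S or total_s_mg_L column")
  sp <- setdiff(names(raw), c("day", "pH", "total_s"))
  lod <- as.data.frame(matrix(FALSE, nrow(raw), length(sp),
                              dimnames = list(NULL, sp)))
  for (s in sp) {
    cens <- grepl("^\\s*<\\s*LOD\\s*$", as.character(raw[[s]]),
                  ignore.case = TRUE)
    v <- suppressWarnings(as.numeric(as.character(raw[[s]])))
    v[cens] <- 0
    if (any(is.na(v))) stop("non-numeric value in column ", s)
    raw[[s]] <- v
    lod[[s]] <- cens
  }
  speciation_ts(raw, treatment = treatment, below_lod = lod)
}

#' @rdname read_speciation_csv
#' @param ts A \code{speciation_ts} to write.
#' @export
write_speciation_csv <- function(ts, path) {
  df <- ts$data
  names(df)[names(df) == "total_s"] <- "total_s_mM_S"
  if (!is.null(ts$below_lod)) {
    for (s in names(ts$below_lod)) {
      if (s %in% names(df)) {
        df[[s]] <- ifelse(ts$below_lod[[s]], "<LOD", as.character(df[[s]]))
      }
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# treatment: ", ts$treatment), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Unresolved ("Other SOI") sulfur pool by difference
#'
#' Total dissolved sulfur minus the sulfur-atom sum of all individually
#' measured dissolved species. The dissolved pool is
#' \code{SO4^2-, S^2-, S2O3^2-, SO3^2-, S0} (colloidal); particulate S0 is
#' excluded because total aqueous S is the filtered (< 0.45 um) fraction.
#' Small negative results (measurement scatter) are clamped to zero with a
#' warning; deficits beyond \code{tol_neg} raise a mass-balance error.
#'
#' @param ts A \code{speciation_ts}, or a single-row data.frame/list with
#'   \code{total_s} and species entries.
#' @param tol_neg Largest tolerated deficit, default 5\% of \code{total_s}.
#' @param registry Species registry.
#' @return Numeric vector (one per record) of Other-SOI in mM-S.
#' @examples
#' rec <- data.frame(day = 5, pH = 1.5, total_s = 39, `SO4^2-` = 13.7,
#'                   check.names = FALSE)
#' other_soi(rec)  # 25.3
#' @export
other_soi <- function(ts, tol_neg = NULL, registry = species_registry()) {
  df <- if (inherits(ts, "speciation_ts")) ts$data else as.data.frame(ts,
    check.names = FALSE)
  present <- intersect(DISSOLVED_POOL, names(df))
  ssum <- rep(0, nrow(df))
  for (s in present) ssum <- ssum + to_mm_s(s, df[[s]], registry)
  out <- df$total_s - ssum
  tol <- if (is.null(tol_neg)) 0.05 * df$total_s else rep_len(tol_neg, nrow(df))
  bad <- out < -tol
  if (any(bad)) {
    stop("mass-balance violation: measured species exceed total S by ",
         format(max(-out[bad]), digits = 4), " mM-S (tolerance ",
         format(tol[which(bad)[1]], digits = 4), ") at day ",
         df$day[which(bad)[1]])
  }
  neg <- out < 0
  if (any(neg)) {
    warning("Other-SOI deficit within tolerance clamped to 0 at day(s) ",
            paste(df$day[neg], collapse = ", "))
    out[neg] <- 0
  }
  out
}

#' pH to proton concentration
#'
#' Interprets pH as -log10 of the proton concentration in mol/L (no
#' activity correction) and returns mM.
#'
#' @param pH Numeric pH value(s).
#' @return Proton concentration in mM: \code{10^(-pH) * 1000}.
#' @examples
#' ph_to_proton(3)    # 1 mM
#' ph_to_proton(1.5)  # 31.62 mM
#' @export
ph_to_proton <- function(pH) {
  stopifnot(all(is.finite(pH)))
  10^(-pH) * 1000
}

#' @rdname ph_to_proton
#' @param proton_mm Proton concentration in mM.
#' @export
proton_to_ph <- function(proton_mm) {
  stopifnot(all(proton_mm > 0))
  -log10(proton_mm / 1000)
}

#' Interval concentration-change vector
#'
#' Signed end-minus-start changes over an interval of a speciation series:
#' per measured species in mM-S (colloidal and particulate S0 are summed
#' into one \code{S0} entry), the proton change from pH, and the Other-SOI
#' change by difference.
#'
#' @param series A \code{speciation_ts}.
#' @param day_start,day_end Days present in the series.
#' @param registry Species registry.
#' @return Object of class \code{delta_vector}: list with \code{interval},
#'   \code{d_species} (named, mM-S), \code{d_proton} (mM), \code{d_other_soi}
#'   (mM-S).
#' @export
deltas <- function(series, day_start, day_end,
                   registry = species_registry()) {
  stopifnot(inherits(series, "speciation_ts"))
  df <- series$data
  i0 <- match(day_start, df$day); i1 <- match(day_end, df$day)
  if (is.na(i0) || is.na(i1)) {
    stop("day ", if (is.na(i0)) day_start else day_end,
         " not in series; available days: ", paste(df$day, collapse = ", "))
  }
  if (day_end <= day_start) stop("interval must be ordered: day_end > day_start")
  sp <- intersect(DISSOLVED_POOL, names(df))
  d <- stats::setNames(numeric(length(sp)), sp)
  for (s in sp) d[s] <- to_mm_s(s, df[[s]][i1], registry) -
                        to_mm_s(s, df[[s]][i0], registry)
  if ("S0_particulate" %in% names(df)) {
    part <- df$S0_particulate[i1] - df$S0_particulate[i0]
    if ("S0" %in% names(d)) d["S0"] <- d["S0"] + part
    else d <- c(d, S0 = part)
  }
  soi <- other_soi(series, registry = registry)
  delta_vector(interval = c(day_start, day_end), d_species = d,
               d_proton = ph_to_proton(df$pH[i1]) - ph_to_proton(df$pH[i0]),
               d_other_soi = soi[i1] - soi[i0])
}

#' @rdname deltas
#' @param interval Length-2 numeric \code{c(day_start, day_end)}.
#' @param d_species Named numeric vector of species changes in mM-S.
#' @param d_proton Proton change in mM (may be \code{NA} if unobserved).
#' @param d_other_soi Other-SOI change in mM-S.
#' @export
delta_vector <- function(interval = c(0, 1), d_species = numeric(0),
                         d_proton = NA_real_, d_other_soi = 0) {
  stopifnot(length(interval) == 2, interval[2] > interval[1])
  structure(list(interval = as.numeric(interval),
                 d_species = d_species,
                 d_proton = as.numeric(d_proton),
                 d_other_soi = as.numeric(d_other_soi)),
            class = "delta_vector")
}

#' @export
print.delta_vector <- function(x, ...) {
  cat("<delta vector> days ", x$interval[1], " -> ", x$interval[2], "\n", sep = "")
  for (s in names(x$d_species)) {
    cat(sprintf("  %-10s %+8.3f mM-S\n", s, x$d_species[[s]]))
  }
  cat(sprintf("  %-10s %+8.3f mM-S\n", "Other SOI", x$d_other_soi))
  if (!is.na(x$d_proton)) cat(sprintf("  %-10s %+8.3f mM\n", "H+", x$d_proton))
  invisible(x)
}
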