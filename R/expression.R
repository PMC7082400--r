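FPKM_CATEGORIES <- c("none_low", "low", "medium", "high", "very_high")

#' Categorise FPKM values into the five expression bins
#'
#' Bins: below 200 is interpreted as low-to-no expression
#' (\code{none_low}); 200-1,000 \code{low}; 1,000-4,000 \code{medium};
#' 4,000-10,000 \code{high}; above 10,000 \code{very_high}. A shared edge
#' belongs to the lower bin (upper-edge inclusive), so 10,000 is
#' \code{high} and anything strictly above is \code{very_high}; the data
#' never sit exactly on an edge, so this convention is a documented choice.
#'
#' @param fpkm Nonnegative numeric vector of FPKM values.
#' @return Ordered factor with levels
#'   \code{none_low < low < medium < high < very_high}.
#' @examples
#' categorize_fpkm(c(150, 5000, 10000, 10001))
#' @export
categorize_fpkm <- function(fpkm) {
  if (any(is.na(fpkm)) || any(fpkm < 0)) stop("FPKM values must be nonnegative")
  lev <- ifelse(fpkm < 200, "none_low",
         ifelse(fpkm <= 1000, "low",
         ifelse(fpkm <= 4000, "medium",
         ifelse(fpkm <= 10000, "high", "very_high"))))
  factor(lev, levels = FPKM_CATEGORIES, ordered = TRUE)
}

#' Log2 expression ratio
#'
#' \code{log2((num + pc) / (den + pc))} with a pseudocount guarding zeros.
#' Values are returned unclipped; \code{\link{clip_log2}} applies the
#' +/- 6 display clip used in heatmap-style comparisons.
#'
#' @param fpkm_num,fpkm_den Nonnegative FPKM values.
#' @param pseudocount Positive pseudocount, default 1.
#' @return Unclipped log2 ratio(s).
#' @examples
#' log2_ratio(1600, 800, pseudocount = 1e-9)  # ~1
#' @export
log2_ratio <- function(fpkm_num, fpkm_den, pseudocount = 1) {
  stopifnot(all(fpkm_num >= 0), all(fpkm_den >= 0), pseudocount > 0)
  log2((fpkm_num + pseudocount) / (fpkm_den + pseudocount))
}

#' @rdname log2_ratio
#' @param x Log2 ratios.
#' @param limit Display clip magnitude, default 6.
#' @export
clip_log2 <- function(x, limit = 6) pmin(limit, pmax(-limit, x))

#' Expression profile for one condition
#'
#' @param entries data.frame with columns \code{gene}, \code{copy},
#'   \code{fpkm}; (gene, copy) pairs must be unique and FPKM nonnegative.
#' @param condition Condition label, e.g. \code{"S0_pH2.5_day3"}.
#' @return Object of class \code{expression_profile}.
#' @export
expression_profile <- function(entries, condition) {
  stopifnot(is.data.frame(entries),
            all(c("gene", "copy", "fpkm") %in% names(entries)))
  if (any(entries$fpkm < 0)) stop("FPKM values must be nonnegative")
  key <- paste(entries$gene, entries$copy)
  if (anyDuplicated(key)) stop("duplicate (gene, copy) entries: ",
                               key[duplicated(key)][1])
  structure(list(condition = condition,
                 entries = entries[, c("gene", "copy", "fpkm")]),
            class = "expression_profile")
}

#' Read / write FPKM tables
#'
#' TSV dialect: columns \code{gene}, \code{copy}, \code{condition},
#' \code{fpkm}.
#'
#' @param path File path.
#' @return A named list of \code{expression_profile}, one per condition.
#' @export
read_fpkm_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "copy", "condition", "fpkm") %in% names(df)))
  conds <- unique(df$condition)
  stats::setNames(lapply(conds, function(cc) {
    expression_profile(df[df$condition == cc, ], condition = cc)
  }), conds)
}

#' @rdname read_fpkm_tsv
#' @param profiles List of \code{expression_profile} objects.
#' @export
write_fpkm_tsv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    cbind(p$entries[, c("gene", "copy")], condition = p$condition,
          fpkm = p$entries$fpkm)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate FPKM across gene copies
#'
#' Multi-copy genes (e.g. three sdo copies, two rhd copies, three hdrA
#' copies) are summarised by one number per gene: the default \code{max}
#' treats a pathway as available if any copy is expressed; \code{sum} and
#' \code{mean} support sensitivity analysis.
#'
#' @param profile An \code{expression_profile}.
#' @param gene Gene name.
#' @param method One of \code{"max"}, \code{"sum"}, \code{"mean"}.
#' @return Aggregated FPKM.
#' @export
aggregate_copies <- function(profile, gene, method = c("max", "sum", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "expression_profile"))
  v <- profile$entries$fpkm[profile$entries$gene == gene]
  if (length(v) == 0) stop("gene '", gene, "' not in profile for condition '",
                           profile$condition, "'")
  switch(method, max = max(v), sum = sum(v), mean = mean(v))
}

#' Default gene-to-enzyme-to-reaction map
#'
#' Maps the sulfur-metabolism enzymes of \emph{A. thiooxidans}-type
#' organisms to the library reactions they catalyse, with compartment
#' annotations. Sox covers the two operon copies; Sdo three copies; Rhd
#' two; the Hdr-like complex hdrA x3, hdrB, hdrC. TetH is mapped to
#' tetrathionate oxidation and hydrolysis and, as an open candidate
#' (alongside DoxD), to thiosulfate-to-tetrathionate conversion, since
#' which protein catalyses that step is unresolved.
#'
#' @return Named list of enzyme entries: \code{genes}, \code{reactions},
#'   \code{compartment}, optional \code{note}.
#' @export
gene_reaction_map <- function() {
  list(
    Sox = list(genes = c("sox-1", "sox-2"),
               reactions = c("F1.sox", "T3.eq4f", "T3.eq4r"),
               compartment = "periplasm"),
    TetH = list(genes = "tetH",
                reactions = c("T3.eq6", "T3.eq10", "T3.eq5"),
                compartment = "periplasm",
                note = "T3.eq5 assignment is a candidate (possible reverse activity); DoxD or an unknown protein may catalyse it instead"),
    DoxD = list(genes = "doxD", reactions = "T3.eq5",
                compartment = "membrane"),
    Sqr = list(genes = "sqr", reactions = "F1.sqr",
               compartment = "membrane"),
    Sdo = list(genes = c("sdo-1", "sdo-2", "sdo-3"), reactions = "T3.eq2",
               compartment = "cytoplasm"),
    Sor = list(genes = "sor", reactions = "T3.eq2",
               compartment = "cytoplasm"),
    Rhd = list(genes = c("rhd-1", "rhd-2"),
               reactions = c("T3.eq4f", "T3.eq4r"),
               compartment = "cytoplasm"),
    Hdr = list(genes = c("hdrA-1", "hdrA-2", "hdrA-3", "hdrB", "hdrC"),
               reactions = "T3.eq2", compartment = "cytoplasm"),
    Aps = list(genes = "aps", reactions = "T3.eq9",
               compartment = "cytoplasm"),
    Paps = list(genes = "paps", reactions = "T3.eq9",
                compartment = "cytoplasm")
  )
}

#' Read a gene-to-reaction map from JSON
#'
#' @param path JSON file mirroring the structure of
#'   \code{\link{gene_reaction_map}}.
#' @return Named list of enzyme entries.
#' @export
read_gene_reaction_map <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(m, function(e) {
    e$genes <- as.character(unlist(e$genes))
    e$reactions <- as.character(unlist(e$reactions))
    e
  })
}

#' Score reaction support from an expression profile
#'
#' Each mapped reaction receives the expression category of its
#' best-expressed catalysing enzyme (enzyme FPKM = max over its genes,
#' each gene aggregated over copies). Reactions whose every catalyst falls
#' below the support threshold are flagged unsupported unless the reaction
#' can proceed abiotically; library reactions with no mapped enzyme are
#' retained as \code{"abiotic/unknown"}. The result is invariant to the
#' order of profile entries.
#'
#' @param profile An \code{expression_profile}.
#' @param map Gene-to-reaction map (default \code{\link{gene_reaction_map}}).
#' @param library A \code{reaction_library}.
#' @param threshold_category Highest category still counted as unsupported
#'   (default \code{"none_low"}: a catalyst must reach at least
#'   \code{"low"}, i.e. 200 FPKM).
#' @param aggregate Copy-aggregation method, see
#'   \code{\link{aggregate_copies}}.
#' @return data.frame with columns \code{reaction_id}, \code{support}
#'   (ordered factor or NA for unmapped), \code{basis}
#'   (expressed/abiotic/unsupported/abiotic_unknown), \code{supported}
#'   (logical), \code{best_enzyme}, \code{compartment}.
#' @export
reaction_support <- function(profile, map = gene_reaction_map(),
                             library = load_reaction_library(),
                             threshold_category = "none_low",
                             aggregate = "max") {
  stopifnot(inherits(profile, "expression_profile"))
  threshold_category <- match.arg(threshold_category, FPKM_CATEGORIES)
  thr <- factor(threshold_category, levels = FPKM_CATEGORIES, ordered = TRUE)
  enz_fpkm <- vapply(map, function(e) {
    v <- vapply(e$genes, function(g) {
      if (any(profile$entries$gene == g)) {
        aggregate_copies(profile, g, aggregate)
      } else 0
    }, numeric(1))
    max(v)
  }, numeric(1))
  enz_cat <- categorize_fpkm(enz_fpkm)
  out <- data.frame(reaction_id = names(library), support = NA_character_,
                    basis = NA_character_, supported = FALSE,
                    best_enzyme = NA_character_,
                    compartment = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(library)) {
    id <- names(library)[i]
    enzymes <- names(map)[vapply(map, function(e) id %in% e$reactions,
                                 logical(1))]
    if (length(enzymes) == 0) {
      out$basis[i] <- "abiotic_unknown"
      out$supported[i] <- isTRUE(library[[i]]$abiotic_possible)
      next
    }
    best <- enzymes[which.max(as.integer(enz_cat[enzymes]))]
    cat_best <- enz_cat[[best]]
    out$support[i] <- as.character(cat_best)
    out$best_enzyme[i] <- best
    out$compartment[i] <- map[[best]]$compartment
    if (cat_best > thr) {
      out$basis[i] <- "expressed"
      out$supported[i] <- TRUE
    } else if (isTRUE(library[[i]]$abiotic_possible)) {
      out$basis[i] <- "abiotic"
      out$supported[i] <- TRUE
    } else {
      out$basis[i] <- "unsupported"
      out$supported[i] <- FALSE
    }
  }
  out$support <- factor(out$support, levels = FPKM_CATEGORIES, ordered = TRUE)
  out
}

#' Pairwise log2 comparison table for two conditions
#'
#' Mirrors heatmap-style pairwise comparisons: per gene, the log2 ratio of
#' aggregated FPKM between two conditions, with the +/- 6 display clip in a
#' separate column.
#'
#' @param profile_num,profile_den \code{expression_profile} objects
#'   (numerator and denominator conditions).
#' @param pseudocount,aggregate See \code{\link{log2_ratio}} and
#'   \code{\link{aggregate_copies}}.
#' @return data.frame: gene, condition_pair, log2_ratio, clipped_value.
#' @export
expression_comparison <- function(profile_num, profile_den, pseudocount = 1,
                                  aggregate = "max") {
  genes <- intersect(unique(profile_num$entries$gene),
                     unique(profile_den$entries$gene))
  lr <- vapply(genes, function(g) {
    log2_ratio(aggregate_copies(profile_num, g, aggregate),
               aggregate_copies(profile_den, g, aggregate), pseudocount)
  }, numeric(1))
  data.frame(gene = genes,
             condition_pair = paste0(profile_num$condition, "/",
                                     profile_den$condition),
             log2_ratio = lr,
             clipped_value = clip_log2(lr),
             stringsAsFactors = FALSE)
}
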