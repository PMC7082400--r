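#' Run the full analysis pipeline
#'
#' End-to-end orchestration: load the reaction library and species data,
#' compute the Other-SOI mass balance and interval change vectors, fit
#' nonnegative reaction extents, normalise the net reaction, score
#' expression support (when an FPKM table is supplied), assemble the
#' pathway model and write all artifacts to the output directory. The run
#' is deterministic for a fixed config and seed; the log records the
#' package version, seed and a hash of the configuration.
#'
#' @param config Either a named list or the path to a JSON config file.
#'   Recognised fields: \code{speciation_csv} (required),
#'   \code{treatment}, \code{condition}, \code{fpkm_tsv} (optional; when
#'   absent a chemistry-only model is built), \code{library_json},
#'   \code{map_json}, \code{interval} (length-2 days; default first and
#'   last), \code{out_dir} (required), \code{net_target},
#'   \code{proton_weight}, \code{l1}, \code{support_threshold},
#'   \code{seed}.
#' @return The \code{pathway_model}, invisibly. Stage failures raise
#'   errors naming the stage; artifacts written before the failure are
#'   retained.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  need <- function(field) {
    if (is.null(config[[field]])) stop("config is missing '", field, "'")
    config[[field]]
  }
  getd <- function(field, default) {
    if (is.null(config[[field]])) default else config[[field]]
  }
  out_dir <- need("out_dir")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- getd("seed", 20200313)
  cfg_hash <- sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 1e9
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    stage, msg)
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf(name, paste0("FAILED: ", conditionMessage(e)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cat("", file = log_path)  # truncate
  logf("init", sprintf("thiostoich %s | seed %d | config hash %d",
                       as.character(utils::packageVersion("thiostoich")),
                       as.integer(seed), as.integer(cfg_hash)))
  set.seed(seed)

  library_ <- stage("load_library", load_reaction_library(getd("library_json", NULL)))
  series <- stage("load_speciation",
                  read_speciation_csv(need("speciation_csv"),
                                      treatment = getd("treatment", "other")))
  logf("load", sprintf("%d records, %d library reactions",
                       nrow(series$data), length(library_)))

  iv <- getd("interval", range(series$data$day))
  delta <- stage("deltas", deltas(series, iv[1], iv[2]))
  jsonlite::write_json(list(interval = delta$interval,
                            d_species = as.list(delta$d_species),
                            d_proton = delta$d_proton,
                            d_other_soi = delta$d_other_soi),
                       file.path(out_dir, "deltas.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  weights <- NULL
  pw <- getd("proton_weight", NULL)
  if (!is.null(pw)) weights <- c("H+" = pw)
  fit <- stage("fit_extents",
               fit_extents(delta, library_, weights = weights,
                           l1 = getd("l1", 0)))
  jsonlite::write_json(list(interval = delta$interval,
                            extents = as.list(fit$extents),
                            residuals = as.list(fit$residual),
                            objective = fit$objective,
                            proton_predicted = predict_proton(fit, library_),
                            proton_observed = delta$d_proton,
                            null_space_dim = fit$nullspace_dim),
                       file.path(out_dir, "extent_fit.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("fit", sprintf("objective %.4g, null-space dim %d", fit$objective,
                      fit$nullspace_dim))

  net <- stage("net_reaction",
               normalize_net_reaction(delta, getd("net_target", "auto")))
  writeLines(reaction_string(net$reaction),
             file.path(out_dir, "net_reaction.txt"))

  chem_only <- is.null(config$fpkm_tsv)
  if (chem_only) {
    support <- data.frame(reaction_id = names(library_),
                          support = factor(NA, levels = FPKM_CATEGORIES,
                                           ordered = TRUE),
                          basis = "absent", supported = TRUE,
                          best_enzyme = NA_character_,
                          compartment = NA_character_,
                          stringsAsFactors = FALSE)
    logf("expression", "no FPKM table; chemistry-only model")
  } else {
    map <- if (is.null(config$map_json)) gene_reaction_map()
           else read_gene_reaction_map(config$map_json)
    profiles <- stage("load_fpkm", read_fpkm_tsv(config$fpkm_tsv))
    cond <- getd("condition", names(profiles)[1])
    if (!(cond %in% names(profiles))) {
      stop("condition '", cond, "' not in FPKM table (has: ",
           paste(names(profiles), collapse = ", "), ")")
    }
    support <- stage("reaction_support",
                     reaction_support(profiles[[cond]], map = map,
                                      library = library_,
                                      threshold_category =
                                        getd("support_threshold", "none_low")))
    utils::write.table(support, file.path(out_dir, "support.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  model <- stage("build_model",
                 build_model(fit, support, delta, library_,
                             condition = getd("condition",
                                              series$treatment),
                             net_target = getd("net_target", "auto")))
  if (chem_only) model$notes <- c(model$notes, "expression data absent")
  writeLines(render_report(model, format = "json"),
             file.path(out_dir, "model.json"))
  writeLines(render_report(model, format = "text"),
             file.path(out_dir, "report.txt"))
  logf("done", sprintf("%d reactions retained; artifacts in %s",
                       length(model$reactions), out_dir))
  invisible(model)
}
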