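# End-to-end orchestration: clean -> bioregions -> sympatry -> size
# divergence -> comparative fits & dispersion -> richness correlates, from
# one validated configuration, with per-stage seeds and a reproducibility
# manifest of content digests.

.pipeline_defaults <- function() list(
  occurrences = NULL, ranges = NULL, tree = NULL, traits = NULL,
  elevation = NULL, biomes = NULL, output_dir = NULL,
  threshold_km = 5, min_points = 10, symmetrize = FALSE,
  max_deg = 4, min_deg = 2, max_capacity = 100, min_capacity = 10,
  k_classes = 3, breaks = NULL, neutral_band = 0, include_focal = FALSE,
  n_null = 999, seed = 1
)

#' Validate a pipeline configuration
#'
#' Accepts a named list or a YAML file path; unknown keys are rejected,
#' referenced input files must exist, and parameters must lie in their
#' documented bounds. Defaults are filled in and echoed into the manifest.
#'
#' @param config named list or path to a YAML file.
#' @return validated config list with all defaults resolved.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- .pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  for (key in c("occurrences", "tree", "traits")) {
    if (is.null(cfg[[key]]))
      stop(sprintf("config requires '%s'", key), call. = FALSE)
  }
  for (key in c("occurrences", "ranges", "tree", "traits", "elevation",
                "biomes")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop(sprintf("input file for '%s' not found: %s", key, cfg[[key]]),
           call. = FALSE)
  }
  if (is.null(cfg$output_dir)) stop("config requires 'output_dir'", call. = FALSE)
  if (cfg$threshold_km <= 0 || cfg$min_points < 1 || cfg$n_null < 1 ||
      cfg$neutral_band < 0 || cfg$k_classes < 2)
    stop("parameter out of bounds", call. = FALSE)
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

.write_output <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order from a validated configuration:
#' input reading and species reconciliation, occurrence cleaning against
#' ranges (when supplied), quadtree binning and bioregion detection,
#' per-region summaries and richness correlates, the directed sympatry
#' matrix, size classification and divergent sympatry with its composition
#' tests, BM/OU/EB and lambda fits, ancestral states, PGLS residuals and
#' their correlation with divergent sympatry, and MPD dispersion per
#' bioregion. Any stage failure halts with a stage-named error. All report
#' tables are written as CSV under `output_dir`, together with a JSON
#' manifest of the configuration, per-stage seeds and output digests.
#'
#' @param config named list or YAML path (see [pipeline_config()]).
#' @return invisibly, a list with the manifest and all in-memory stage
#'   results.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(bioregions = child_seed(cfg$seed, "bioregions"),
                dispersion = child_seed(cfg$seed, "dispersion"))
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }

  note("reading inputs")
  occ <- .stage("read", read_occurrences(cfg$occurrences))
  tree <- .stage("read", read_tree(cfg$tree))
  traits <- .stage("read", read_traits(cfg$traits))
  ranges <- if (!is.null(cfg$ranges)) .stage("read", read_ranges(cfg$ranges))
  elev <- if (!is.null(cfg$elevation)) .stage("read", read_raster(cfg$elevation))
  biome <- if (!is.null(cfg$biomes)) .stage("read", read_raster(cfg$biomes))

  cleaning <- NULL
  if (!is.null(ranges)) {
    cleaning <- .stage("clean", filter_by_range(occ, ranges))
    occ <- cleaning$occurrences
    note("cleaning removed %d records, %d unfilterable",
         sum(cleaning$report$removed), sum(cleaning$report$unfilterable))
  } else note("no ranges supplied; cleaning skipped")

  recon <- .stage("reconcile", reconcile_species(occ, tree, traits))
  note("species reconciliation: %d shared; orphans occ=%d tree=%d traits=%d",
       length(recon$shared), length(recon$orphans$occurrences),
       length(recon$orphans$tree), length(recon$orphans$traits))

  cls <- .stage("classify", classify_sizes(traits, k = cfg$k_classes,
                                           breaks = cfg$breaks))
  note("size classes: breaks at %s mm",
       paste(format(cls$breaks, digits = 5), collapse = ", "))

  cells <- .stage("bioregions", quadtree_bin(occ, cfg$max_deg, cfg$min_deg,
                                             cfg$max_capacity, cfg$min_capacity))
  net <- .stage("bioregions", build_bipartite(cells, occ))
  assignment <- .stage("bioregions", detect_bioregions(net, seed = seeds$bioregions))
  summaries <- .stage("bioregions", summarize_bioregions(assignment, cells,
                                                         elev, biome, cls))
  note("%d bioregions over %d cells", assignment$n_regions, nrow(cells$cells))

  correlates <- .stage("correlates", tryCatch(richness_correlates(summaries),
                                              error = function(e) NULL))
  if (is.null(correlates)) note("richness correlates skipped (too few regions)")
  if (is.null(elev)) note("no elevation raster; elevation covariate undefined")

  symp <- .stage("sympatry", sympatry_matrix(occ, cfg$threshold_km,
                                             cfg$min_points, cfg$symmetrize))
  note("sympatry: %d directed calls (threshold %.3g km, min %d points%s)",
       sum(symp$S, na.rm = TRUE), cfg$threshold_km, cfg$min_points,
       if (cfg$symmetrize) ", symmetrized" else "")

  divergence <- .stage("divergence",
                       divergent_sympatry_all(symp, cls, cfg$include_focal))
  note("divergence: %d of %d species defined (pool %s focal)",
       sum(divergence$defined), nrow(divergence),
       if (cfg$include_focal) "includes" else "excludes")
  sign_tests <- lapply(cls$class_names, function(cl) {
    tryCatch(sign_category_test(divergence, cl, cfg$neutral_band),
             error = function(e) NULL)
  })
  names(sign_tests) <- cls$class_names
  composition <- .stage("divergence", bioregion_size_composition(assignment, cls))

  shared <- recon$shared
  tr_shared <- if (length(setdiff(tree$tip.label, shared)))
    ape::keep.tip(tree, intersect(tree$tip.label, shared)) else tree
  fits <- .stage("comparative", list(
    bm = bm_fit(tr_shared, traits),
    ou = ou_fit(tr_shared, traits),
    eb = eb_fit(tr_shared, traits),
    lambda = pagels_lambda(tr_shared, traits)
  ))
  anc <- .stage("comparative", ancestral_states_bm(tr_shared, traits))
  resid <- .stage("comparative", pgls_residuals(tr_shared, traits))
  div_ok <- divergence[divergence$defined &
                         divergence$focal %in% names(resid), , drop = FALSE]
  resid_cor <- if (nrow(div_ok) >= 3)
    correlate(resid[div_ok$focal], div_ok$signed_score, "pearson")
  note("comparative: BM logLik %.2f sigma2 %.3g; lambda %.3g",
       fits$bm$log_likelihood, fits$bm$sigma2, fits$lambda$lambda)

  assemblages <- lapply(assignment$region_species, intersect, tree$tip.label)
  assemblages <- assemblages[lengths(assemblages) >= 2]
  dispersion <- if (length(assemblages))
    .stage("dispersion", mpd_ses(assemblages, tree, cfg$n_null,
                                 seed = seeds$dispersion))

  # -- reports ---------------------------------------------------------
  outs <- list()
  cell_table <- cells$cells
  cell_table$region <- assignment$cell_region[cell_table$cell_id]
  outs$cells <- .write_output(cell_table, cfg$output_dir, "cells.csv")
  outs$network <- .write_output(net$edges, cfg$output_dir, "network_edges.csv")
  outs$regions <- .write_output(summaries, cfg$output_dir, "region_summary.csv")
  outs$sympatry <- .write_output(sympatry_table(symp), cfg$output_dir,
                                 "sympatry.csv")
  outs$divergence <- .write_output(divergence, cfg$output_dir, "divergence.csv")
  fit_table <- data.frame(
    model = c("BM", "OU", "EB", "lambda"),
    log_likelihood = c(fits$bm$log_likelihood, fits$ou$log_likelihood,
                       fits$eb$log_likelihood, fits$lambda$log_likelihood),
    sigma2 = c(fits$bm$sigma2, fits$ou$sigma2, fits$eb$sigma2,
               fits$lambda$sigma2),
    parameter = c(NA, fits$ou$alpha, fits$eb$r, fits$lambda$lambda),
    root_state = c(fits$bm$root_state, fits$ou$root_state,
                   fits$eb$root_state, fits$lambda$root_state),
    converged = c(fits$bm$converged, fits$ou$converged, fits$eb$converged,
                  TRUE))
  outs$fits <- .write_output(fit_table, cfg$output_dir, "fits.csv")
  if (!is.null(dispersion))
    outs$mpd <- .write_output(as.data.frame(dispersion), cfg$output_dir,
                              "mpd.csv")
  if (!is.null(correlates))
    outs$correlates <- .write_output(correlates, cfg$output_dir,
                                     "correlates.csv")
  comp_table <- do.call(rbind, lapply(composition, function(ct) data.frame(
    unit = ct$unit, chi2 = ct$chi2, df = ct$df, p_value = ct$p_value,
    tested = isTRUE(ct$tested))))
  outs$composition <- .write_output(comp_table, cfg$output_dir,
                                    "region_composition.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("sympatria")),
    config = cfg[!vapply(cfg, is.null, TRUE)],
    seeds = seeds,
    exclusions = recon$orphans,
    stage_order = c("read", "clean", "reconcile", "classify", "bioregions",
                    "correlates", "sympatry", "divergence", "comparative",
                    "dispersion", "report"),
    input_digests = as.list(tools::md5sum(unlist(
      cfg[c("occurrences", "ranges", "tree", "traits", "elevation", "biomes")],
      use.names = TRUE))),
    output_digests = as.list(tools::md5sum(unlist(outs))),
    log = log_lines
  )
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(manifest = manifest, config = cfg, occurrences = occ,
                 cleaning = cleaning, reconciliation = recon,
                 classification = cls, cells = cells, network = net,
                 assignment = assignment, summaries = summaries,
                 correlates = correlates, sympatry = symp,
                 divergence = divergence, sign_tests = sign_tests,
                 composition = composition, fits = fits,
                 ancestral = anc, residuals = resid,
                 residual_correlation = resid_cor,
                 dispersion = dispersion, outputs = outs))
}

#' Simulate a data set and run the pipeline on it
#'
#' Generates synthetic inputs under a [sim_config()] (optionally with a
#' planted co-occurrence design), writes them to `dir`, then runs
#' [run_pipeline()] on the written files. This is the end-to-end harness
#' used by the test suite.
#'
#' @param sim a [sim_config()].
#' @param dir working directory for generated inputs and outputs.
#' @param design optional design passed to [simulate_dataset()]
#'   ("divergent", "assorted" or "none").
#' @param ... pipeline parameter overrides (threshold_km, n_null, ...).
#' @return the [run_pipeline()] result list.
#' @export
simulate_and_run <- function(sim = sim_config(), dir = tempfile("simrun"),
                             design = NULL, ...) {
  data_dir <- file.path(dir, "data")
  dat <- simulate_dataset(sim, dir = data_dir, design = design)
  overrides <- list(...)
  cfg <- utils::modifyList(list(
    occurrences = dat$files$occurrences,
    ranges = dat$files$ranges,
    tree = dat$files$tree,
    traits = dat$files$traits,
    elevation = dat$files$elevation,
    biomes = dat$files$biome,
    output_dir = file.path(dir, "out"),
    seed = sim$seed
  ), overrides)
  run_pipeline(cfg)
}
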