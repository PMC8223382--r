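#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: exactly one input source
#' (a child-table path or a synthetic configuration), the covariate schema,
#' decomposition settings, meta-analysis options and the output directory.
#'
#' @param input_path path to a child-level CSV, or `NULL` when simulating.
#' @param synthetic a [synthetic_config()], or `NULL` when reading a file.
#' @param schema a [covariate_schema()]; defaults to the synthetic config's
#'   schema or [default_schema()].
#' @param decomposition a [decomposition_spec()].
#' @param metric meta-analysis metric, `"rd"` or `"log_or"`.
#' @param prevalence_threshold quadrant cut for
#'   [classify_inequality()]; `NULL` = pooled prevalence.
#' @param out_dir output directory (created if missing).
#' @param force_decompose decompose every country rather than only those
#'   classified pro-illiterate.
#' @param neighbourhood_ses attach the PCA-based neighbourhood SES quintile
#'   before analysis (requires wealth and employment factors).
#' @param sep field separator of the input file.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_path = NULL, synthetic = NULL,
                            schema = NULL,
                            decomposition = decomposition_spec(n_replications = 200L),
                            metric = c("rd", "log_or"),
                            prevalence_threshold = NULL,
                            out_dir = "results",
                            force_decompose = FALSE,
                            neighbourhood_ses = TRUE,
                            sep = ",") {
  if (is.null(input_path) == is.null(synthetic)) {
    stop("exactly one of input_path / synthetic must be given")
  }
  if (is.null(schema)) {
    schema <- if (!is.null(synthetic)) synthetic$schema else default_schema()
  }
  structure(list(
    input_path = input_path, synthetic = synthetic, schema = schema,
    decomposition = decomposition, metric = match.arg(metric),
    prevalence_threshold = prevalence_threshold, out_dir = out_dir,
    force_decompose = isTRUE(force_decompose),
    neighbourhood_ses = isTRUE(neighbourhood_ses), sep = sep
  ), class = "pipeline_config")
}

#' Run the full inequality pipeline
#'
#' Reads or simulates the child table, optionally attaches the
#' neighbourhood SES quintile, computes per-country prevalences and risk
#' differences, pools them by fixed- and random-effects meta-analysis,
#' computes Mantel-Haenszel pooled odds ratios with a homogeneity test,
#' classifies countries into the prevalence x inequality quadrants, and
#' runs the nonlinear decomposition for every country flagged
#' pro-illiterate (or all, when forced). All numeric artifacts are written
#' under `out_dir`; identical configuration and seed give identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every computed object (`records`,
#'   `effects`, `meta`, `mh`, `classes`, `decompositions`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  schema <- config$schema
  if (!is.null(config$synthetic)) {
    sim <- generate_children(config$synthetic)
    records <- sim$records
  } else {
    records <- read_child_table(config$input_path, schema, sep = config$sep)
  }
  ses <- NULL
  if (config$neighbourhood_ses &&
      all(c("wealth", "employment") %in% names(records))) {
    ses_out <- compute_neighbourhood_ses(records)
    records <- ses_out$records
    ses <- ses_out$clusters
    if (!"neighbourhood_ses" %in% names(schema)) {
      sch_list <- lapply(unclass(schema), function(f) f$categories)
      sch_list$neighbourhood_ses <- as.character(1:5)
      attr(sch_list, "class") <- NULL
      schema <- covariate_schema(sch_list)
    }
  }

  effects <- country_effects(records)
  meta <- meta_fixed_random(effects, metric = config$metric)
  mh <- mantel_haenszel_or(country_strata(records))
  classes <- classify_inequality(effects, config$prevalence_threshold)
  forest <- forest_table(effects, meta, classes)

  targets <- if (config$force_decompose) {
    effects$country_id[effects$computable]
  } else {
    classes$country_id[classes$label == "pro_illiterate"]
  }
  factors <- intersect(names(schema), names(records))
  decompositions <- list()
  for (cid in targets) {
    cc <- records[records$country_id == cid, , drop = FALSE]
    samples <- fairlie_samples(cc, schema, factors)
    decompositions[[cid]] <- decompose(samples$sample_I, samples$sample_L,
                                       config$decomposition)
  }

  files <- c(forest = file.path(config$out_dir, "forest.csv"),
             meta = file.path(config$out_dir, "meta_summary.json"),
             manifest = file.path(config$out_dir, "manifest.json"))
  utils::write.csv(forest, files[["forest"]], row.names = FALSE)
  if (!is.null(ses)) {
    files[["cluster_ses"]] <- file.path(config$out_dir, "cluster_ses.csv")
    utils::write.csv(ses, files[["cluster_ses"]], row.names = FALSE)
  }
  jsonlite::write_json(list(
    metric = meta$metric,
    fixed_effect = meta$fixed_effect, fixed_ci = meta$fixed_ci,
    random_effect = meta$random_effect, random_ci = meta$random_ci,
    Q = meta$Q, df = meta$df, tau2 = meta$tau2, i2 = meta$i2,
    mh_or = mh$or, mh_ci = mh$ci, mh_p = mh$p,
    mh_homogeneity_chi2 = mh$chi2_homogeneity,
    mh_homogeneity_df = mh$df, mh_homogeneity_p = mh$p_homogeneity
  ), files[["meta"]], auto_unbox = TRUE, digits = NA)
  for (cid in names(decompositions)) {
    f <- file.path(config$out_dir, paste0("decomposition_", cid, ".csv"))
    write_decomposition_csv(decompositions[[cid]], f)
    files[[paste0("decomposition_", cid)]] <- f
  }
  manifest <- list(
    seed = config$decomposition$seed,
    n_records = nrow(records),
    n_countries = length(unique(records$country_id)),
    metric = config$metric,
    n_replications = config$decomposition$n_replications,
    decomposed_countries = as.list(names(decompositions)),
    input = if (is.null(config$input_path)) "synthetic" else config$input_path,
    package_version = as.character(utils::packageVersion("ineqdecomp"))
  )
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(list(records = records, effects = effects, meta = meta, mh = mh,
                 classes = classes, forest = forest,
                 decompositions = decompositions, cluster_ses = ses,
                 files = files))
}
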