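#' Run the full immune-risk pipeline
#'
#' Executes every stage in order: preprocessing, differential expression,
#' gene-lncRNA pair screening, per-population and integrated network
#' construction, power-law degree analysis, rank-based risk-feature and
#' risk-population calling, three-group stratification, and Kaplan-Meier /
#' log-rank survival comparison (three-group plus the two-group splits at
#' boundaries 6 and 7).  Identical inputs and configuration give identical
#' outputs.
#'
#' @param x A raw-scale `ExpressionMatrix` (or a preprocessed one, detected
#'   by its `log2` attribute).
#' @param sets An `ImmuneGeneSets` object.
#' @param clinical Optional clinical data frame (`sample_id`, `time`,
#'   `event`); `NULL` skips the survival stage.
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, every intermediate result
#'   is written there as TSV/JSON.
#' @param two_group_boundaries Integer boundaries for the two-group
#'   sensitivity splits (default `c(6, 7)`).
#' @return An `immrisk_run` list: `preprocessed`, `de`, `pairs`,
#'   `networks` (per population), `integrated` network, `power_law`,
#'   `risk_calls`, `profiles`, `survival` (curves + log-rank results, or
#'   `NULL`), and `manifest` (per-stage record counts, configuration,
#'   version).
#' @export
run_pipeline <- function(x, sets, clinical = NULL,
                         cfg = pipeline_config(), out_dir = NULL,
                         two_group_boundaries = c(6L, 7L)) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  cfg <- as_pipeline_config(cfg)

  pre <- if (isTRUE(attr(x, "log2"))) x else preprocess(x, cfg)
  de <- call_specific_features(pre, sets, cfg)
  spec <- specific_features(de)
  pairs <- screen_pairs(pre, spec$genes, spec$lncs, cfg)

  pops <- names(spec$genes)
  networks <- setNames(lapply(pops, function(p)
    suppressWarnings(build_network(pairs, cfg, scope = p))), pops)
  integrated <- suppressWarnings(build_network(pairs, cfg, "integrated"))
  power_law <- tryCatch(fit_power_law(integrated), error = function(e) {
    message("power-law fit skipped: ", conditionMessage(e))
    NULL
  })

  node_lists <- lapply(networks, function(net) net$nodes$id)
  rf <- call_risk_features(pre, node_lists, spec$directions, cfg)
  risk_calls <- suppressWarnings(call_risk_populations(rf, cfg))
  profiles <- risk_profiles(risk_calls, cfg)

  surv <- NULL
  if (!is.null(clinical)) {
    clin <- validate_clinical(clinical)
    merged <- merge(profiles, clin, by.x = "patient_id",
                    by.y = "sample_id")
    n_missing <- nrow(profiles) - nrow(merged)
    if (n_missing > 0)
      message(sprintf("survival: %d patients without clinical records dropped",
                      n_missing))
    surv <- list(n_missing_clinical = n_missing)
    if (nrow(merged) && length(unique(merged$group[!is.na(merged$group)])) >= 2) {
      surv$curves <- km_by_group(merged, merged$group)
      surv$three_group <- log_rank(merged, merged$group)
    } else {
      message("survival: fewer than 2 non-empty groups; log-rank skipped")
    }
    surv$two_group <- list()
    n_pops_scored <- length(unique(risk_calls$population))
    for (bnd in two_group_boundaries) {
      if (bnd <= 0 || bnd >= n_pops_scored) next
      split <- suppressWarnings(
        two_group_split(profiles, bnd, n_populations = n_pops_scored))
      if (length(split$low) && length(split$high)) {
        lab <- ifelse(merged$patient_id %in% split$high, "high", "low")
        if (length(unique(lab)) == 2)
          surv$two_group[[as.character(bnd)]] <- log_rank(merged, lab)
      }
    }
  }

  manifest <- list(
    package_version = as.character(packageVersion("immrisk")),
    seed = cfg$seed,
    config = unclass(cfg),
    counts = list(
      features_in = nrow(x$values),
      features_kept = nrow(pre$values),
      features_dropped = attr(pre, "n_dropped"),
      significant_genes_per_population =
        setNames(as.list(de$summary$n_significant), de$summary$population),
      significant_lncrnas = sum(de$lncrnas$significant),
      pairs_screened = nrow(pairs),
      edges_integrated = nrow(integrated$edges),
      patients_scored = nrow(profiles),
      patients_per_group = as.list(table(profiles$group))))

  run <- structure(list(preprocessed = pre, de = de, pairs = pairs,
                        networks = networks, integrated = integrated,
                        power_law = power_law, risk_calls = risk_calls,
                        profiles = profiles, survival = surv,
                        manifest = manifest),
                   class = "immrisk_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.immrisk_run <- function(x, ...) {
  m <- x$manifest$counts
  cat("Immune-risk pipeline run\n")
  cat(sprintf("  features: %d kept of %d; screened pairs: %d; integrated edges: %d\n",
              m$features_kept, m$features_in, m$pairs_screened,
              m$edges_integrated))
  cat(sprintf("  patients: %d (%s)\n", m$patients_scored,
              paste(names(m$patients_per_group), unlist(m$patients_per_group),
                    sep = "=", collapse = ", ")))
  if (!is.null(x$survival$three_group))
    cat(sprintf("  three-group log-rank p = %.4g\n",
                x$survival$three_group$p_value))
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' @param run An `immrisk_run` object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_de_results(run$de, p("differential_expression.tsv"))
  write.table(run$de$summary, p("population_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_pairs(run$pairs, p("screened_pairs.tsv"))
  write_network(run$integrated, p("network_integrated.tsv"))
  deg <- data.frame(id = run$integrated$nodes$id,
                    type = run$integrated$nodes$type,
                    degree = as.integer(run$integrated$degree))
  write.table(deg, p("degree_integrated.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(run$power_law))
    jsonlite::write_json(unclass(run$power_law), p("power_law.json"),
                         auto_unbox = TRUE, digits = NA)
  write_risk(run$risk_calls, run$profiles, p("risk_matrix.tsv"),
             p("risk_profiles.tsv"))
  if (!is.null(run$survival)) {
    if (!is.null(run$survival$curves))
      write_km_curves(run$survival$curves, p("km_curves.tsv"))
    res <- list(three_group =
                  if (!is.null(run$survival$three_group))
                    unclass(run$survival$three_group) else NULL,
                two_group = lapply(run$survival$two_group, unclass))
    jsonlite::write_json(res, p("logrank.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Run the pipeline from a YAML configuration file
#'
#' The YAML file holds the input paths (`expression`, `class_map`,
#' `gene_sets`, `clinical`, `out_dir`) and, optionally, a `config` block
#' with [pipeline_config()] fields.  This file-level entry point is the
#' scripted interface to the whole pipeline.
#'
#' @param config_path Path to the YAML configuration.
#' @return The `immrisk_run` object, invisibly.
#' @export
run_pipeline_files <- function(config_path) {
  conf <- yaml::read_yaml(config_path)
  for (nm in c("expression", "class_map", "gene_sets"))
    if (is.null(conf[[nm]]) || !file.exists(conf[[nm]]))
      stop("config must point to an existing '", nm, "' file",
           call. = FALSE)
  cfg <- if (is.null(conf$config)) pipeline_config() else
    do.call(pipeline_config, conf$config)
  x <- read_expression(conf$expression, conf$class_map)
  sets <- read_gene_sets(conf$gene_sets)
  clinical <- if (!is.null(conf$clinical)) read_clinical(conf$clinical)
  invisible(run_pipeline(x, sets, clinical, cfg, out_dir = conf$out_dir))
}
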