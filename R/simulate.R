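#' Simulation configuration
#'
#' Defines a synthetic tumour/normal cohort with planted ground truth for
#' every pipeline stage: differentially expressed features, gene-lncRNA
#' pairs whose correlation differs between groups, and survival times whose
#' hazard depends on each patient's risk-population count.  The defaults
#' describe the study conditions the pipeline targets: a large tumour arm
#' with a small adjacent-normal arm (300/50), 17 immune cell populations,
#' unit residual noise on the log2 scale, 2-log2-unit expression shifts and
#' planted correlations of magnitude 0.9.
#'
#' @param n_tumor,n_normal Samples per group (each >= 3; defaults 300/50).
#' @param n_populations Number of immune cell populations (default 17; with
#'   17 the standard population names are used).
#' @param genes_per_population Marker genes per population (default 10).
#' @param n_lncs Number of lncRNAs (default 200).
#' @param frac_de Fraction of background features differentially expressed
#'   (default 0.3).
#' @param de_effect Mean tumour shift for DE features, log2 units
#'   (default 2).
#' @param n_diffcoex_pairs Planted differential co-expression pairs per
#'   population (default 3).  Planted-pair members are always
#'   differentially expressed so the pairs survive the DE filter.
#' @param r_planted Within-group correlation magnitude of planted pairs
#'   (default 0.9): correlation `+r_planted` in tumour and, depending on
#'   `r_normal`, `-r_planted` (`"opposite"`, default) or 0 (`"zero"`) in
#'   normal samples.
#' @param r_normal `"opposite"` or `"zero"` (see `r_planted`).
#' @param noise_sd Residual standard deviation, log2 units (default 1).
#' @param base_mean Baseline log2 expression level (default 8).
#' @param hazard_multiplier Multiplicative hazard per risk population
#'   (default 1.3; values < 1 make immune-diverse patients survive longer,
#'   values > 1 the opposite; 1 = no survival effect).
#' @param baseline_hazard Hazard for a patient with zero risk populations,
#'   per day (default `log(2)/730`: two-year median survival).
#' @param censor_rate Fraction of patients censored (default 0.3).
#' @param seed Integer seed.
#' @return A `sim_config` object (validated named list).
#' @export
sim_config <- function(n_tumor = 300L, n_normal = 50L,
                       n_populations = 17L, genes_per_population = 10L,
                       n_lncs = 200L, frac_de = 0.3, de_effect = 2,
                       n_diffcoex_pairs = 3L, r_planted = 0.9,
                       r_normal = c("opposite", "zero"),
                       noise_sd = 1, base_mean = 8,
                       hazard_multiplier = 1.3,
                       baseline_hazard = log(2) / 730,
                       censor_rate = 0.3, seed = 1L) {
  r_normal <- match.arg(r_normal)
  stopifnot(n_tumor >= 3, n_normal >= 3, n_populations >= 1,
            genes_per_population >= 1, n_lncs >= 0,
            frac_de >= 0, frac_de <= 1, de_effect >= 0,
            n_diffcoex_pairs >= 0, r_planted > 0, r_planted < 1,
            noise_sd > 0, hazard_multiplier > 0, baseline_hazard > 0,
            censor_rate >= 0, censor_rate <= 1, seed == round(seed))
  structure(list(n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal),
                 n_populations = as.integer(n_populations),
                 genes_per_population = as.integer(genes_per_population),
                 n_lncs = as.integer(n_lncs), frac_de = frac_de,
                 de_effect = de_effect,
                 n_diffcoex_pairs = as.integer(n_diffcoex_pairs),
                 r_planted = r_planted, r_normal = r_normal,
                 noise_sd = noise_sd, base_mean = base_mean,
                 hazard_multiplier = hazard_multiplier,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, seed = as.integer(seed)),
            class = "sim_config")
}

.population_names <- function(n) {
  std <- c("B cells", "eosinophils", "macrophages", "mast cells",
           "NK CD56bright cells", "NK CD56dim cells", "neutrophils",
           "T helper cells", "Tcm cells", "Tem cells", "Tfh cells",
           "aDCs", "iDCs", "activated CD8 T cells", "gamma delta T cells",
           "Tregs", "cytotoxic cells")
  if (n == length(std)) std else sprintf("population_%02d", seq_len(n))
}

#' Simulate an expression cohort with planted truth
#'
#' Generates a raw-scale `ExpressionMatrix` (2^log2-signal, so the standard
#' preprocessing recovers the simulated log2 values up to the monotone
#' pseudocount shift), the population gene sets, and a `SimTruth` record.
#' Base expression is i.i.d. normal on the log2 scale with mean
#' `base_mean` and sd `noise_sd`; DE features get a +/- `de_effect` tumour
#' shift; planted gene-lncRNA pairs share a latent factor giving
#' correlation `+r_planted` in tumour and `-r_planted` (or 0) in normal.
#' Planted-pair members are always differentially expressed (random
#' direction) so they pass the DE filter; `frac_de` applies to the
#' remaining features.
#'
#' @param cfg A [sim_config()].
#' @return List with `expression` (raw scale), `sets` (`ImmuneGeneSets`)
#'   and `truth` (list: `de` data frame, `pairs` data frame, `features`
#'   per-population planted node lists, `directions`).
#' @export
simulate_expression <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_genes <- cfg$n_populations * cfg$genes_per_population
  if (cfg$n_diffcoex_pairs > cfg$genes_per_population)
    stop("more planted pairs per population than available genes",
         call. = FALSE)
  if (cfg$n_diffcoex_pairs * cfg$n_populations > cfg$n_lncs)
    stop("more planted pairs than available lncRNAs", call. = FALSE)

  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  lnc_ids <- if (cfg$n_lncs) sprintf("L%04d", seq_len(cfg$n_lncs))
             else character(0)
  sample_ids <- c(sprintf("T%03d", seq_len(cfg$n_tumor)),
                  sprintf("N%03d", seq_len(cfg$n_normal)))
  groups <- setNames(rep(c("tumor", "normal"),
                         c(cfg$n_tumor, cfg$n_normal)), sample_ids)
  feats <- c(gene_ids, lnc_ids)
  classes <- setNames(rep(c("gene", "lncRNA"),
                          c(n_genes, length(lnc_ids))), feats)

  pops <- .population_names(cfg$n_populations)
  sets <- split(gene_ids, rep(pops, each = cfg$genes_per_population))[pops]
  class(sets) <- "ImmuneGeneSets"
  attr(sets, "description") <- setNames(rep("simulated", length(pops)), pops)

  n_s <- length(sample_ids)
  log2_mat <- matrix(rnorm(length(feats) * n_s, cfg$base_mean,
                           cfg$noise_sd),
                     nrow = length(feats), ncol = n_s,
                     dimnames = list(feats, sample_ids))

  # planted differential co-expression pairs: one latent factor per pair
  pair_rows <- list()
  feature_lists <- setNames(vector("list", length(pops)), pops)
  lnc_pool <- lnc_ids
  tum <- groups == "tumor"
  a <- sqrt(cfg$r_planted)
  b <- sqrt(1 - cfg$r_planted)
  for (i in seq_along(pops)) {
    if (cfg$n_diffcoex_pairs == 0L) { feature_lists[[i]] <- character(0); next }
    pg <- sample(sets[[i]], cfg$n_diffcoex_pairs)
    pl <- lnc_pool[seq_len(cfg$n_diffcoex_pairs)]
    lnc_pool <- lnc_pool[-seq_len(cfg$n_diffcoex_pairs)]
    for (j in seq_len(cfg$n_diffcoex_pairs)) {
      z <- rnorm(n_s)
      sgn <- ifelse(tum, 1,
                    if (cfg$r_normal == "opposite") -1 else 0)
      # zero mode: the normal-group lncRNA is pure unit-variance noise
      scale_l <- ifelse(tum | cfg$r_normal == "opposite", b, 1)
      log2_mat[pg[j], ] <- cfg$base_mean +
        cfg$noise_sd * (a * z + b * rnorm(n_s))
      log2_mat[pl[j], ] <- cfg$base_mean +
        cfg$noise_sd * (sgn * a * z + scale_l * rnorm(n_s))
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        population = pops[i], gene_id = pg[j], lnc_id = pl[j],
        r_tumor = cfg$r_planted,
        r_normal = if (cfg$r_normal == "opposite") -cfg$r_planted else 0,
        stringsAsFactors = FALSE)
    }
    feature_lists[[i]] <- c(pg, pl)
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(population = character(0), gene_id = character(0),
               lnc_id = character(0), r_tumor = numeric(0),
               r_normal = numeric(0), stringsAsFactors = FALSE)

  # differential expression: planted-pair members always, plus frac_de of
  # the remaining features
  pair_feats <- unique(c(pairs$gene_id, pairs$lnc_id))
  background <- setdiff(feats, pair_feats)
  n_bg_de <- round(cfg$frac_de * length(background))
  de_feats <- c(pair_feats,
                if (n_bg_de) sample(background, n_bg_de) else character(0))
  de_dir <- setNames(sample(c("up", "down"), length(de_feats),
                            replace = TRUE), de_feats)
  if (length(de_feats) && cfg$de_effect > 0)
    log2_mat[de_feats, tum] <- log2_mat[de_feats, tum] +
      ifelse(de_dir == "up", cfg$de_effect, -cfg$de_effect)

  truth_de <- data.frame(
    feature_id = de_feats,
    feature_class = unname(classes[de_feats]),
    direction = unname(de_dir),
    stringsAsFactors = FALSE)

  expr <- expression_matrix(2^log2_mat, classes, groups)
  list(expression = expr, sets = sets,
       truth = list(de = truth_de, pairs = pairs,
                    features = feature_lists, directions = de_dir))
}

#' Simulate survival from risk-population counts
#'
#' Event times are exponential with hazard
#' `baseline_hazard * hazard_multiplier^count`; a `censor_rate` fraction of
#' patients is censored at a uniform fraction of its drawn event time.
#' Uses `cfg$seed + 1` so it is reproducible independently of
#' [simulate_expression()].
#'
#' @param risk_counts Named integer vector: patient id -> risk-population
#'   count.
#' @param cfg A [sim_config()].
#' @return Clinical data frame (`sample_id`, `time`, `event`).
#' @export
simulate_survival <- function(risk_counts, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"), !is.null(names(risk_counts)))
  set.seed(cfg$seed + 1L)
  n <- length(risk_counts)
  rate <- cfg$baseline_hazard * cfg$hazard_multiplier^risk_counts
  time <- rexp(n, rate)
  censored <- runif(n) < cfg$censor_rate
  time[censored] <- time[censored] * runif(sum(censored))
  data.frame(sample_id = names(risk_counts), time = time,
             event = as.integer(!censored), stringsAsFactors = FALSE)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: simulates expression, derives each patient's true
#' risk-population count by applying the rank-based risk rules to the
#' planted networks with the planted directions, and simulates survival
#' from those counts.
#'
#' @param cfg A [sim_config()].
#' @param pcfg A [pipeline_config()] used for the truth risk scoring.
#' @return List with `expression`, `sets`, `clinical` and `truth`
#'   (the truth gains `risk`: a [risk_profiles()] data frame).
#' @export
simulate_cohort <- function(cfg = sim_config(),
                            pcfg = pipeline_config(seed = cfg$seed)) {
  sim <- simulate_expression(cfg)
  log_x <- preprocess(sim$expression, pcfg)
  rf <- call_risk_features(log_x, sim$truth$features,
                           sim$truth$directions, pcfg)
  calls <- call_risk_populations(rf, pcfg)
  profiles <- risk_profiles(calls, pcfg)
  counts <- setNames(profiles$risk_population_count, profiles$patient_id)
  clinical <- simulate_survival(counts, cfg)
  sim$truth$risk <- profiles
  c(sim, list(clinical = clinical))
}

#' Write a simulated cohort to disk
#'
#' Writes the expression TSV, class/group map, GMT gene sets, clinical TSV
#' and a truth JSON into a directory.
#'
#' @param sim Output of [simulate_cohort()] (or [simulate_expression()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expression, file.path(dir, "expression.tsv"),
                   file.path(dir, "class_map.tsv"))
  write_gene_sets(sim$sets, file.path(dir, "gene_sets.gmt"))
  if (!is.null(sim$clinical))
    write_clinical(sim$clinical, file.path(dir, "clinical.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
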