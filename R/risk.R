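#' Call per-patient risk features by expression rank
#'
#' For every feature of every population network, tumour patients are ranked
#' by that feature's expression from high to low (ties broken by patient id,
#' ascending).  With `N` patients and boundary index
#' `k = ceiling(down_risk_frac * N)`: for an up-regulated feature, patients
#' ranked strictly below the top block (rank > k, i.e. the bottom 70% by
#' default) carry the feature as a risk feature; for a down-regulated
#' feature, patients inside the top block (rank <= k, the top 30%) carry it.
#'
#' @param x An `ExpressionMatrix`; only its tumour samples are used.
#' @param network_features Named list: population -> character vector of
#'   network node ids (genes and lncRNAs).
#' @param directions Named character vector (`up`/`down`) covering every
#'   network feature.
#' @param cfg A [pipeline_config()].
#' @return A `risk_feature_calls` object: named list (one element per
#'   population) of logical patient x feature matrices, with the boundary
#'   index in attribute `"k"`.
#' @export
call_risk_features <- function(x, network_features, directions,
                               cfg = pipeline_config()) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  cfg <- as_pipeline_config(cfg)
  pids <- names(x$sample_group)[x$sample_group == "tumor"]
  if (length(pids) < 2L)
    stop("need at least 2 tumor patients", call. = FALSE)
  vals <- x$values[, pids, drop = FALSE]
  n <- length(pids)
  k <- ceiling(cfg$down_risk_frac * n)

  all_feats <- unique(unlist(network_features, use.names = FALSE))
  no_dir <- setdiff(intersect(all_feats, rownames(vals)), names(directions))
  if (length(no_dir))
    stop("network feature(s) missing a direction: ",
         paste(head(no_dir, 10), collapse = ", "), call. = FALSE)

  out <- lapply(network_features, function(feats) {
    feats <- intersect(feats, rownames(vals))
    m <- matrix(FALSE, nrow = n, ncol = length(feats),
                dimnames = list(pids, feats))
    for (f in feats) {
      ord <- order(-vals[f, ], pids)
      ranks <- integer(n)
      ranks[ord] <- seq_len(n)
      m[, f] <- if (directions[[f]] == "up") ranks > k else ranks <= k
    }
    m
  })
  structure(out, k = k, patients = pids, class = "risk_feature_calls")
}

#' Call risk immune cell populations per patient
#'
#' A population is a risk population for a patient when the patient carries
#' strictly more than `cfg$pop_risk_frac` (default 50%) of that population
#' network's features as risk features.  Populations with empty networks
#' are skipped with a warning and excluded from the population total.
#'
#' @param risk_features A `risk_feature_calls` object.
#' @param cfg A [pipeline_config()].
#' @return Data frame with one row per (patient, non-empty population):
#'   `patient_id`, `population`, `n_risk_features`, `n_features`, `is_risk`.
#' @export
call_risk_populations <- function(risk_features, cfg = pipeline_config()) {
  stopifnot(inherits(risk_features, "risk_feature_calls"))
  cfg <- as_pipeline_config(cfg)
  empty <- names(risk_features)[vapply(risk_features, ncol, 0L) == 0L]
  if (length(empty))
    warning("population(s) with empty networks skipped: ",
            paste(empty, collapse = ", "), call. = FALSE)
  keep <- setdiff(names(risk_features), empty)
  rows <- lapply(keep, function(pop) {
    m <- risk_features[[pop]]
    n_risk <- rowSums(m)
    data.frame(patient_id = rownames(m), population = pop,
               n_risk_features = unname(n_risk), n_features = ncol(m),
               is_risk = unname(n_risk / ncol(m) > cfg$pop_risk_frac),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(patient_id = character(0), population = character(0),
                      n_risk_features = integer(0), n_features = integer(0),
                      is_risk = logical(0), stringsAsFactors = FALSE)
  out
}

#' Assign an immune-risk group from a risk-population count
#'
#' Counts up to `group_bounds[1]` are `min_immune`, counts up to
#' `group_bounds[2]` are `media_immune`, larger counts are `multi_immune`
#' (defaults: 0-4 / 5-9 / 10+).
#'
#' @param risk_population_count Integer vector of per-patient counts.
#' @param cfg A [pipeline_config()].
#' @param n_populations Total number of scored populations (default 17);
#'   counts outside `[0, n_populations]` are an error.
#' @return Factor with levels `min_immune`, `media_immune`, `multi_immune`.
#' @export
assign_group <- function(risk_population_count, cfg = pipeline_config(),
                         n_populations = 17L) {
  cfg <- as_pipeline_config(cfg)
  cnt <- risk_population_count
  if (any(cnt != round(cnt)) || any(cnt < 0) || any(cnt > n_populations))
    stop(sprintf("risk-population counts must be integers in [0, %d]",
                 n_populations), call. = FALSE)
  lab <- ifelse(cnt <= cfg$group_bounds[1], "min_immune",
         ifelse(cnt <= cfg$group_bounds[2], "media_immune", "multi_immune"))
  factor(lab, levels = c("min_immune", "media_immune", "multi_immune"))
}

#' Per-patient immune-risk profiles
#'
#' Aggregates risk-population calls into one row per patient with the
#' risk-population count and the three-level immune-risk group.
#'
#' @param risk_calls Data frame from [call_risk_populations()].
#' @param cfg A [pipeline_config()].
#' @return Data frame `patient_id`, `risk_population_count`, `group`.
#' @export
risk_profiles <- function(risk_calls, cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  n_pop <- length(unique(risk_calls$population))
  counts <- tapply(risk_calls$is_risk, risk_calls$patient_id, sum)
  pid <- sort(unique(risk_calls$patient_id))
  out <- data.frame(patient_id = pid,
                    risk_population_count = as.integer(counts[pid]),
                    stringsAsFactors = FALSE)
  out$group <- assign_group(out$risk_population_count, cfg,
                            n_populations = n_pop)
  out
}

#' Split patients into two groups at a risk-count boundary
#'
#' Supports the two-group sensitivity analyses: patients with
#' `risk_population_count >= boundary` form the high-diversity side,
#' the rest the low side.
#'
#' @param profiles Data frame from [risk_profiles()].
#' @param boundary Integer in `(0, n_populations)`.
#' @param n_populations Total number of scored populations (default 17).
#' @return List with character vectors `low` (`count < boundary`) and
#'   `high` (`count >= boundary`); an empty side triggers a warning.
#' @export
two_group_split <- function(profiles, boundary, n_populations = 17L) {
  if (boundary <= 0 || boundary >= n_populations)
    stop("boundary must lie strictly between 0 and the number of populations",
         call. = FALSE)
  high <- profiles$patient_id[profiles$risk_population_count >= boundary]
  low <- profiles$patient_id[profiles$risk_population_count < boundary]
  if (!length(high) || !length(low))
    warning("one side of the two-group split is empty; survival comparison ",
            "will be skipped", call. = FALSE)
  list(low = low, high = high)
}

#' Write the patient x population risk matrix and profiles
#'
#' @param risk_calls Data frame from [call_risk_populations()].
#' @param profiles Data frame from [risk_profiles()].
#' @param matrix_path,profile_path Output TSV paths.
#' @return Invisibly, `matrix_path`.
#' @export
write_risk <- function(risk_calls, profiles, matrix_path, profile_path) {
  pops <- unique(risk_calls$population)
  pids <- sort(unique(risk_calls$patient_id))
  m <- matrix(0L, length(pids), length(pops),
              dimnames = list(pids, pops))
  m[cbind(risk_calls$patient_id, risk_calls$population)] <-
    as.integer(risk_calls$is_risk)
  df <- data.frame(patient_id = pids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(profiles, profile_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(matrix_path)
}
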