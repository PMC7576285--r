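#' Expression matrix with feature classes and sample groups
#'
#' Container for a features x samples expression matrix in which every
#' feature is either a coding gene or a lncRNA and every sample belongs to
#' the tumour or the normal group.  Values are on the raw scale until
#' [preprocess()] is applied, after which they are log2-transformed.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param feature_class Character vector, one of `"gene"`/`"lncRNA"` per
#'   feature; either named by feature id or in row order.
#' @param sample_group Character vector, one of `"tumor"`/`"normal"` per
#'   sample; either named by sample id or in column order.
#' @param require_both_groups If `TRUE`, error when a group has no samples.
#'
#' @return An `ExpressionMatrix` object: a list with elements `values`,
#'   `feature_class` and `sample_group` (the latter two named by id).
#' @export
expression_matrix <- function(values, feature_class, sample_group,
                              require_both_groups = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("values must have feature rownames and sample colnames",
         call. = FALSE)
  dup <- unique(fid[duplicated(fid)])
  if (length(dup))
    stop("duplicate feature ids: ", paste(head(dup, 10), collapse = ", "),
         call. = FALSE)
  dup <- unique(sid[duplicated(sid)])
  if (length(dup))
    stop("duplicate sample ids: ", paste(head(dup, 10), collapse = ", "),
         call. = FALSE)

  feature_class <- .aligned_labels(feature_class, fid, c("gene", "lncRNA"),
                                   "feature")
  sample_group <- .aligned_labels(sample_group, sid, c("tumor", "normal"),
                                  "sample")
  if (require_both_groups) {
    for (g in c("tumor", "normal"))
      if (!any(sample_group == g))
        stop(sprintf("group has no samples: %s", g), call. = FALSE)
  }
  if (anyNA(values))
    stop("missing expression values are not permitted", call. = FALSE)

  structure(list(values = values,
                 feature_class = feature_class,
                 sample_group = sample_group),
            class = "ExpressionMatrix")
}

.aligned_labels <- function(lab, ids, allowed, what) {
  if (!is.null(names(lab))) {
    missing <- setdiff(ids, names(lab))
    if (length(missing))
      stop(sprintf("%s ids missing from %s map: %s", what, what,
                   paste(head(missing, 10), collapse = ", ")),
           call. = FALSE)
    lab <- lab[ids]
  } else if (length(lab) != length(ids)) {
    stop(sprintf("%s labels must be named or match %s count", what, what),
         call. = FALSE)
  }
  lab <- as.character(lab)
  bad <- unique(lab[!lab %in% allowed])
  if (length(bad))
    stop(sprintf("invalid %s label(s): %s (allowed: %s)", what,
                 paste(head(bad, 10), collapse = ", "),
                 paste(allowed, collapse = ", ")),
         call. = FALSE)
  names(lab) <- ids
  lab
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d features (%d genes, %d lncRNAs) x %d samples (%d tumor, %d normal)\n",
    nrow(x$values), sum(x$feature_class == "gene"),
    sum(x$feature_class == "lncRNA"), ncol(x$values),
    sum(x$sample_group == "tumor"), sum(x$sample_group == "normal")))
  if (!is.null(attr(x, "log2")))
    cat("  values: log2 scale\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix
#'
#' @param x An `ExpressionMatrix`.
#' @param features Feature ids to keep (`NULL` keeps all).
#' @param samples Sample ids to keep (`NULL` keeps all).
#' @param group Optional sample group (`"tumor"` or `"normal"`) to keep.
#' @return The subset `ExpressionMatrix`; preprocessing attributes are kept.
#' @export
subset_expression <- function(x, features = NULL, samples = NULL,
                              group = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  fid <- rownames(x$values)
  sid <- colnames(x$values)
  if (!is.null(features)) {
    missing <- setdiff(features, fid)
    if (length(missing))
      stop("unknown feature ids: ", paste(head(missing, 10), collapse = ", "),
           call. = FALSE)
    fid <- features
  }
  if (!is.null(group)) {
    group <- match.arg(group, c("tumor", "normal"))
    sid <- sid[x$sample_group[sid] == group]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, sid)
    if (length(missing))
      stop("unknown sample ids: ", paste(head(missing, 10), collapse = ", "),
           call. = FALSE)
    sid <- samples
  }
  out <- expression_matrix(x$values[fid, sid, drop = FALSE],
                           x$feature_class[fid], x$sample_group[sid])
  attr(out, "log2") <- attr(x, "log2")
  attr(out, "n_dropped") <- attr(x, "n_dropped")
  out
}

#' Read an expression matrix with a class/group map
#'
#' The expression file is tab-separated with a `feature_id` first column and
#' sample ids in the header.  The map file is a two-column TSV (`id`,
#' `label`) assigning every feature to `gene`/`lncRNA` and every sample to
#' `tumor`/`normal`.
#'
#' @param path Path to the expression TSV.
#' @param class_map Path to the id/label TSV.
#' @return A raw-scale [expression_matrix()].
#' @export
read_expression <- function(path, class_map) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || names(raw)[1] != "feature_id")
    stop("expression file must start with a 'feature_id' column",
         call. = FALSE)
  fid <- as.character(raw[[1]])
  dup <- unique(fid[duplicated(fid)])
  if (length(dup))
    stop("duplicate feature ids in ", path, ": ",
         paste(head(dup, 10), collapse = ", "), call. = FALSE)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals))
    stop("expression values must be numeric", call. = FALSE)
  rownames(vals) <- fid

  map <- read.delim(class_map, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(map) < 2L)
    stop("class map must have two columns (id, label)", call. = FALSE)
  labels <- setNames(as.character(map[[2]]), as.character(map[[1]]))

  fc <- labels[fid]
  missing <- fid[is.na(fc)]
  if (length(missing))
    stop("features missing from class map: ",
         paste(head(missing, 10), collapse = ", "), call. = FALSE)
  sg <- labels[colnames(vals)]
  missing <- colnames(vals)[is.na(sg)]
  if (length(missing))
    stop("samples missing from class map: ",
         paste(head(missing, 10), collapse = ", "), call. = FALSE)

  expression_matrix(vals, setNames(fc, fid),
                    setNames(sg, colnames(vals)),
                    require_both_groups = TRUE)
}

#' Write an expression matrix and its class/group map
#'
#' Inverse of [read_expression()]: round-trips bit-identically for matrices
#' whose values print exactly (e.g. integers or short decimals).
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output TSV path for the matrix.
#' @param class_map Output TSV path for the id/label map.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path, class_map) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- data.frame(
    id = c(names(x$feature_class), names(x$sample_group)),
    label = c(unname(x$feature_class), unname(x$sample_group)),
    stringsAsFactors = FALSE)
  write.table(map, class_map, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Zero-filter and log2-transform an expression matrix
#'
#' Features whose fraction of zero values exceeds `cfg$zero_filter_frac` are
#' removed (the default 0 removes any feature containing a zero), then the
#' remaining values are replaced by `log2(value + cfg$pseudocount)`.
#'
#' @param x A raw-scale `ExpressionMatrix`.
#' @param cfg A [pipeline_config()].
#' @return A log2-scale `ExpressionMatrix`; the number of removed features is
#'   recorded in the `"n_dropped"` attribute.
#' @export
preprocess <- function(x, cfg = pipeline_config()) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  cfg <- as_pipeline_config(cfg)
  if (isTRUE(attr(x, "log2")))
    stop("matrix is already preprocessed", call. = FALSE)
  if (any(x$values < 0))
    stop("raw expression values must be non-negative", call. = FALSE)

  zero_frac <- rowMeans(x$values == 0)
  keep <- zero_frac <= cfg$zero_filter_frac
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop("all features removed by the zero filter", call. = FALSE)
  if (n_dropped > 0)
    message(sprintf("preprocess: removed %d of %d features by the zero filter",
                    n_dropped, length(keep)))

  vals <- log2(x$values[keep, , drop = FALSE] + cfg$pseudocount)
  if (!all(is.finite(vals)))
    stop("non-finite values after log2 transform; check pseudocount",
         call. = FALSE)
  out <- expression_matrix(vals, x$feature_class[keep], x$sample_group)
  attr(out, "log2") <- TRUE
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read immune-cell-population gene sets (GMT)
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then gene symbols.  Symbols absent from a given expression
#' matrix are tolerated here and reconciled downstream.
#'
#' @param path Path to a GMT file.
#' @return An `ImmuneGeneSets` object: a named list of character vectors in
#'   file order, with set descriptions in the `"description"` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene-set file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[`, character(1), 1L)
  dup <- unique(names_[duplicated(names_)])
  if (length(dup))
    stop("duplicate gene-set names: ", paste(head(dup, 10), collapse = ", "),
         call. = FALSE)
  desc <- vapply(fields, function(f)
    if (length(f) >= 2L) f[2] else "", character(1))
  sets <- lapply(fields, function(f) {
    g <- if (length(f) >= 3L) f[-(1:2)] else character(0)
    g <- g[nzchar(g)]
    unique(g)
  })
  empty <- names_[lengths(sets) == 0L]
  if (length(empty))
    stop("empty gene set(s): ", paste(head(empty, 10), collapse = ", "),
         call. = FALSE)
  names(sets) <- names_
  structure(sets, description = setNames(desc, names_),
            class = "ImmuneGeneSets")
}

#' Write gene sets in GMT format
#'
#' @param sets An `ImmuneGeneSets` object or named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(seq_along(sets), function(i) {
    d <- if (!is.null(desc)) desc[[names(sets)[i]]] else ""
    paste(c(names(sets)[i], d, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.ImmuneGeneSets <- function(x, ...) {
  cat(sprintf("ImmuneGeneSets: %d populations, %d symbols total\n",
              length(x), sum(lengths(x))))
  for (nm in head(names(x), 20))
    cat(sprintf("  %-28s %d genes\n", nm, length(x[[nm]])))
  if (length(x) > 20) cat("  ...\n")
  invisible(x)
}

#' The 17 immune cell populations
#'
#' Loads the bundled gene-set fixture covering the 17 immune cell populations
#' used throughout the pipeline (B cells, eosinophils, macrophages, mast
#' cells, NK CD56bright cells, NK CD56dim cells, neutrophils, T helper
#' cells, Tcm cells, Tem cells, Tfh cells, aDCs, iDCs, activated CD8 T
#' cells, gamma delta T cells, Tregs and cytotoxic cells).  The population
#' names are the standard catalogue names; the member symbols bundled here
#' are a compact synthetic marker catalogue (well-known lineage markers per
#' population) suitable for examples and tests, not a published marker
#' resource.
#'
#' @return An `ImmuneGeneSets` object with 17 populations.
#' @export
immune_populations <- function() {
  read_gene_sets(system.file("extdata", "immune_populations_synthetic.gmt",
                             package = "immrisk", mustWork = TRUE))
}

#' Read a clinical follow-up table
#'
#' TSV with columns `sample_id`, `time_days` (non-negative follow-up time)
#' and `event` (1 = death observed, 0 = censored).
#'
#' @param path Path to the clinical TSV.
#' @return A data frame with columns `sample_id`, `time`, `event`.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "time_days", "event")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("clinical table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(sample_id = as.character(df$sample_id),
                    time = as.numeric(df$time_days),
                    event = as.integer(df$event),
                    stringsAsFactors = FALSE)
  validate_clinical(out)
}

validate_clinical <- function(df) {
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate clinical sample ids: ",
         paste(head(dup, 10), collapse = ", "), call. = FALSE)
  if (anyNA(df$time) || any(df$time < 0))
    stop("clinical times must be non-negative and non-missing",
         call. = FALSE)
  if (anyNA(df$event) || !all(df$event %in% c(0L, 1L)))
    stop("clinical event must be 0 (censored) or 1 (death)", call. = FALSE)
  df
}

#' Write a clinical table
#'
#' @param clinical Data frame with `sample_id`, `time`, `event`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_clinical <- function(clinical, path) {
  out <- data.frame(sample_id = clinical$sample_id,
                    time_days = clinical$time,
                    event = clinical$event)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
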