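#' Pearson correlation with p-value
#'
#' @param u,v Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Named numeric vector `c(r, p)`; the two-sided p-value comes from
#'   the t-distribution with n - 2 degrees of freedom.
#' @export
pcc <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  if (length(u) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("values must be finite", call. = FALSE)
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop("constant vector", call. = FALSE)
  fit <- cor.test(u, v, method = "pearson")
  c(r = unname(fit$estimate), p = unname(fit$p.value))
}

# p-value of a Pearson r from the t-distribution (vectorised).
.cor_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t_stat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-t_stat, n - 2)
}

#' Classify a pair's correlation change pattern
#'
#' A sign flip from negative (normal) to non-negative (tumour) is
#' `negative_to_positive`; the reverse flip is `positive_to_negative`.
#' Same-sign pairs are `same_sign_strengthened` when the tumour correlation
#' is larger in magnitude, otherwise `same_sign_weakened`.
#'
#' @param pcc_normal,pcc_tumor Correlations in `[-1, 1]` (vectorised).
#' @return Character vector of pattern labels.
#' @export
classify_pattern <- function(pcc_normal, pcc_tumor) {
  stopifnot(all(abs(pcc_normal) <= 1), all(abs(pcc_tumor) <= 1))
  out <- ifelse(pcc_normal < 0 & pcc_tumor >= 0, "negative_to_positive",
         ifelse(pcc_normal > 0 & pcc_tumor <= 0, "positive_to_negative",
         ifelse(abs(pcc_tumor) > abs(pcc_normal), "same_sign_strengthened",
                "same_sign_weakened")))
  out
}

#' Screen gene-lncRNA pairs by correlation difference
#'
#' For each population, computes the Pearson correlation of every
#' tumour-specific member gene with every tumour-specific lncRNA separately
#' in tumour and in normal samples, and retains pairs whose absolute
#' correlation difference `delta = |pcc_tumor - pcc_normal|` strictly
#' exceeds `cfg$delta_screen`.  Pair p-values are recorded but not filtered
#' on unless `cfg$pair_p_max` is set.
#'
#' @param x A preprocessed `ExpressionMatrix`.
#' @param specific_genes Named list: population -> tumour-specific gene ids.
#' @param specific_lncs Character vector of tumour-specific lncRNA ids.
#' @param cfg A [pipeline_config()].
#' @return Data frame of class `coex_pairs` with columns `population`,
#'   `gene_id`, `lnc_id`, `pcc_tumor`, `pcc_normal`, `p_tumor`, `p_normal`,
#'   `delta`, `pattern`, sorted by population (input order), gene and
#'   lncRNA id.
#' @export
screen_pairs <- function(x, specific_genes, specific_lncs,
                         cfg = pipeline_config()) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  cfg <- as_pipeline_config(cfg)
  tum <- names(x$sample_group)[x$sample_group == "tumor"]
  nor <- names(x$sample_group)[x$sample_group == "normal"]
  if (length(tum) < 3L || length(nor) < 3L)
    stop("need at least 3 samples per group for correlations",
         call. = FALSE)

  usable <- function(ids) {
    ids <- intersect(ids, rownames(x$values))
    if (!length(ids)) return(ids)
    sd_t <- apply(x$values[ids, tum, drop = FALSE], 1, stats::sd)
    sd_n <- apply(x$values[ids, nor, drop = FALSE], 1, stats::sd)
    flat <- ids[sd_t == 0 | sd_n == 0]
    if (length(flat))
      warning("constant features excluded from correlation: ",
              paste(head(flat, 10), collapse = ", "), call. = FALSE)
    setdiff(ids, flat)
  }

  lncs <- usable(specific_lncs)
  empty <- .empty_pairs()
  out <- vector("list", length(specific_genes))
  for (i in seq_along(specific_genes)) {
    pop <- names(specific_genes)[i]
    genes <- usable(specific_genes[[i]])
    if (!length(genes) || !length(lncs)) {
      message(sprintf("screen_pairs: population '%s' has no screenable pairs",
                      pop))
      out[[i]] <- empty
      next
    }
    rt <- cor(t(x$values[genes, tum, drop = FALSE]),
              t(x$values[lncs, tum, drop = FALSE]))
    rn <- cor(t(x$values[genes, nor, drop = FALSE]),
              t(x$values[lncs, nor, drop = FALSE]))
    delta <- abs(rt - rn)
    hit <- which(delta > cfg$delta_screen, arr.ind = TRUE)
    if (!nrow(hit)) { out[[i]] <- empty; next }
    df <- data.frame(
      population = pop,
      gene_id = genes[hit[, 1]],
      lnc_id = lncs[hit[, 2]],
      pcc_tumor = rt[hit],
      pcc_normal = rn[hit],
      p_tumor = .cor_p(rt[hit], length(tum)),
      p_normal = .cor_p(rn[hit], length(nor)),
      delta = delta[hit],
      stringsAsFactors = FALSE)
    df$pattern <- classify_pattern(df$pcc_normal, df$pcc_tumor)
    if (!is.null(cfg$pair_p_max))
      df <- df[pmin(df$p_tumor, df$p_normal) <= cfg$pair_p_max, ,
               drop = FALSE]
    out[[i]] <- df[order(df$gene_id, df$lnc_id), , drop = FALSE]
  }
  res <- do.call(rbind, c(list(empty), out))
  rownames(res) <- NULL
  class(res) <- c("coex_pairs", "data.frame")
  res
}

.empty_pairs <- function() {
  data.frame(population = character(0), gene_id = character(0),
             lnc_id = character(0), pcc_tumor = numeric(0),
             pcc_normal = numeric(0), p_tumor = numeric(0),
             p_normal = numeric(0), delta = numeric(0),
             pattern = character(0), stringsAsFactors = FALSE)
}

#' Histogram of correlation differences
#'
#' Counts screened pairs in |dPCC| bins of width `by` starting at `from`
#' (bins are `(low, high]`; pairs are pooled over populations, so a
#' gene-lncRNA pair recurring in several populations is counted each time).
#'
#' @param pairs A `coex_pairs` data frame.
#' @param from Lower edge of the first bin (default 0.3).
#' @param by Bin width (default 0.1).
#' @return Data frame with `bin_low`, `bin_high`, `n`.
#' @export
delta_histogram <- function(pairs, from = 0.3, by = 0.1) {
  edges <- seq(from, 2 + by / 2, by = by)
  idx <- findInterval(pairs$delta, edges, left.open = TRUE,
                      rightmost.closed = FALSE)
  idx <- idx[idx >= 1 & idx < length(edges)]
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
             n = counts)
}

#' Write screened pairs as TSV
#'
#' @param pairs A `coex_pairs` data frame.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
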