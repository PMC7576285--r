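#' Welch two-sample t-test for one feature
#'
#' Two-sided Welch (unequal-variance) t-test of tumour versus normal
#' expression for a single feature.  Degenerate inputs are defined rather
#' than errors: when both groups have zero variance, identical means give
#' `t = 0, p = 1` and different means give an infinite statistic with
#' `p = 0`.
#'
#' @param values_tumor,values_normal Numeric vectors, each of length >= 2.
#' @return Named numeric vector `c(t_stat, p_value)`; the statistic is
#'   oriented as tumour minus normal.
#' @export
welch_test <- function(values_tumor, values_normal) {
  if (length(values_tumor) < 2L || length(values_normal) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (!all(is.finite(values_tumor)) || !all(is.finite(values_normal)))
    stop("values must be finite", call. = FALSE)
  v1 <- stats::var(values_tumor)
  v2 <- stats::var(values_normal)
  if (v1 == 0 && v2 == 0) {
    d <- mean(values_tumor) - mean(values_normal)
    if (d == 0) return(c(t_stat = 0, p_value = 1))
    return(c(t_stat = sign(d) * Inf, p_value = 0))
  }
  fit <- t.test(values_tumor, values_normal, var.equal = FALSE)
  c(t_stat = unname(fit$statistic), p_value = unname(fit$p.value))
}

# Vectorised Welch test over matrix rows; same degenerate-case conventions
# as welch_test (cross-checked against t.test in the test suite).
.row_welch <- function(mt, mn) {
  n1 <- ncol(mt); n2 <- ncol(mn)
  m1 <- rowMeans(mt); m2 <- rowMeans(mn)
  v1 <- rowSums((mt - m1)^2) / (n1 - 1)
  v2 <- rowSums((mn - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  zero <- v1 == 0 & v2 == 0
  if (any(zero)) {
    same <- zero & (m1 == m2)
    t_stat[same] <- 0; p[same] <- 1
    diff <- zero & (m1 != m2)
    t_stat[diff] <- sign(m1 - m2)[diff] * Inf; p[diff] <- 0
  }
  data.frame(mean_tumor = m1, mean_normal = m2,
             t_stat = t_stat, p_value = p,
             row.names = rownames(mt), stringsAsFactors = FALSE)
}

#' Call tumour-specific marker genes and lncRNAs
#'
#' Runs a feature-level Welch t-test (tumour vs normal) on every feature of
#' a preprocessed expression matrix, then reports, per immune cell
#' population, the results for its member genes present in the matrix, and
#' separately the results for all lncRNAs.  Significance uses `cfg$p_gene`
#' for genes and `cfg$p_lnc` for lncRNAs (raw p-values by default;
#' Benjamini-Hochberg-adjusted values are stored in `p_adj`).  Direction is
#' `up` when the tumour mean exceeds the normal mean, otherwise `down`.
#'
#' @param x A preprocessed `ExpressionMatrix` with both groups present.
#' @param sets An `ImmuneGeneSets` object.
#' @param cfg A [pipeline_config()].
#' @return A list of class `de_results`:
#'   \describe{
#'     \item{genes}{data frame of per-population gene results (a gene shared
#'       by two populations appears once per population with identical test
#'       values).}
#'     \item{lncrnas}{data frame of lncRNA results.}
#'     \item{summary}{per-population counts: members mapped, significant,
#'       fraction significant, up/down counts among significant genes.}
#'   }
#' @export
call_specific_features <- function(x, sets, cfg = pipeline_config()) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  cfg <- as_pipeline_config(cfg)
  tum <- x$sample_group == "tumor"
  nor <- x$sample_group == "normal"
  if (sum(tum) < 2L || sum(nor) < 2L)
    stop("each sample group needs at least 2 samples", call. = FALSE)

  tests <- .row_welch(x$values[, tum, drop = FALSE],
                      x$values[, nor, drop = FALSE])
  tests$direction <- ifelse(tests$mean_tumor > tests$mean_normal,
                            "up", "down")

  gene_ids <- rownames(x$values)[x$feature_class == "gene"]
  lnc_ids <- rownames(x$values)[x$feature_class == "lncRNA"]

  # BH adjustment within feature class, over features actually tested
  tested_genes <- intersect(unique(unlist(sets, use.names = FALSE)),
                            gene_ids)
  p_adj <- setNames(rep(NA_real_, nrow(tests)), rownames(tests))
  if (length(tested_genes))
    p_adj[tested_genes] <- p.adjust(tests[tested_genes, "p_value"],
                                    method = "BH")
  if (length(lnc_ids))
    p_adj[lnc_ids] <- p.adjust(tests[lnc_ids, "p_value"], method = "BH")

  one_class <- function(ids, class, population, threshold) {
    res <- tests[ids, , drop = FALSE]
    pv <- if (cfg$use_adjusted_p) p_adj[ids] else res$p_value
    data.frame(feature_id = ids,
               feature_class = rep(class, length(ids)),
               population = rep(population, length(ids)),
               mean_tumor = res$mean_tumor,
               mean_normal = res$mean_normal,
               t_stat = res$t_stat,
               p_value = res$p_value,
               p_adj = unname(p_adj[ids]),
               direction = res$direction,
               significant = pv < threshold,
               row.names = NULL, stringsAsFactors = FALSE)
  }

  gene_res <- vector("list", length(sets))
  summ <- vector("list", length(sets))
  n_unmapped <- 0L
  for (i in seq_along(sets)) {
    pop <- names(sets)[i]
    members <- intersect(sets[[i]], gene_ids)
    n_unmapped <- n_unmapped + length(sets[[i]]) - length(members)
    if (!length(members)) {
      warning(sprintf("population '%s' has no mappable genes", pop),
              call. = FALSE)
      gene_res[[i]] <- one_class(character(0), "gene", pop, cfg$p_gene)
    } else {
      gene_res[[i]] <- one_class(members, "gene", pop, cfg$p_gene)
    }
    g <- gene_res[[i]]
    sig <- g[g$significant, , drop = FALSE]
    summ[[i]] <- data.frame(
      population = pop,
      n_features = nrow(g),
      n_significant = nrow(sig),
      frac_significant = if (nrow(g)) nrow(sig) / nrow(g) else NA_real_,
      n_up = sum(sig$direction == "up"),
      n_down = sum(sig$direction == "down"),
      stringsAsFactors = FALSE)
  }
  if (n_unmapped > 0)
    message(sprintf(
      "call_specific_features: %d gene-set symbols absent from the matrix",
      n_unmapped))

  structure(list(genes = do.call(rbind, gene_res),
                 lncrnas = one_class(lnc_ids, "lncRNA", "lncRNA", cfg$p_lnc),
                 summary = do.call(rbind, summ)),
            class = "de_results")
}

#' @export
print.de_results <- function(x, ...) {
  cat(sprintf("Differential expression: %d populations, %d lncRNAs tested\n",
              nrow(x$summary), nrow(x$lncrnas)))
  cat(sprintf("  significant lncRNAs: %d (%.1f%%)\n",
              sum(x$lncrnas$significant),
              100 * mean(x$lncrnas$significant)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Extract tumour-specific feature lists from DE results
#'
#' @param de A `de_results` object.
#' @return List with `genes` (named list population -> significant gene
#'   ids), `lncs` (significant lncRNA ids) and `directions` (named `up`/
#'   `down` vector over all tested features).
#' @export
specific_features <- function(de) {
  stopifnot(inherits(de, "de_results"))
  pops <- unique(de$genes$population)
  genes <- lapply(setNames(pops, pops), function(p) {
    g <- de$genes[de$genes$population == p & de$genes$significant, ]
    g$feature_id
  })
  all_feats <- rbind(
    de$genes[!duplicated(de$genes$feature_id),
             c("feature_id", "direction")],
    de$lncrnas[, c("feature_id", "direction")])
  list(genes = genes,
       lncs = de$lncrnas$feature_id[de$lncrnas$significant],
       directions = setNames(all_feats$direction, all_feats$feature_id))
}

#' Write differential-expression results as TSV
#'
#' @param de A `de_results` object.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_de_results <- function(de, path) {
  out <- rbind(de$genes, de$lncrnas)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
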