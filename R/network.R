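#' Build a bipartite gene-lncRNA co-expression network
#'
#' Promotes screened pairs with `delta > cfg$delta_network` (strict) to
#' edges of a bipartite network.  For `scope = "integrated"` the pairs of
#' all populations are pooled and a gene-lncRNA edge recurring in several
#' populations is collapsed to its maximum-delta instance; otherwise only
#' the named population's pairs are used.
#'
#' @param pairs A `coex_pairs` data frame from [screen_pairs()].
#' @param cfg A [pipeline_config()].
#' @param scope `"integrated"` or a population name.
#' @return A `CoexNetwork`: list with `scope`, `nodes` (data frame `id`,
#'   `type`), `edges` (the retained pairs) and `degree` (named integer
#'   vector).  An empty network is returned with a warning.
#' @export
build_network <- function(pairs, cfg = pipeline_config(),
                          scope = "integrated") {
  cfg <- as_pipeline_config(cfg)
  stopifnot(is.data.frame(pairs))
  df <- if (identical(scope, "integrated")) pairs else
    pairs[pairs$population == scope, , drop = FALSE]
  df <- df[df$delta > cfg$delta_network, , drop = FALSE]

  if (identical(scope, "integrated") && nrow(df)) {
    df <- df[order(-df$delta, df$population, df$gene_id, df$lnc_id), ,
             drop = FALSE]
    df <- df[!duplicated(paste(df$gene_id, df$lnc_id, sep = "\r")), ,
             drop = FALSE]
    df <- df[order(df$gene_id, df$lnc_id), , drop = FALSE]
  }
  rownames(df) <- NULL

  if (!nrow(df)) {
    warning(sprintf("network '%s' is empty", scope), call. = FALSE)
    nodes <- data.frame(id = character(0), type = character(0),
                        stringsAsFactors = FALSE)
    return(structure(list(scope = scope, nodes = nodes, edges = df,
                          degree = integer(0)),
                     class = "CoexNetwork"))
  }

  genes <- sort(unique(df$gene_id))
  lncs <- sort(unique(df$lnc_id))
  overlap <- intersect(genes, lncs)
  if (length(overlap))
    stop("feature id(s) appear as both gene and lncRNA: ",
         paste(head(overlap, 10), collapse = ", "), call. = FALSE)
  nodes <- data.frame(id = c(genes, lncs),
                      type = rep(c("gene", "lncRNA"),
                                 c(length(genes), length(lncs))),
                      stringsAsFactors = FALSE)
  deg <- table(factor(c(df$gene_id, df$lnc_id), levels = nodes$id))
  structure(list(scope = scope, nodes = nodes, edges = df,
                 degree = setNames(as.integer(deg), nodes$id)),
            class = "CoexNetwork")
}

#' @export
print.CoexNetwork <- function(x, ...) {
  cat(sprintf("CoexNetwork '%s': %d edges, %d genes, %d lncRNAs\n",
              x$scope, nrow(x$edges), sum(x$nodes$type == "gene"),
              sum(x$nodes$type == "lncRNA")))
  invisible(x)
}

#' Fit a power law to a degree distribution
#'
#' Ordinary least squares of `log10(frequency)` on `log10(degree)` over the
#' degree values (>= 1) with nonzero frequency, the conventional check that
#' a network is scale-free.
#'
#' @param x A `CoexNetwork`, or an integer vector of node degrees.
#' @return A `power_law_fit`: list with `slope`, `intercept`, `r_squared`,
#'   `n_points`.
#' @export
fit_power_law <- function(x) {
  deg <- if (inherits(x, "CoexNetwork")) x$degree else as.integer(x)
  deg <- deg[deg >= 1L]
  freq <- table(deg)
  if (length(freq) < 3L)
    stop("insufficient degree diversity (need >= 3 distinct degrees)",
         call. = FALSE)
  d <- as.numeric(names(freq))
  f <- as.numeric(freq)
  fit <- lm(log10(f) ~ log10(d))
  # an exact power law triggers summary.lm's perfect-fit warning; R^2 = 1
  # is a legitimate outcome here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 n_points = length(d)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: slope %.3f, R^2 = %.3f (%d degree values)\n",
              x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Report hub nodes of a network
#'
#' Nodes ranked by degree (descending, ties broken by id), reported
#' separately for genes and lncRNAs.
#'
#' @param net A `CoexNetwork`.
#' @param top_k Number of hubs to keep per node type (default 10).
#' @return List with data frames `genes` and `lncrnas`
#'   (columns `id`, `degree`).
#' @export
hub_report <- function(net, top_k = 10L) {
  stopifnot(inherits(net, "CoexNetwork"))
  rank_type <- function(type) {
    ids <- net$nodes$id[net$nodes$type == type]
    deg <- net$degree[ids]
    ord <- order(-deg, ids)
    head(data.frame(id = ids[ord], degree = unname(deg[ord]),
                    stringsAsFactors = FALSE), top_k)
  }
  list(genes = rank_type("gene"), lncrnas = rank_type("lncRNA"))
}

#' Write a network as edge-list TSV and SIF
#'
#' @param net A `CoexNetwork`.
#' @param path Output TSV path; a `.sif` file with the same stem is written
#'   alongside when `sif = TRUE`.
#' @param sif Also write a SIF file for graph viewers (default TRUE).
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, sif = TRUE) {
  stopifnot(inherits(net, "CoexNetwork"))
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sif) {
    sif_path <- sub("\\.tsv$", ".sif", path)
    if (identical(sif_path, path)) sif_path <- paste0(path, ".sif")
    lines <- if (nrow(net$edges))
      paste(net$edges$gene_id, "coexpr", net$edges$lnc_id) else character(0)
    writeLines(lines, sif_path)
  }
  invisible(path)
}
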