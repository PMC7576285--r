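#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' The defaults reproduce the published analysis settings: genes are called
#' tumour-specific at p < 0.05 and lncRNAs at p < 0.01; gene-lncRNA pairs are
#' screened at |dPCC| > 0.3 and promoted to network edges at |dPCC| > 0.7;
#' per-patient risk features use the 70%/30% rank rule; a population is a risk
#' population when more than 50% of its network features are risk features;
#' and patients are grouped by risk-population count with bounds 4 and 9
#' (0-4 min-immune, 5-9 media-immune, 10+ multi-immune).
#'
#' @param p_gene Significance threshold for immune-cell-population marker
#'   genes (default 0.05).
#' @param p_lnc Significance threshold for lncRNAs (default 0.01).
#' @param delta_screen Absolute Pearson-correlation-difference threshold used
#'   to screen gene-lncRNA pairs (default 0.3, strict inequality).
#' @param delta_network Stricter |dPCC| threshold used to admit a screened
#'   pair as a network edge (default 0.7, strict inequality).
#' @param up_risk_frac For up-regulated features, the fraction of patients
#'   (ranked high-to-low by expression) that carry the feature as a risk
#'   feature: the bottom `up_risk_frac` of the ranking (default 0.70).
#' @param down_risk_frac For down-regulated features, the top fraction of the
#'   ranking that carries the feature as a risk feature (default 0.30).
#'   Must equal `1 - up_risk_frac`: one boundary index governs both rules.
#' @param pop_risk_frac A population is a risk population for a patient when
#'   the patient's risk-feature fraction strictly exceeds this value
#'   (default 0.50).
#' @param group_bounds Two integers `c(b1, b2)` partitioning risk-population
#'   counts into min-immune (0..b1), media-immune (b1+1..b2) and multi-immune
#'   (> b2) groups (default `c(4, 9)`).
#' @param zero_filter_frac Maximum tolerated fraction of zero expression
#'   values per feature before the feature is removed in preprocessing
#'   (default 0: any zero removes the feature).
#' @param pseudocount Value added to raw expression before log2
#'   transformation (default 1).
#' @param pair_p_max Optional ceiling on the smaller of a pair's two
#'   correlation p-values; `NULL` (default) disables the filter, matching the
#'   published analysis, which records pair p-values but does not filter on
#'   them.
#' @param use_adjusted_p If `TRUE`, significance flags use
#'   Benjamini-Hochberg-adjusted p-values instead of raw ones
#'   (default `FALSE`; the published thresholds are raw).
#' @param seed Integer seed for stochastic components (default 1).
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$delta_network
#' @export
pipeline_config <- function(p_gene = 0.05,
                            p_lnc = 0.01,
                            delta_screen = 0.3,
                            delta_network = 0.7,
                            up_risk_frac = 0.70,
                            down_risk_frac = 0.30,
                            pop_risk_frac = 0.50,
                            group_bounds = c(4L, 9L),
                            zero_filter_frac = 0,
                            pseudocount = 1,
                            pair_p_max = NULL,
                            use_adjusted_p = FALSE,
                            seed = 1L) {
  stop_unless <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  stop_unless(num1(p_gene) && p_gene > 0 && p_gene <= 1,
              "p_gene must be a single value in (0, 1]")
  stop_unless(num1(p_lnc) && p_lnc > 0 && p_lnc <= 1,
              "p_lnc must be a single value in (0, 1]")
  stop_unless(num1(delta_screen) && delta_screen > 0 && delta_screen <= 2,
              "delta_screen must be in (0, 2]")
  stop_unless(num1(delta_network) && delta_network > 0 && delta_network <= 2,
              "delta_network must be in (0, 2]")
  for (nm in c("up_risk_frac", "down_risk_frac", "pop_risk_frac")) {
    v <- get(nm)
    stop_unless(num1(v) && v > 0 && v < 1,
                paste0(nm, " must be a fraction in (0, 1)"))
  }
  stop_unless(abs(up_risk_frac + down_risk_frac - 1) < 1e-8,
              "up_risk_frac and down_risk_frac must sum to 1")
  stop_unless(is.numeric(group_bounds) && length(group_bounds) == 2L &&
                all(group_bounds == round(group_bounds)) &&
                group_bounds[1] >= 0 && group_bounds[1] < group_bounds[2],
              "group_bounds must be two integers with 0 <= b1 < b2")
  stop_unless(num1(zero_filter_frac) && zero_filter_frac >= 0 &&
                zero_filter_frac < 1,
              "zero_filter_frac must be in [0, 1)")
  stop_unless(num1(pseudocount) && pseudocount >= 0,
              "pseudocount must be non-negative")
  if (!is.null(pair_p_max))
    stop_unless(num1(pair_p_max) && pair_p_max > 0 && pair_p_max <= 1,
                "pair_p_max must be NULL or in (0, 1]")
  stop_unless(num1(seed) && seed == round(seed), "seed must be an integer")

  structure(
    list(p_gene = p_gene, p_lnc = p_lnc,
         delta_screen = delta_screen, delta_network = delta_network,
         up_risk_frac = up_risk_frac, down_risk_frac = down_risk_frac,
         pop_risk_frac = pop_risk_frac,
         group_bounds = as.integer(group_bounds),
         zero_filter_frac = zero_filter_frac, pseudocount = pseudocount,
         pair_p_max = pair_p_max, use_adjusted_p = use_adjusted_p,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  DE thresholds: genes p < %g, lncRNAs p < %g%s\n",
              x$p_gene, x$p_lnc,
              if (x$use_adjusted_p) " (BH-adjusted)" else ""))
  cat(sprintf("  |dPCC|: screen > %g, network > %g\n",
              x$delta_screen, x$delta_network))
  cat(sprintf("  Risk ranks: up %.0f%% / down %.0f%%; population > %.0f%%\n",
              100 * x$up_risk_frac, 100 * x$down_risk_frac,
              100 * x$pop_risk_frac))
  cat(sprintf("  Group bounds: 0-%d / %d-%d / >%d\n",
              x$group_bounds[1], x$group_bounds[1] + 1L, x$group_bounds[2],
              x$group_bounds[2]))
  invisible(x)
}

as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  if (is.list(x)) return(do.call(pipeline_config, x))
  stop("cannot interpret object as a pipeline configuration", call. = FALSE)
}
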