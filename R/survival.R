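#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimate `S(t) = prod(1 - d_i / n_i)` over the observed
#' event times, with right censoring reducing the risk set without a step.
#' At a time carrying both deaths and censorings, deaths are counted first
#' (the standard convention).
#'
#' @param records Data frame with columns `time` (>= 0) and `event`
#'   (1 = death, 0 = censored); a `sample_id` column is allowed and ignored.
#' @param group Optional label stored on the curve.
#' @return A `km_curve`: list with `group`, `times` (increasing event
#'   times), `survival` (non-increasing), `at_risk`, `n` (records used).
#'   With no events the curve is flat at 1 (empty `times`).
#' @export
km_estimate <- function(records, group = NULL) {
  if (!is.data.frame(records) || !nrow(records))
    stop("need at least one survival record", call. = FALSE)
  df <- data.frame(time = as.numeric(records$time),
                   event = as.integer(records$event))
  validate_clinical(data.frame(sample_id = as.character(seq_len(nrow(df))),
                               df, stringsAsFactors = FALSE))
  fit <- survfit(Surv(time, event) ~ 1, data = df)
  keep <- fit$n.event > 0
  structure(list(group = group,
                 times = fit$time[keep],
                 survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep],
                 n = nrow(df)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve%s: %d records, %d event times\n",
              if (!is.null(x$group)) paste0(" [", x$group, "]") else "",
              x$n, length(x$times)))
  invisible(x)
}

#' K-sample log-rank test
#'
#' Standard unweighted log-rank chi-square comparing the survival of two or
#' more groups, with `df = k - 1` for `k` non-empty groups.
#'
#' @param records Data frame with columns `time` and `event`.
#' @param group Vector of group labels, one per record.
#' @return A `logrank_result`: list with `statistic`, `df`, `p_value`,
#'   `groups` (labels) and `n` (records used).
#' @export
log_rank <- function(records, group) {
  if (length(group) != nrow(records))
    stop("group labels must match record count", call. = FALSE)
  group <- as.character(group)
  keep <- !is.na(group)
  df <- data.frame(time = as.numeric(records$time[keep]),
                   event = as.integer(records$event[keep]),
                   group = group[keep], stringsAsFactors = FALSE)
  labs <- unique(df$group)
  if (length(labs) < 2L)
    stop("log-rank test needs at least 2 non-empty groups", call. = FALSE)
  fit <- survdiff(Surv(time, event) ~ group, data = df)
  k <- length(labs)
  structure(list(statistic = unname(fit$chisq),
                 df = k - 1L,
                 p_value = pchisq(unname(fit$chisq), df = k - 1L,
                                  lower.tail = FALSE),
                 groups = labs, n = nrow(df)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square %.3f on %d df, p = %.4g (%d groups, n = %d)\n",
              x$statistic, x$df, x$p_value, length(x$groups), x$n))
  invisible(x)
}

#' Kaplan-Meier curves by group
#'
#' @param records Data frame with columns `time` and `event`.
#' @param group Vector of group labels, one per record.
#' @return Named list of `km_curve` objects (empty groups omitted).
#' @export
km_by_group <- function(records, group) {
  group <- as.character(group)
  labs <- unique(group[!is.na(group)])
  setNames(lapply(labs, function(g)
    km_estimate(records[group %in% g, , drop = FALSE], group = g)), labs)
}

#' Write KM curves as one TSV
#'
#' @param curves Named list of `km_curve` objects.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_km_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    if (!length(cv$times))
      return(data.frame(group = character(0), time = numeric(0),
                        survival = numeric(0), at_risk = integer(0)))
    data.frame(group = cv$group, time = cv$times, survival = cv$survival,
               at_risk = cv$at_risk, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
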