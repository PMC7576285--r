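# Independent brute-force oracles, deliberately written with naive loops and
# textbook formulas so they share no code path with the package.

# Pearson r by direct evaluation of the covariance / sd*sd formula.
oracle_pearson <- function(u, v) {
  n <- length(u)
  mu <- sum(u) / n
  mv <- sum(v) / n
  num <- sum((u - mu) * (v - mv))
  den <- sqrt(sum((u - mu)^2)) * sqrt(sum((v - mv)^2))
  num / den
}

# Welch t statistic and two-sided p from the textbook formulas.
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df))
}

# Product-limit estimator by an explicit loop over distinct times; at a tied
# time, deaths are processed before censorings.
oracle_km <- function(time, event) {
  ut <- sort(unique(time))
  s <- 1
  out_t <- numeric(0); out_s <- numeric(0); out_n <- numeric(0)
  for (t in ut) {
    n_at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    if (d > 0) {
      s <- s * (1 - d / n_at_risk)
      out_t <- c(out_t, t); out_s <- c(out_s, s)
      out_n <- c(out_n, n_at_risk)
    }
  }
  list(times = out_t, survival = out_s, at_risk = out_n)
}

# Literal re-implementation of the four-step risk algorithm, O(N^2) ranking:
# a patient's rank = 1 + number of patients with strictly higher expression,
# or equal expression and a lexicographically smaller id.
oracle_risk <- function(expr, pids, networks, directions,
                        down_frac = 0.3, pop_frac = 0.5,
                        bounds = c(4, 9)) {
  n <- length(pids)
  k <- ceiling(down_frac * n)
  risk_sets <- list()
  for (pop in names(networks)) {
    feats <- networks[[pop]]
    for (p in pids) risk_sets[[pop]][[p]] <- character(0)
    for (f in feats) {
      for (p in pids) {
        r <- 1
        for (q in pids) {
          if (q == p) next
          if (expr[f, q] > expr[f, p] ||
              (expr[f, q] == expr[f, p] && q < p)) r <- r + 1
        }
        hit <- if (directions[[f]] == "up") r > k else r <= k
        if (hit) risk_sets[[pop]][[p]] <- c(risk_sets[[pop]][[p]], f)
      }
    }
  }
  counts <- setNames(integer(n), pids)
  for (pop in names(networks)) {
    nf <- length(networks[[pop]])
    if (nf == 0) next
    for (p in pids) {
      if (length(risk_sets[[pop]][[p]]) / nf > pop_frac)
        counts[p] <- counts[p] + 1L
    }
  }
  groups <- character(n)
  for (i in seq_len(n)) {
    c_i <- counts[i]
    groups[i] <- if (c_i <= bounds[1]) "min_immune"
                 else if (c_i <= bounds[2]) "media_immune"
                 else "multi_immune"
  }
  list(risk_sets = risk_sets, counts = counts,
       groups = setNames(groups, pids))
}

# Small helpers for building fixtures in code ---------------------------------

# ExpressionMatrix from a log2-scale matrix (bypasses preprocessing).
make_log2_matrix <- function(vals, classes, groups) {
  x <- expression_matrix(vals, classes, groups)
  attr(x, "log2") <- TRUE
  x
}

# Random small instance for oracle-equivalence testing.
random_risk_instance <- function(n_patients, n_pops, max_features,
                                 with_ties = FALSE) {
  pids <- sprintf("P%02d", seq_len(n_patients))
  pops <- sprintf("pop%d", seq_len(n_pops))
  networks <- list()
  feats <- character(0)
  for (pop in pops) {
    nf <- sample(1:max_features, 1)
    f <- sprintf("%s_f%d", gsub("pop", "X", pop), seq_len(nf))
    networks[[pop]] <- f
    feats <- c(feats, f)
  }
  vals <- matrix(round(rnorm(length(feats) * n_patients), 2),
                 nrow = length(feats),
                 dimnames = list(feats, pids))
  if (with_ties) {
    # force ties in a random feature row
    f <- sample(feats, 1)
    vals[f, ] <- sample(c(0, 1), n_patients, replace = TRUE)
  }
  directions <- setNames(sample(c("up", "down"), length(feats),
                                replace = TRUE), feats)
  classes <- setNames(rep("gene", length(feats)), feats)
  groups <- setNames(rep("tumor", n_patients), pids)
  list(x = make_log2_matrix(vals, classes, groups),
       vals = vals, pids = pids, networks = networks,
       directions = directions)
}

# Tiny two-group expression fixture on the log2 scale.
toy_expression <- function(n_feat = 6, n_tumor = 10, n_normal = 8,
                           n_lnc = 2, seed = 42) {
  set.seed(seed)
  fid <- c(sprintf("G%02d", seq_len(n_feat - n_lnc)),
           sprintf("L%02d", seq_len(n_lnc)))
  sid <- c(sprintf("T%02d", seq_len(n_tumor)),
           sprintf("N%02d", seq_len(n_normal)))
  vals <- matrix(rnorm(length(fid) * length(sid), 8, 1),
                 nrow = length(fid), dimnames = list(fid, sid))
  classes <- setNames(rep(c("gene", "lncRNA"), c(n_feat - n_lnc, n_lnc)),
                      fid)
  groups <- setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)), sid)
  make_log2_matrix(vals, classes, groups)
}
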