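test_that("pcc matches the direct covariance formula and cor.test", {
  u <- c(1, 2, 3, 4, 5)
  expect_equal(unname(pcc(u, u)["r"]), 1.0)
  expect_equal(unname(pcc(u, -u)["r"]), -1.0)

  v <- c(2, 1, 4, 3, 6)
  res <- pcc(u, v)
  expect_equal(unname(res["r"]), 0.821994936526786, tolerance = 1e-12)
  expect_equal(unname(res["r"]), oracle_pearson(u, v), tolerance = 1e-14)
  ref <- cor.test(u, v)
  expect_equal(unname(res["p"]), ref$p.value, tolerance = 1e-12)

  expect_error(pcc(c(1, 1, 1), c(1, 2, 3)), "constant vector")
  expect_error(pcc(1:2, 1:2), "at least 3")
  expect_error(pcc(1:4, 1:5), "length")
})

test_that("pcc agrees with the brute-force oracle on 100 random pairs", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    u <- rnorm(n); v <- rnorm(n)
    expect_equal(unname(pcc(u, v)["r"]), oracle_pearson(u, v),
                 tolerance = 1e-12)
  }
})

test_that("correlation change patterns follow the sign-flip rules", {
  # published worked examples: ABCB4-LINC00844-like flip and its converse
  expect_equal(classify_pattern(-0.58, 0.58), "negative_to_positive")
  expect_equal(classify_pattern(0.70, -0.28), "positive_to_negative")
  expect_equal(classify_pattern(0.4, 0.9), "same_sign_strengthened")
  expect_equal(classify_pattern(-0.9, -0.2), "same_sign_weakened")
  expect_equal(classify_pattern(c(-0.5, 0.5), c(0.5, 0.8)),
               c("negative_to_positive", "same_sign_strengthened"))
})

# Build a small matrix with one planted sign-flipping pair via a shared
# latent factor; all other features are independent noise.
planted_pair_matrix <- function(n_t = 60, n_n = 60, seed = 17) {
  set.seed(seed)
  sid <- c(sprintf("T%03d", 1:n_t), sprintf("N%03d", 1:n_n))
  groups <- setNames(rep(c("tumor", "normal"), c(n_t, n_n)), sid)
  fid <- c("G1", "G2", "G3", "L1", "L2", "L3")
  vals <- matrix(rnorm(length(fid) * length(sid), 8, 1), nrow = length(fid),
                 dimnames = list(fid, sid))
  z <- rnorm(length(sid))
  a <- sqrt(0.9); b <- sqrt(0.1)
  sgn <- ifelse(groups == "tumor", 1, -1)
  vals["G1", ] <- 8 + a * z + b * rnorm(length(sid))
  vals["L1", ] <- 8 + sgn * a * z + b * rnorm(length(sid))
  classes <- setNames(rep(c("gene", "lncRNA"), each = 3), fid)
  make_log2_matrix(vals, classes, groups)
}

test_that("screen_pairs retains the planted pair with correct fields", {
  x <- planted_pair_matrix()
  pairs <- screen_pairs(x, list(pop1 = c("G1", "G2", "G3")),
                        c("L1", "L2", "L3"), pipeline_config())
  expect_s3_class(pairs, "coex_pairs")
  hit <- pairs[pairs$gene_id == "G1" & pairs$lnc_id == "L1", ]
  expect_equal(nrow(hit), 1)
  expect_gt(hit$delta, 1.5)
  expect_equal(hit$delta, abs(hit$pcc_tumor - hit$pcc_normal))
  expect_equal(hit$pattern, "negative_to_positive")
  expect_lt(hit$p_tumor, 1e-6)
  # every retained pair respects the strict screening threshold
  expect_true(all(pairs$delta > 0.3))

  # fields agree with scalar pcc on the same vectors
  tum <- x$sample_group == "tumor"
  expect_equal(hit$pcc_tumor,
               unname(pcc(x$values["G1", tum], x$values["L1", tum])["r"]),
               tolerance = 1e-12)
})

test_that("identical correlation structure in both groups yields nothing", {
  # independent features in both groups: population deltas are 0 and with
  # 300 samples per group the sampling noise stays far below 0.3
  set.seed(30)
  x <- toy_expression(n_feat = 8, n_tumor = 300, n_normal = 300, n_lnc = 3)
  pairs <- screen_pairs(x, list(p = sprintf("G%02d", 1:5)),
                        sprintf("L%02d", 1:3), pipeline_config())
  expect_equal(nrow(pairs), 0)
})

test_that("screening is invariant to sample and feature ordering", {
  x <- planted_pair_matrix(seed = 23)
  cfg <- pipeline_config()
  base <- screen_pairs(x, list(pop1 = c("G1", "G2", "G3")),
                       c("L1", "L2", "L3"), cfg)
  set.seed(1)
  xp <- subset_expression(x, features = sample(rownames(x$values)),
                          samples = sample(colnames(x$values)))
  perm <- screen_pairs(xp, list(pop1 = c("G3", "G1", "G2")),
                       c("L2", "L3", "L1"), cfg)
  expect_equal(base, perm)
})

test_that("delta is symmetric in the two groups up to pattern relabeling", {
  x <- planted_pair_matrix(seed = 41)
  sw <- x
  sw$sample_group[] <- ifelse(x$sample_group == "tumor", "normal", "tumor")
  cfg <- pipeline_config()
  a <- screen_pairs(x, list(p = c("G1", "G2", "G3")), c("L1", "L2", "L3"),
                    cfg)
  b <- screen_pairs(sw, list(p = c("G1", "G2", "G3")), c("L1", "L2", "L3"),
                    cfg)
  key <- function(df) paste(df$gene_id, df$lnc_id)
  expect_setequal(key(a), key(b))
  m <- match(key(a), key(b))
  expect_equal(a$delta, b$delta[m], tolerance = 1e-12)
  expect_equal(a$pcc_tumor, b$pcc_normal[m])
})

test_that("delta histogram bins pooled pairs on (low, high] edges", {
  pairs <- data.frame(delta = c(0.31, 0.35, 0.4, 0.45, 0.71, 1.16))
  h <- delta_histogram(pairs)
  expect_equal(h$n[h$bin_low == 0.3], 3)  # 0.4 falls in (0.3, 0.4]
  expect_equal(h$n[h$bin_low == 0.4], 1)
  expect_equal(h$n[abs(h$bin_low - 0.7) < 1e-9], 1)
  expect_equal(sum(h$n), 6)
})
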