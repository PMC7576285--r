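test_that("expression TSV + class map round-trips through read/write", {
  x <- toy_expression()
  x$values <- round(x$values, 3)  # exact decimal printing
  d <- withr::local_tempdir()
  ep <- file.path(d, "expr.tsv"); mp <- file.path(d, "map.tsv")
  write_expression(x, ep, mp)
  y <- read_expression(ep, mp)
  expect_equal(y$values, x$values)
  expect_equal(y$feature_class, x$feature_class)
  expect_equal(y$sample_group, x$sample_group)

  # bit-identical second write
  ep2 <- file.path(d, "expr2.tsv")
  write_expression(y, ep2, file.path(d, "map2.tsv"))
  expect_identical(readLines(ep), readLines(ep2))
})

test_that("reader validation names the offending records", {
  d <- withr::local_tempdir()
  ep <- file.path(d, "expr.tsv"); mp <- file.path(d, "map.tsv")
  writeLines(c("feature_id\tS1\tS2\tS3\tS4",
               "F1\t1\t2\t3\t4", "F1\t5\t6\t7\t8"), ep)
  writeLines(c("id\tlabel", "F1\tgene", "S1\ttumor", "S2\ttumor",
               "S3\tnormal", "S4\tnormal"), mp)
  expect_error(read_expression(ep, mp), "duplicate feature ids.*F1")

  writeLines(c("feature_id\tS1\tS2\tS3\tS4",
               "F1\t1\t2\t3\t4", "F2\t5\t6\t7\t8"), ep)
  writeLines(c("id\tlabel", "F1\tgene", "S1\ttumor", "S2\ttumor",
               "S3\tnormal", "S4\tnormal"), mp)
  expect_error(read_expression(ep, mp), "missing from class map.*F2")

  # all samples tumor: the normal group is empty
  writeLines(c("id\tlabel", "F1\tgene", "F2\tgene", "S1\ttumor",
               "S2\ttumor", "S3\ttumor", "S4\ttumor"), mp)
  expect_error(read_expression(ep, mp), "group has no samples")
})

test_that("preprocess drops any-zero features and log2-transforms", {
  vals <- rbind(A = c(3, 1, 7, 15), B = c(0, 2, 4, 8), C = c(1, 1, 1, 3))
  colnames(vals) <- c("T1", "T2", "N1", "N2")
  x <- expression_matrix(vals,
                         setNames(rep("gene", 3), rownames(vals)),
                         setNames(c("tumor", "tumor", "normal", "normal"),
                                  colnames(vals)))
  expect_message(out <- preprocess(x, pipeline_config()), "removed 1 of 3")
  expect_equal(rownames(out$values), c("A", "C"))
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_equal(out$values["A", "T1"], log2(4))  # 3 with pseudocount 1 -> 2
  expect_equal(out$values["A", "T1"], 2.0)
  expect_true(all(is.finite(out$values)))

  # relaxed zero filter keeps the feature with one zero in four samples
  cfg <- pipeline_config(zero_filter_frac = 0.5)
  expect_equal(nrow(preprocess(x, cfg)$values), 3)

  # monotone transform: all-positive matrix, no drops, order preserved
  x2 <- expression_matrix(vals[c("A", "C"), ],
                          setNames(rep("gene", 2), c("A", "C")),
                          x$sample_group)
  out2 <- preprocess(x2, pipeline_config())
  expect_equal(attr(out2, "n_dropped"), 0L)
  expect_equal(order(out2$values["A", ]), order(vals["A", ]))

  expect_error(preprocess(
    expression_matrix(matrix(0, 1, 4,
                             dimnames = list("Z", colnames(vals))),
                      c(Z = "gene"), x$sample_group),
    pipeline_config()), "all features removed")
})

test_that("bundled fixture provides the 17 immune cell populations", {
  sets <- immune_populations()
  expect_s3_class(sets, "ImmuneGeneSets")
  expect_length(sets, 17)
  expect_true(all(c("B cells", "Tregs", "neutrophils") %in% names(sets)))
  expect_true(all(lengths(sets) > 0))
  expect_false(anyDuplicated(names(sets)) > 0)
  # symbols unique within each population
  expect_true(all(vapply(sets, function(s) !anyDuplicated(s), logical(1))))
})

test_that("GMT parsing handles minimal files and rejects malformed ones", {
  d <- withr::local_tempdir()
  p <- file.path(d, "one.gmt")
  writeLines("my set\tdesc\tA\tB\tC", p)
  sets <- read_gene_sets(p)
  expect_equal(names(sets), "my set")
  expect_equal(sets[["my set"]], c("A", "B", "C"))

  writeLines(c("s1\td\tA", "s1\td\tB"), p)
  expect_error(read_gene_sets(p), "duplicate gene-set names.*s1")

  writeLines(c("s1\td\tA", "s2\td"), p)
  expect_error(read_gene_sets(p), "empty gene set.*s2")
})

test_that("clinical table reader enforces the time/event contract", {
  d <- withr::local_tempdir()
  p <- file.path(d, "clin.tsv")
  writeLines(c("sample_id\ttime_days\tevent",
               "P1\t100\t1", "P2\t250.5\t0"), p)
  clin <- read_clinical(p)
  expect_equal(clin$sample_id, c("P1", "P2"))
  expect_equal(clin$time, c(100, 250.5))
  expect_equal(clin$event, c(1L, 0L))

  writeLines(c("sample_id\ttime_days\tevent", "P1\t-3\t1"), p)
  expect_error(read_clinical(p), "non-negative")
  writeLines(c("sample_id\ttime_days\tevent", "P1\t3\t2"), p)
  expect_error(read_clinical(p), "event")
  writeLines(c("sample_id\ttime_days\tevent", "P1\t3\t1", "P1\t4\t0"), p)
  expect_error(read_clinical(p), "duplicate")
})

test_that("configuration validation rejects out-of-range thresholds", {
  expect_error(pipeline_config(delta_network = 2.1), "delta_network")
  expect_error(pipeline_config(p_gene = 0), "p_gene")
  expect_error(pipeline_config(up_risk_frac = 0.8), "sum to 1")
  expect_error(pipeline_config(group_bounds = c(9, 4)), "group_bounds")
  expect_silent(cfg <- pipeline_config(delta_screen = 0.5,
                                       delta_network = 0.5))
  expect_equal(cfg$delta_screen, 0.5)
})
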