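# One-feature instance with expression arranged so patient P01 has rank 1,
# P02 rank 2, ...: expression 10, 9, 8, ... for ids in order.
ranked_instance <- function(n = 10, direction = "up") {
  pids <- sprintf("P%02d", seq_len(n))
  vals <- matrix(seq(n, 1), nrow = 1, dimnames = list("F1", pids))
  x <- make_log2_matrix(vals, c(F1 = "gene"),
                        setNames(rep("tumor", n), pids))
  call_risk_features(x, list(pop1 = "F1"),
                     c(F1 = direction), pipeline_config())
}

test_that("rank boundary: ceil(0.3 N) splits risk calls as specified", {
  # N = 10, k = 3: up-regulated -> ranks 4..10 are risk
  up <- ranked_instance(10, "up")[["pop1"]][, "F1"]
  expect_false(up[["P03"]])  # rank 3: top block, not risk
  expect_true(up[["P04"]])   # rank 4: risk
  expect_equal(sum(up), 7)

  # down-regulated -> ranks 1..3 are risk
  dn <- ranked_instance(10, "down")[["pop1"]][, "F1"]
  expect_true(dn[["P01"]])
  expect_false(dn[["P04"]])
  expect_equal(sum(dn), 3)

  # N = 7, k = ceil(2.1) = 3
  up7 <- ranked_instance(7, "up")[["pop1"]][, "F1"]
  expect_equal(sum(up7), 4)
  expect_false(up7[["P03"]])
  expect_true(up7[["P04"]])
})

test_that("expression ties resolve deterministically by patient id", {
  pids <- sprintf("P%02d", 1:6)
  vals <- matrix(rep(5, 6), nrow = 1, dimnames = list("F1", pids))
  x <- make_log2_matrix(vals, c(F1 = "gene"),
                        setNames(rep("tumor", 6), pids))
  a <- call_risk_features(x, list(p = "F1"), c(F1 = "down"),
                          pipeline_config())
  b <- call_risk_features(x, list(p = "F1"), c(F1 = "down"),
                          pipeline_config())
  expect_identical(a[["p"]], b[["p"]])
  # all tied: the top block is the k lexicographically smallest ids
  expect_equal(sum(a[["p"]][, "F1"]), ceiling(0.3 * 6))
  expect_true(all(a[["p"]][c("P01", "P02"), "F1"]))
})

test_that("missing directions are reported by feature name", {
  pids <- c("P1", "P2", "P3")
  vals <- matrix(rnorm(6), nrow = 2, dimnames = list(c("F1", "F2"), pids))
  x <- make_log2_matrix(vals, c(F1 = "gene", F2 = "gene"),
                        setNames(rep("tumor", 3), pids))
  expect_error(call_risk_features(x, list(p = c("F1", "F2")),
                                  c(F1 = "up"), pipeline_config()),
               "missing a direction.*F2")
})

test_that("risk populations need strictly more than 50% risk features", {
  m <- matrix(FALSE, nrow = 3, ncol = 20,
              dimnames = list(c("Pa", "Pb", "Pc"), sprintf("F%d", 1:20)))
  m["Pa", 1:11] <- TRUE  # 55% -> risk
  m["Pb", 1:10] <- TRUE  # exactly 50% -> not risk
  rf <- structure(list(pop1 = m), k = 1, patients = rownames(m),
                  class = "risk_feature_calls")
  calls <- call_risk_populations(rf, pipeline_config())
  expect_equal(calls$is_risk[calls$patient_id == "Pa"], TRUE)
  expect_equal(calls$is_risk[calls$patient_id == "Pb"], FALSE)
  expect_equal(calls$is_risk[calls$patient_id == "Pc"], FALSE)
  expect_equal(calls$n_risk_features[calls$patient_id == "Pa"], 11)
})

test_that("empty population networks are skipped with a warning", {
  m1 <- matrix(TRUE, 2, 3, dimnames = list(c("Pa", "Pb"),
                                           c("F1", "F2", "F3")))
  m0 <- matrix(FALSE, 2, 0, dimnames = list(c("Pa", "Pb"), NULL))
  rf <- structure(list(full = m1, empty = m0), k = 1,
                  patients = c("Pa", "Pb"), class = "risk_feature_calls")
  expect_warning(calls <- call_risk_populations(rf, pipeline_config()),
                 "empty")
  expect_equal(unique(calls$population), "full")
  # the skipped population does not enter the per-patient total
  prof <- risk_profiles(calls, pipeline_config())
  expect_equal(prof$risk_population_count, c(1L, 1L))
})

test_that("group bounds map counts 0,4 / 5,9 / 10,17 to the three groups", {
  cfg <- pipeline_config()
  expect_equal(as.character(assign_group(c(0, 4), cfg)),
               rep("min_immune", 2))
  expect_equal(as.character(assign_group(c(5, 9), cfg)),
               rep("media_immune", 2))
  expect_equal(as.character(assign_group(c(10, 17), cfg)),
               rep("multi_immune", 2))
  expect_error(assign_group(18, cfg), "in \\[0, 17\\]")
  expect_error(assign_group(-1, cfg), "in \\[0, 17\\]")
})

test_that("two-group splits at boundaries 6 and 7 are nested partitions", {
  profiles <- data.frame(patient_id = c("Pa", "Pb", "Pc"),
                         risk_population_count = c(3L, 7L, 12L),
                         stringsAsFactors = FALSE)
  s7 <- two_group_split(profiles, 7)
  expect_equal(s7$low, "Pa")
  expect_equal(s7$high, c("Pb", "Pc"))
  s6 <- two_group_split(profiles, 6)
  expect_true(all(s7$high %in% s6$high))
  expect_true(all(s6$low %in% s7$low))
  # every patient on exactly one side
  expect_setequal(c(s7$low, s7$high), profiles$patient_id)

  all_zero <- data.frame(patient_id = c("Pa", "Pb"),
                         risk_population_count = c(0L, 0L))
  expect_warning(two_group_split(all_zero, 1), "empty")
  expect_error(two_group_split(profiles, 0), "boundary")
})

test_that("full risk pipeline equals the literal brute-force oracle", {
  set.seed(77)
  cfg <- pipeline_config()
  for (i in 1:25) {
    inst <- random_risk_instance(n_patients = sample(3:10, 1),
                                 n_pops = sample(1:5, 1),
                                 max_features = 8,
                                 with_ties = i %% 3 == 0)
    rf <- call_risk_features(inst$x, inst$networks, inst$directions, cfg)
    calls <- call_risk_populations(rf, cfg)
    prof <- risk_profiles(calls, cfg)
    orc <- oracle_risk(inst$vals, inst$pids, inst$networks,
                       inst$directions)
    expect_equal(setNames(prof$risk_population_count, prof$patient_id),
                 orc$counts[prof$patient_id])
    expect_equal(as.character(prof$group),
                 unname(orc$groups[prof$patient_id]))
    # per-feature risk sets match too
    for (pop in names(inst$networks)) {
      pkg_sets <- apply(rf[[pop]], 1, function(r) sort(names(which(r))),
                        simplify = FALSE)
      for (p in inst$pids)
        expect_equal(sort(pkg_sets[[p]]), sort(orc$risk_sets[[pop]][[p]]))
    }
  }
})

test_that("raising an up-regulated feature never adds it to a risk set", {
  set.seed(13)
  inst <- random_risk_instance(8, 1, 4)
  f <- inst$networks[[1]][1]
  inst$directions[f] <- "up"
  cfg <- pipeline_config()
  before <- call_risk_features(inst$x, inst$networks, inst$directions,
                               cfg)[[1]][, f]
  for (p in inst$pids) {
    x2 <- inst$x
    x2$values[f, p] <- x2$values[f, p] + 5
    after <- call_risk_features(x2, inst$networks, inst$directions,
                                cfg)[[1]][, f]
    expect_true(!after[[p]] || before[[p]])
  }
})

test_that("risk-population counts are monotone in the population threshold", {
  set.seed(14)
  inst <- random_risk_instance(8, 3, 5)
  cfg_hi <- pipeline_config(pop_risk_frac = 0.999)
  rf <- call_risk_features(inst$x, inst$networks, inst$directions, cfg_hi)
  prof_hi <- risk_profiles(call_risk_populations(rf, cfg_hi), cfg_hi)
  cfg_lo <- pipeline_config(pop_risk_frac = 0.001)
  prof_lo <- risk_profiles(call_risk_populations(rf, cfg_lo), cfg_lo)
  # counts weakly increase as the population threshold drops
  expect_true(all(prof_lo$risk_population_count >=
                    prof_hi$risk_population_count))
  # exhaustiveness: every patient in exactly one group
  expect_equal(sum(table(prof_lo$group)), length(inst$pids))
})
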