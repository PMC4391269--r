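test_that("weighted difference matches the closed-form logistic", {
  expect_equal(weighted_diff(1.0, 1.0, 1.0), 1 / (1 + exp(5)))
  expect_equal(weighted_diff(1.0, 1.0, 1.0), 0.006693, tolerance = 1e-4)
  expect_equal(weighted_diff(1.5, 1.0, 1.0), 0.5)
  expect_equal(weighted_diff(2.0, 1.0, 1.0), 1 / (1 + exp(-5)))
  expect_equal(weighted_diff(2.0, 1.0, 1.0), 0.993307, tolerance = 1e-4)
  # sums over points per series
  expect_equal(weighted_diff(c(1.5, 1.5), c(1, 1), c(1, 1)), 1.0)
  expect_error(weighted_diff(1, 1, 0), "positive")
  expect_error(weighted_diff(1:2, 1, 1), "lengths")
})

test_that("weighted difference grows monotonically with the mismatch", {
  difs <- seq(0, 3, by = 0.1)
  vals <- vapply(difs, function(d) weighted_diff(1 + d, 1, 1), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("objective evaluation separates good from hopeless settings", {
  cfg <- gi2_config()
  truth <- partition_table2("gi2", 1)
  meas <- generate_measurements(synthetic_study(truth = truth, cv = 0),
                                cfg, seed = 1)
  ob <- evaluate_setting(truth, cfg, meas)
  expect_named(ob, c("leaf_area", "leaf_mass", "root_mass", "stem_mass"))
  expect_true(all(ob < 4 * 0.0067 + 1e-4))   # dif = 0 at every point
  # no allocation to leaf area growth: gross underprediction saturates
  noarea <- unclass(truth)
  noarea[, "lambda_t"] <- noarea[, "lambda_t"] + noarea[, "lambda_s"]
  noarea[, "lambda_s"] <- 0
  noarea["germination", ] <- c(0, 0, 0, 1)
  ob2 <- evaluate_setting(partition_set(noarea), cfg, meas)
  expect_gte(ob2[["leaf_area"]], 1)
})

test_that("constraint box defaults encode the stated physiology", {
  box <- constraint_box()
  expect_equal(unname(box$lower["early_vegetative", "iota"]), 0)
  expect_equal(unname(box$upper["early_vegetative", "iota"]), 0)
  expect_equal(unname(box$lower["late_vegetative", "rho"]), 0.01)
  expect_equal(unname(box$lower["reproductive", "rho"]), 0.01)
  expect_error(constraint_box(lower = matrix(0.5, 4, 4),
                              upper = matrix(0.4, 4, 4)),
               "lower bound above")
})

test_that("simplex repair renormalizes and respects bounds", {
  box <- constraint_box(lower = matrix(0, 4, 4), upper = matrix(1, 4, 4))
  ps <- leafcarbon:::genome_to_partitions(rep(0.2, 16), box)
  expect_equal(unname(unclass(ps)), matrix(0.25, 4, 4))
  # bounded repair: pinned zeros stay zero, floors hold
  ps2 <- leafcarbon:::genome_to_partitions(runif(16), constraint_box())
  m <- unclass(ps2)
  expect_equal(unname(m["early_vegetative", "iota"]), 0)
  expect_gte(m["late_vegetative", "rho"], 0.01)
  expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-9)
})

test_that("non-dominated sorting and crowding behave on known cases", {
  objs <- rbind(c(1, 1, 1, 1),    # dominates everything below
                c(2, 2, 2, 2),
                c(1, 3, 1, 1),    # dominated by row 1 only
                c(3, 1, 1, 1))
  rk <- leafcarbon:::nds_rank(objs)
  expect_equal(rk[1], 1L)
  expect_true(all(rk[2:4] == 2L))
  cd <- leafcarbon:::crowding_distance(rbind(c(0, 2), c(1, 1), c(2, 0)))
  expect_true(is.infinite(cd[1]) && is.infinite(cd[3]))
  expect_true(is.finite(cd[2]))
})

test_that("moment-matching estimate lands near a noiseless truth", {
  cfg <- gi2_config()
  truth <- partition_table2("gi2", 1)
  meas <- generate_measurements(synthetic_study(truth = truth, cv = 0),
                                cfg, seed = 1)
  est <- unclass(estimate_partitions(meas, cfg))
  tr <- unclass(truth)
  for (p in c("early_vegetative", "late_vegetative", "reproductive"))
    expect_lt(max(abs(est[p, ] - tr[p, ])), 0.11)
})

test_that("small calibration runs are reproducible and non-dominated", {
  cfg <- gi2_config()
  meas <- generate_measurements(
    synthetic_study(truth = partition_table2("gi2", 1), cv = 0),
    cfg, seed = 1)
  f1 <- suppressWarnings(fit_nsga2(cfg, meas, pop_size = 8, generations = 3,
                                   seed = 5, init = "random"))
  f2 <- suppressWarnings(fit_nsga2(cfg, meas, pop_size = 8, generations = 3,
                                   seed = 5, init = "random"))
  expect_identical(f1$pareto, f2$pareto)
  ob <- as.matrix(f1$pareto[, c("leaf_area", "leaf_mass",
                                "root_mass", "stem_mass")])
  expect_true(all(leafcarbon:::nds_rank(ob) == 1L))
  expect_error(fit_nsga2(cfg, meas, pop_size = 7), "even")
})

test_that("clustering recovers planted structure and ranks by leaf fit", {
  coef_cols <- paste(rep(c("germination", "early_vegetative",
                           "late_vegetative", "reproductive"), each = 4),
                     c("iota", "rho", "lambda_s", "lambda_t"), sep = ".")
  set.seed(9)
  mk <- function(center, n) {
    m <- matrix(rep(center, n), n, 16, byrow = TRUE) +
      matrix(rnorm(n * 16, 0, 0.005), n, 16)
    colnames(m) <- coef_cols
    m
  }
  a <- mk(rep(c(0, 0, 0.8, 0.2), 4), 6)
  b <- mk(rep(c(0.3, 0.3, 0.2, 0.2), 4), 6)
  q <- data.frame(rbind(a, b),
                  leaf_area = c(runif(6, 0, 0.2), runif(6, 0.3, 0.5)),
                  leaf_mass = runif(12, 0, 0.2),
                  root_mass = runif(12, 0, 1), stem_mass = runif(12, 0, 1))
  cr <- cluster_and_rank(q)
  expect_equal(cr$k, 2)
  lab <- cr$settings$cluster[match(as.character(1:12),
                                   rownames(cr$settings))]
  expect_equal(length(unique(lab[1:6])), 1)    # group a intact
  expect_equal(length(unique(lab[7:12])), 1)   # group b intact
  expect_true(lab[1] != lab[7])                # and separated
  expect_true(all(cr$settings$rank_score == sort(cr$settings$rank_score)))
  # better leaf objectives rank first
  expect_lt(cr$top2$rank_score[1], max(q$leaf_area + q$leaf_mass))

  dup <- q[rep(1, 5), ]
  cr2 <- cluster_and_rank(dup)
  expect_equal(cr2$k, 1L)
  expect_warning(cluster_and_rank(q[1, ]), "fewer than 2")
})
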