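test_that("perturbations touch exactly the named quantities", {
  cfg <- col0_config()
  base <- unclass(cfg$partitions)

  p1 <- perturbation("coefficient", 0.01, phase = "early_vegetative",
                     coeff = "lambda_t", compensate = "lambda_s")
  m1 <- unclass(apply_perturbation(cfg, p1)$partitions)
  expect_equal(m1["early_vegetative", "lambda_t"],
               base["early_vegetative", "lambda_t"] + 0.01)
  expect_equal(m1["early_vegetative", "lambda_s"],
               base["early_vegetative", "lambda_s"] - 0.01)
  expect_equal(m1["early_vegetative", c("iota", "rho")],
               base["early_vegetative", c("iota", "rho")])
  expect_equal(m1["late_vegetative", ], base["late_vegetative", ])

  p2 <- perturbation("coefficient", 0.01, phase = "early_vegetative",
                     coeff = "rho", compensate = "lambda_t")
  m2 <- unclass(apply_perturbation(cfg, p2)$partitions)
  expect_equal(m2["early_vegetative", "rho"],
               base["early_vegetative", "rho"] + 0.01)
  expect_equal(m2["early_vegetative", "lambda_t"],
               base["early_vegetative", "lambda_t"] - 0.01)
  expect_equal(m2["early_vegetative", "lambda_s"],
               base["early_vegetative", "lambda_s"])

  p3 <- perturbation("photosynthesis", 0.01)
  cfg3 <- apply_perturbation(cfg, p3)
  expect_equal(cfg3$photo$coefficients, cfg$photo$coefficients * 1.01)
  expect_equal(unclass(cfg3$partitions), base)

  # compensation that would leave the simplex fails loudly
  bad <- perturbation("coefficient", 0.5, phase = "early_vegetative",
                      coeff = "lambda_t", compensate = "iota")
  expect_error(apply_perturbation(cfg, bad), "infeasible")
  expect_error(apply_perturbation(cfg, perturbation("sigma", 0.5)),
               "sigma")
})

test_that("a null perturbation changes nothing", {
  cfg <- col0_config()
  tab <- sensitivity_table(cfg,
                           perturbations = list(perturbation("sigma", 0)))
  expect_true(all(tab$pct_change == 0))
  expect_true(all(!tab$sensitive))
})

test_that("one-percent vegetative-length changes truncate to no shift", {
  cfg <- col0_config()
  for (d in c(0.01, -0.01)) {
    cfg2 <- apply_perturbation(cfg, perturbation("vegetative_length", d))
    expect_equal(cfg2$schedule$intervals, cfg$schedule$intervals)
  }
  # a shift large enough for a whole day moves the boundary
  cfg3 <- apply_perturbation(cfg, perturbation("vegetative_length", 0.017))
  expect_equal(cfg3$schedule$intervals$late_vegetative[2], 67L)
  expect_equal(cfg3$schedule$intervals$reproductive[1], 68L)
})

test_that("sensitivity report flags the >1% responses", {
  cfg <- col0_config()
  batt <- list(perturbation("photosynthesis", 0.01),
               perturbation("sigma", 0.01))
  tab <- sensitivity_table(cfg, batt)
  expect_equal(nrow(tab), 2 * 2 * 4)     # 2 perturbations x 2 outputs x 4 DAS
  photo <- tab[tab$target == "photosynthesis", ]
  expect_true(all(photo$sensitive))
  sig <- tab[tab$target == "sigma", ]
  expect_true(all(!sig$sensitive))       # starch split is a weak lever
})
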