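test_that("effective photosynthesizing area discounts shaded leaves", {
  expect_equal(effective_photo_area(0.01, 1.0, 0.1), 0.01)
  expect_equal(effective_photo_area(0.01, 0.8, 0.1), 0.0082)
  expect_equal(effective_photo_area(0.01, 0.0, 0.1), 0.001)
  expect_true(all(effective_photo_area(0.01, seq(0, 1, 0.1), 0.1) <= 0.01))
  expect_error(effective_photo_area(-1, 0.5), "non-negative")
  expect_error(effective_photo_area(0.01, 1.2), "\\[0, 1\\]")
})

test_that("daytime NAR nets out starch, maintenance and exudation", {
  cn <- model_constants()
  expect_equal(nar_day(5, 0.0082, 0.6, 0, 0, cn, exude = TRUE),
               5 * 0.0082 * 0.4 * 3600 - 0.001)
  expect_equal(nar_day(5, 0.0082, 0.6, 0, 0, cn, exude = TRUE), 59.039,
               tolerance = 1e-6)
  expect_equal(nar_day(0, 0.0082, 0.6, 0, 0, cn, exude = FALSE), 0)
  expect_equal(nar_day(5, 0.0082, 1.0, 0, 0, cn, exude = FALSE), 0)
  # maintenance can exceed supply
  expect_lt(nar_day(0.01, 1e-6, 0.6, 1, 1, cn), 0)
  expect_error(nar_day(-1, 0.01, 0.6, 0, 0, cn), "non-negative")
})

test_that("daily starch pool sums the light-hour set-aside", {
  expect_equal(starch_day_total(rep(5, 8), 0.0082, 0.6),
               5 * 0.0082 * 0.6 * 3600 * 8)
  expect_equal(starch_day_total(rep(5, 8), 0.0082, 0.6), 708.48,
               tolerance = 1e-9)
  expect_equal(starch_day_total(rep(5, 8), 0.0082, 0), 0)
  expect_equal(starch_day_total(1, 1, 0.5), 1800)
  expect_error(starch_day_total(numeric(0), 1, 0.5), "empty")
})

test_that("night NAR draws starch at a constant rate and charges leaves", {
  cn <- model_constants()
  expect_equal(nar_night(708.48, 16, 0.01, 0, 0, cn, exude = TRUE),
               708.48 / 16 - 0.35 * 0.01 * 3600 - 0.001)
  expect_equal(nar_night(708.48, 16, 0.01, 0, 0, cn, exude = TRUE),
               31.679, tolerance = 1e-6)
  expect_equal(nar_night(0, 16, 0, 0, 0, cn, exude = FALSE), 0)
  # a large respiring area drives night NAR negative (growth clamps later)
  expect_lt(nar_night(708.48, 16, 1, 0, 0, cn), 0)
  expect_error(nar_night(100, 0, 0.01, 0, 0, cn), "night_h")
})

test_that("growth allocation splits substrate by coefficients", {
  cn <- model_constants()
  a <- allocate_growth(37500, c(iota = 0, rho = 0, lambda_s = 1,
                                lambda_t = 0), sla_current = 0.02,
                       constants = cn)
  expect_equal(a$dM_L, 0.896)
  expect_equal(a$ds, 0.01792)
  expect_equal(a$dM_i, 0); expect_equal(a$dM_r, 0)

  z <- allocate_growth(0, c(iota = 0.1, rho = 0.2, lambda_s = 0.5,
                            lambda_t = 0.2), 0.02, cn)
  expect_true(all(unlist(z[c("dM_i", "dM_r", "dM_L", "ds")]) == 0))

  row <- c(iota = 0.01, rho = 0.06, lambda_s = 0.75, lambda_t = 0.18)
  b <- allocate_growth(37500, row, 0.02, cn)
  expect_equal(b$dM_i, 0.0083)
  expect_equal(b$dM_r, 0.0522)
  expect_equal(b$dM_L, 0.83328)

  # negative NAR: increments zero, shortfall logged
  neg <- allocate_growth(-100, row, 0.02, cn)
  expect_equal(neg$dM_L, 0)
  expect_equal(neg$deficit_C, 100)
  expect_error(allocate_growth(1, row, 0, cn), "sla_current")
})

test_that("allocation conserves carbon within the hour", {
  cn <- model_constants()
  set.seed(11)
  for (i in 1:25) {
    x <- rexp(4); row <- x / sum(x)
    names(row) <- c("iota", "rho", "lambda_s", "lambda_t")
    nar <- runif(1, 0, 5e4)
    a <- allocate_growth(nar, row, runif(1, 0.005, 0.3), cn)
    expect_equal(a$biomass_C + a$growth_resp_C, nar, tolerance = 1e-9)
  }
})

test_that("optimal starch fraction follows the closed form", {
  expect_equal(optimal_sigma(100, 10, 10, 8), 16 / 24)
  expect_equal(optimal_sigma(100, 10, 10, 12), 0.5)
  expect_equal(optimal_sigma(100, 10, 30, 8), 0.8)   # R_N - R_D = 0.2 A
  # limit P -> 0: sigma -> 1 - (R_D - R_N)/A
  expect_equal(optimal_sigma(100, 40, 20, 1e-9), 1 - 0.2, tolerance = 1e-6)
  expect_equal(optimal_sigma(1, 100, 0, 8), 0)        # clipped at 0
  expect_error(optimal_sigma(0, 1, 1, 8), "positive")
  expect_error(optimal_sigma(10, 1, 1, 24), "strictly between")
})
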