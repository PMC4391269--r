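test_that("carbon ledger closes every day on fixtures and random configs", {
  for (traj in list(col0_traj(), gi2_traj())) {
    res <- vapply(traj$daily$das, function(d) ledger_residual(traj, d),
                  numeric(1))
    expect_lt(max(abs(res)), 1e-9)
    expect_equal(max(traj$daily$deficit_C), 0)   # fixtures never starve
  }
  set.seed(101)
  for (i in 1:8) {
    traj <- simulate_plant(random_config())
    expect_lt(abs(ledger_residual(traj)), 1e-9)
  }
})

test_that("masses and areas never decrease (no senescence)", {
  set.seed(202)
  trajs <- c(list(col0_traj()), replicate(4, simulate_plant(random_config()),
                                          simplify = FALSE))
  for (traj in trajs) {
    d <- traj$daily
    for (col in c("s", "M_L", "M_i", "M_r", "M_P"))
      expect_true(all(diff(d[[col]]) >= 0), label = paste("monotone", col))
    expect_true(all(d$starch >= 0))
  }
})

test_that("with zero photosynthesis nothing grows after the seed reserve", {
  cfg <- col0_config()
  cfg$photo <- photo_curve(c(0, 0, 0, 0), range = c(1, 90))
  d <- simulate_plant(cfg)$daily
  expect_gt(d$M_L[4], d$M_L[1] * 0.9)   # heterotrophic growth happened
  expect_equal(d$M_L[90], d$M_L[4])
  expect_equal(d$s[90], d$s[4])
  expect_equal(d$M_i[90], 0)
  expect_equal(d$M_r[90], 0)
})

test_that("fixture plant mass rises strictly through the vegetative phase", {
  d <- col0_traj()$daily
  veg <- d$das >= 5 & d$das <= 66
  expect_true(all(diff(d$M_P[veg]) > 0))
})

test_that("seed reserve depletes geometrically and organs wait for light", {
  d <- col0_traj()$daily
  R0 <- model_constants()$initial_leaf_mass
  expect_equal(d$seed_reserve[1], 0.75 * R0, tolerance = 1e-12)
  expect_equal(d$seed_reserve[2], 0.50 * R0, tolerance = 1e-12)
  expect_lt(d$seed_reserve[4], 1e-12 * R0)
  expect_equal(d$M_r[4], 0)
  expect_equal(d$M_i[4], 0)

  st <- list(das = 1L, s = 5e-6, M_L = 1.8e-5, M_i = 0, M_r = 0,
             seed_reserve = R0, initial_reserve = R0)
  st <- heterotrophic_step(st, col0_config())
  expect_equal(st$seed_reserve, 0.75 * R0, tolerance = 1e-12)
  expect_equal(st$das, 2L)
  st$das <- 10L
  expect_error(heterotrophic_step(st, col0_config()), "outside")
})

test_that("starch pool empties at dawn and hourly output is complete", {
  traj <- simulate_plant(col0_config(), hourly = TRUE)
  h <- traj$hourly
  expect_equal(nrow(h), 90 * 24)
  # end of each autotrophic day's last night hour: pool is (numerically) empty
  last_hours <- h[h$hour == 23 & h$das > 4, ]
  peak <- max(h$starch)
  expect_lt(max(last_hours$starch) / peak, 1e-9)
})

test_that("daytime leaf-area gain matches the subtraction form", {
  cn <- model_constants()
  set.seed(33)
  for (i in 1:30) {
    x <- rexp(4); row <- x / sum(x)
    names(row) <- c("iota", "rho", "lambda_s", "lambda_t")
    nar <- runif(1, 0, 5e4)
    slaval <- runif(1, 0.005, 0.3)
    a <- allocate_growth(nar, row, slaval, cn)
    ds_sub <- slaval * (1 - cn$gL_growth_coeff) *
      (nar / cn$carbon_conc -
         a$dM_L_thick / (1 - cn$gL_growth_coeff) -
         a$dM_i / (1 - cn$gi_growth_coeff) -
         a$dM_r / (1 - cn$gr_growth_coeff))
    expect_equal(a$ds, ds_sub, tolerance = 1e-12)
  }
})

test_that("night allocation via the complement equals the direct share", {
  cn <- model_constants()
  set.seed(44)
  for (i in 1:20) {
    x <- rexp(4); row <- x / sum(x)
    names(row) <- c("iota", "rho", "lambda_s", "lambda_t")
    comp <- row
    comp[["lambda_s"]] <- 1 - row[["lambda_t"]] - row[["iota"]] - row[["rho"]]
    a <- allocate_growth(1234, row, 0.02, cn)
    b <- allocate_growth(1234, comp, 0.02, cn)
    expect_equal(a$ds, b$ds, tolerance = 1e-12)
  }
})

test_that("leaf-area gain is linear in the area-mass increment with slope SLA", {
  cn <- model_constants()
  slaval <- 0.037
  nars <- c(1e3, 2e3, 7e3, 3e4)
  row <- c(iota = 0.1, rho = 0.1, lambda_s = 0.6, lambda_t = 0.2)
  out <- vapply(nars, function(n) {
    a <- allocate_growth(n, row, slaval, cn)
    a$ds / a$dM_L_area
  }, numeric(1))
  expect_equal(out, rep(slaval, length(nars)), tolerance = 1e-12)
})

test_that("per-second integration of one late-life day agrees closely", {
  cfg <- col0_config()
  traj <- col0_traj()
  d0 <- traj$daily[79, ]                      # state entering DAS 80
  cn <- cfg$constants
  A <- eval_driver(cfg$photo, 80)
  r <- eval_driver(cfg$overlap, 80)
  row <- unclass(cfg$partitions)["reproductive", ]
  P <- cfg$schedule$photoperiod_h
  s <- d0$s; M_L <- d0$M_L; M_i <- d0$M_i; M_r <- d0$M_r
  starch <- d0$starch
  night_draw <- 0
  for (sec in 0:(86400 - 1)) {
    if (sec < P * 3600) {
      s_eff <- r * s + cn$shaded_photo_fraction * (1 - r) * s
      fx <- A * s_eff
      starch <- starch + fx * cn$sigma
      nar <- fx * (1 - cn$sigma) -
        (cn$ri_maint_coeff * M_i + cn$rr_maint_coeff * M_r) -
        cn$exudation / 3600
    } else {
      if (sec == P * 3600) night_draw <- starch / ((24 - P) * 3600)
      draw <- min(night_draw, starch)
      starch <- starch - draw
      nar <- draw - (cn$rL_maint * s + cn$ri_maint_coeff * M_i +
                       cn$rr_maint_coeff * M_r) - cn$exudation / 3600
    }
    if (nar > 0) {
      G <- nar / cn$carbon_conc
      dMi <- G * row[["iota"]] * (1 - cn$gi_growth_coeff)
      dMr <- G * row[["rho"]] * (1 - cn$gr_growth_coeff)
      dMLs <- G * row[["lambda_s"]] * (1 - cn$gL_growth_coeff)
      dMLt <- G * row[["lambda_t"]] * (1 - cn$gL_growth_coeff)
      ds <- (s / M_L) * dMLs
      M_i <- M_i + dMi; M_r <- M_r + dMr
      M_L <- M_L + dMLs + dMLt; s <- s + ds
    }
  }
  d1 <- traj$daily[80, ]
  inc_hourly <- c(d1$s - d0$s, d1$M_L - d0$M_L, d1$M_i - d0$M_i,
                  d1$M_r - d0$M_r)
  inc_oracle <- c(s - d0$s, M_L - d0$M_L, M_i - d0$M_i, M_r - d0$M_r)
  expect_lt(max(abs(inc_hourly - inc_oracle) / inc_oracle), 1e-3)
})

test_that("the compiled fast path reproduces the reference engine", {
  set.seed(77)
  cfgs <- c(list(col0_config(), gi2_config()),
            replicate(3, random_config(), simplify = FALSE))
  for (cfg in cfgs) {
    ref <- as.matrix(simulate_plant(cfg)$daily[, c("s", "M_L", "M_i", "M_r")])
    fast <- leafcarbon:::sim_state_fast(cfg)
    expect_lt(max(abs(fast - ref) / pmax(abs(ref), 1e-12)), 1e-10)
  }
})

test_that("drivers must cover the simulated range", {
  drv <- fixture_drivers("col0")
  short <- photo_curve(drv$photo$coefficients, range = c(1, 80))
  expect_error(growth_config(photo = short, overlap = drv$overlap),
               "cover")
})
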