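#' Simulate the whole life cycle at hourly resolution
#'
#' Runs the carbon-balance model from seeding to the end of the schedule
#' (default 90 days) with a fixed 1 h step (explicit Euler: drivers and
#' state are evaluated at the start of each hour).  During the
#' heterotrophic phase a fixed fraction of the initial seed reserve is
#' mobilized per day, funds cotyledon maintenance first, and the remainder
#' becomes cotyledon mass; root and inflorescence growth begin only once
#' photosynthesis starts.  During autotrophic days, daylight hours fix C at
#' the driver rate over the effective (overlap-corrected) area, divert the
#' sigma fraction to starch and allocate the rest; night hours draw the
#' dusk starch pool at a constant rate, charge leaf maintenance, and
#' allocate with the same coefficients, so the pool empties exactly at
#' dawn.  Hours where maintenance exceeds supply clamp growth to zero and
#' log the shortfall in a deficit ledger; biomass is never decremented (no
#' senescence is modeled).
#'
#' @param config a [growth_config()].
#' @param hourly also record the per-hour trajectory (24x the memory).
#' @return An object of class `growth_trajectory`: a list with `daily` (one
#'   row per DAS: state at end of day, cumulative carbon ledger, and
#'   within-day flux totals), optionally `hourly`, and the `config`.
#'   All carbon ledger columns are umol C.
#' @examples
#' traj <- simulate_plant(col0_config())
#' tail(traj$daily[, c("das", "s", "M_L", "M_P")], 3)
#' @export
simulate_plant <- function(config, hourly = FALSE) {
  validate_config(config)
  sched <- config$schedule
  cn <- config$constants
  P <- sched$photoperiod_h
  nightH <- 24 - P
  ndays <- sched$total_days

  das_seq <- seq_len(ndays)
  phase_idx <- match(phase_of(sched, das_seq), phase_names())
  A_das <- eval_driver(config$photo, das_seq)
  part <- unclass(config$partitions)

  # force cotyledon-only allocation during the heterotrophic phase
  germ <- part["germination", ]
  if (germ[["iota"]] > 0 || germ[["rho"]] > 0) {
    lam <- germ[["lambda_s"]] + germ[["lambda_t"]]
    if (lam <= 0) stop("germination-phase leaf allocation must be positive")
    germ <- c(iota = 0, rho = 0,
              lambda_s = germ[["lambda_s"]] / lam,
              lambda_t = germ[["lambda_t"]] / lam)
  }
  part["germination", ] <- germ

  # scalar state
  s <- cn$initial_leaf_area
  M_L <- cn$initial_leaf_mass
  M_i <- 0; M_r <- 0
  starch <- 0
  # seed storage reserve: the cotyledons (initial leaf mass) are 90% of the
  # seed and carry its storage material
  R0 <- cn$initial_leaf_mass
  reserve <- R0
  mob_day_g <- cn$seed_mobilization_ratio * R0

  # cumulative ledger (umol C)
  fixed_C <- 0; mobilized_C <- 0; maint_C <- 0; growth_resp_C <- 0
  exuded_C <- 0; biomass_C <- 0; deficit_C <- 0

  # hoisted constants
  Cc <- cn$carbon_conc
  ri36 <- cn$ri_maint_coeff * 3600
  rr36 <- cn$rr_maint_coeff * 3600
  rL36 <- cn$rL_maint * 3600
  E <- cn$exudation
  sig <- cn$sigma
  shade <- cn$shaded_photo_fraction
  gL <- cn$gL_growth_coeff; gi <- cn$gi_growth_coeff; gr <- cn$gr_growth_coeff

  het_end <- sched$intervals$germination[2]

  daily <- matrix(0, ndays, 22)
  colnames(daily) <- c("das", "s", "M_L", "M_i", "M_r", "M_P", "sla",
                       "starch", "seed_reserve",
                       "fixed_C", "mobilized_C", "maint_C", "growth_resp_C",
                       "exuded_C", "biomass_C", "deficit_C",
                       "day_avail_C", "day_dMi_C", "day_dMr_C",
                       "day_dMLs_C", "day_dMLt_C", "day_starch_resid_C")
  if (hourly) {
    hmat <- matrix(0, ndays * 24, 8)
    colnames(hmat) <- c("das", "hour", "s", "M_L", "M_i", "M_r",
                        "starch", "nar")
    hrow <- 0L
  }

  for (d in das_seq) {
    pidx <- phase_idx[d]
    io <- part[pidx, 1L]; rh <- part[pidx, 2L]
    ls <- part[pidx, 3L]; lt <- part[pidx, 4L]
    lam <- ls + lt
    heterotrophic <- d <= het_end
    A <- A_das[d]
    r_proj <- if (config$overlap$on == "das")
      eval_driver(config$overlap, d) else eval_driver(config$overlap, s)

    day_avail <- 0; day_dMi <- 0; day_dMr <- 0; day_dMLs <- 0; day_dMLt <- 0
    starch_at_dawn <- starch
    night_draw <- 0

    for (h in 0:23) {
      daylight <- h < P
      if (heterotrophic) {
        mob_g <- min(mob_day_g / 24, reserve)
        reserve <- reserve - mob_g
        supply <- mob_g * Cc
        mobilized_C <- mobilized_C + supply
        maint <- rL36 * s
        maint_C <- maint_C + maint
        nar <- supply - maint
        day_avail <- day_avail + supply
        io_h <- 0; rh_h <- 0
        ls_h <- germ[["lambda_s"]]; lt_h <- germ[["lambda_t"]]
      } else if (daylight) {
        s_eff <- r_proj * s + shade * (1 - r_proj) * s
        fx <- A * s_eff * 3600
        fixed_C <- fixed_C + fx
        starch <- starch + fx * sig
        ex <- if (M_r > 0) E else 0
        maint <- ri36 * M_i + rr36 * M_r
        maint_C <- maint_C + maint
        exuded_C <- exuded_C + ex
        nar <- fx * (1 - sig) - maint - ex
        day_avail <- day_avail + fx
        io_h <- io; rh_h <- rh; ls_h <- ls; lt_h <- lt
      } else {
        if (h == P) night_draw <- starch / nightH   # set at dusk
        draw <- min(night_draw, starch)
        starch <- starch - draw
        ex <- if (M_r > 0) E else 0
        maint <- rL36 * s + ri36 * M_i + rr36 * M_r
        maint_C <- maint_C + maint
        exuded_C <- exuded_C + ex
        nar <- draw - maint - ex
        io_h <- io; rh_h <- rh; ls_h <- ls; lt_h <- lt
      }

      if (nar > 0) {
        G <- nar / Cc
        dMi <- G * io_h * (1 - gi)
        dMr <- G * rh_h * (1 - gr)
        dMLs <- G * ls_h * (1 - gL)
        dMLt <- G * lt_h * (1 - gL)
        ds <- (s / M_L) * dMLs
        gresp <- G * (io_h * gi + rh_h * gr + (ls_h + lt_h) * gL) * Cc
        M_i <- M_i + dMi; M_r <- M_r + dMr
        M_L <- M_L + dMLs + dMLt; s <- s + ds
        growth_resp_C <- growth_resp_C + gresp
        biomass_C <- biomass_C + (dMi + dMr + dMLs + dMLt) * Cc
        day_dMi <- day_dMi + dMi * Cc
        day_dMr <- day_dMr + dMr * Cc
        day_dMLs <- day_dMLs + dMLs * Cc
        day_dMLt <- day_dMLt + dMLt * Cc
      } else if (nar < 0) {
        deficit_C <- deficit_C - nar
      }

      if (hourly) {
        hrow <- hrow + 1L
        hmat[hrow, ] <- c(d, h, s, M_L, M_i, M_r, starch, nar)
      }
    }

    daily[d, ] <- c(d, s, M_L, M_i, M_r, M_L + M_i + M_r, s / M_L,
                    starch, reserve,
                    fixed_C, mobilized_C, maint_C, growth_resp_C,
                    exuded_C, biomass_C, deficit_C,
                    day_avail, day_dMi, day_dMr, day_dMLs, day_dMLt,
                    starch - 0)  # residual pool at end of day
    # note: starch at end of day == pool carried into next day's night total
  }

  daily <- as.data.frame(daily)
  daily$phase <- phase_names()[phase_idx]
  out <- list(daily = daily,
              hourly = if (hourly) as.data.frame(hmat) else NULL,
              config = config)
  class(out) <- "growth_trajectory"
  out
}

#' @export
print.growth_trajectory <- function(x, ...) {
  last <- x$daily[nrow(x$daily), ]
  cat("Growth trajectory:", nrow(x$daily), "days\n")
  cat(sprintf("  final leaf area %.4g m2 (%.1f cm2), leaf %.4g g, plant %.4g g\n",
              last$s, last$s * 1e4, last$M_L, last$M_P))
  cat(sprintf("  carbon closure residual: %.3g (relative)\n",
              ledger_residual(x)))
  invisible(x)
}

#' Relative carbon-ledger closure residual
#'
#' Conservation check: cumulative fixed plus mobilized plus deficit carbon
#' must equal biomass carbon plus maintenance and growth respiration plus
#' exudation plus the residual starch pool.  Returns the relative
#' imbalance at the requested day (default: end of run).
#'
#' @param traj a `growth_trajectory`.
#' @param das day at which to evaluate (default last).
#' @return Relative residual (dimensionless).
#' @export
ledger_residual <- function(traj, das = NULL) {
  d <- traj$daily
  row <- if (is.null(das)) d[nrow(d), ] else d[d$das == das, ]
  if (nrow(row) != 1) stop("das not in trajectory")
  inp <- row$fixed_C + row$mobilized_C + row$deficit_C
  out <- row$biomass_C + row$maint_C + row$growth_resp_C +
    row$exuded_C + row$starch
  (inp - out) / max(inp, .Machine$double.eps)
}

#' Advance one heterotrophic (seed-reserve) day
#'
#' Exposes the germination-phase update used inside [simulate_plant()]: the
#' daily mobilized fraction of the initial seed reserve pays cotyledon
#' maintenance first and the remainder becomes cotyledon mass under the
#' germination-phase coefficients (inflorescence and root allocation forced
#' to zero).  Intended for inspecting the reserve-depletion dynamics.
#'
#' @param state list with `das`, `s`, `M_L`, `M_i`, `M_r`, `seed_reserve`,
#'   and `initial_reserve` (g).
#' @param config a [growth_config()].
#' @return The state advanced by one day (`das + 1`).
#' @export
heterotrophic_step <- function(state, config) {
  sched <- config$schedule
  if (state$das < sched$intervals$germination[1] ||
      state$das > sched$intervals$germination[2])
    stop("heterotrophic_step called outside the heterotrophic phase (DAS ",
         state$das, ")")
  cn <- config$constants
  germ <- unclass(config$partitions)["germination", ]
  lam <- germ[["lambda_s"]] + germ[["lambda_t"]]
  fs <- if (lam > 0) germ[["lambda_s"]] / lam else 1
  mob_day <- cn$seed_mobilization_ratio * state$initial_reserve
  s <- state$s; M_L <- state$M_L
  reserve <- state$seed_reserve
  for (h in 1:24) {
    mob_g <- min(mob_day / 24, reserve)
    reserve <- reserve - mob_g
    nar <- mob_g * cn$carbon_conc - cn$rL_maint * s * 3600
    if (nar > 0) {
      G <- nar / cn$carbon_conc
      dMLs <- G * fs * (1 - cn$gL_growth_coeff)
      dMLt <- G * (1 - fs) * (1 - cn$gL_growth_coeff)
      s <- s + (s / M_L) * dMLs
      M_L <- M_L + dMLs + dMLt
    }
  }
  state$s <- s; state$M_L <- M_L
  state$seed_reserve <- reserve
  state$das <- state$das + 1L
  state
}
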