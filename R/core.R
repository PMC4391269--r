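#' Effective photosynthesizing leaf area
#'
#' Leaves shaded by upper leaves (total minus projected area) are assumed to
#' photosynthesize at a fraction (default 10%) of the rate of exposed
#' leaves, so the effective area is
#' `r * s + f * (1 - r) * s`.
#'
#' @param s_total total leaf area, m2.
#' @param r_proj projected-to-total leaf area ratio, in \[0, 1\].
#' @param shaded_fraction relative photosynthetic rate of shaded area.
#' @return Effective area in m2, never exceeding `s_total`.
#' @examples
#' effective_photo_area(0.01, 0.8, 0.1)  # 0.0082
#' @export
effective_photo_area <- function(s_total, r_proj, shaded_fraction = 0.1) {
  if (any(s_total < 0)) stop("leaf area must be non-negative")
  if (any(r_proj < 0 | r_proj > 1)) stop("r_proj must lie in [0, 1]")
  if (any(shaded_fraction < 0 | shaded_fraction > 1))
    stop("shaded_fraction must lie in [0, 1]")
  r_proj * s_total + shaded_fraction * (1 - r_proj) * s_total
}

#' Daytime net assimilation rate (per hour)
#'
#' NAR during a daylight hour: whole-plant assimilation minus the starch
#' set-aside, minus inflorescence and root maintenance respiration, minus
#' exudation.  Leaf maintenance is not charged by day because measured net
#' CO2 uptake (gas exchange) already nets it out.  May be negative when
#' maintenance exceeds supply.
#'
#' @param A area-based net photosynthesis, umol m-2 s-1.
#' @param s_eff effective photosynthesizing area, m2.
#' @param sigma starch fraction of daytime fixed C.
#' @param M_i,M_r inflorescence and root dry mass, g.
#' @param constants a [model_constants()] (supplies maintenance coefficients
#'   and exudation).
#' @param exude charge root exudation this hour (default: only when
#'   `M_r > 0`).
#' @return NAR in umol plant-1 h-1.
#' @examples
#' nar_day(5, 0.0082, 0.6, 0, 0, model_constants(), exude = TRUE)  # 59.039
#' @export
nar_day <- function(A, s_eff, sigma, M_i, M_r, constants = model_constants(),
                    exude = M_r > 0) {
  if (any(A < 0)) stop("A must be non-negative (net assimilation)")
  A * s_eff * (1 - sigma) * 3600 -
    constants$ri_maint_coeff * M_i * 3600 -
    constants$rr_maint_coeff * M_r * 3600 -
    ifelse(exude, constants$exudation, 0)
}

#' Starch accumulated over one day
#'
#' The starch pool available at night is the sum over all light hours of
#' the fixed C diverted to starch, `A * s_eff * sigma * 3600`.
#'
#' @param A_series hourly area-based photosynthesis over the photoperiod,
#'   umol m-2 s-1.
#' @param s_eff_series hourly effective areas, m2 (recycled if length 1).
#' @param sigma starch fraction.
#' @return Total starch, umol C.
#' @examples
#' starch_day_total(rep(5, 8), 0.0082, 0.6)  # 708.48
#' @export
starch_day_total <- function(A_series, s_eff_series, sigma) {
  if (length(A_series) == 0) stop("empty photoperiod series")
  sum(A_series * s_eff_series * sigma * 3600)
}

#' Night-time net assimilation rate (per hour)
#'
#' At night the starch pool is degraded at a constant rate (pool divided by
#' night length); leaf maintenance respiration IS charged at night (it is
#' not netted out of any measurement), along with inflorescence and root
#' maintenance and exudation.
#'
#' @param starch_pool umol C available at dusk.
#' @param night_h night length in hours (24 - photoperiod).
#' @param s total leaf area, m2 (all leaf tissue respires).
#' @param M_i,M_r organ masses, g.
#' @param constants a [model_constants()].
#' @param exude charge root exudation this hour.
#' @return NAR in umol plant-1 h-1; may be negative (growth is clamped
#'   downstream, never biomass loss).
#' @examples
#' nar_night(708.48, 16, 0.01, 0, 0, model_constants(), exude = TRUE)
#' @export
nar_night <- function(starch_pool, night_h, s, M_i, M_r,
                      constants = model_constants(), exude = M_r > 0) {
  if (night_h <= 0) stop("night_h must be positive")
  starch_pool / night_h -
    constants$rL_maint * s * 3600 -
    constants$ri_maint_coeff * M_i * 3600 -
    constants$rr_maint_coeff * M_r * 3600 -
    ifelse(exude, constants$exudation, 0)
}

#' Partition one hour of growth carbon among sinks
#'
#' Converts the hour's NAR to growth substrate `G = max(NAR, 0) / C` grams
#' and splits it by the phase's partition coefficients, discounting each
#' organ's share by its growth respiration coefficient.  Leaf area gain is
#' linear in the leaf-area mass increment with slope SLA.  The night
#' allocation uses the identical formula: the night-time share
#' `1 - lambda_t - iota - rho` equals `lambda_s` on the simplex.
#'
#' @param nar umol plant-1 h-1 (negative values yield zero increments and a
#'   logged deficit).
#' @param coeffs named numeric with `iota`, `rho`, `lambda_s`, `lambda_t`
#'   (one row of a [partition_set()]).
#' @param sla_current instantaneous specific leaf area s/M_L, m2 g-1.
#' @param constants a [model_constants()].
#' @return A list with increments `dM_i`, `dM_r`, `dM_L_area`,
#'   `dM_L_thick`, `dM_L`, `ds` (g and m2), `growth_resp_C` and
#'   `biomass_C` (umol C), and `deficit_C` (umol, positive when NAR < 0).
#' @examples
#' allocate_growth(37500, c(iota = 0, rho = 0, lambda_s = 1, lambda_t = 0),
#'                 sla_current = 0.02)
#' @export
allocate_growth <- function(nar, coeffs, sla_current,
                            constants = model_constants()) {
  if (!is.finite(nar)) stop("nar must be finite")
  if (sla_current <= 0) stop("sla_current must be positive")
  G <- max(nar, 0) / constants$carbon_conc      # g of growth substrate
  lam <- coeffs[["lambda_s"]] + coeffs[["lambda_t"]]
  dM_i <- G * coeffs[["iota"]] * (1 - constants$gi_growth_coeff)
  dM_r <- G * coeffs[["rho"]] * (1 - constants$gr_growth_coeff)
  dM_L_area <- G * coeffs[["lambda_s"]] * (1 - constants$gL_growth_coeff)
  dM_L_thick <- G * coeffs[["lambda_t"]] * (1 - constants$gL_growth_coeff)
  growth_resp_C <- G * (coeffs[["iota"]] * constants$gi_growth_coeff +
                          coeffs[["rho"]] * constants$gr_growth_coeff +
                          lam * constants$gL_growth_coeff) *
    constants$carbon_conc
  list(dM_i = dM_i, dM_r = dM_r,
       dM_L_area = dM_L_area, dM_L_thick = dM_L_thick,
       dM_L = dM_L_area + dM_L_thick,
       ds = sla_current * dM_L_area,
       growth_resp_C = growth_resp_C,
       biomass_C = (dM_i + dM_r + dM_L_area + dM_L_thick) *
         constants$carbon_conc,
       deficit_C = max(-nar, 0))
}

#' Optimal starch partitioning fraction
#'
#' The starch/sucrose split that equalizes day and night growth rates, so
#' that machinery such as ribosomes is used at the same rate around the
#' clock:
#' `sigma = (1 - (Rm_D - Rm_N) / A) / (1 + P / (24 - P))`,
#' clipped to \[0, 1\].  With equal day and night maintenance this reduces
#' to `(24 - P) / 24` (2/3 for an 8 h photoperiod); with night maintenance
#' exceeding day maintenance by 20% of assimilation it reaches 0.8, the
#' theoretical optimum reported for a mid-life plant under an 8 h day.
#'
#' @param A whole-plant assimilation over the day (any per-time unit, as
#'   long as `rm_day`/`rm_night` share it).
#' @param rm_day,rm_night maintenance respiration during day and night.
#' @param P photoperiod, hours, in (0, 24).
#' @return sigma in \[0, 1\].
#' @examples
#' optimal_sigma(100, 10, 10, P = 8)   # (24 - 8) / 24 = 2/3
#' @export
optimal_sigma <- function(A, rm_day, rm_night, P) {
  if (A <= 0) stop("A must be positive")
  if (P <= 0 || P >= 24) stop("P must lie strictly between 0 and 24")
  sig <- (1 - (rm_day - rm_night) / A) / (1 + P / (24 - P))
  min(1, max(0, sig))
}
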