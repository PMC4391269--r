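#' Specific leaf area
#'
#' Leaf area per unit leaf dry mass, `s / M_L` (m2 g-1) — the inverse proxy
#' for leaf thickness.
#'
#' @param s leaf area, m2.
#' @param M_L leaf dry mass, g (> 0).
#' @return SLA in m2 g-1.
#' @export
sla <- function(s, M_L) {
  if (any(M_L <= 0)) stop("M_L must be positive")
  if (any(s < 0)) stop("s must be non-negative")
  s / M_L
}

#' Two-point relative growth rate
#'
#' Classical log-difference RGR between two harvests:
#' `(ln x2 - ln x1) / (t2 - t1)`.  On the mass basis the result is scaled
#' by 1000 to g kg-1 day-1; on the area basis it is left in
#' m2 m-2 day-1.
#'
#' @param x1,x2 positive sizes (areas or masses) at `t1_das` and `t2_das`.
#' @param t1_das,t2_das days after seeding, `t2_das > t1_das`.
#' @param scale `"area"` (RGR_S) or `"mass"` (RGR_M).
#' @return RGR on the requested basis.
#' @examples
#' rgr(0.5, 1.0, 44, 66, "mass")   # 1000 * log(2) / 22
#' @export
rgr <- function(x1, x2, t1_das, t2_das, scale = c("area", "mass")) {
  scale <- match.arg(scale)
  if (any(x1 <= 0) || any(x2 <= 0))
    stop("sizes must be positive for a log growth rate")
  if (any(t2_das <= t1_das)) stop("t2_das must exceed t1_das")
  r <- (log(x2) - log(x1)) / (t2_das - t1_das)
  if (scale == "mass") 1000 * r else r
}

#' Daily growth summary of a trajectory
#'
#' Per-day derived quantities: SLA, area- and mass-based relative growth
#' rates (successive-day log differences), the leaf/stem/root mass ratios
#' (which sum to 1), and the leaf area ratio (leaf area per unit plant
#' mass).
#'
#' @param traj a `growth_trajectory` from [simulate_plant()].
#' @return A data.frame, one row per DAS (RGR columns are `NA` on the
#'   first day).
#' @export
growth_summary <- function(traj) {
  d <- traj$daily
  n <- nrow(d)
  rgr_s <- c(NA, diff(log(d$s)))
  rgr_m <- c(NA, diff(log(d$M_P))) * 1000
  data.frame(das = d$das, phase = d$phase,
             sla = d$sla,
             rgr_s = rgr_s, rgr_m = rgr_m,
             leaf_mass_ratio = d$M_L / d$M_P,
             stem_mass_ratio = d$M_i / d$M_P,
             root_mass_ratio = d$M_r / d$M_P,
             leaf_area_ratio = d$s / d$M_P)
}

#' Daily carbon-partitioning fractions
#'
#' Expresses each day's carbon fate as fractions of the day's available C
#' (fixed plus mobilized): maintenance respiration, growth respiration,
#' exudation, growth of the inflorescence, root, leaf area and leaf
#' thickness, plus the change in the residual starch pool.  Fractions sum
#' to 1 on days with a closed budget; days with zero available C are
#' flagged undefined.
#'
#' @param traj a `growth_trajectory`.
#' @return A data.frame, one row per DAS, with a logical `defined` column.
#' @export
partition_summary <- function(traj) {
  d <- traj$daily
  per_day <- function(x) diff(c(0, x))
  avail <- d$day_avail_C
  maint <- per_day(d$maint_C)
  gresp <- per_day(d$growth_resp_C)
  exud <- per_day(d$exuded_C)
  deficit <- per_day(d$deficit_C)
  starch_resid <- diff(c(0, d$starch))
  defined <- avail > 0
  frac <- function(x) ifelse(defined, x / avail, NA_real_)
  data.frame(das = d$das, phase = d$phase, defined = defined,
             available_C = avail,
             maintenance = frac(maint - deficit),
             growth_respiration = frac(gresp),
             exudation = frac(exud),
             inflorescence_growth = frac(d$day_dMi_C),
             root_growth = frac(d$day_dMr_C),
             leaf_area_growth = frac(d$day_dMLs_C),
             leaf_thickening = frac(d$day_dMLt_C),
             starch_residual = frac(starch_resid))
}

#' Leaf-area / plant-mass relationship table
#'
#' Paired daily series underlying the growth-relationship analyses:
#' projected and total leaf area vs plant mass, leaf mass vs plant mass,
#' SLA vs plant mass, and the two relative growth rates against each
#' other.
#'
#' @param traj a `growth_trajectory`.
#' @return A tidy data.frame, one row per day.
#' @export
relationship_table <- function(traj) {
  d <- traj$daily
  r_proj <- if (traj$config$overlap$on == "das")
    eval_driver(traj$config$overlap, d$das)
  else eval_driver(traj$config$overlap, d$s)
  gs <- growth_summary(traj)
  data.frame(das = d$das, phase = d$phase,
             projected_area = r_proj * d$s,
             total_area = d$s,
             M_L = d$M_L, M_P = d$M_P,
             sla = d$sla,
             rgr_s = gs$rgr_s, rgr_m = gs$rgr_m)
}
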