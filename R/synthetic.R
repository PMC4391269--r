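#' Fixture driver curves for the two genotype profiles
#'
#' The study's measured gas-exchange and overlap curves were never
#' deposited, so the package ships shape-faithful stand-ins built at run
#' time (synthetic; not the study's numeric curves).  The "col0" profile is
#' a cubic declining from about 4.5 to 3.1 umol m-2 s-1 over the life
#' cycle (chosen so the simulated wild type reaches a realistic rosette of
#' roughly 200 cm2 and well under 1 g dry mass by the final harvest), and
#' a power-law projected/total ratio declining from about 0.95
#' at first harvest to about 0.62 at final harvest.  The "gi2" profile
#' scales photosynthesis down by 20% (within the reported 15--23% band) and
#' reduces leaf overlap (1 - ratio) by 7.5% (within the reported 5--10%
#' band).
#'
#' @param profile `"col0"` or `"gi2"`.
#' @return List with elements `photo` ([photo_curve()]) and `overlap`
#'   ([overlap_curve()]).
#' @examples
#' drv <- fixture_drivers("col0")
#' eval_driver(drv$photo, c(26, 86))
#' @export
fixture_drivers <- function(profile = c("col0", "gi2")) {
  profile <- match.arg(profile)
  # cubic through four anchor harvests, declining over [5, 90]
  anchor_das <- c(5, 30, 60, 90)
  anchor_A <- c(4.5, 4.2, 3.8, 3.1)
  if (profile == "gi2") anchor_A <- 0.80 * anchor_A
  V <- outer(anchor_das, 0:3, `^`)
  photo <- photo_curve(solve(V, anchor_A), range = c(1, 90))

  r1 <- 0.95; r2 <- 0.62                  # col0 ratio anchors at 26/86 DAS
  if (profile == "gi2") {                 # 7.5% less overlap
    r1 <- 1 - 0.925 * (1 - r1)
    r2 <- 1 - 0.925 * (1 - r2)
  }
  b <- log(r2 / r1) / log(86 / 26)
  overlap <- overlap_curve(a = r1 / 26^b, b = b)
  list(photo = photo, overlap = overlap)
}

#' Packaged fixture configurations
#'
#' Full configurations combining the published constants and calibrated
#' partition coefficients with the synthetic fixture drivers.
#'
#' @param sim published coefficient set, 1 or 2.
#' @return A [growth_config()].
#' @export
col0_config <- function(sim = 1) {
  drv <- fixture_drivers("col0")
  growth_config(partitions = partition_table2("col0", sim),
                photo = drv$photo, overlap = drv$overlap)
}

#' @rdname col0_config
#' @export
gi2_config <- function(sim = 1) {
  drv <- fixture_drivers("gi2")
  growth_config(partitions = partition_table2("gi2", sim),
                photo = drv$photo, overlap = drv$overlap)
}

#' Describe a synthetic measurement study
#'
#' Defines the sparse-harvest design the generator emulates: by default
#' four destructive harvests (26, 44, 66, 86 DAS) of n = 10 plants each,
#' with multiplicative (lognormal) replicate noise at 10% CV.  With
#' `cv = 0` the reported means equal the model trajectory exactly and each
#' series carries a nominal relative SD (`sd_floor`) so that the
#' calibration objective remains defined.
#'
#' @param truth ground-truth [partition_set()].
#' @param harvest_das harvest days.
#' @param n replicates per harvest.
#' @param cv replicate coefficient of variation.
#' @param noise `"lognormal"` (default; masses are positive and spread
#'   grows with the mean) or `"normal"`.
#' @param sd_floor minimum reported SD as a fraction of the mean.
#' @return An object of class `synthetic_study`.
#' @export
synthetic_study <- function(truth = partition_table2("col0", 1),
                            harvest_das = c(26, 44, 66, 86),
                            n = 10, cv = 0.1,
                            noise = c("lognormal", "normal"),
                            sd_floor = 0.05) {
  noise <- match.arg(noise)
  stopifnot(inherits(truth, "partition_set"), n >= 2, cv >= 0,
            sd_floor > 0, all(harvest_das >= 1))
  structure(list(truth = truth, harvest_das = harvest_das, n = n,
                 cv = cv, noise = noise, sd_floor = sd_floor),
            class = "synthetic_study")
}

#' Generate sparse harvest measurements from a known truth
#'
#' Simulates the configuration with the study's ground-truth coefficients
#' and draws noisy replicate harvests of the four observables (leaf area,
#' leaf mass, root mass, stem/inflorescence mass), reporting mean, SD and n
#' per harvest day — the same table a destructive growth analysis would
#' yield.  Deterministic for a fixed `seed`.
#'
#' @param study a [synthetic_study()].
#' @param config a [growth_config()]; its partitions are replaced by the
#'   study truth.
#' @param seed integer seed for the replicate noise.
#' @return A data.frame with columns `observable`, `das`, `mean`, `sd`,
#'   `n` (a measurement series table; leaf area in m2, masses in g).
#' @export
generate_measurements <- function(study, config = col0_config(), seed = 1) {
  stopifnot(inherits(study, "synthetic_study"))
  config <- set_partitions(config, study$truth)
  if (any(study$harvest_das > config$schedule$total_days))
    stop("harvest DAS outside the simulated range")
  traj <- simulate_plant(config)
  idx <- match(study$harvest_das, traj$daily$das)
  obs <- c(leaf_area = "s", leaf_mass = "M_L",
           root_mass = "M_r", stem_mass = "M_i")
  set.seed(seed)
  rows <- list()
  for (k in seq_along(obs)) {
    mu <- traj$daily[[obs[k]]][idx]
    for (j in seq_along(mu)) {
      m <- mu[j]
      if (study$cv == 0 || m == 0) {
        mean_j <- m
        sd_j <- max(study$sd_floor * m, .Machine$double.xmin)
      } else if (study$noise == "lognormal") {
        sdl <- sqrt(log(1 + study$cv^2))
        reps <- stats::rlnorm(study$n, log(m) - sdl^2 / 2, sdl)
        mean_j <- mean(reps); sd_j <- stats::sd(reps)
      } else {
        reps <- stats::rnorm(study$n, m, study$cv * m)
        mean_j <- mean(reps); sd_j <- stats::sd(reps)
      }
      if (sd_j <= 0) sd_j <- max(study$sd_floor * mean_j,
                                 .Machine$double.xmin)
      rows[[length(rows) + 1L]] <-
        data.frame(observable = names(obs)[k], das = study$harvest_das[j],
                   mean = mean_j, sd = sd_j, n = study$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
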