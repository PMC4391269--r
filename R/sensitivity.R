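#' Define a one-at-a-time perturbation
#'
#' Partition coefficients are perturbed by absolute percentage points
#' (delta = +/-0.01 means one coefficient gains 0.01 while a named
#' compensating coefficient in the same phase loses it, keeping the
#' simplex intact).  Scalar inputs (photosynthesis, initial leaf area) are
#' perturbed by +/-1% relative; sigma, itself a fraction, by absolute
#' points.  The vegetative-phase length is perturbed by the relative
#' `delta` truncated to whole days (the schedule is day-indexed), shifting
#' the vegetative/reproductive boundary; +/-1% of a 62-day vegetative
#' phase truncates to zero days and is a null perturbation, which is why
#' the published protocol reports no sensitivity to this input.
#'
#' @param target one of `"photosynthesis"`, `"sigma"`,
#'   `"initial_leaf_area"`, `"coefficient"`, `"vegetative_length"`.
#' @param delta signed perturbation (see above for units per target).
#' @param phase,coeff,compensate for `target = "coefficient"`: the phase,
#'   the coefficient receiving `delta`, and the coefficient absorbing
#'   `-delta`.
#' @param label optional display label.
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(target, delta, phase = NULL, coeff = NULL,
                         compensate = NULL, label = NULL) {
  target <- match.arg(target, c("photosynthesis", "sigma",
                                "initial_leaf_area", "coefficient",
                                "vegetative_length"))
  if (target == "coefficient") {
    stopifnot(phase %in% phase_names(),
              coeff %in% c("iota", "rho", "lambda_s", "lambda_t"),
              compensate %in% c("iota", "rho", "lambda_s", "lambda_t"),
              coeff != compensate)
  }
  if (is.null(label)) {
    label <- if (target == "coefficient")
      sprintf("%s %s (%+g, comp. %s)", coeff, phase, delta, compensate)
    else sprintf("%s (%+g)", target, delta)
  }
  structure(list(target = target, delta = delta, phase = phase,
                 coeff = coeff, compensate = compensate, label = label),
            class = "perturbation")
}

#' Apply a perturbation to a configuration
#'
#' @param config a [growth_config()].
#' @param p a [perturbation()].
#' @return The perturbed configuration; exactly the named quantities
#'   differ from the baseline.
#' @export
apply_perturbation <- function(config, p) {
  stopifnot(inherits(p, "perturbation"))
  switch(p$target,
    photosynthesis = {
      config$photo$coefficients <- config$photo$coefficients * (1 + p$delta)
      config
    },
    sigma = {
      s <- config$constants$sigma + p$delta
      if (s < 0 || s >= 1) stop("perturbed sigma outside [0, 1)")
      config$constants$sigma <- s
      config
    },
    initial_leaf_area = {
      config$constants$initial_leaf_area <-
        config$constants$initial_leaf_area * (1 + p$delta)
      config
    },
    coefficient = {
      m <- unclass(config$partitions)
      m[p$phase, p$coeff] <- m[p$phase, p$coeff] + p$delta
      m[p$phase, p$compensate] <- m[p$phase, p$compensate] - p$delta
      if (any(m[p$phase, ] < -1e-12) || any(m[p$phase, ] > 1 + 1e-12))
        stop("infeasible compensation: coefficient leaves [0, 1] in phase ",
             p$phase)
      m[m < 0] <- 0
      m[m > 1] <- 1
      config$partitions <- partition_set(m)
      config
    },
    vegetative_length = {
      iv <- config$schedule$intervals
      veg_days <- iv$late_vegetative[2] - iv$early_vegetative[1] + 1
      d <- as.integer(trunc(p$delta * veg_days))
      config$schedule <- phase_schedule(
        heterotrophic = iv$germination,
        early_vegetative = iv$early_vegetative,
        late_vegetative = c(iv$late_vegetative[1], iv$late_vegetative[2] + d),
        reproductive = c(iv$reproductive[1] + d, iv$reproductive[2]),
        photoperiod_h = config$schedule$photoperiod_h,
        step_h = config$schedule$step_h)
      config
    })
}

#' The standard perturbation battery
#'
#' The published one-at-a-time protocol: +/-1% photosynthesis, +/-1 point
#' starch partitioning, +/-1% initial leaf area, +/-1 point early
#' vegetative leaf thickening (compensated by leaf area growth), +/-1
#' point early vegetative root allocation (compensated by thickening,
#' area growth held constant), +/-1 point late vegetative inflorescence
#' allocation (compensated by thickening), and +/-1% vegetative phase
#' length (a null perturbation at day resolution; see [perturbation()]).
#'
#' @return List of [perturbation()]s (paired +/- rows in order).
#' @export
default_battery <- function() {
  b <- list()
  add <- function(...) b[[length(b) + 1L]] <<- perturbation(...)
  for (d in c(0.01, -0.01)) add("photosynthesis", d)
  for (d in c(0.01, -0.01)) add("sigma", d)
  for (d in c(0.01, -0.01)) add("initial_leaf_area", d)
  for (d in c(0.01, -0.01))
    add("coefficient", d, phase = "early_vegetative",
        coeff = "lambda_t", compensate = "lambda_s")
  for (d in c(0.01, -0.01))
    add("coefficient", d, phase = "early_vegetative",
        coeff = "rho", compensate = "lambda_t")
  for (d in c(0.01, -0.01))
    add("coefficient", d, phase = "late_vegetative",
        coeff = "iota", compensate = "lambda_t")
  for (d in c(0.01, -0.01)) add("vegetative_length", d)
  b
}

#' Run the sensitivity protocol
#'
#' Simulates the baseline and each perturbed configuration and reports the
#' percent change in leaf area and plant mass at the checkpoint days.  A
#' perturbation is flagged sensitive where the output change exceeds 1% in
#' magnitude.
#'
#' @param config baseline [growth_config()].
#' @param perturbations list of [perturbation()]s
#'   (default: [default_battery()]).
#' @param checkpoints DAS checkpoints (default harvest days 26/44/66/86).
#' @return A data.frame with one row per perturbation x output x
#'   checkpoint: `label`, `target`, `delta`, `output`, `das`,
#'   `pct_change`, `sensitive`.
#' @export
sensitivity_table <- function(config, perturbations = default_battery(),
                              checkpoints = c(26, 44, 66, 86)) {
  base <- simulate_plant(config)$daily
  idx <- match(checkpoints, base$das)
  if (anyNA(idx)) stop("checkpoint outside the simulated range")
  outputs <- c(leaf_area = "s", plant_mass = "M_P")
  rows <- list()
  for (p in perturbations) {
    pert <- simulate_plant(apply_perturbation(config, p))$daily
    for (o in names(outputs)) {
      b <- base[[outputs[o]]][idx]
      v <- pert[[outputs[o]]][idx]
      pct <- ifelse(b > 0, 100 * (v - b) / b, NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(label = p$label, target = p$target, delta = p$delta,
                   output = o, das = checkpoints, pct_change = pct,
                   sensitive = abs(pct) > 1)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
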