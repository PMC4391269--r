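#' Developmental phase schedule
#'
#' Defines the four developmental phases of the simulated life cycle on the
#' DAS (days after seeding) axis, together with the photoperiod and the
#' fixed integration step.  The default is the Col-0 schedule under an 8 h
#' photoperiod: heterotrophic (germination) phase 1--4 DAS, early vegetative
#' 5--45 DAS (first two thirds of the vegetative phase), late vegetative
#' 46--66 DAS, reproductive 67--90 DAS.
#'
#' @param heterotrophic inclusive DAS interval of the seed-reserve-fed phase.
#' @param early_vegetative inclusive DAS interval.
#' @param late_vegetative inclusive DAS interval.
#' @param reproductive inclusive DAS interval.
#' @param photoperiod_h hours of light per day, in (0, 24).
#' @param step_h integration step in hours; must divide 24.
#'
#' @return An object of class `phase_schedule`.
#' @examples
#' sched <- phase_schedule()
#' phase_of(sched, 30)
#' @export
phase_schedule <- function(heterotrophic = c(1L, 4L),
                           early_vegetative = c(5L, 45L),
                           late_vegetative = c(46L, 66L),
                           reproductive = c(67L, 90L),
                           photoperiod_h = 8,
                           step_h = 1) {
  iv <- list(germination = as.integer(heterotrophic),
             early_vegetative = as.integer(early_vegetative),
             late_vegetative = as.integer(late_vegetative),
             reproductive = as.integer(reproductive))
  for (nm in names(iv)) {
    if (length(iv[[nm]]) != 2L || iv[[nm]][1] > iv[[nm]][2])
      stop("phase interval '", nm, "' must be an inclusive [lo, hi] pair")
  }
  # contiguity: each phase starts the day after the previous one ends
  starts <- vapply(iv, `[`, integer(1), 1L)
  ends <- vapply(iv, `[`, integer(1), 2L)
  if (starts[1] != 1L)
    stop("heterotrophic phase must start at DAS 1")
  if (any(starts[-1] != ends[-4] + 1L))
    stop("phase intervals must be contiguous and non-overlapping")
  if (!(photoperiod_h > 0 && photoperiod_h < 24))
    stop("photoperiod_h must lie strictly between 0 and 24")
  if (24 %% step_h != 0)
    stop("step_h must divide 24")
  structure(list(intervals = iv,
                 photoperiod_h = photoperiod_h,
                 total_days = unname(ends[4]),
                 step_h = step_h),
            class = "phase_schedule")
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat("Phase schedule (", x$total_days, " days, photoperiod ",
      x$photoperiod_h, " h):\n", sep = "")
  for (nm in names(x$intervals))
    cat(sprintf("  %-17s DAS %2d-%2d\n", nm,
                x$intervals[[nm]][1], x$intervals[[nm]][2]))
  invisible(x)
}

#' Phase label for a given day
#'
#' @param schedule a [phase_schedule()].
#' @param das day after seeding (vectorised).
#' @return Character vector with values in
#'   `c("germination", "early_vegetative", "late_vegetative", "reproductive")`.
#' @export
phase_of <- function(schedule, das) {
  stopifnot(inherits(schedule, "phase_schedule"))
  out <- rep(NA_character_, length(das))
  for (nm in names(schedule$intervals)) {
    iv <- schedule$intervals[[nm]]
    out[das >= iv[1] & das <= iv[2]] <- nm
  }
  if (anyNA(out))
    stop("DAS outside the simulated range [1, ", schedule$total_days, "]")
  out
}

#' Physiological constants of the carbon-balance model
#'
#' All defaults are the published input values for Col-0: the
#' starch set-aside fraction sigma = 0.6 of daytime fixed carbon, carbon
#' concentration 37,500 umol C per g dry mass (45% C at 12 g/mol), leaf
#' maintenance respiration 0.35 umol m-2 s-1, inflorescence and root
#' maintenance coefficients 7.0e-3 and 1.6e-2 umol g-1 s-1, growth
#' respiration coefficients 0.104 / 0.17 / 0.13 g g-1 for leaf /
#' inflorescence / root, root exudation 1.0e-3 umol plant-1 h-1, and a
#' seed-reserve mobilization ratio of 0.25 of the initial reserve per day
#' (depleting the reserve by the end of DAS 4).
#'
#' @param sigma fraction of daytime fixed C diverted to transient starch.
#' @param carbon_conc umol C per g dry biomass.
#' @param rL_maint leaf maintenance respiration, umol m-2 s-1.
#' @param ri_maint_coeff inflorescence maintenance coefficient, umol g-1 s-1.
#' @param rr_maint_coeff root maintenance coefficient, umol g-1 s-1.
#' @param gL_growth_coeff leaf growth respiration coefficient, g g-1.
#' @param gi_growth_coeff inflorescence growth respiration coefficient, g g-1.
#' @param gr_growth_coeff root growth respiration coefficient, g g-1.
#' @param exudation root exudation, umol plant-1 h-1.
#' @param shaded_photo_fraction photosynthetic rate of shaded (overlapped)
#'   leaf area relative to exposed area.
#' @param seed_mobilization_ratio fraction of the initial seed reserve
#'   mobilized per day during the heterotrophic phase.
#' @param cotyledon_seed_fraction cotyledon (initial leaf) mass as a fraction
#'   of seed mass; also the storage fraction of the seed.
#' @param initial_leaf_area m2, expanded cotyledons.
#' @param initial_leaf_mass g, 90% of seed weight.
#'
#' @return An object of class `model_constants`.
#' @export
model_constants <- function(sigma = 0.6,
                            carbon_conc = 37500,
                            rL_maint = 0.35,
                            ri_maint_coeff = 7.0e-3,
                            rr_maint_coeff = 1.6e-2,
                            gL_growth_coeff = 0.104,
                            gi_growth_coeff = 0.17,
                            gr_growth_coeff = 0.13,
                            exudation = 1.0e-3,
                            shaded_photo_fraction = 0.1,
                            seed_mobilization_ratio = 0.25,
                            cotyledon_seed_fraction = 0.9,
                            initial_leaf_area = 5.0e-6,
                            initial_leaf_mass = 1.8e-5) {
  x <- list(sigma = sigma, carbon_conc = carbon_conc,
            rL_maint = rL_maint,
            ri_maint_coeff = ri_maint_coeff,
            rr_maint_coeff = rr_maint_coeff,
            gL_growth_coeff = gL_growth_coeff,
            gi_growth_coeff = gi_growth_coeff,
            gr_growth_coeff = gr_growth_coeff,
            exudation = exudation,
            shaded_photo_fraction = shaded_photo_fraction,
            seed_mobilization_ratio = seed_mobilization_ratio,
            cotyledon_seed_fraction = cotyledon_seed_fraction,
            initial_leaf_area = initial_leaf_area,
            initial_leaf_mass = initial_leaf_mass)
  if (any(vapply(x, function(v) !is.numeric(v) || length(v) != 1 ||
                   !is.finite(v) || v < 0, logical(1))))
    stop("all model constants must be single non-negative finite numbers")
  if (sigma >= 1) stop("sigma must lie in [0, 1)")
  if (any(c(gL_growth_coeff, gi_growth_coeff, gr_growth_coeff) >= 1))
    stop("growth respiration coefficients must lie in [0, 1)")
  if (shaded_photo_fraction > 1)
    stop("shaded_photo_fraction must lie in [0, 1]")
  structure(x, class = "model_constants")
}

phase_names <- function() {
  c("germination", "early_vegetative", "late_vegetative", "reproductive")
}

#' Partition coefficient set
#'
#' The 16 calibratable coefficients: for each of the four developmental
#' phases, the fractions of NAR (net assimilation rate) allocated to
#' inflorescence+stem growth (iota), root growth (rho), leaf area growth
#' (lambda_s) and leaf thickening (lambda_t).  Within each phase the four
#' fractions must sum to 1; total leaf allocation is
#' lambda = lambda_s + lambda_t.
#'
#' @param coeffs a 4 x 4 numeric matrix (rows = phases in the order
#'   germination, early_vegetative, late_vegetative, reproductive; columns
#'   `iota`, `rho`, `lambda_s`, `lambda_t`), or a data.frame with those
#'   columns and a `phase` column.
#' @return An object of class `partition_set`: a 4 x 4 matrix with phase
#'   rownames.
#' @examples
#' ps <- partition_table2("col0", 1)
#' rowSums(ps)                 # each phase sums to 1
#' ps["early_vegetative", ]
#' @export
partition_set <- function(coeffs) {
  cols <- c("iota", "rho", "lambda_s", "lambda_t")
  if (is.data.frame(coeffs)) {
    stopifnot(all(c("phase", cols) %in% names(coeffs)))
    m <- as.matrix(coeffs[match(phase_names(), coeffs$phase), cols])
  } else {
    m <- as.matrix(coeffs)
    if (is.null(colnames(m))) colnames(m) <- cols
    m <- m[, cols, drop = FALSE]
  }
  rownames(m) <- phase_names()
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop("partition coefficients must lie in [0, 1]")
  bad <- abs(rowSums(m) - 1) > 1e-9
  if (any(bad))
    stop("partition coefficients must sum to 1 per phase; violated in: ",
         paste(rownames(m)[bad], collapse = ", "))
  structure(m, class = c("partition_set", "matrix", "array"))
}

#' @export
print.partition_set <- function(x, ...) {
  cat("Partition coefficients (fractions of NAR):\n")
  print(unclass(x))
  invisible(x)
}

# Published simulation-1/2 coefficient sets for Col-0 and gi-2 (vegetative
# and reproductive phases); the germination row is not part of the published
# table and defaults to cotyledon-only allocation (iota = rho = 0).
.table2 <- list(
  col0 = list(
    `1` = rbind(early_vegetative = c(0.01, 0.06, 0.75, 0.18),
                late_vegetative  = c(0.06, 0.11, 0.70, 0.13),
                reproductive     = c(0.34, 0.10, 0.32, 0.23)),
    `2` = rbind(early_vegetative = c(0.00, 0.05, 0.76, 0.19),
                late_vegetative  = c(0.02, 0.11, 0.67, 0.20),
                reproductive     = c(0.40, 0.10, 0.45, 0.05))),
  gi2 = list(
    `1` = rbind(early_vegetative = c(0.00, 0.08, 0.77, 0.15),
                late_vegetative  = c(0.02, 0.12, 0.74, 0.12),
                reproductive     = c(0.20, 0.14, 0.51, 0.15)),
    `2` = rbind(early_vegetative = c(0.00, 0.06, 0.78, 0.16),
                late_vegetative  = c(0.02, 0.11, 0.76, 0.12),
                reproductive     = c(0.25, 0.14, 0.54, 0.07))))

#' Published calibrated partition coefficients
#'
#' Returns the selected calibrated coefficient sets ("simulation 1" and
#' "simulation 2") for the Col-0 wild type and the large-rosette gi-2
#' mutant.  The germination-phase row was not published; the packaged
#' default allocates all mobilized reserve C to the cotyledons
#' (iota = rho = 0, lambda_s = 0.8, lambda_t = 0.2).
#'
#' Two published rows round to 0.99 and 1.01; for simulation the rows are
#' renormalized to sum exactly 1 (set `normalize = FALSE` to retrieve the
#' printed values, e.g. for reproducing quoted allocation percentages).
#'
#' @param genotype `"col0"` or `"gi2"`.
#' @param sim simulation set, 1 (lowest-score setting) or 2.
#' @param germination optional numeric length-4 vector
#'   (iota, rho, lambda_s, lambda_t) overriding the germination row.
#' @param normalize renormalize rows to sum exactly 1 (default).
#' @return A [partition_set()], or a plain matrix if `normalize = FALSE`.
#' @export
partition_table2 <- function(genotype = c("col0", "gi2"), sim = 1,
                             germination = c(0, 0, 0.8, 0.2),
                             normalize = TRUE) {
  genotype <- match.arg(genotype)
  sim <- as.character(sim)
  if (!sim %in% c("1", "2")) stop("sim must be 1 or 2")
  m <- rbind(germination = germination, .table2[[genotype]][[sim]])
  colnames(m) <- c("iota", "rho", "lambda_s", "lambda_t")
  if (!normalize) return(m)
  partition_set(m / rowSums(m))
}
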