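#' Photosynthesis driver curve
#'
#' Area-based net photosynthesis A(DAS) as a cubic polynomial in days after
#' seeding, mirroring the third-order regression used to extrapolate sparse
#' gas-exchange measurements over the whole life cycle.  Evaluations are
#' clipped at `floor` (default 0): cubic tails outside the measured range
#' are untrustworthy and net assimilation cannot be negative as a driver.
#'
#' @param coefficients numeric length 4, `c(c0, c1, c2, c3)` so that
#'   `A(das) = c0 + c1*das + c2*das^2 + c3*das^3` in umol m-2 s-1.
#' @param range valid DAS range, inclusive.
#' @param floor lower clip value, >= 0.
#' @return An object of class `photo_curve`, callable via [eval_driver()].
#' @export
photo_curve <- function(coefficients, range = c(1, 90), floor = 0) {
  stopifnot(is.numeric(coefficients), length(coefficients) == 4,
            all(is.finite(coefficients)), floor >= 0,
            length(range) == 2, range[1] < range[2])
  structure(list(coefficients = as.numeric(coefficients),
                 range = as.numeric(range), floor = floor),
            class = "photo_curve")
}

#' Projected-to-total leaf area ratio curve
#'
#' The overlap driver r(DAS) = a * das^b, a power law fitted to measured
#' projected/total leaf area ratios.  Predictions are clamped to
#' `(clamp_min, 1]`: the projected area can never exceed the total area.
#' The curve is parameterized on DAS by default; `on = "area"` evaluates it
#' on total leaf area instead (state-coupled driver).
#'
#' @param a,b power-law parameters.
#' @param clamp_min lower clamp (exclusive floor for the ratio), > 0.
#' @param on `"das"` (default) or `"area"` — the abscissa the law is
#'   evaluated on.
#' @return An object of class `overlap_curve`.
#' @export
overlap_curve <- function(a, b, clamp_min = 1e-3, on = c("das", "area")) {
  on <- match.arg(on)
  stopifnot(is.finite(a), a > 0, is.finite(b), clamp_min > 0, clamp_min < 1)
  structure(list(a = a, b = b, clamp_min = clamp_min, on = on),
            class = "overlap_curve")
}

#' Evaluate a driver curve
#'
#' @param curve a [photo_curve()] or [overlap_curve()].
#' @param x DAS for a `photo_curve`; DAS or total leaf area (m2) for an
#'   `overlap_curve` depending on its `on` field.
#' @return Numeric vector of driver values (clipped/clamped).
#' @export
eval_driver <- function(curve, x) UseMethod("eval_driver")

#' @export
eval_driver.photo_curve <- function(curve, x) {
  if (any(x < curve$range[1] - 1e-9 | x > curve$range[2] + 1e-9))
    stop("driver curve undefined at DAS outside [",
         curve$range[1], ", ", curve$range[2], "]")
  cf <- curve$coefficients
  pmax(curve$floor, cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3)
}

#' @export
eval_driver.overlap_curve <- function(curve, x) {
  if (any(x <= 0)) stop("overlap curve requires a positive abscissa")
  pmin(1, pmax(curve$clamp_min, curve$a * x^curve$b))
}

#' Fit the cubic photosynthesis curve to measurements
#'
#' Least-squares third-order polynomial regression of area-based net
#' photosynthesis on DAS.  With exactly four points the fit interpolates.
#'
#' @param points data.frame with columns `das` and `A` (umol m-2 s-1), or a
#'   two-column matrix.
#' @param range valid DAS range of the returned curve.
#' @return A [photo_curve()]; the residuals of the fit are attached as
#'   attribute `"residuals"`.
#' @export
fit_photo_curve <- function(points, range = c(1, 90)) {
  points <- as.data.frame(points)
  if (!all(c("das", "A") %in% names(points)))
    names(points)[1:2] <- c("das", "A")
  if (nrow(points) < 4)
    stop("at least 4 points are needed to fit a cubic")
  X <- stats::poly(points$das, 3, raw = TRUE)
  fit <- stats::lm(points$A ~ X)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: DAS values do not support a cubic fit")
  cv <- unname(stats::coef(fit))
  out <- photo_curve(cv, range = range)
  attr(out, "residuals") <- unname(stats::residuals(fit))
  out
}

#' Fit the power-law overlap curve to measurements
#'
#' Log-log linear least squares of the projected/total leaf area ratio on
#' DAS (or total area).  Ratios must lie in (0, 1].
#'
#' @param points data.frame with columns `das` (or `area`) and `ratio`.
#' @param on abscissa, `"das"` or `"area"`.
#' @return An [overlap_curve()] with residuals (log scale) attached as
#'   attribute `"residuals"`.
#' @export
fit_overlap_curve <- function(points, on = c("das", "area")) {
  on <- match.arg(on)
  points <- as.data.frame(points)
  xcol <- if (on == "das") "das" else "area"
  if (!xcol %in% names(points)) names(points)[1] <- xcol
  if (!"ratio" %in% names(points)) names(points)[2] <- "ratio"
  if (nrow(points) < 2) stop("at least 2 points are needed")
  if (any(points[[xcol]] <= 0) || any(points$ratio <= 0))
    stop("power-law fit requires positive abscissa and ratios")
  if (any(points$ratio > 1)) stop("ratios must lie in (0, 1]")
  fit <- stats::lm(log(points$ratio) ~ log(points[[xcol]]))
  cv <- unname(stats::coef(fit))
  out <- overlap_curve(a = exp(cv[1]), b = cv[2], on = on)
  attr(out, "residuals") <- unname(stats::residuals(fit))
  out
}

#' Light schedule
#'
#' Flags daylight hours.  The light block occupies hours `[0, P)` of each
#' day; the model has no within-day asymmetry, so the placement of the block
#' is inconsequential.
#'
#' @param das day after seeding (unused beyond validation; kept for a stable
#'   driver signature).
#' @param hour hour of day in `[0, 24)`.
#' @param schedule a [phase_schedule()].
#' @return Logical: `TRUE` during the photoperiod.
#' @export
is_daylight <- function(das, hour, schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  if (any(hour < 0 | hour >= 24)) stop("hour must lie in [0, 24)")
  hour < schedule$photoperiod_h
}
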