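#' Assemble a model configuration
#'
#' Bundles everything one simulation needs: the phase schedule, the
#' physiological constants, the partition coefficients, and the two driver
#' curves (area-based photosynthesis and projected/total leaf area ratio).
#'
#' @param schedule a [phase_schedule()].
#' @param constants a [model_constants()].
#' @param partitions a [partition_set()].
#' @param photo a [photo_curve()] defined on the full simulated range.
#' @param overlap an [overlap_curve()].
#' @return An object of class `growth_config`.
#' @examples
#' cfg <- growth_config(partitions = partition_table2("col0", 1),
#'                      photo = fixture_drivers("col0")$photo,
#'                      overlap = fixture_drivers("col0")$overlap)
#' @export
growth_config <- function(schedule = phase_schedule(),
                          constants = model_constants(),
                          partitions = partition_table2("col0", 1),
                          photo, overlap) {
  stopifnot(inherits(schedule, "phase_schedule"),
            inherits(constants, "model_constants"),
            inherits(partitions, "partition_set"),
            inherits(photo, "photo_curve"),
            inherits(overlap, "overlap_curve"))
  if (photo$range[1] > schedule$intervals$early_vegetative[1] ||
      photo$range[2] < schedule$total_days)
    stop("photosynthesis curve must cover the autotrophic DAS range [",
         schedule$intervals$early_vegetative[1], ", ",
         schedule$total_days, "]")
  structure(list(schedule = schedule, constants = constants,
                 partitions = partitions, photo = photo, overlap = overlap),
            class = "growth_config")
}

#' Replace the partition set of a configuration
#'
#' Convenience used heavily during calibration, where only the coefficients
#' change between evaluations.
#'
#' @param config a [growth_config()].
#' @param partitions a [partition_set()].
#' @return The modified configuration.
#' @export
set_partitions <- function(config, partitions) {
  stopifnot(inherits(config, "growth_config"),
            inherits(partitions, "partition_set"))
  config$partitions <- partitions
  config
}

#' Read / write a configuration as JSON
#'
#' The on-disk form is a plain key-value tree mirroring the constructor
#' arguments, so configurations are portable and diffable.
#'
#' @param config a [growth_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   [growth_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "growth_config"))
  x <- list(
    schedule = list(
      heterotrophic = config$schedule$intervals$germination,
      early_vegetative = config$schedule$intervals$early_vegetative,
      late_vegetative = config$schedule$intervals$late_vegetative,
      reproductive = config$schedule$intervals$reproductive,
      photoperiod_h = config$schedule$photoperiod_h,
      step_h = config$schedule$step_h),
    constants = unclass(config$constants),
    partitions = as.data.frame(cbind(
      phase = rownames(config$partitions),
      as.data.frame(unclass(config$partitions)))),
    photo = unclass(config$photo),
    overlap = unclass(config$overlap))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  part <- x$partitions
  part[c("iota", "rho", "lambda_s", "lambda_t")] <-
    lapply(part[c("iota", "rho", "lambda_s", "lambda_t")], as.numeric)
  growth_config(
    schedule = phase_schedule(
      heterotrophic = x$schedule$heterotrophic,
      early_vegetative = x$schedule$early_vegetative,
      late_vegetative = x$schedule$late_vegetative,
      reproductive = x$schedule$reproductive,
      photoperiod_h = x$schedule$photoperiod_h,
      step_h = x$schedule$step_h),
    constants = do.call(model_constants, x$constants),
    partitions = partition_set(part),
    photo = photo_curve(x$photo$coefficients, range = x$photo$range,
                        floor = x$photo$floor),
    overlap = overlap_curve(x$overlap$a, x$overlap$b,
                            clamp_min = x$overlap$clamp_min,
                            on = x$overlap$on))
}

#' Validate a configuration, reporting field paths
#'
#' @param config a candidate `growth_config`.
#' @return `TRUE` invisibly, or an error naming the offending field.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "growth_config"))
    stop("not a growth_config")
  sums <- rowSums(config$partitions)
  bad <- which(abs(sums - 1) > 1e-9)
  if (length(bad))
    stop("partitions$", rownames(config$partitions)[bad[1]],
         ": coefficients sum to ", signif(sums[bad[1]], 6), ", not 1")
  invisible(TRUE)
}
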