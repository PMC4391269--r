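# shared fixtures built in code; trajectories are cached per session since
# the packaged configurations are deterministic

col0_traj <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_plant(col0_config())
    val
  }
})

gi2_traj <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_plant(gi2_config())
    val
  }
})

# a random valid configuration: random simplex partitions, jittered
# constants, a random declining positive photosynthesis cubic and a random
# declining overlap power law
random_config <- function() {
  rsimplex <- function(k = 4) { x <- stats::rexp(k); x / sum(x) }
  m <- rbind(germination = c(0, 0, rsimplex(2)),
             early_vegetative = rsimplex(),
             late_vegetative = rsimplex(),
             reproductive = rsimplex())
  colnames(m) <- c("iota", "rho", "lambda_s", "lambda_t")
  cn <- model_constants(
    sigma = stats::runif(1, 0.3, 0.8),
    rL_maint = stats::runif(1, 0.1, 0.6),
    ri_maint_coeff = stats::runif(1, 1e-3, 2e-2),
    rr_maint_coeff = stats::runif(1, 1e-3, 3e-2),
    gL_growth_coeff = stats::runif(1, 0.05, 0.2),
    gi_growth_coeff = stats::runif(1, 0.05, 0.3),
    gr_growth_coeff = stats::runif(1, 0.05, 0.3))
  A_hi <- stats::runif(1, 4, 7)
  A_lo <- stats::runif(1, 1, A_hi - 0.5)
  V <- outer(c(5, 35, 65, 90), 0:3, `^`)
  photo <- photo_curve(solve(V, c(A_hi,
                                  A_hi - (A_hi - A_lo) * 0.3,
                                  A_hi - (A_hi - A_lo) * 0.7,
                                  A_lo)),
                       range = c(1, 90))
  r1 <- stats::runif(1, 0.85, 0.99)
  r2 <- stats::runif(1, 0.4, r1 - 0.1)
  b <- log(r2 / r1) / log(86 / 26)
  growth_config(partitions = partition_set(m), photo = photo,
                overlap = overlap_curve(a = r1 / 26^b, b = b))
}
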