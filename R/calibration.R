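#' Sigmoid objective weights
#'
#' The per-point transform of the model--data mismatch is the logistic
#' `1 / (1 + exp(alpha * |dif| / SD + beta))`.  With the defaults
#' alpha = -10, beta = 5 a point contributes about 0.0067 when the model
#' matches exactly, 0.5 when it misses by half an SD, and about 0.993 when
#' it misses by one SD — so a series objective reaches 1 as soon as any
#' single point falls outside the measured standard deviation.
#'
#' @param alpha sigmoid slope (negative).
#' @param beta sigmoid offset.
#' @param threshold qualification threshold on each series objective.
#' @return An object of class `objective_weights`.
#' @export
objective_weights <- function(alpha = -10, beta = 5, threshold = 1) {
  stopifnot(is.finite(alpha), is.finite(beta), threshold > 0)
  structure(list(alpha = alpha, beta = beta, threshold = threshold),
            class = "objective_weights")
}

#' Weighted absolute difference between model and data
#'
#' Sums the sigmoid-transformed standardized absolute differences over the
#' points of one measurement series.
#'
#' @param modeled modeled values at the measured days.
#' @param measured_mean,measured_sd measured means and standard deviations
#'   (same length; `measured_sd > 0`).
#' @param weights an [objective_weights()].
#' @return Scalar objective value (>= 0; at most the number of points).
#' @examples
#' weighted_diff(1.5, 1.0, 1.0)   # one point, dif = 0.5 SD -> 0.5
#' @export
weighted_diff <- function(modeled, measured_mean, measured_sd,
                          weights = objective_weights()) {
  if (any(measured_sd <= 0)) stop("measured SDs must be positive")
  if (length(modeled) != length(measured_mean))
    stop("modeled and measured lengths differ")
  dif <- abs(modeled - measured_mean)
  sum(1 / (1 + exp(weights$alpha * dif / measured_sd + weights$beta)))
}

# fast state trajectory via the compiled hourly kernel; mirrors
# simulate_plant() and is asserted equal to it in the tests
sim_state_fast <- function(config) {
  sched <- config$schedule
  ndays <- sched$total_days
  das_seq <- seq_len(ndays)
  pidx <- match(phase_of(sched, das_seq), phase_names())
  part <- unclass(config$partitions)
  germ <- part["germination", ]
  lam <- germ[["lambda_s"]] + germ[["lambda_t"]]
  if (lam <= 0) stop("germination-phase leaf allocation must be positive")
  if (config$overlap$on != "das")
    stop("the fast engine supports DAS-parameterized overlap curves only")
  .sim_state_cpp(ndays, as.integer(sched$photoperiod_h),
                 sched$intervals$germination[2],
                 eval_driver(config$photo, das_seq),
                 eval_driver(config$overlap, das_seq),
                 part[pidx, 1L], part[pidx, 2L],
                 part[pidx, 3L], part[pidx, 4L],
                 germ[["lambda_s"]] / lam, germ[["lambda_t"]] / lam,
                 unlist(config$constants))
}

#' Evaluate the four fit objectives for one coefficient setting
#'
#' Simulates the configuration under the candidate partition coefficients
#' and computes the weighted absolute difference for each of the four
#' measurement series (leaf area, leaf mass, root mass, stem mass).
#'
#' @param partitions a [partition_set()] (the candidate setting).
#' @param config a [growth_config()] supplying everything else.
#' @param measurements data.frame with columns `observable`, `das`,
#'   `mean`, `sd` (and optionally `n`), as produced by
#'   [generate_measurements()] or [read_measurements()].
#' @param weights an [objective_weights()].
#' @param engine `"cpp"` (compiled fast path, default) or `"r"`.
#' @return Named numeric of length 4 (`leaf_area`, `leaf_mass`,
#'   `root_mass`, `stem_mass`); `Inf`s if the simulation fails.
#' @export
evaluate_setting <- function(partitions, config, measurements,
                             weights = objective_weights(),
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  config <- set_partitions(config, partitions)
  obs_col <- c(leaf_area = "s", leaf_mass = "M_L",
               root_mass = "M_r", stem_mass = "M_i")
  state <- tryCatch({
    if (engine == "cpp") sim_state_fast(config)
    else as.matrix(simulate_plant(config)$daily[, c("s", "M_L", "M_i", "M_r")])
  }, error = function(e) NULL)
  out <- stats::setNames(rep(Inf, 4), names(obs_col))
  if (is.null(state)) return(out)
  for (nm in names(obs_col)) {
    ser <- measurements[measurements$observable == nm, ]
    if (nrow(ser) == 0) stop("no measurements for observable '", nm, "'")
    modeled <- state[ser$das, obs_col[[nm]]]
    out[nm] <- weighted_diff(modeled, ser$mean, ser$sd, weights)
  }
  out
}

#' Calibration bounds for the partition coefficients
#'
#' Per-phase `[lo, hi]` boxes for the 16 coefficients.  The published
#' constraint table is not available, so the defaults are a documented
#' stand-in: no inflorescence allocation during germination or the early
#' vegetative phase, no zero allocation to roots after germination
#' (floor 0.01), and modest physiological caps (rho <= 0.30,
#' lambda_t <= 0.50, iota <= 0.30 late vegetative / 0.60 reproductive).
#'
#' @param lower,upper optional 4 x 4 matrices (phases x coefficients)
#'   overriding the defaults.
#' @return An object of class `constraint_box`: list of matrices `lower`
#'   and `upper`.
#' @export
constraint_box <- function(lower = NULL, upper = NULL) {
  cols <- c("iota", "rho", "lambda_s", "lambda_t")
  lo <- matrix(0, 4, 4, dimnames = list(phase_names(), cols))
  hi <- matrix(1, 4, 4, dimnames = list(phase_names(), cols))
  hi["germination", c("iota", "rho")] <- 0
  hi["early_vegetative", "iota"] <- 0
  lo[c("early_vegetative", "late_vegetative", "reproductive"), "rho"] <- 0.01
  hi[c("early_vegetative", "late_vegetative", "reproductive"), "rho"] <- 0.30
  hi["late_vegetative", "iota"] <- 0.30
  hi["reproductive", "iota"] <- 0.60
  hi[, "lambda_t"] <- pmin(hi[, "lambda_t"], 0.50)
  if (!is.null(lower)) lo[] <- lower
  if (!is.null(upper)) hi[] <- upper
  if (any(lo > hi)) stop("constraint box has lower bound above upper bound")
  if (any(rowSums(lo) > 1 + 1e-12) || any(rowSums(hi) < 1 - 1e-12))
    stop("constraint box leaves no feasible simplex point in some phase")
  structure(list(lower = lo, upper = hi), class = "constraint_box")
}

# project one phase row onto the bounded simplex: clip, then shift
# proportionally within the remaining slack until the row sums to 1
repair_row <- function(x, lo, hi) {
  x <- pmin(hi, pmax(lo, x))
  for (it in 1:20) {
    s <- sum(x)
    if (abs(s - 1) < 1e-12) break
    if (s > 1) {
      slack <- x - lo
      tot <- sum(slack)
      if (tot <= 0) break
      x <- x - slack * min(1, (s - 1) / tot)
    } else {
      room <- hi - x
      tot <- sum(room)
      if (tot <= 0) break
      x <- x + room * min(1, (1 - s) / tot)
    }
  }
  x
}

# genome (16 raw genes in [0,1], phase-major) -> feasible partition_set
genome_to_partitions <- function(genes, box) {
  m <- matrix(genes, 4, 4, byrow = TRUE,
              dimnames = list(phase_names(),
                              c("iota", "rho", "lambda_s", "lambda_t")))
  for (p in 1:4) m[p, ] <- repair_row(m[p, ], box$lower[p, ], box$upper[p, ])
  partition_set(m)
}

#' Moment-matching estimate of the partition coefficients
#'
#' A direct "expert estimate" of the coefficients from the harvest
#' increments, used to seed the genetic calibration (mirroring the
#' two-arm workflow of manual estimation plus GA fine-tuning).  Between
#' consecutive harvests each organ's mass gain, inflated by its growth
#' respiration coefficient, estimates the growth substrate it received, so
#' the coefficient ratios follow directly; the leaf-area versus thickening
#' split comes from the area gain divided by the mean SLA over the
#' interval.  Each interval is assigned to the phase containing its
#' midpoint; uncovered phases inherit the nearest interval's estimate and
#' the germination row keeps its default.
#'
#' @param measurements measurement table (see [evaluate_setting()]).
#' @param config a [growth_config()].
#' @param box a [constraint_box()] used to repair the estimate.
#' @return A [partition_set()].
#' @export
estimate_partitions <- function(measurements, config, box = constraint_box()) {
  get_series <- function(nm) {
    x <- measurements[measurements$observable == nm, ]
    x[order(x$das), c("das", "mean")]
  }
  sA <- get_series("leaf_area"); mL <- get_series("leaf_mass")
  mR <- get_series("root_mass"); mI <- get_series("stem_mass")
  das <- sA$das
  if (length(das) < 2) stop("need at least two harvests to estimate")
  cn <- config$constants
  est <- list(); mid <- numeric(0)
  for (k in seq_len(length(das) - 1)) {
    dML <- max(mL$mean[k + 1] - mL$mean[k], 0)
    dMI <- max(mI$mean[k + 1] - mI$mean[k], 0)
    dMR <- max(mR$mean[k + 1] - mR$mean[k], 0)
    SL <- dML / (1 - cn$gL_growth_coeff)
    Si <- dMI / (1 - cn$gi_growth_coeff)
    Sr <- dMR / (1 - cn$gr_growth_coeff)
    S <- SL + Si + Sr
    if (S <= 0) next
    lam <- SL / S
    sla_mid <- (sA$mean[k] / mL$mean[k] + sA$mean[k + 1] / mL$mean[k + 1]) / 2
    dMs <- min(max((sA$mean[k + 1] - sA$mean[k]) / sla_mid, 0), dML)
    ls <- if (dML > 0) lam * dMs / dML else 0
    est[[length(est) + 1]] <- c(iota = Si / S, rho = Sr / S,
                                lambda_s = ls, lambda_t = lam - ls)
    mid <- c(mid, (das[k] + das[k + 1]) / 2)
  }
  if (!length(est)) stop("measurements carry no growth signal")
  phs <- phase_of(config$schedule, mid)
  m <- matrix(NA_real_, 4, 4,
              dimnames = list(phase_names(),
                              c("iota", "rho", "lambda_s", "lambda_t")))
  m["germination", ] <- c(0, 0, 0.8, 0.2)
  for (p in phase_names()[-1]) {
    hit <- which(phs == p)
    if (length(hit)) m[p, ] <- colMeans(do.call(rbind, est[hit]))
  }
  # phase midpoints per schedule, to borrow the nearest estimate
  for (p in which(is.na(m[, 1]))) {
    ctr <- mean(config$schedule$intervals[[rownames(m)[p]]])
    m[p, ] <- est[[which.min(abs(mid - ctr))]]
  }
  for (p in 1:4) m[p, ] <- repair_row(m[p, ], box$lower[p, ], box$upper[p, ])
  partition_set(m)
}

# Smooth surrogate refinement of a coefficient estimate: BFGS on the
# log-scale sum of squared model-data differences, with the coefficients
# softmax-parameterized per phase (coefficients fixed to zero by the box
# are excluded).  The sigmoid calibration objective saturates outside ~2 SD
# and offers no gradient there; this surrogate is informative everywhere
# and pulls a moment-matching estimate close enough for the genetic search
# to take over.
refine_estimate <- function(start, config, measurements,
                            box = constraint_box(), maxit = 200) {
  m0 <- unclass(start)
  free <- box$lower < box$upper
  fixed_val <- ifelse(free, 0, box$lower)   # pinned coefficients keep lo == hi
  obs_col <- c(leaf_area = "s", leaf_mass = "M_L",
               root_mass = "M_r", stem_mass = "M_i")
  ser <- lapply(names(obs_col), function(nm)
    measurements[measurements$observable == nm, c("das", "mean")])
  names(ser) <- names(obs_col)
  eps <- vapply(ser, function(x) 1e-6 * max(x$mean), numeric(1))

  to_m <- function(theta) {
    m <- fixed_val
    k <- 0L
    for (p in 1:4) {
      idx <- which(free[p, ])
      w <- exp(theta[k + seq_along(idx)])
      m[p, idx] <- w / sum(w) * (1 - sum(fixed_val[p, ]))
      k <- k + length(idx)
    }
    dimnames(m) <- dimnames(m0)
    m
  }
  th0 <- unlist(lapply(1:4, function(p)
    log(pmax(m0[p, free[p, ]], 1e-4))))
  objf <- function(theta) {
    ps <- tryCatch(partition_set(to_m(theta)), error = function(e) NULL)
    if (is.null(ps)) return(1e10)
    st <- tryCatch(sim_state_fast(set_partitions(config, ps)),
                   error = function(e) NULL)
    if (is.null(st)) return(1e10)
    tot <- 0
    for (nm in names(obs_col)) {
      x <- ser[[nm]]
      tot <- tot + sum((log(st[x$das, obs_col[[nm]]] + eps[[nm]]) -
                          log(x$mean + eps[[nm]]))^2)
    }
    tot
  }
  op <- stats::optim(th0, objf, method = "BFGS",
                     control = list(maxit = maxit, reltol = 1e-14))
  m <- to_m(op$par)
  for (p in 1:4) m[p, ] <- repair_row(m[p, ], box$lower[p, ], box$upper[p, ])
  partition_set(m)
}

# ---- NSGA-II machinery (minimization) -------------------------------------

# returns integer front rank per row of the objective matrix
nds_rank <- function(objs) {
  n <- nrow(objs)
  rank_out <- integer(n)
  dominates_set <- vector("list", n)   # individuals that row i dominates
  dom_count <- integer(n)              # how many rows dominate row j
  for (i in seq_len(n)) {
    le <- objs[i, 1] <= objs[, 1] & objs[i, 2] <= objs[, 2] &
      objs[i, 3] <= objs[, 3] & objs[i, 4] <= objs[, 4]
    lt <- objs[i, 1] < objs[, 1] | objs[i, 2] < objs[, 2] |
      objs[i, 3] < objs[, 3] | objs[i, 4] < objs[, 4]
    dominates_set[[i]] <- which(le & lt)
  }
  for (i in seq_len(n)) dom_count[dominates_set[[i]]] <-
    dom_count[dominates_set[[i]]] + 1L
  front <- which(dom_count == 0L)
  r <- 1L
  while (length(front)) {
    rank_out[front] <- r
    nxt <- integer(0)
    for (i in front) {
      for (j in dominates_set[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- nxt
    r <- r + 1L
  }
  rank_out
}

crowding_distance <- function(objs) {
  n <- nrow(objs)
  d <- numeric(n)
  if (n <= 2) return(rep(Inf, n))
  for (m in seq_len(ncol(objs))) {
    o <- order(objs[, m])
    d[o[c(1, n)]] <- Inf
    span <- objs[o[n], m] - objs[o[1], m]
    if (span > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (objs[o[3:n], m] - objs[o[1:(n - 2)], m]) / span
  }
  d
}

sbx_crossover <- function(p1, p2, eta = 15, pc = 0.9) {
  n <- length(p1)
  c1 <- p1; c2 <- p2
  if (stats::runif(1) < pc) {
    swap <- stats::runif(n) < 0.5
    u <- stats::runif(n)
    beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                   (1 / (2 * (1 - u)))^(1 / (eta + 1)))
    mean_p <- (p1 + p2) / 2
    diff_p <- abs(p1 - p2) / 2
    a <- mean_p - beta * diff_p
    b <- mean_p + beta * diff_p
    c1[swap] <- a[swap]; c2[swap] <- b[swap]
    c1[!swap] <- b[!swap]; c2[!swap] <- a[!swap]
  }
  list(pmin(1, pmax(0, c1)), pmin(1, pmax(0, c2)))
}

poly_mutation <- function(x, eta = 20, pm = 1 / length(x)) {
  hit <- stats::runif(length(x)) < pm
  if (any(hit)) {
    u <- stats::runif(sum(hit))
    delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                    1 - (2 * (1 - u))^(1 / (eta + 1)))
    x[hit] <- pmin(1, pmax(0, x[hit] + delta))
  }
  x
}

#' Calibrate the partition coefficients with NSGA-II
#'
#' Multi-objective genetic search over the 16 partition coefficients,
#' minimizing the four weighted-difference objectives simultaneously.
#' Uses fast non-dominated sorting with crowding-distance selection,
#' binary tournaments, simulated binary crossover and polynomial mutation;
#' offspring are projected onto the bounded simplex by the constraint-box
#' repair.  Every setting encountered whose four objectives all fall at or
#' below the qualification threshold is recorded (qualification is a
#' census over the whole run, not just the final front).
#'
#' @param config a [growth_config()] (its partitions are ignored).
#' @param measurements measurement table (see [evaluate_setting()]).
#' @param pop_size population size (>= 8, even).
#' @param generations number of generations.
#' @param seed integer seed; runs are reproducible per seed.
#' @param weights an [objective_weights()].
#' @param box a [constraint_box()].
#' @param eta_c,eta_m SBX and mutation distribution indices.
#' @param p_crossover SBX probability per mating.
#' @param init `"seeded"` (default) devotes a quarter of the initial
#'   population to jittered copies of the moment-matching estimate
#'   ([estimate_partitions()]), the two-arm workflow; `"random"` uses a
#'   fully random feasible initial population.
#' @return An object of class `pareto_result`: list with `pareto`
#'   (data.frame of the final non-dominated settings and objectives),
#'   `qualified` (data.frame of all qualified settings encountered,
#'   deduplicated), `n_evaluations`, and the call parameters.
#' @export
fit_nsga2 <- function(config, measurements, pop_size = 64,
                      generations = 200, seed = 1,
                      weights = objective_weights(),
                      box = constraint_box(),
                      eta_c = 15, eta_m = 20, p_crossover = 0.9,
                      init = c("seeded", "random")) {
  if (pop_size < 8 || pop_size %% 2 != 0)
    stop("pop_size must be an even number >= 8")
  init <- match.arg(init)
  set.seed(seed)
  ngene <- 16L
  obj_names <- c("leaf_area", "leaf_mass", "root_mass", "stem_mass")

  qual_genes <- list(); qual_objs <- list()
  evaluate_genome <- function(genes) {
    ps <- genome_to_partitions(genes, box)
    ob <- evaluate_setting(ps, config, measurements, weights)
    if (all(is.finite(ob)) && all(ob <= weights$threshold)) {
      qual_genes[[length(qual_genes) + 1L]] <<- as.vector(t(unclass(ps)))
      qual_objs[[length(qual_objs) + 1L]] <<- ob
    }
    ob
  }

  pop <- matrix(stats::runif(pop_size * ngene), pop_size, ngene)
  if (init == "seeded") {
    guess <- tryCatch({
      est <- estimate_partitions(measurements, config, box)
      as.vector(t(unclass(refine_estimate(est, config, measurements, box))))
    }, error = function(e) NULL)
    if (!is.null(guess)) {
      n_seed <- pop_size %/% 4
      jitter_sd <- rep(c(0, 0.005, 0.01, 0.02), length.out = n_seed)
      for (k in seq_len(n_seed))
        pop[k, ] <- pmin(1, pmax(0, guess +
                                   stats::rnorm(ngene, 0, jitter_sd[k])))
    }
  }
  objs <- t(apply(pop, 1, evaluate_genome))
  n_eval <- pop_size

  for (gen in seq_len(generations)) {
    rk <- nds_rank(objs)
    cd <- numeric(pop_size)
    for (r in unique(rk)) {
      idx <- which(rk == r)
      cd[idx] <- crowding_distance(objs[idx, , drop = FALSE])
    }
    pick <- function() {
      ij <- sample.int(pop_size, 2)
      i <- ij[1]; j <- ij[2]
      if (rk[i] < rk[j]) i
      else if (rk[j] < rk[i]) j
      else if (cd[i] >= cd[j]) i else j
    }
    child <- matrix(0, pop_size, ngene)
    for (k in seq(1, pop_size, by = 2)) {
      cs <- sbx_crossover(pop[pick(), ], pop[pick(), ], eta_c, p_crossover)
      child[k, ] <- poly_mutation(cs[[1]], eta_m)
      child[k + 1, ] <- poly_mutation(cs[[2]], eta_m)
    }
    cobj <- t(apply(child, 1, evaluate_genome))
    n_eval <- n_eval + pop_size

    allpop <- rbind(pop, child)
    allobj <- rbind(objs, cobj)
    rk2 <- nds_rank(allobj)
    sel <- integer(0)
    for (r in sort(unique(rk2))) {
      idx <- which(rk2 == r)
      if (length(sel) + length(idx) <= pop_size) {
        sel <- c(sel, idx)
      } else {
        cdr <- crowding_distance(allobj[idx, , drop = FALSE])
        sel <- c(sel, idx[order(cdr, decreasing = TRUE)
                          [seq_len(pop_size - length(sel))]])
        break
      }
    }
    pop <- allpop[sel, , drop = FALSE]
    objs <- allobj[sel, , drop = FALSE]
  }

  colnames(objs) <- obj_names
  front <- which(nds_rank(objs) == 1L)
  coef_cols <- paste(rep(phase_names(), each = 4),
                     c("iota", "rho", "lambda_s", "lambda_t"), sep = ".")
  front_coef <- t(apply(pop[front, , drop = FALSE], 1, function(g)
    as.vector(t(unclass(genome_to_partitions(g, box))))))
  colnames(front_coef) <- coef_cols
  pareto <- data.frame(front_coef, objs[front, , drop = FALSE])

  if (length(qual_genes)) {
    qg <- do.call(rbind, qual_genes)
    qo <- do.call(rbind, qual_objs)
    colnames(qg) <- coef_cols
    colnames(qo) <- obj_names
    keep <- !duplicated(round(qg, 10))
    qualified <- data.frame(qg[keep, , drop = FALSE],
                            qo[keep, , drop = FALSE])
  } else {
    warning("no qualified parameter settings were encountered")
    qualified <- data.frame()
  }
  structure(list(pareto = pareto, qualified = qualified,
                 n_evaluations = n_eval,
                 pop_size = pop_size, generations = generations,
                 seed = seed, weights = weights, box = box),
            class = "pareto_result")
}

#' @export
print.pareto_result <- function(x, ...) {
  cat("NSGA-II calibration: ", x$n_evaluations, " evaluations (pop ",
      x$pop_size, " x ", x$generations, " generations, seed ", x$seed,
      ")\n", sep = "")
  cat("  Pareto front size:", nrow(x$pareto), "\n")
  cat("  qualified settings:", nrow(x$qualified), "\n")
  invisible(x)
}

#' Cluster and rank qualified parameter settings
#'
#' Agglomerative hierarchical clustering (average linkage, Euclidean
#' distance) of the qualified settings in 16-dimensional coefficient
#' space, with the cluster count chosen by mean silhouette width over
#' `k = 2..k_max` unless fixed.  Settings are ranked by the sum of the
#' leaf-area and leaf-mass objectives (the calibration emphasis), and the
#' per-cluster medoids plus the two best-ranked settings are returned.
#'
#' @param qualified data.frame from [fit_nsga2()] (`$qualified`).
#' @param k fixed cluster count, or `NULL` for silhouette selection.
#' @param k_max largest k considered during selection.
#' @return List with `settings` (input plus `cluster` and `rank_score`
#'   columns, ranked), `medoids` (one representative row per cluster),
#'   `top2`, and `k`.  With fewer than 2 settings, a passthrough with a
#'   warning.
#' @export
cluster_and_rank <- function(qualified, k = NULL, k_max = 8) {
  coef_cols <- grep("\\.(iota|rho|lambda_s|lambda_t)$", names(qualified))
  score <- qualified$leaf_area + qualified$leaf_mass
  if (nrow(qualified) < 2) {
    warning("fewer than 2 qualified settings; returning passthrough")
    out <- qualified
    if (nrow(out)) { out$cluster <- 1L; out$rank_score <- score }
    return(list(settings = out, medoids = out, top2 = out,
                k = min(1L, nrow(out))))
  }
  X <- as.matrix(qualified[, coef_cols])
  D <- stats::dist(X)
  hc <- stats::hclust(D, method = "average")
  if (is.null(k)) {
    ks <- 2:min(k_max, nrow(X) - 1)
    if (max(D) < 1e-12) {           # all duplicates: one cluster
      k <- 1L
    } else {
      sil <- vapply(ks, function(kk)
        mean_silhouette(stats::cutree(hc, kk), as.matrix(D)), numeric(1))
      k <- ks[which.max(sil)]
    }
  }
  cl <- if (k == 1L) rep(1L, nrow(X)) else stats::cutree(hc, k)
  qualified$cluster <- cl
  qualified$rank_score <- score
  ord <- order(score)
  settings <- qualified[ord, ]
  Dm <- as.matrix(D)
  medoids <- do.call(rbind, lapply(split(seq_len(nrow(X)), cl), function(idx) {
    med <- idx[which.min(colSums(Dm[idx, idx, drop = FALSE]))]
    qualified[med, ]
  }))
  list(settings = settings, medoids = medoids,
       top2 = settings[seq_len(min(2, nrow(settings))), ], k = k)
}

# mean silhouette width of a flat clustering, from a distance matrix
mean_silhouette <- function(cl, Dm) {
  n <- length(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]
    a <- if (sum(own) > 1) mean(Dm[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(g) mean(Dm[i, cl == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}
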