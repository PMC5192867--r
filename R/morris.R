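# Morris elementary-effects screening.
#
# One-at-a-time trajectories on a p-level grid over the unit cube: each
# trajectory starts at a random grid point and moves each factor exactly
# once by +/- delta (random order, random feasible direction).  Elementary
# effects are finite differences in unit-cube coordinates, so factors with
# different physical units are directly comparable; mu ranks importance,
# mu* (mean absolute effect) is robust to sign cancellation, and sigma
# flags interactions / nonlinearity.

#' Morris grid step
#'
#' The recommended step for a `p`-level grid: `p/(2(p-1))` (requires even
#' `p`), or the alternative `1/(p-1)`, which can detect nonmonotonic
#' responses the standard step may miss.
#'
#' @param p Number of grid levels (>= 2; even for the standard mode).
#' @param mode `"standard"`, `"alternative"`, or `"auto"` (standard when `p`
#'   is even, alternative otherwise).
#' @return The unit-cube step delta.
#' @export
morris_delta <- function(p, mode = c("auto", "standard", "alternative")) {
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (p %% 2 == 0) "standard" else "alternative"
  p <- as.integer(p)
  if (p < 2L) abort_ibmsens("invalid_levels", "p must be >= 2")
  if (mode == "standard") {
    if (p %% 2L != 0L)
      abort_ibmsens("invalid_levels", "standard delta requires an even number of levels p")
    p / (2 * (p - 1))
  } else 1 / (p - 1)
}

#' Morris trajectory design
#'
#' Generates `r` randomized-orientation trajectories of `k + 1` points each:
#' a random base point on the level grid, then one +/-delta move per factor
#' in random order, the direction drawn uniformly among those that keep the
#' point inside `[0, 1]`.  All coordinates stay on the grid
#' `{0, 1/(p-1), ..., 1}`.
#'
#' @param table A non-empty `factor_table`.
#' @param p Grid levels per factor.
#' @param r Number of trajectories (>= 2).
#' @param delta_mode Passed to [morris_delta()].
#' @return A `morris_plan`: `design` (`r (k + 1)` rows, trajectory-major),
#'   `steps` (per transition: trajectory, step, factor index, direction),
#'   plus `k`, `p`, `r`, `delta`.
#' @export
morris_design <- function(table, p = 5, r = 10, delta_mode = "auto") {
  check_nonempty(table)
  stopifnot(r >= 2)
  k <- nrow(table)
  delta <- morris_delta(p, delta_mode)
  # delta spans an integer number of grid cells, so every transition is
  # between two grid points x and x + delta with x on the feasible sub-grid
  m <- as.integer(round(delta * (p - 1)))
  n_feas <- p - m  # base levels with x + delta <= 1
  stopifnot(n_feas >= 1L)

  pts <- vector("list", r)
  steps <- vector("list", r)
  for (t in seq_len(r)) {
    # per factor: the transition pair {lo, lo + delta}, lo uniform on the
    # feasible sub-grid; direction decides which end the walk starts from
    lo <- (sample.int(n_feas, k, replace = TRUE) - 1L) / (p - 1)
    dirs_k <- sample(c(-1L, 1L), k, replace = TRUE)
    x <- ifelse(dirs_k > 0, lo, lo + delta)
    order_k <- sample.int(k)
    traj <- matrix(0, k + 1, k)
    traj[1, ] <- x
    dirs <- integer(k)
    for (s in seq_len(k)) {
      i <- order_k[s]
      x[i] <- x[i] + dirs_k[i] * delta
      dirs[s] <- dirs_k[i]
      traj[s + 1, ] <- x
    }
    pts[[t]] <- traj
    steps[[t]] <- data.frame(trajectory = t, step = seq_len(k),
                             factor = order_k, direction = dirs)
  }
  structure(list(k = k, p = as.integer(p), r = as.integer(r), delta = delta,
                 trajectories = pts,
                 steps = do.call(rbind, steps),
                 design = new_design_matrix(do.call(rbind, pts), table)),
            class = "morris_plan")
}

#' Elementary effects from evaluated design points
#'
#' For each within-trajectory transition where factor `i` moved, computes
#' `ee_i = (y(upper) - y(lower)) / delta` with "upper" the point whose i-th
#' unit-cube coordinate is larger, so the estimate does not depend on the
#' walk direction.
#'
#' @param plan A `morris_plan`.
#' @param outputs Per-design-point scalars: a numeric vector, or a matrix /
#'   data frame with one row per design row and one column per output.
#' @return An `elementary_effects` object: a named list (one `r x k` matrix
#'   of signed effects per output) with the plan attached.
#' @export
elementary_effects <- function(plan, outputs) {
  stopifnot(inherits(plan, "morris_plan"))
  if (is.null(dim(outputs))) outputs <- matrix(outputs, ncol = 1,
                                               dimnames = list(NULL, "y"))
  outputs <- as.matrix(outputs)
  n_expected <- plan$r * (plan$k + 1)
  if (nrow(outputs) != n_expected)
    abort_ibmsens("shape_error",
                  sprintf("expected %d output rows (r(k+1)), got %d",
                          n_expected, nrow(outputs)))
  ee <- lapply(seq_len(ncol(outputs)), function(col) {
    y <- outputs[, col]
    m <- matrix(NA_real_, plan$r, plan$k)
    for (t in seq_len(plan$r)) {
      base_row <- (t - 1L) * (plan$k + 1L)
      st <- plan$steps[plan$steps$trajectory == t, ]
      for (s in seq_len(plan$k)) {
        lo_row <- base_row + s
        hi_row <- base_row + s + 1L
        i <- st$factor[s]
        dy <- y[hi_row] - y[lo_row]
        # orient so the numerator is y at the larger i-th coordinate
        if (st$direction[s] < 0) dy <- -dy
        m[t, i] <- dy / plan$delta
      }
    }
    colnames(m) <- plan$design$factor_names
    m
  })
  names(ee) <- colnames(outputs)
  structure(ee, class = "elementary_effects", plan = plan)
}

#' Morris screening metrics
#'
#' Per factor and output: `mu` (mean signed effect), `mu_star` (mean
#' absolute effect) and `sigma` (dispersion of effects, population form
#' with divisor `r`; set `sigma_divisor = "r-1"` for the sample form used by
#' some other toolkits).  A low `|mu|` with high `mu_star` signals
#' nonmonotone response; high `sigma` signals interaction or nonlinearity.
#'
#' @param ee An `elementary_effects` object.
#' @param sigma_divisor `"r"` (default) or `"r-1"`.
#' @return A `morris_indices` data frame: `output`, `factor`, `mu`,
#'   `mu_star`, `sigma`.
#' @export
morris_metrics <- function(ee, sigma_divisor = c("r", "r-1")) {
  sigma_divisor <- match.arg(sigma_divisor)
  stopifnot(inherits(ee, "elementary_effects"))
  rows <- lapply(names(ee), function(out) {
    m <- ee[[out]]
    r <- nrow(m)
    div <- if (sigma_divisor == "r") r else r - 1
    mu <- colMeans(m)
    data.frame(output = out, factor = colnames(m),
               mu = mu,
               mu_star = colMeans(abs(m)),
               sigma = sqrt(colSums((m - rep(mu, each = r))^2) / div),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("morris_indices", "data.frame")
  out
}

#' One-call Morris screening of a model
#'
#' Pipeline: trajectory design -> parameter sets -> seeded experiment ->
#' per-design-point mean over replications -> elementary effects -> metrics.
#' For stochastic models the replicate mean is the response entering the
#' finite differences, which targets the expected output and damps
#' elementary-effect noise.
#'
#' @inheritParams morris_design
#' @param model An `sa_model`.
#' @param ticks,replications,master_seed Passed to [run_spec()].
#' @param objective Objective function (see [run_experiment()]).
#' @return List with `plan`, `experiment`, `effects` and the tidy `indices`
#'   table.
#' @export
easy_morris <- function(model, table, p = 5, r = 10, ticks = 300,
                        replications = 1, objective = objective_output_means(),
                        master_seed = 1, delta_mode = "auto") {
  set.seed(master_seed)
  plan <- morris_design(table, p = p, r = r, delta_mode = delta_mode)
  spec <- run_spec(ticks = ticks, replications = replications,
                   master_seed = master_seed)
  exp <- run_experiment(model, plan$design, spec, objective)
  agg <- aggregate_output(exp, "mean")
  ee <- elementary_effects(plan, agg[setdiff(names(agg), "run")])
  list(plan = plan, experiment = exp, effects = ee,
       indices = morris_metrics(ee))
}
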