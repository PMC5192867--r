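# Objective-function building blocks and sampling-based calibration.
#
# Calibration compares model outputs against reference values through a cost
# (objective) function whose return is inversely proportional to the quality
# of fit, zero meaning a perfect fit.  The search is pure sampling: evaluate
# the cost over a Latin-hypercube design and rank.

#' Acceptance interval for an output
#' @param lower,upper Interval bounds, `lower <= upper`.
#' @return An `acceptance_range`.
#' @export
acceptance_range <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper), lower <= upper)
  structure(list(lower = lower, upper = upper), class = "acceptance_range")
}

#' Categorical calibration cost
#'
#' The indicator-style criterion: 0 when the simulated value falls inside
#' the inclusive acceptance interval (perfect fit), 1 otherwise.  The
#' classic worked case is a net reproductive rate with acceptance interval
#' `[0.8, 1.2]`: `categorical_cost(1.0, ...)` is 0, `categorical_cost(1.3,
#' ...)` is 1.
#'
#' @param y Simulated value(s); vectorised.
#' @param range An `acceptance_range` (or a length-2 numeric).
#' @return 0/1 per value of `y`.
#' @export
categorical_cost <- function(y, range) {
  if (is.numeric(range) && length(range) == 2)
    range <- acceptance_range(range[1], range[2])
  stopifnot(inherits(range, "acceptance_range"))
  as.numeric(!(y >= range$lower & y <= range$upper))
}

#' Normalized root-mean-square deviation
#'
#' RMSE between simulated and reference series divided by the reference
#' range `max(reference) - min(reference)`; the range normalizer (rather
#' than the mean) stays well defined when the reference crosses zero.
#'
#' @param simulated,reference Equal-length numeric series.
#' @return NRMSD (>= 0; 0 iff the series are identical).
#' @export
nrmsd <- function(simulated, reference) {
  if (length(simulated) != length(reference))
    abort_ibmsens("shape_error", "simulated and reference lengths differ")
  rng <- max(reference) - min(reference)
  if (rng == 0)
    abort_ibmsens("degenerate_reference", "reference series is constant; NRMSD undefined")
  sqrt(mean((simulated - reference)^2)) / rng
}

#' Distance-based calibration cost
#'
#' Any of the supported metrics satisfies the distance axioms required of a
#' calibration criterion: zero iff simulated equals reference, positive
#' otherwise.
#'
#' @inheritParams nrmsd
#' @param metric `"nrmsd"`, `"rmse"` or `"sse"`.
#' @return Non-negative scalar cost.
#' @export
distance_cost <- function(simulated, reference, metric = c("nrmsd", "rmse", "sse")) {
  metric <- match.arg(metric)
  if (length(simulated) != length(reference))
    abort_ibmsens("shape_error", "simulated and reference lengths differ")
  switch(metric,
         nrmsd = nrmsd(simulated, reference),
         rmse = sqrt(mean((simulated - reference)^2)),
         sse = sum((simulated - reference)^2))
}

#' Sampling-based calibration
#'
#' Evaluates a user cost objective over a Latin-hypercube design
#' (`n_samples` points, `replications` seeded runs each), averages the cost
#' per design point, and ranks ascending.  Multiple cost scalars are
#' combined by their unweighted sum for ranking (per-scalar costs are kept
#' in the table); ties keep design order.
#'
#' @param model An `sa_model`.
#' @param table A non-empty `factor_table`.
#' @param n_samples Number of sampled parameter sets.
#' @param replications,ticks,master_seed Passed to [run_spec()].
#' @param objective Cost objective: `function(params, series)` returning one
#'   or more named non-negative scalars, 0 = perfect fit, lower = better.
#' @return A `calibration_result`: `ranked` (parameter values, per-scalar
#'   mean costs, `cost` total, ascending), `best` (first row's parameter
#'   list) and the `experiment`.
#' @export
easy_calibration <- function(model, table, n_samples, replications = 1,
                             ticks = 300, objective, master_seed = 1) {
  check_nonempty(table)
  stopifnot(n_samples >= 1)
  set.seed(master_seed)
  design <- sample_latin_hypercube(n_samples, table)
  spec <- run_spec(ticks = ticks, replications = replications,
                   master_seed = master_seed)
  exp <- run_experiment(model, design, spec, objective)
  agg <- aggregate_output(exp, "mean")
  cost_cols <- setdiff(names(agg), "run")
  total <- rowSums(agg[cost_cols, drop = FALSE])
  ranked <- cbind(exp$paramset[match(agg$run, exp$paramset$run), , drop = FALSE],
                  agg[cost_cols, drop = FALSE], cost = total)
  ord <- order(total, agg$run)  # stable: ties broken by design order
  ranked <- ranked[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  best_run <- ranked$run[1]
  best <- build_parameter_set(design, model$parameters)[[best_run]]
  structure(list(ranked = ranked, best = best, best_cost = ranked$cost[1],
                 experiment = exp),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration over %d sampled parameter sets; best cost %.6g\n",
              nrow(x$ranked), x$best_cost))
  print(utils::head(x$ranked, 5))
  invisible(x)
}
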