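# Model contract, seeded replication, and the experiment result triple.
#
# A model is a closure factory: setup(params) builds a fresh instance whose
# run(ticks) advances the simulation and returns a tick-indexed data frame of
# named numeric outputs.  All stochasticity must come from R's RNG: the
# engine calls set.seed() with a per-replication seed immediately before
# setup(), which makes every run exactly reproducible.

#' Define a simulation model
#'
#' @param name Registered model name.
#' @param parameters Named list of every declared parameter with its default.
#'   Integer-typed defaults mark parameters that are rounded when swept.
#' @param setup `function(params)` returning an instance: a list with at
#'   least `run(ticks)`, which advances `ticks` steps and returns a data
#'   frame with a `tick` column (strictly increasing, starting at 1 on the
#'   first call) and one numeric column per output.  Instances may expose a
#'   `state()` element for introspection; the engine only uses `run`.
#' @param factors Optional canonical `factor_table` of sweep ranges (used by
#'   the command-line interface when a config declares no factors).
#' @return An object of class `sa_model`.
#' @export
sa_model <- function(name, parameters, setup, factors = NULL) {
  stopifnot(is.character(name), is.list(parameters), is.function(setup))
  structure(list(name = name, parameters = parameters, setup = setup,
                 factors = factors),
            class = "sa_model")
}

#' @export
print.sa_model <- function(x, ...) {
  cat(sprintf("sa_model '%s' with %d parameters\n", x$name, length(x$parameters)))
  invisible(x)
}

#' Declared parameters of a model
#' @param model An `sa_model`.
#' @return Named list of defaults (a copy; the declaration is immutable).
#' @export
model_parameters <- function(model) model$parameters

#' Replication settings
#'
#' @param ticks Simulated time steps per run (default 300).
#' @param replications Number of repetitions per design point.
#' @param master_seed Integer seed from which per-replication seeds derive.
#' @param seeds Optional explicit distinct seeds, one per replication,
#'   overriding the derivation.
#' @return A `run_spec` list.
#' @export
run_spec <- function(ticks = 300, replications = 1, master_seed = 1, seeds = NULL) {
  stopifnot(ticks >= 1, replications >= 1)
  if (!is.null(seeds)) {
    if (length(seeds) != replications || anyDuplicated(seeds))
      abort_ibmsens("invalid_seeds",
                    "seeds must contain exactly `replications` distinct values")
  }
  structure(list(ticks = as.integer(ticks),
                 replications = as.integer(replications),
                 master_seed = as.integer(master_seed),
                 seeds = seeds),
            class = "run_spec")
}

#' Derive per-run seeds from a master seed
#'
#' Deterministic and stable across releases: each seed is a 3-round bijective
#' 31-bit linear-congruential mix of `(master_seed, counter)`.  Because every
#' round is a bijection modulo 2^31 and counters are distinct, the derived
#' seeds are guaranteed distinct for a given master seed.
#'
#' @param master_seed Integer.
#' @param n Number of seeds (>= 1).
#' @return Numeric vector of `n` distinct values in `[0, 2^31)`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(n >= 1)
  m <- 2^31
  mix <- function(x) {
    for (i in 1:3) x <- (69069 * x + 1234567) %% m
    x
  }
  base <- mix(abs(as.numeric(master_seed)) %% m)
  mix((base + seq_len(n) - 1) %% m)
}

validate_series <- function(series, context) {
  if (!is.data.frame(series) || !"tick" %in% names(series))
    abort_ibmsens("model_execution_error",
                  sprintf("%s: model must return a data frame with a 'tick' column", context))
  if (nrow(series) > 1 && any(diff(series$tick) <= 0))
    abort_ibmsens("model_execution_error",
                  sprintf("%s: ticks must be strictly increasing", context))
  series
}

#' Run seeded replications of one parameter set
#'
#' Replication `i` runs under `seeds[i]` (derived from the master seed when
#' not given explicitly), so the returned list is identical on every call
#' with the same arguments.
#'
#' @param model An `sa_model`.
#' @param params Complete named parameter list for the model.
#' @param spec A `run_spec`.
#' @return List of tick-indexed output data frames, one per replication.
#' @export
run_replicates <- function(model, params, spec) {
  stopifnot(inherits(model, "sa_model"), inherits(spec, "run_spec"))
  seeds <- if (is.null(spec$seeds)) derive_seeds(spec$master_seed, spec$replications)
           else spec$seeds
  lapply(seq_len(spec$replications), function(i) {
    run_one(model, params, seeds[i], spec$ticks,
            context = sprintf("replication %d (seed %.0f)", i, seeds[i]))
  })
}

run_one <- function(model, params, seed, ticks, context = "run") {
  set.seed(seed)
  inst <- tryCatch(model$setup(params), error = function(e)
    abort_ibmsens("model_execution_error",
                  sprintf("%s: setup failed: %s", context, conditionMessage(e))))
  series <- tryCatch(inst$run(ticks), error = function(e)
    abort_ibmsens("model_execution_error",
                  sprintf("%s: run failed: %s", context, conditionMessage(e))))
  validate_series(series, context)
}

#' Execute a full experimental design
#'
#' Runs every design point for `spec$replications` seeded repetitions
#' (design-major, replication-minor order) and evaluates the objective
#' function once per run.  Returns the result triple: `paramset` (one row
#' per design point), `output` (one row per design point x replication with
#' the objective's named scalars), and `dataset` (all tick-level series
#' concatenated, tagged with run and replication ids).
#'
#' @param model An `sa_model`.
#' @param design A `design_matrix` over (a subset of) the model's parameters.
#' @param spec A `run_spec`.
#' @param objective `function(params, series)` returning a named numeric
#'   vector of one or more scalars; must return the same names on every call.
#'   Defaults to the per-column time average of all model outputs.
#' @return An `experiment_result` list with elements `paramset`, `output`,
#'   `dataset` and the `design`.
#' @export
run_experiment <- function(model, design, spec, objective = objective_output_means()) {
  stopifnot(inherits(model, "sa_model"), inherits(design, "design_matrix"),
            inherits(spec, "run_spec"))
  psets <- build_parameter_set(design, model$parameters)
  npts <- length(psets)
  seeds <- matrix(derive_seeds(spec$master_seed, max(1L, npts * spec$replications)),
                  nrow = max(1L, npts), byrow = TRUE)

  paramset <- data.frame(run = seq_len(npts))
  for (j in seq_along(design$factor_names)) {
    nm <- design$factor_names[j]
    paramset[[nm]] <- vapply(psets, function(p) as.numeric(p[[nm]]), numeric(1))
  }

  obj_names <- NULL
  out_rows <- vector("list", npts * spec$replications)
  data_rows <- vector("list", npts * spec$replications)
  idx <- 0L
  for (i in seq_len(npts)) {
    for (rrep in seq_len(spec$replications)) {
      idx <- idx + 1L
      sd_i <- seeds[i, rrep]
      series <- run_one(model, psets[[i]], sd_i, spec$ticks,
                        context = sprintf("run %d rep %d", i, rrep))
      vals <- objective(psets[[i]], series)
      if (is.null(names(vals)) || any(!nzchar(names(vals))) || !is.numeric(vals))
        abort_ibmsens("objective_contract_error",
                      "objective must return a named numeric vector")
      if (is.null(obj_names)) obj_names <- names(vals)
      else if (!identical(names(vals), obj_names))
        abort_ibmsens("objective_contract_error",
                      sprintf("objective returned names (%s) != first call (%s)",
                              paste(names(vals), collapse = ","),
                              paste(obj_names, collapse = ",")))
      out_rows[[idx]] <- data.frame(run = i, replication = rrep, seed = sd_i,
                                    t(vals))
      data_rows[[idx]] <- cbind(data.frame(run = i, replication = rrep), series)
    }
  }
  structure(list(paramset = paramset,
                 output = do.call(rbind, out_rows),
                 dataset = do.call(rbind, data_rows),
                 design = design,
                 spec = spec),
            class = "experiment_result")
}

#' Default objective: time-average of every model output
#'
#' @return An objective function returning the mean of each non-`tick`
#'   column of the run's series (the "average population sizes" objective
#'   used by the worked screening examples).
#' @export
objective_output_means <- function() {
  function(params, series) {
    cols <- setdiff(names(series), "tick")
    vapply(cols, function(cl) mean(series[[cl]]), numeric(1))
  }
}

#' Summarise replications per design point
#'
#' @param result An `experiment_result`.
#' @param statistic `"mean"` or `"median"`, applied to each objective scalar
#'   over the replications of each design point.
#' @return Data frame with one row per design point (`run` plus one column
#'   per objective scalar).
#' @export
aggregate_output <- function(result, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  fun <- if (statistic == "mean") mean else stats::median
  out <- result$output
  cols <- setdiff(names(out), c("run", "replication", "seed"))
  agg <- stats::aggregate(out[cols], by = list(run = out$run), FUN = fun)
  agg[order(agg$run), , drop = FALSE]
}

#' Write the experiment result triple to CSV
#'
#' Creates `prefix_paramset.csv`, `prefix_output.csv` and
#' `prefix_dataset.csv` (RFC-4180, '.' decimal separator).
#' @param result An `experiment_result`.
#' @param prefix Path prefix.
#' @export
save_experiment <- function(result, prefix) {
  utils::write.csv(result$paramset, paste0(prefix, "_paramset.csv"), row.names = FALSE)
  utils::write.csv(result$output, paste0(prefix, "_output.csv"), row.names = FALSE)
  utils::write.csv(result$dataset, paste0(prefix, "_dataset.csv"), row.names = FALSE)
  invisible(prefix)
}
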