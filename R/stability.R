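# Replication-count determination by coefficient-of-variation convergence.
#
# For a stochastic model the output variance must be estimated from repeated
# runs; the CV of each monitored output is tracked as the replication count
# grows, and the smallest count at which the CV stops changing (within a
# tolerance, for a sustained window) is the recommended number of
# replications.  Replications are simulated once per parameter set and
# checkpoint CVs reuse prefixes of the same seed sequence, so the curve at
# n depends only on the first n runs.

#' Coefficient of variation
#'
#' Sample standard deviation (divisor `n - 1`) over the absolute mean.
#'
#' @param samples Numeric vector, length >= 2, with nonzero mean.
#' @return CV (>= 0).
#' @export
coefficient_of_variation <- function(samples) {
  if (length(samples) < 2)
    abort_ibmsens("insufficient_samples", "CV needs at least 2 samples")
  m <- mean(samples)
  if (m == 0) abort_ibmsens("undefined_cv", "CV undefined: mean is zero")
  stats::sd(samples) / abs(m)
}

#' CV-versus-replications curves
#'
#' Samples `s` parameter sets by Latin hypercube over `table`, runs `r_max`
#' seeded replications of each once, and computes the CV of every monitored
#' output over the first `n` replications for each checkpoint `n`.
#' Monitored outputs are the objective's scalars, or the per-replication
#' time average of every raw output column when no objective is given.
#'
#' @param model An `sa_model`.
#' @param table A non-empty `factor_table`.
#' @param s Number of Latin-hypercube parameter sets (>= 1).
#' @param r_max Replications simulated per parameter set.
#' @param checkpoints Increasing integers in `[2, r_max]` at which the CV is
#'   evaluated (default `{5, 10, ..., r_max}`).
#' @param ticks Simulated time steps per run.
#' @param objective Optional objective function; `NULL` monitors all raw
#'   outputs via their time averages.
#' @param master_seed Integer seed.
#' @return A `stability_curve` data frame: `set`, `output`, `n`, `cv` (`NA`
#'   when the output's mean over the first `n` replications is zero), with
#'   the underlying per-replication scalars in `attr(, "replicates")`.
#' @export
stability_curves <- function(model, table, s, r_max, checkpoints = NULL,
                             ticks = 300, objective = NULL, master_seed = 1) {
  check_nonempty(table)
  stopifnot(s >= 1, r_max >= 2)
  if (is.null(checkpoints)) checkpoints <- seq(5, r_max, by = 5)
  checkpoints <- sort(unique(as.integer(checkpoints)))
  stopifnot(all(checkpoints >= 2), all(checkpoints <= r_max))
  if (is.null(objective)) objective <- objective_output_means()

  set.seed(master_seed)
  design <- sample_latin_hypercube(s, table)
  psets <- build_parameter_set(design, model$parameters)
  rows <- list()
  reps_store <- list()
  for (j in seq_len(s)) {
    spec <- run_spec(ticks = ticks, replications = r_max,
                     master_seed = master_seed + j)
    series_list <- run_replicates(model, psets[[j]], spec)
    scalars <- do.call(rbind, lapply(series_list, function(sr)
      objective(psets[[j]], sr)))
    reps_store[[j]] <- scalars
    for (out in colnames(scalars)) {
      # zero-mean prefixes (e.g. an output that never fires under this
      # parameter set) have no defined CV and are recorded as NA
      cv <- vapply(checkpoints, function(n) {
        x <- scalars[seq_len(n), out]
        if (mean(x) == 0) NA_real_ else coefficient_of_variation(x)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(set = j, output = out,
                                              n = checkpoints, cv = cv)
    }
  }
  curve <- do.call(rbind, rows)
  attr(curve, "replicates") <- reps_store
  attr(curve, "design") <- design
  class(curve) <- c("stability_curve", "data.frame")
  curve
}

#' Detect CV convergence
#'
#' Per (parameter set, output): the recommended replication count `n_star`
#' is the smallest checkpoint that begins a run of `window` consecutive
#' transitions whose successive CV changes are all within `tol`; a group
#' with no such run is reported as not converged.
#'
#' @param curve A `stability_curve`.
#' @param tol Absolute tolerance on successive CV changes (default 0.01).
#' @param window Number of consecutive small transitions required (>= 2
#'   checkpoints involved; default 2).
#' @return A `convergence_report` data frame: `set`, `output`, `converged`,
#'   `n_star` (`NA` when not converged).
#' @export
detect_convergence <- function(curve, tol = 0.01, window = 2) {
  stopifnot(inherits(curve, "stability_curve"), window >= 1)
  groups <- split(seq_len(nrow(curve)),
                  list(curve$set, curve$output), drop = TRUE)
  rows <- lapply(groups, function(ix) {
    g <- curve[ix, ]
    g <- g[order(g$n), ]
    d <- diff(g$cv)                          # transition into checkpoint j+1
    small <- !is.na(d) & abs(d) <= tol
    n_star <- NA_integer_
    # runs of `window` consecutive small transitions; run starting at
    # transition t covers checkpoints t .. t+window, n_star = checkpoint t+1's
    # predecessor start, i.e. the checkpoint the stable stretch begins at
    if (length(small) >= window) {
      for (t in seq_len(length(small) - window + 1L)) {
        if (all(small[t:(t + window - 1L)])) { n_star <- g$n[t + 1L]; break }
      }
    }
    data.frame(set = g$set[1], output = g$output[1],
               converged = !is.na(n_star), n_star = n_star)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("convergence_report", "data.frame")
  out
}

#' One-call stability analysis
#'
#' Composes Latin-hypercube parameter sampling, seeded replication,
#' [stability_curves()] and [detect_convergence()]; the curve table gives
#' CV versus replication count per output, the report the recommended
#' minimum replication count.
#'
#' @inheritParams stability_curves
#' @param tol,window Passed to [detect_convergence()].
#' @return List with `curve`, `report` and the sampled `design`.
#' @export
easy_stability <- function(model, table, s, r_max = 100, ticks = 300,
                           objective = NULL, master_seed = 1,
                           checkpoints = NULL, tol = 0.01, window = 2) {
  curve <- stability_curves(model, table, s, r_max, checkpoints = checkpoints,
                            ticks = ticks, objective = objective,
                            master_seed = master_seed)
  list(curve = curve,
       report = detect_convergence(curve, tol = tol, window = window),
       design = attr(curve, "design"))
}
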