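# Sobol variance-decomposition sensitivity analysis.
#
# A/B/AB_i sampling plan with the Saltelli (2010) first-order estimator and
# the Jansen total-order estimator: Si = Vi / V(Y) is the fraction of output
# variance attributable to factor i alone, STi the fraction involving it in
# any combination; STi - Si measures interactions.  At small base sample
# sizes estimates can come out slightly negative; they are reported as-is
# because that is a useful small-sample diagnostic, not clamped.

#' Sobol sampling plan
#'
#' Two independent `N x k` unit-cube matrices `A` and `B` plus the hybrid
#' matrices `AB_i` (`A` with column `i` taken from `B`), stacked in
#' evaluation order `A, B, AB_1, ..., AB_k` — `N (k + 2)` model evaluations.
#'
#' @param table A non-empty `factor_table`.
#' @param N Base sample size (>= 2).
#' @param sampler `"random"` (i.i.d. uniform, default) or `"lhs"`.
#' @return A `sobol_plan` with `A`, `B`, `AB` (list), `N`, `k` and the
#'   stacked `design`.
#' @export
sobol_design <- function(table, N, sampler = c("random", "lhs")) {
  check_nonempty(table)
  sampler <- match.arg(sampler)
  if (N < 2) abort_ibmsens("invalid_sample_size", "N must be >= 2")
  N <- as.integer(N)
  k <- nrow(table)
  draw <- function() if (sampler == "random") matrix(stats::runif(N * k), N, k)
                     else lhs::randomLHS(N, k)
  A <- draw(); B <- draw()
  AB <- lapply(seq_len(k), function(i) { M <- A; M[, i] <- B[, i]; M })
  unit <- do.call(rbind, c(list(A, B), AB))
  structure(list(N = N, k = k, A = A, B = B, AB = AB,
                 design = new_design_matrix(unit, table)),
            class = "sobol_plan")
}

#' First- and total-order Sobol indices
#'
#' With `fA`, `fB`, `fABi` the output blocks of the plan:
#' total variance `V(Y)` is the sample variance of the pooled `fA, fB`
#' (divisor `2N - 1`); `Vi = mean(fB * (fABi - fA))` (Saltelli 2010);
#' the total-order numerator is `mean((fA - fABi)^2) / 2` (Jansen).
#' Optional bootstrap confidence intervals resample the `N` rows of
#' `A`/`B`/`AB` jointly.
#'
#' @param plan A `sobol_plan`.
#' @param outputs Per-design-point scalars (vector, matrix or data frame with
#'   `N (k + 2)` rows).
#' @param n_boot Bootstrap resamples for confidence intervals (0 = none).
#' @param conf Confidence level for the bootstrap percentile intervals.
#' @return A `sobol_indices` data frame: `output`, `factor`, `S`, `ST`
#'   (plus CI bounds when `n_boot > 0`), with total variances in
#'   `attr(, "VY")` and `N` attached.
#' @export
sobol_indices <- function(plan, outputs, n_boot = 0, conf = 0.95) {
  stopifnot(inherits(plan, "sobol_plan"))
  if (is.null(dim(outputs))) outputs <- matrix(outputs, ncol = 1,
                                               dimnames = list(NULL, "y"))
  outputs <- as.matrix(outputs)
  N <- plan$N; k <- plan$k
  if (nrow(outputs) != N * (k + 2))
    abort_ibmsens("shape_error",
                  sprintf("expected %d output rows (N(k+2)), got %d",
                          N * (k + 2), nrow(outputs)))
  est <- function(fA, fB, fABmat) {
    VY <- stats::var(c(fA, fB))
    # centring by the pooled mean leaves the estimator unbiased and sharply
    # reduces its Monte Carlo variance when E[Y] is far from 0
    ctr <- mean(c(fA, fB))
    fA <- fA - ctr; fB <- fB - ctr; fABmat <- fABmat - ctr
    Si <- vapply(seq_len(k), function(i) mean(fB * (fABmat[, i] - fA)) / VY,
                 numeric(1))
    STi <- vapply(seq_len(k), function(i) mean((fA - fABmat[, i])^2) / (2 * VY),
                  numeric(1))
    list(S = Si, ST = STi, VY = VY)
  }
  VYs <- numeric(0)
  rows <- lapply(colnames(outputs), function(out) {
    y <- outputs[, out]
    fA <- y[seq_len(N)]
    fB <- y[N + seq_len(N)]
    fABmat <- vapply(seq_len(k), function(i) y[(i + 1) * N + seq_len(N)],
                     numeric(N))
    if (stats::var(c(fA, fB)) == 0)
      abort_ibmsens("degenerate_variance",
                    sprintf("output '%s' is constant over the design; Sobol indices are undefined", out))
    e <- est(fA, fB, fABmat)
    VYs[out] <<- e$VY
    res <- data.frame(output = out, factor = plan$design$factor_names,
                      S = e$S, ST = e$ST, row.names = NULL)
    if (n_boot > 0) {
      bs <- replicate(n_boot, {
        j <- sample.int(N, N, replace = TRUE)
        eb <- est(fA[j], fB[j], fABmat[j, , drop = FALSE])
        c(eb$S, eb$ST)
      })
      a <- (1 - conf) / 2
      qs <- apply(bs, 1, stats::quantile, probs = c(a, 1 - a), names = FALSE)
      res$S_lo <- qs[1, seq_len(k)];      res$S_hi <- qs[2, seq_len(k)]
      res$ST_lo <- qs[1, k + seq_len(k)]; res$ST_hi <- qs[2, k + seq_len(k)]
    }
    if (any(e$S < 0) || any(e$ST < 0))
      warning(sprintf("output '%s': negative Sobol index estimate(s); increase N (small-sample Monte Carlo noise)", out),
              call. = FALSE)
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "VY") <- VYs
  attr(out, "N") <- N
  class(out) <- c("sobol_indices", "data.frame")
  out
}

#' One-call Sobol analysis of a model
#'
#' Pipeline: A/B/AB sampling plan -> parameter sets -> seeded experiment ->
#' per-design-point mean over replications -> index estimation.
#'
#' @inheritParams sobol_design
#' @param model An `sa_model`.
#' @param ticks,replications,master_seed Passed to [run_spec()].
#' @param objective Objective function (see [run_experiment()]).
#' @param n_boot Bootstrap resamples for confidence intervals (0 = none).
#' @return List with `plan`, `experiment` and the tidy `indices` table.
#' @export
easy_sobol <- function(model, table, N, ticks = 300, replications = 1,
                       objective = objective_output_means(), master_seed = 1,
                       sampler = "random", n_boot = 0) {
  set.seed(master_seed)
  plan <- sobol_design(table, N, sampler = sampler)
  spec <- run_spec(ticks = ticks, replications = replications,
                   master_seed = master_seed)
  exp <- run_experiment(model, plan$design, spec, objective)
  agg <- aggregate_output(exp, "mean")
  list(plan = plan, experiment = exp,
       indices = sobol_indices(plan, agg[setdiff(names(agg), "run")],
                               n_boot = n_boot))
}
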