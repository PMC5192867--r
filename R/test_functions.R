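# Analytic fixtures with known sensitivity structure.
#
# Each fixture satisfies the model contract (deterministic, side-effect
# free) and emits its value as a single-tick series with column "y", so the
# whole experiment pipeline can be exercised — and checked against closed
# forms — without a biological simulator in the loop.

analytic_model <- function(name, k, f, factors) {
  pars <- as.list(rep(0.5, k))
  names(pars) <- paste0("x", seq_len(k))
  sa_model(name, pars,
           setup = function(params) {
             x <- vapply(paste0("x", seq_len(k)), function(nm)
               as.numeric(params[[nm]]), numeric(1))
             list(run = function(ticks)
               data.frame(tick = 1L, y = f(x)))
           },
           factors = factors)
}

#' Linear test model
#'
#' `f(x) = sum(coeffs * x)` on the unit cube.  For uniform inputs the
#' first-order Sobol index of factor i is `coeffs[i]^2 / sum(coeffs^2)` and
#' all interactions vanish; every Morris elementary effect equals the
#' coefficient exactly.
#'
#' @param coeffs Numeric coefficients (length >= 1).
#' @return An `sa_model` named `fx_linear`.
#' @export
linear_model <- function(coeffs = c(3, 5)) {
  k <- length(coeffs)
  stopifnot(k >= 1)
  ft <- do.call(factor_table,
                stats::setNames(rep(list(c(0, 1)), k), paste0("x", seq_len(k))))
  analytic_model("fx_linear", k, function(x) sum(coeffs * x), ft)
}

#' Ishigami test model
#'
#' `f(x) = sin(x1) + a sin^2(x2) + b x3^4 sin(x1)` with all inputs uniform
#' on `[-pi, pi]` — the standard nonlinear, nonmonotone benchmark with a
#' pure x1–x3 interaction and an exactly zero first-order index for x3.
#'
#' @param a,b Shape constants (classic values 7 and 0.1).
#' @return An `sa_model` named `fx_ishigami` with canonical factor ranges
#'   `[-pi, pi]`.
#' @export
ishigami_model <- function(a = 7, b = 0.1) {
  ft <- factor_table(x1 = c(-pi, pi), x2 = c(-pi, pi), x3 = c(-pi, pi))
  analytic_model("fx_ishigami", 3,
                 function(x) sin(x[1]) + a * sin(x[2])^2 + b * x[3]^4 * sin(x[1]),
                 ft)
}

#' Closed-form Ishigami sensitivity indices
#'
#' The exact variance decomposition of the Ishigami function for uniform
#' inputs on `[-pi, pi]`:
#' `V(Y) = a^2/8 + b pi^4/5 + b^2 pi^8/18 + 1/2`,
#' `V1 = (1 + b pi^4/5)^2 / 2`, `V2 = a^2/8`, `V3 = 0`, and the only
#' interaction `V13 = b^2 pi^8 (1/18 - 1/50)`.
#'
#' @param a,b Shape constants.
#' @return Named list `S1, S2, S3, ST1, ST2, ST3, VY`.
#' @export
ishigami_analytic_indices <- function(a = 7, b = 0.1) {
  VY <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 1 / 2
  V1 <- (1 + b * pi^4 / 5)^2 / 2
  V2 <- a^2 / 8
  V13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  list(S1 = V1 / VY, S2 = V2 / VY, S3 = 0,
       ST1 = (V1 + V13) / VY, ST2 = V2 / VY, ST3 = V13 / VY,
       VY = VY)
}

#' Constant test model
#'
#' `f(x) = value` regardless of input — the degenerate-variance fixture.
#' @param value The constant (default 7).
#' @return An `sa_model` named `fx_constant`.
#' @export
constant_model <- function(value = 7) {
  ft <- factor_table(x1 = c(0, 1), x2 = c(0, 1))
  analytic_model("fx_constant", 2, function(x) value, ft)
}

#' Product (interaction) test model
#'
#' `f(x) = x1 * x2` on the unit cube: for uniform inputs
#' `V(Y) = 7/144`, `V1 = V2 = 1/48` and the interaction `V12 = 1/144`, so
#' both total-order indices exceed the first-order ones.
#'
#' @return An `sa_model` named `fx_product`.
#' @export
product_model <- function() {
  ft <- factor_table(x1 = c(0, 1), x2 = c(0, 1))
  analytic_model("fx_product", 2, function(x) x[1] * x[2], ft)
}

#' Closed-form indices of the product fixture
#' @return Named list `S1, S2, ST1, ST2, VY` for `f = x1 x2`, x uniform on
#'   the unit square.
#' @export
product_analytic_indices <- function() {
  VY <- 7 / 144
  V1 <- 1 / 48
  V12 <- 1 / 144
  list(S1 = V1 / VY, S2 = V1 / VY,
       ST1 = (V1 + V12) / VY, ST2 = (V1 + V12) / VY, VY = VY)
}
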