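# Factor declaration and experimental designs.
#
# A factor table declares the sweep space: an ordered set of named factors,
# each with an inclusive physical range [lower, upper].  Designs are carried
# both in physical units and as the unit-cube preimage, because the
# sensitivity-analysis machinery works on [0,1]^k so that factors with
# different physical units remain comparable.

#' Declare a factor to sweep
#'
#' Appends a named factor with an inclusive range `[lower, upper]` to a factor
#' table, creating the table when called without one.  Column order of every
#' design generated from the table follows the declaration order.
#'
#' @param table A `factor_table`, or `NULL` to start a new one.
#' @param name Factor name; must match a parameter declared by the target
#'   model and be unique within the table.
#' @param lower,upper Inclusive physical bounds; `lower < upper` is required
#'   (degenerate ranges belong in the fixed parameters, not the sweep).
#' @return A `factor_table` (a data frame with columns `name`, `lower`,
#'   `upper`); the input table is not modified.
#' @examples
#' ft <- add_factor(NULL, "sheepgainfromfood", 2, 8)
#' ft <- add_factor(ft, "grassregrowthtime", 10, 60)
#' @export
add_factor <- function(table = NULL, name, lower, upper) {
  if (is.null(table)) table <- empty_factor_table()
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L)
  if (name %in% table$name)
    abort_ibmsens("duplicate_factor", sprintf("factor '%s' already declared", name))
  if (!(lower < upper))
    abort_ibmsens("invalid_range",
                  sprintf("factor '%s': lower (%g) must be < upper (%g)", name, lower, upper))
  out <- rbind(table, data.frame(name = name, lower = as.numeric(lower),
                                 upper = as.numeric(upper),
                                 stringsAsFactors = FALSE))
  class(out) <- c("factor_table", "data.frame")
  out
}

empty_factor_table <- function() {
  out <- data.frame(name = character(), lower = numeric(), upper = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("factor_table", "data.frame")
  out
}

#' Build a factor table in one call
#'
#' @param ... Named numeric vectors of length two, e.g.
#'   `factor_table(a = c(0, 1), b = c(2, 8))`.
#' @return A `factor_table`.
#' @export
factor_table <- function(...) {
  specs <- list(...)
  ft <- empty_factor_table()
  for (nm in names(specs)) ft <- add_factor(ft, nm, specs[[nm]][1], specs[[nm]][2])
  ft
}

check_nonempty <- function(table) {
  if (!inherits(table, "factor_table"))
    stop("expected a factor_table (see add_factor())")
  if (nrow(table) == 0L)
    abort_ibmsens("empty_factor_table", "factor table has no factors")
}

# Affine map [0,1]^k -> physical space; the exact inverse relation
# rows = lower + unit * (upper - lower) is an invariant of every design.
new_design_matrix <- function(unit_rows, table) {
  k <- nrow(table)
  unit_rows <- matrix(as.numeric(unit_rows), ncol = k)
  lo <- matrix(table$lower, nrow(unit_rows), k, byrow = TRUE)
  hi <- matrix(table$upper, nrow(unit_rows), k, byrow = TRUE)
  rows <- lo + unit_rows * (hi - lo)
  colnames(rows) <- colnames(unit_rows) <- table$name
  structure(list(factor_names = table$name, rows = rows, unit_rows = unit_rows,
                 table = table),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d rows x %d factors (%s)\n",
              nrow(x$rows), length(x$factor_names),
              paste(x$factor_names, collapse = ", ")))
  invisible(x)
}

#' Simple random (Monte Carlo) design
#'
#' Draws `n` points i.i.d. uniform on the unit cube and maps them onto the
#' declared physical ranges.  Reproducible under `set.seed()`.
#'
#' @param n Number of design points.
#' @param table A non-empty `factor_table`.
#' @return A `design_matrix` with elements `rows` (physical units),
#'   `unit_rows` (the `[0,1]^k` preimage) and `factor_names`.
#' @export
sample_random <- function(n, table) {
  check_nonempty(table)
  stopifnot(n >= 1)
  new_design_matrix(matrix(stats::runif(n * nrow(table)), nrow = n), table)
}

#' Latin hypercube design
#'
#' Stratified design: per factor, exactly one point falls in each of the `n`
#' equal-probability strata, placed uniformly within its stratum, with an
#' independent random stratum-to-row permutation per factor
#' (via [lhs::randomLHS()]).
#'
#' @inheritParams sample_random
#' @return A `design_matrix`.
#' @export
sample_latin_hypercube <- function(n, table) {
  check_nonempty(table)
  stopifnot(n >= 1)
  new_design_matrix(lhs::randomLHS(n, nrow(table)), table)
}

#' Full factorial design
#'
#' The Cartesian product of per-factor grids; each grid is `levels[i]` evenly
#' spaced points including both range endpoints (declared ranges are
#' inclusive bounds).
#'
#' @param table A non-empty `factor_table`.
#' @param levels Integer (scalar, recycled, or one per factor), each >= 2.
#' @return A `design_matrix` with `prod(levels)` rows.
#' @export
design_full_factorial <- function(table, levels) {
  check_nonempty(table)
  k <- nrow(table)
  levels <- rep_len(as.integer(levels), k)
  if (any(levels < 2L))
    abort_ibmsens("invalid_levels", "each factor needs at least 2 levels")
  grids <- lapply(levels, function(l) seq(0, 1, length.out = l))
  unit <- as.matrix(rev(expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE)))
  dimnames(unit) <- NULL
  new_design_matrix(unit, table)
}

#' Merge a design with model defaults into full parameter sets
#'
#' Produces one complete parameter set per design row: swept parameters take
#' the row's value, everything else the model default.  Parameters whose
#' default is stored as an R integer are swept on the continuous scale and
#' rounded half-up here, so the emitted parameter table records the value the
#' model actually receives.
#'
#' @param design A `design_matrix`.
#' @param defaults Named list of the model's declared parameters.
#' @return A list of named parameter lists, one per design row.
#' @export
build_parameter_set <- function(design, defaults) {
  stopifnot(inherits(design, "design_matrix"), is.list(defaults))
  unknown <- setdiff(design$factor_names, names(defaults))
  if (length(unknown))
    abort_ibmsens("unknown_parameter",
                  sprintf("factor(s) not declared by the model: %s",
                          paste(unknown, collapse = ", ")))
  n <- nrow(design$rows)
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i) {
    ps <- defaults
    for (j in seq_along(design$factor_names)) {
      nm <- design$factor_names[j]
      v <- design$rows[i, j]
      if (is.integer(defaults[[nm]])) v <- floor(v + 0.5)  # round half-up
      ps[[nm]] <- v
    }
    ps
  })
}

#' Write a design to CSV
#'
#' Headered RFC-4180 CSV in physical units; set `unit = TRUE` for the
#' unit-cube image instead.
#' @param design A `design_matrix`.
#' @param path Output file path.
#' @param unit Write the `[0,1]^k` preimage instead of physical values.
#' @export
save_design <- function(design, path, unit = FALSE) {
  m <- if (unit) design$unit_rows else design$rows
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}
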