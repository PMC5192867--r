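test_that("sampling plan has the A/B/AB block structure", {
  set.seed(3)
  ft <- unit_table(4)
  plan <- sobol_design(ft, 100)
  expect_equal(nrow(plan$design$rows), 600)  # N (k + 2)
  expect_identical(plan$AB[[2]][, -2], plan$A[, -2])
  expect_identical(plan$AB[[2]][, 2], plan$B[, 2])
  # stacked design reproduces the blocks in evaluation order
  expect_equal(unname(plan$design$unit_rows[1:100, ]), unname(plan$A))
  expect_equal(unname(plan$design$unit_rows[201:300, ]), unname(plan$AB[[1]]))

  set.seed(3); p2 <- sobol_design(ft, 100)
  expect_identical(plan$design$rows, p2$design$rows)
  expect_error(sobol_design(ft, 1), class = "ibmsens_invalid_sample_size")
})

test_that("single active factor concentrates all variance on it", {
  set.seed(8)
  plan <- sobol_design(unit_table(2), 4096)
  y <- plan$design$unit_rows[, 1]
  si <- sobol_indices(plan, y)
  # S1 carries the Saltelli-estimator Monte Carlo noise (sd ~ 0.027 at this
  # N); the inactive factor's indices are exact up to arithmetic noise
  expect_lt(abs(si$S[1] - 1), 0.05)
  expect_lt(abs(si$S[2]), 0.02)
  expect_lt(abs(si$ST[2]), 0.02)
})

test_that("additive symmetric model splits variance evenly", {
  set.seed(9)
  plan <- sobol_design(unit_table(2), 8192)
  y <- rowSums(plan$design$unit_rows)
  si <- sobol_indices(plan, y)
  expect_lt(max(abs(si$S - 0.5)), 0.05)
  expect_lt(abs(sum(si$S) - 1), 0.05)
  expect_true(all(abs(si$ST - si$S) < 0.05))
})

test_that("Ishigami indices match the closed-form decomposition", {
  an <- ishigami_analytic_indices(7, 0.1)
  set.seed(10)
  m <- ishigami_model(7, 0.1)
  plan <- sobol_design(m$factors, 8192)
  y <- eval_on_design(plan$design, function(x)
    sin(x[1]) + 7 * sin(x[2])^2 + 0.1 * x[3]^4 * sin(x[1]))
  si <- sobol_indices(plan, y)
  expect_lt(max(abs(si$S - c(an$S1, an$S2, an$S3))), 0.05)
  expect_lt(max(abs(si$ST - c(an$ST1, an$ST2, an$ST3))), 0.05)
})

test_that("estimation error shrinks with N on the Ishigami fixture", {
  an <- ishigami_analytic_indices(7, 0.1)
  truth <- c(an$S1, an$S2, an$S3)
  f <- function(x) sin(x[1]) + 7 * sin(x[2])^2 + 0.1 * x[3]^4 * sin(x[1])
  ft <- ishigami_model()$factors
  wins <- 0
  for (s in 1:10) {
    err <- vapply(c(512, 8192), function(N) {
      set.seed(s * 1000 + N)
      plan <- sobol_design(ft, N)
      # negative estimates at N = 512 are the expected small-N diagnostic
      si <- suppressWarnings(sobol_indices(plan, eval_on_design(plan$design, f)))
      max(abs(si$S - truth))
    }, numeric(1))
    wins <- wins + (err[2] < err[1])
  }
  expect_gte(wins, 9)
})

test_that("interacting fixture shows ST exceeding S for both factors", {
  set.seed(12)
  m <- product_model()
  plan <- sobol_design(m$factors, 8192)
  y <- eval_on_design(plan$design, function(x) x[1] * x[2])
  si <- sobol_indices(plan, y)
  an <- product_analytic_indices()
  expect_lt(max(abs(si$S - c(an$S1, an$S2))), 0.05)
  expect_lt(max(abs(si$ST - c(an$ST1, an$ST2))), 0.05)
  expect_true(all(si$ST - si$S > 0.05))
})

test_that("constant output raises a degenerate-variance error", {
  set.seed(13)
  plan <- sobol_design(unit_table(2), 16)
  expect_error(sobol_indices(plan, rep(7, nrow(plan$design$rows))),
               class = "ibmsens_degenerate_variance")
  m <- constant_model()
  expect_error(easy_sobol(m, m$factors, N = 8, ticks = 1, master_seed = 1),
               class = "ibmsens_degenerate_variance")
})

test_that("easy_sobol runs the pipeline end to end on the linear fixture", {
  m <- linear_model(c(3, 5))
  res <- easy_sobol(m, m$factors, N = 2048, ticks = 1, master_seed = 5)
  # Si for sum(ci xi) with uniform inputs is ci^2 / sum(ci^2)
  expect_lt(max(abs(res$indices$S - c(9, 25) / 34)), 0.05)
  expect_equal(nrow(res$experiment$paramset), 2048 * 4)
})

test_that("bootstrap intervals bracket the point estimates", {
  set.seed(14)
  plan <- sobol_design(unit_table(2), 256)
  y <- rowSums(plan$design$unit_rows)
  si <- sobol_indices(plan, y, n_boot = 200)
  expect_true(all(si$S_lo <= si$S & si$S <= si$S_hi))
  expect_true(all(si$ST_lo <= si$ST & si$ST <= si$ST_hi))
})
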