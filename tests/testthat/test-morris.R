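test_that("grid step follows the level-count formulas", {
  expect_equal(morris_delta(4, "standard"), 2 / 3)
  expect_equal(morris_delta(4, "alternative"), 1 / 3)
  expect_equal(morris_delta(2, "standard"), 1)
  expect_equal(morris_delta(5), 1 / 4)  # auto: odd p -> alternative
  expect_error(morris_delta(5, "standard"), class = "ibmsens_invalid_levels")
  expect_error(morris_delta(1), class = "ibmsens_invalid_levels")
})

test_that("trajectories move one factor at a time on the level grid", {
  for (case in list(list(k = 3, p = 4, r = 10), list(k = 7, p = 5, r = 10),
                    list(k = 2, p = 8, r = 5))) {
    set.seed(case$k * 100 + case$p)
    plan <- morris_design(unit_table(case$k), p = case$p, r = case$r)
    expect_equal(nrow(plan$design$rows), case$r * (case$k + 1))
    grid <- seq(0, 1, length.out = case$p)
    mind <- apply(abs(outer(c(plan$design$unit_rows), grid, "-")), 1, min)
    expect_true(all(mind < 1e-12))  # every coordinate sits on the level grid
    for (traj in plan$trajectories) {
      steps <- diff(traj)
      # exactly one coordinate moves per transition, by +/- delta
      expect_true(all(rowSums(steps != 0) == 1))
      expect_true(all(abs(abs(steps[steps != 0]) - plan$delta) < 1e-12))
      # each factor moves exactly once
      expect_equal(sort(apply(steps != 0, 2, sum)), rep(1, case$k))
      expect_true(all(traj >= 0 & traj <= 1))
    }
  }
})

test_that("elementary effects recover hand-computed finite differences", {
  # f(x) = 3 x1: every effect is 3; f constant: all zero
  set.seed(2)
  plan <- morris_design(unit_table(2), p = 4, r = 6)
  ee <- elementary_effects(plan, 3 * plan$design$unit_rows[, 1])
  expect_equal(unname(ee$y[, 1]), rep(3, 6))
  expect_equal(unname(ee$y[, 2]), rep(0, 6))
  ee0 <- elementary_effects(plan, rep(5, nrow(plan$design$rows)))
  expect_true(all(ee0$y == 0))

  # f(x) = x1^2, p = 4, delta = 2/3: effect from x1 = 0 is (4/9)/(2/3) = 2/3
  ee2 <- elementary_effects(plan, plan$design$unit_rows[, 1]^2)
  lows <- vapply(seq_len(plan$r), function(t) {
    st <- plan$steps[plan$steps$trajectory == t, ]
    s <- which(st$factor == 1)
    pts <- plan$trajectories[[t]][c(s, s + 1), 1]
    min(pts)
  }, numeric(1))
  expect_equal(unname(ee2$y[lows < 1e-12, 1]),
               rep(2 / 3, sum(lows < 1e-12)))
  expect_error(elementary_effects(plan, 1:5), class = "ibmsens_shape_error")
})

test_that("metrics use the printed divisor-r dispersion", {
  fake <- structure(list(y = matrix(c(3, 3, 3), ncol = 1,
                                    dimnames = list(NULL, "f1"))),
                    class = "elementary_effects")
  m <- morris_metrics(fake)
  expect_equal(c(m$mu, m$mu_star, m$sigma), c(3, 3, 0))

  fake$y <- matrix(c(-2, 2), ncol = 1, dimnames = list(NULL, "f1"))
  m <- morris_metrics(fake)
  expect_equal(c(m$mu, m$mu_star, m$sigma), c(0, 2, 2))

  fake$y <- matrix(c(1, 3), ncol = 1, dimnames = list(NULL, "f1"))
  expect_equal(unlist(morris_metrics(fake)[, c("mu", "mu_star", "sigma")],
                      use.names = FALSE), c(2, 2, 1))
  expect_equal(morris_metrics(fake, "r-1")$sigma, sqrt(2))
})

test_that("affine responses give exact mu = mu* and zero sigma for all settings", {
  for (p in c(4, 6, 8)) for (r in c(5, 20)) {
    set.seed(p * r)
    plan <- morris_design(unit_table(3), p = p, r = r)
    y <- 3 * plan$design$unit_rows[, 1] + 5 * plan$design$unit_rows[, 2] +
      0 * plan$design$unit_rows[, 3] + 1
    m <- morris_metrics(elementary_effects(plan, y))
    expect_equal(m$mu, c(3, 5, 0), tolerance = 1e-12)
    expect_equal(m$mu_star, c(3, 5, 0), tolerance = 1e-12)
    expect_true(all(m$sigma <= 1e-9))
    expect_true(all(m$mu_star >= abs(m$mu) - 1e-12))
  }
})

test_that("effect bookkeeping yields exactly r effects per factor", {
  set.seed(33)
  plan <- morris_design(unit_table(5), p = 6, r = 12)
  ee <- elementary_effects(plan, stats::runif(nrow(plan$design$rows)))
  expect_equal(dim(ee$y), c(12, 5))
  expect_false(anyNA(ee$y))
})

test_that("easy_morris screens a linear model end to end", {
  m <- linear_model(c(3, 5))
  set.seed(1)
  res <- easy_morris(m, m$factors, p = 4, r = 20, ticks = 1, master_seed = 1)
  ind <- res$indices
  expect_equal(ind$mu_star, c(3, 5), tolerance = 1e-9)
  expect_true(all(ind$sigma < 1e-9))
  expect_equal(nrow(res$experiment$paramset), 20 * 3)
})

test_that("nonmonotone responses show low |mu| with high mu* (alternative step)", {
  set.seed(1)
  plan <- morris_design(unit_table(1), p = 8, r = 50,
                        delta_mode = "alternative")
  y <- sin(2 * pi * plan$design$unit_rows[, 1])
  m <- morris_metrics(elementary_effects(plan, y))
  expect_gt(m$mu_star, 5 * abs(m$mu))
})
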