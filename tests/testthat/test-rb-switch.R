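test_that("phosphorylation rate matches its closed form and domain", {
  p <- rb_params()
  expect_equal(gamma_P(0.3, 0, p), 0)
  expect_equal(gamma_P(p$k2, p$k1, p), p$V / 4)  # half-saturation in both
  # hand-expanded evaluation at (r = 0.5, C = 0.7)
  expect_equal(gamma_P(0.5, 0.7, p), 100 * (0.7 / 1.7) * (1 / 26),
               tolerance = 1e-12)
  expect_error(gamma_P(-0.1, 1, p), "non-negative")
  expect_error(gamma_P(1, -0.1, p), "non-negative")
  # monotone: decreasing in r, increasing and saturating in C
  r <- seq(0, 2, by = 0.1)
  expect_true(all(diff(gamma_P(r, 0.5, p)) < 0))
  Cs <- seq(0.1, 50, length.out = 50)
  g <- gamma_P(0.2, Cs, p)
  expect_true(all(diff(g) > 0))
  expect_lt(g[50], p$V / (1 + (0.2 / p$k2)^2))  # saturates below V bound
})

test_that("drift has the stated fixed points and signs", {
  p <- rb_params()
  expect_equal(rb_drift(0, 5, p), 1)
  expect_equal(rb_drift(1, 0, p), 0)  # C = 0 fixed point at r = 1/gamma_D
  expect_lt(rb_drift(4, 0.7, p), 0)
})

test_that("rb_params validates its invariants", {
  expect_error(rb_params(V = -1), "positive")
  expect_error(rb_params(r_thresh = 5), "below r0")
  p <- rb_params()
  expect_equal(p$V, 100)
  expect_equal(p$k2, 0.1)
})

test_that("activity proxy is a decreasing map onto [0, 1]", {
  expect_equal(activity_proxy(0), 1)
  expect_lt(activity_proxy(50), 1e-12)
  r <- seq(0, 5, by = 0.25)
  expect_true(all(diff(activity_proxy(r)) < 0))
  # the S-entry activity used by the ghost thresholds
  expect_equal(threshold_spec()$s_entry, activity_proxy(0.05))
})

test_that("fixed points agree with the cubic polynomial oracle", {
  set.seed(11)
  for (i in 1:100) {
    p <- rb_params(gamma_D = runif(1, 0.5, 2), V = runif(1, 1, 200),
                   k1 = runif(1, 0.5, 2), k2 = runif(1, 0.05, 0.3))
    C <- runif(1, 0, 1)
    fp <- find_fixed_points(C, p)
    oracle <- polyroot_fixed_points(C, p)
    expect_equal(length(fp$roots), length(oracle))
    expect_equal(fp$roots, oracle, tolerance = 1e-8)
  }
})

test_that("fixed-point structure over the control parameter", {
  p <- rb_params()
  fp0 <- find_fixed_points(0, p)
  expect_equal(fp0$roots, 1 / p$gamma_D, tolerance = 1e-9)
  expect_equal(fp0$stabilities, "stable")

  fp <- find_fixed_points(0.2, p)
  expect_length(fp$roots, 1)
  expect_equal(fp$roots, 0.79, tolerance = 0.02)

  fp3 <- find_fixed_points(0.30, p)
  expect_length(fp3$roots, 3)
  expect_equal(fp3$stabilities, c("stable", "unstable", "stable"))

  # scanning C over [0, 2]: root-count pattern is 1, 3, 1
  counts <- vapply(seq(0, 2, by = 0.01),
                   function(C) length(find_fixed_points(C, p)$roots),
                   integer(1))
  expect_equal(rle(counts)$values, c(1, 3, 1))
})

test_that("fold location matches the algebraic oracle", {
  bf <- find_bifurcation(rb_params())
  expect_true(bf$bistable)
  expect_lt(bf$C_crit_low, bf$C_crit_high)
  # the printed critical CycD level, to two decimals
  expect_equal(round(bf$C_crit_high, 2), 0.35)
  # independent algebraic fold oracle (gamma_D = 1)
  alg <- algebraic_folds(k2 = 0.1, V = 100, k1 = 1)
  expect_equal(bf$r_fold_high, alg$high$r, tolerance = 1e-6)
  expect_equal(bf$r_fold_low, alg$low$r, tolerance = 1e-6)
  expect_equal(bf$C_crit_high, alg$high$C, tolerance = 1e-4)
  expect_equal(bf$C_crit_low, alg$low$C, tolerance = 1e-4)
})

test_that("a weak switch has no bistable window", {
  bf <- find_bifurcation(rb_params(V = 1))
  expect_false(bf$bistable)
})

test_that("deterministic trajectories: sub-critical persistence, super-critical exit", {
  p <- rb_params(sigma = 1e-12)
  tr <- simulate_rb(p, C = 0.2, dt = 0.05, t_max = 150, seed = 1)
  expect_false(tr$exited)
  # converges to the stable root at this C
  root <- find_fixed_points(0.2, rb_params())$roots[1]
  expect_equal(tr$r[length(tr$r)], root, tolerance = 1e-3)

  exits <- vapply(c(0.5, 0.8, 1.2, 2.0), function(C) {
    simulate_rb(p, C = C, dt = 0.01, t_max = 200, seed = 1)$exit_time
  }, numeric(1))
  expect_true(all(is.finite(exits)))
  expect_true(all(diff(exits) < 0))  # monotone transit in C
})

test_that("trajectories are reproducible and export the standard columns", {
  p <- rb_params()
  t1 <- simulate_rb(p, C = 0.7, dt = 0.05, t_max = 100, seed = 7)
  t2 <- simulate_rb(p, C = 0.7, dt = 0.05, t_max = 100, seed = 7)
  expect_identical(t1$r, t2$r)
  df <- as.data.frame(t1)
  expect_named(df, c("time_h", "r", "activity"))
  expect_true(all(df$r >= 0))
  expect_equal(df$activity, 1 - tanh(df$r))
  if (t1$exited) expect_lt(t1$r[length(t1$r)], p$r_thresh)
})

test_that("ensemble exit times converge under step halving", {
  p <- rb_params()
  sp <- condition_spec("conv", 1, 0.7, 0.05, 2000)
  a <- simulate_condition(sp, p, dt = 0.05, t_max = 100, seed = 5)
  b <- simulate_condition(sp, p, dt = 0.025, t_max = 100, seed = 6)
  m_a <- mean(a$g1_hours, na.rm = TRUE); m_b <- mean(b$g1_hours, na.rm = TRUE)
  se <- sqrt(stats::var(a$g1_hours, na.rm = TRUE) / sum(!a$censored) +
             stats::var(b$g1_hours, na.rm = TRUE) / sum(!b$censored))
  expect_lt(abs(m_a - m_b), 3 * se)
})
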