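# Frozen high-precision reference values (40-digit arbitrary-precision
# Airy evaluations) for the special functions and the mean-delay formula.

test_that("Airy pair matches high-precision reference values", {
  ref <- data.frame(
    x  = c(0, 1, 5, 25, 30, -1, -5, -30),
    Ai = c(0.35502805388781724, 0.13529241631288142, 0.00010834442813607442,
           8.1160268246913867e-38, 3.2082175915504956e-49,
           0.53556088329235212, 0.35076100902411432, -0.087968188456842163),
    Bi = c(0.61492662744600074, 1.2074235949528713, 657.79204417117118,
           3.9220307780413818e+35, 9.057288512151307e+46,
           0.10399738949694461, -0.13836913490160058, -0.22444694220056632))
  expect_equal(airy_ai(ref$x), ref$Ai, tolerance = 1e-10)
  expect_equal(airy_bi(ref$x), ref$Bi, tolerance = 1e-10)
  # log-space sum agrees with the direct sum across the switch-over
  xs <- c(seq(-4, 7.99, by = 0.5), 7.999, 8.001, 10, 30)
  expect_equal(airy_sq_log(xs), log(airy_ai(xs)^2 + airy_bi(xs)^2),
               tolerance = 1e-9)
})

test_that("exact mean delay reproduces reference values and stays finite in log space", {
  expect_equal(mfpt_exact(0, 1), 6.269435118352459, tolerance = 1e-10)
  # log-scale references, including a deeply sub-critical case that
  # overflows double precision on the natural scale
  expect_equal(mfpt_exact(-0.5, 0.05, log = TRUE), 378.6156586423283,
               tolerance = 1e-10)
  expect_equal(mfpt_exact(-0.3, 0.1, log = TRUE), 45.57101222511650,
               tolerance = 1e-10)
  expect_equal(mfpt_exact(0.05, 0.1, log = TRUE), 2.620609578511864,
               tolerance = 1e-10)
  expect_equal(mfpt_exact(-0.2, 0.2, log = TRUE), 7.972156706900840,
               tolerance = 1e-10)
  expect_error(mfpt_exact(0, -1), "positive")
})

test_that("mean delay is strictly decreasing in mu and collapses onto one scaling variable", {
  xi <- 0.1
  mus <- seq(-0.5, 0.5, by = 0.05)
  lT <- mfpt_exact(mus, xi, log = TRUE)
  expect_true(all(diff(lT) < 0))
  expect_lt(mfpt_exact(0.5, 0.1), mfpt_exact(0, 0.1))
  expect_lt(mfpt_exact(0, 0.1), mfpt_exact(-0.5, 0.1))
  # T * xi^{2/3} depends on mu * xi^{-4/3} only: rescale (mu, xi) jointly
  set.seed(3)
  for (i in 1:20) {
    mu <- runif(1, -0.5, 0.5); xi1 <- runif(1, 0.05, 0.5)
    s <- runif(1, 0.5, 2)
    xi2 <- s * xi1; mu2 <- mu * s^(4 / 3)
    v1 <- mfpt_exact(mu, xi1, log = TRUE) + (2 / 3) * log(xi1)
    v2 <- mfpt_exact(mu2, xi2, log = TRUE) + (2 / 3) * log(xi2)
    expect_equal(v1, v2, tolerance = 1e-10)
  }
})

test_that("Kramers approximation: validity regime and convergence to exact", {
  expect_error(mfpt_kramers(0.1, 0.1), "mu < 0")
  # deep-barrier agreement in log space, within 2%
  lK <- mfpt_kramers(-0.5, 0.05, log = TRUE)
  lE <- mfpt_exact(-0.5, 0.05, log = TRUE)
  expect_lt(abs(lK - lE) / lE, 0.02)
  # log-ratio -> 1 monotonically as |mu|^{3/2}/xi^2 grows
  mus <- -c(0.2, 0.3, 0.45, 0.6, 0.8)
  ratio <- mfpt_kramers(mus, 0.05, log = TRUE) /
    mfpt_exact(mus, 0.05, log = TRUE)
  expect_true(all(diff(abs(ratio - 1)) < 0))
  # shallow-barrier regime deviates visibly (recorded, not asserted small)
  shallow <- mfpt_kramers(-0.1, 0.3) / mfpt_exact(-0.1, 0.3)
  expect_true(is.finite(shallow))
})

test_that("delay scaling law has exponent 3/2", {
  grid <- seq(-0.6, -0.2, length.out = 20)
  sc <- scaling_exponent(0.05, grid)
  expect_true(sc$regime_ok)
  expect_equal(sc$exponent, 1.5, tolerance = 0.05 / 1.5)
  # smaller noise is deeper in the asymptotic regime: closer to 3/2
  sc2 <- scaling_exponent(0.02, grid)
  expect_lt(abs(sc2$exponent - 1.5), abs(sc$exponent - 1.5))
  # regime flag trips when the barrier is shallow
  expect_false(scaling_exponent(0.5, grid)$regime_ok)
})

test_that("empirical passage time approaches the deterministic limit", {
  # dx = (x^2 + 1) dt from -3 to 3 takes 2 atan(3)
  emp <- mfpt_empirical(1, 1e-9, n = 3, dt = 1e-4, seed = 1)
  expect_equal(emp$mean, 2 * atan(3), tolerance = 1e-2)
  expect_equal(emp$censored, 0)
})

test_that("empirical first-passage ensembles match the Airy formula on a 3x3 grid", {
  # the module's central oracle test
  set.seed(20)
  for (mu in c(0.05, 0, -0.05)) {
    for (xi in c(0.15, 0.2, 0.3)) {
      ex <- mfpt_exact(mu, xi)
      emp <- mfpt_empirical(mu, xi, n = 1200, dt = 0.005)
      expect_equal(emp$censored, 0)
      expect_lt(abs(emp$mean - ex), 3 * emp$se + 0.05 * ex)
    }
  }
})

test_that("normal-form ensembles separate the critical and time-driven regimes", {
  # deterministic reduction: all paths identical when xi = 0
  det <- simulate_normal_form(0.5, xi = 0, dt = 0.005, t_max = 50, n = 5)
  expect_equal(length(unique(det$exit_times)), 1)

  # constant mu near zero: heavy-tailed exit times; fast mu ramp: clustered
  const <- simulate_normal_form(0.0, xi = 0.1, dt = 0.01, t_max = 2000,
                                n = 400, seed = 2)
  ramp <- simulate_normal_form(function(t) -1 + 0.2 * t, xi = 0.1,
                               dt = 0.01, t_max = 2000, n = 400, seed = 3)
  cv <- function(x) stats::sd(x, na.rm = TRUE) / mean(x, na.rm = TRUE)
  expect_true(all(!is.na(const$exit_times)))
  expect_true(all(!is.na(ramp$exit_times)))
  expect_lt(cv(ramp$exit_times), 0.5)
  expect_gt(cv(const$exit_times), 2 * cv(ramp$exit_times))
})

test_that("local reduction to the normal form is consistent", {
  red <- reduce_to_normal_form(rb_params())
  # destabilizing direction: mu grows with C above the fold
  expect_gt(red$mu_per_C, 0)
  expect_gt(red$xi_factor, 0)
  # quadratic coefficient agrees with a plain second difference of the drift
  h <- 1e-4
  p <- rb_params()
  num_b <- (rb_drift(red$r_fold + h, red$C_crit, p) -
              2 * rb_drift(red$r_fold, red$C_crit, p) +
              rb_drift(red$r_fold - h, red$C_crit, p)) / h^2 / 2
  expect_equal(red$b, num_b, tolerance = 1e-3)
  expect_error(reduce_to_normal_form(rb_params(V = 1)), "monostable")
})

test_that("mapped normal form predicts switch exit times in its asymptotic regime", {
  # at low molecular noise the local reduction is quantitative: the mean
  # G1 length of the full switch matches the Airy delay for the mapped
  # (mu, xi) within 5%
  p <- rb_params(sigma = 0.05)
  red <- reduce_to_normal_form(p)
  for (dC in c(0.002, 0.005)) {
    sp <- condition_spec("x", 1, red$C_crit + dC, 0, 1500)
    sim <- simulate_condition(sp, p, dt = 0.01, t_max = 2000, seed = 9)
    expect_equal(sum(sim$censored), 0)
    pred <- mfpt_exact(red$mu_per_C * dC, red$xi_factor)
    expect_lt(abs(mean(sim$g1_hours) - pred) / pred, 0.05)
  }
})
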