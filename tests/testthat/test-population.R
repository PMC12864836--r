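test_that("feedback variants hit their anchor identities", {
  hyp <- feedback_spec("hyperbolic_RD")
  expect_equal(feedback_C(100, hyp), 0.35)
  expect_equal(feedback_C(50, hyp), 0.70)
  lin <- feedback_spec("linear_DR")
  expect_equal(feedback_C(100, lin, alpha = 0.5), 0.35 / 2)
  expect_equal(feedback_C(200, lin), 0.70)
  # ligand variants reduce to the direct forms at matched gains
  mit <- feedback_spec("ligand_mitogen", p = 35, k_deg = 1, mitogen_gain = 1)
  for (N in c(10, 100, 400))
    expect_equal(feedback_C(N, mit), feedback_C(N, hyp))
  inh <- feedback_spec("ligand_inhibitor", p = 1, k_deg = 0.35 / 100,
                       inhibitor_gain = 1)
  for (N in c(10, 100, 400))
    expect_equal(feedback_C(N, inh), feedback_C(N, lin))
  # extinction fallback
  expect_message(C0 <- feedback_C(0, hyp), "N = 1")
  expect_equal(C0, feedback_C(1, hyp))
})

test_that("fate assignment follows the competing-risks rule, ties to the late branch", {
  rd <- topology_spec("RD"); dr <- topology_spec("DR")
  expect_equal(assign_fate(rd, 5, 20), "renew")
  expect_equal(assign_fate(dr, 5, 20), "differentiate")
  expect_equal(assign_fate(rd, 25, 20), "differentiate")
  expect_equal(assign_fate(dr, 25, 20), "renew")
  expect_equal(assign_fate(rd, 20, 20), "differentiate")  # tie
  expect_equal(assign_fate(dr, c(5, 25), c(20, 20)),
               c("differentiate", "renew"))
})

test_that("net self-renewal bias theta(T) has the right limits and root", {
  rd <- topology_spec("RD", timer_mean = 20)
  dr <- topology_spec("DR", timer_mean = 20)
  expect_equal(theta_of_T(rd, 0), 1)
  expect_equal(theta_of_T(dr, 0), -1)
  expect_equal(theta_of_T(rd, 20 * log(2)), 0, tolerance = 1e-12)
  expect_equal(theta_of_T(rd, 13.86), 2 * exp(-13.86 / 20) - 1)
  # deterministic timer is a step; gamma timer is smooth and monotone
  det <- topology_spec("RD", timer_distribution = "deterministic")
  expect_equal(theta_of_T(det, c(19.9, 20.1)), c(1, -1))
  gam <- topology_spec("RD", timer_distribution = "gamma", timer_shape = 3)
  expect_true(all(diff(theta_of_T(gam, seq(0, 60, by = 5))) < 0))
})

test_that("growth-rate forms agree near balance and validate their domain", {
  g0 <- growth_rate(10, 0)
  expect_equal(g0$exact, 0); expect_equal(g0$linearized, 0)
  g1 <- growth_rate(10, 1)
  expect_equal(g1$exact, log(2) / 10)
  expect_equal(g1$linearized, 0.1)
  gs <- growth_rate(10, 0.01)
  expect_lt(abs(gs$exact - gs$linearized) / gs$linearized, 0.01)
  expect_error(growth_rate(10, -1), "theta")
  expect_error(growth_rate(0, 0.5), "positive")
})

test_that("stability criterion is the sign table of the feedback chain", {
  expect_equal(stability_check(-1, -1), "stable")    # RD pairing
  expect_equal(stability_check(1, 1), "stable")      # DR pairing
  expect_equal(stability_check(-1, 1), "unstable")
  expect_equal(stability_check(1, -1), "unstable")
  expect_equal(stability_check(0, 1), "marginal")
  expect_error(stability_check(Inf, 1), "finite")
})

test_that("predicted set points invert the feedback at criticality", {
  expect_equal(predicted_set_point(feedback_spec("hyperbolic_RD")), 100)
  expect_equal(predicted_set_point(feedback_spec("linear_DR", N_st = 10)), 10)
  mit <- feedback_spec("ligand_mitogen", p = 35, k_deg = 1)
  expect_equal(predicted_set_point(mit), 100)  # constructed f(100) = C_crit
  pool <- feedback_spec("differentiated_pool")
  expect_equal(predicted_set_point(pool), pool$D_st)
})

test_that("single-step reference implementation conserves cells exactly", {
  pp <- population_params(N0 = 30, capacity = 300, seed = 42, t_max = 100)
  set.seed(42)
  st <- new_population_state(pp)
  for (k in 1:400) {
    n_before <- sum(st$active)
    out <- step_population(st, pp)
    st <- out$state
    expect_identical(sum(st$active),
                     n_before + out$events$renewals - out$events$differentiations)
    expect_true(all(st$alpha == 1))  # no mutation pathway active
  }
  expect_gt(sum(st$active), 0)
})

test_that("engine trace satisfies the exact event-count audit", {
  pp <- population_params(N0 = 50, t_max = 400, seed = 3, record_every = 1)
  tr <- run_homeostasis(pp)
  expect_identical(diff(tr$N), as.numeric(tr$renewals[-1] - tr$differentiations[-1]))
  # disabled mutation spec is identical to no mutation spec
  pp2 <- population_params(N0 = 50, t_max = 400, seed = 3, record_every = 1,
                           mutation = mutation_spec(enabled = FALSE))
  tr2 <- run_homeostasis(pp2)
  expect_identical(tr$N, tr2$N)
})

test_that("both topologies settle at the predicted set point from either side", {
  for (cfg in list(list("RD", "hyperbolic_RD", 10), list("RD", "hyperbolic_RD", 300),
                   list("DR", "linear_DR", 300))) {
    pp <- population_params(
      feedback = feedback_spec(cfg[[2]]), topology = topology_spec(cfg[[1]]),
      N0 = cfg[[3]], t_max = 3000, seed = 1)
    tr <- run_homeostasis(pp)
    expect_false(tr$extinct)
    expect_lt(abs(tr$long_run_mean_N - 100) / 100, 0.1)
  }
})

test_that("a ten-cell niche is held without extinction", {
  means <- c()
  for (cfg in list(list("RD", "hyperbolic_RD"), list("DR", "linear_DR"))) {
    for (s in 1:2) {
      pp <- population_params(
        feedback = feedback_spec(cfg[[2]], N_st = 10),
        topology = topology_spec(cfg[[1]]), N0 = 10, t_max = 5000, seed = s)
      tr <- run_homeostasis(pp)
      expect_false(tr$extinct)
      expect_gt(tr$long_run_mean_N, 5)
      means <- c(means, tr$long_run_mean_N)
    }
  }
  # across topologies and seeds the niche occupancy averages near ten
  # cells; RD holds slightly above the set point and DR slightly below
  # (one cell is 10% of the feedback signal at this size)
  expect_lt(abs(mean(means) - 10) / 10, 0.2)
})

test_that("feedback tunes the population to the vicinity of the fold", {
  # time-averaged control parameter within +-0.05 of C_crit
  pp_rd <- population_params(N0 = 100, t_max = 3000, seed = 4)
  tr <- run_homeostasis(pp_rd)
  sec <- tr$times >= 1500
  C_rd <- mean(0.35 * 100 / tr$N[sec])
  expect_lt(abs(C_rd - 0.35), 0.05)
  pp_dr <- population_params(feedback = feedback_spec("linear_DR"),
                             topology = topology_spec("DR"),
                             N0 = 100, t_max = 3000, seed = 4)
  tr2 <- run_homeostasis(pp_dr)
  C_dr <- mean(0.35 * tr2$N[tr2$times >= 1500] / 100)
  expect_lt(abs(C_dr - 0.35), 0.05)
})

test_that("recovery from a bottleneck is much faster under RD than DR", {
  t90 <- function(kind, variant, seed) {
    pp <- population_params(feedback = feedback_spec(variant),
                            topology = topology_spec(kind),
                            N0 = 10, t_max = 4000, seed = seed)
    tr <- run_homeostasis(pp)
    tr$times[which(tr$N >= 90)[1]]
  }
  for (s in 1:2) {
    rd <- t90("RD", "hyperbolic_RD", s)
    dr <- t90("DR", "linear_DR", s)
    expect_false(is.na(rd)); expect_false(is.na(dr))
    expect_gt(dr / rd, 5)
  }
})

test_that("mis-sensing mutants invade both topologies, faster under RD", {
  res <- lapply(c("RD", "DR"), function(kind) {
    variant <- if (kind == "RD") "hyperbolic_RD" else "linear_DR"
    lapply(1:2, function(s) {
      pp <- population_params(feedback = feedback_spec(variant),
                              topology = topology_spec(kind),
                              mutation = mutation_spec(),
                              N0 = 100, t_max = 6000, seed = s,
                              capacity = 8000)
      run_mutation_experiment(pp)
    })
  })
  names(res) <- c("RD", "DR")
  for (kind in c("RD", "DR")) {
    for (tr in res[[kind]]) {
      expect_lt(tr$clone_summary$final_mean_alpha, 0.9)
      rho <- suppressWarnings(
        stats::cor(tr$times, tr$mean_alpha, method = "spearman"))
      expect_lt(rho, 0)
      lateN <- mean(tr$N[tr$times > 5000])
      expect_gt(lateN, 120)  # drift to a higher population fixed point
    }
  }
  lateN <- function(tr) mean(tr$N[tr$times > 5000])
  expect_gt(mean(sapply(res$RD, lateN)), mean(sapply(res$DR, lateN)))
  # p_m = 0 requirement is enforced
  expect_error(run_mutation_experiment(population_params()), "mutation")
})

test_that("two-compartment feedback balances the differentiation flux", {
  Cs <- 0.3435  # control level whose mean G1 matches the timer root
  for (s in 1:2) {
    fb <- feedback_spec("differentiated_pool", gamma = 0.05)
    D0 <- fb$D_st * (Cs - fb$C_basal) / (fb$C_crit - fb$C_basal)
    pp <- population_params(feedback = fb, topology = topology_spec("DR"),
                            N0 = 100, t_max = 4000, D0 = D0, seed = s,
                            capacity = 8000)
    tr <- run_two_compartment(pp)
    expect_false(tr$extinct)
    ss <- tr$steady_state
    expect_lt(abs(ss$flux_lhs - ss$flux_rhs) / ss$flux_rhs, 0.1)
    # dispersed cycle lengths push the operational cycle length above the
    # sharp-timer value tau_d log 2
    expect_gt(ss$T_s, ss$T_s_timer)
  }
  # wrong variant guard
  expect_error(run_two_compartment(population_params()), "differentiated_pool")
})

test_that("the mitogenic pool feedback requires the DR fate rule", {
  # RD pairing closes a positive loop (more cells -> more differentiated
  # signal -> more mitogen -> faster renewal): the population runs away
  fb <- feedback_spec("differentiated_pool", gamma = 0.05)
  pp <- population_params(feedback = fb, topology = topology_spec("RD"),
                          N0 = 100, t_max = 1500, D0 = fb$D_st, seed = 1,
                          capacity = 20000, on_overflow = "error")
  expect_error(run_two_compartment(pp), "capacity")
})

test_that("fast pool turnover still yields bounded homeostasis", {
  Cs <- 0.3435
  fb <- feedback_spec("differentiated_pool", gamma = 0.5)
  D0 <- fb$D_st * (Cs - fb$C_basal) / (fb$C_crit - fb$C_basal)
  pp <- population_params(feedback = fb, topology = topology_spec("DR"),
                          N0 = 100, t_max = 3000, D0 = D0, seed = 1,
                          capacity = 8000)
  tr <- run_two_compartment(pp)
  expect_false(tr$extinct)
  expect_gt(tr$long_run_mean_N, 20)
  expect_lt(tr$long_run_mean_N, 300)
})

test_that("capacity overflow fails loudly when growth is disabled", {
  pp <- population_params(N0 = 40, capacity = 45, t_max = 500, seed = 1,
                          on_overflow = "error",
                          feedback = feedback_spec("hyperbolic_RD", N_st = 100))
  expect_error(run_homeostasis(pp), "capacity")
})
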