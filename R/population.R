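#' Population feedback specification
#'
#' Defines how the perceived population size sets the CycD control
#' parameter `C` for every cell. Variants:
#' \describe{
#'   \item{`hyperbolic_RD`}{`C = C_crit * N_st / (alpha * N)`; more cells
#'     lower `C` and lengthen G1 (`df/dN < 0`), the pairing required by
#'     the RD fate rule.}
#'   \item{`linear_DR`}{`C = C_crit * (alpha * N) / N_st`; more cells
#'     raise `C` and shorten G1 (`df/dN > 0`), pairing with DR.}
#'   \item{`ligand_mitogen`}{quasi-steady-state mitogenic ligand secreted
#'     by the niche at rate `p` and consumed per-capita at `k_deg`:
#'     `C = mitogen_gain * p / (k_deg * alpha * N)` (RD-paired).}
#'   \item{`ligand_inhibitor`}{quasi-steady-state inhibitory ligand:
#'     `C = inhibitor_gain * k_deg * alpha * N / p` (DR-paired).}
#'   \item{`differentiated_pool`}{a basal niche-derived mitogen plus a
#'     mitogenic ligand secreted by the differentiated pool `D`:
#'     `C = C_basal + (C_crit - C_basal) * (alpha * D) / D_st`, anchored
#'     so `C(D_st) = C_crit`. Requires the DR fate rule (`df/dD > 0`);
#'     the basal term keeps slow cycling alive when the pool is depleted
#'     so the differentiation flux can refill it (see the vignette).}
#' }
#' `alpha` is a cell's private sensing sensitivity (1 for wild type);
#' mis-sensing mutants perceive `alpha * N` instead of `N`.
#'
#' @param variant one of the feedback variants above.
#' @param C_crit critical CycD value the feedback is anchored to.
#' @param N_st target set point (cells) for the direct-N variants.
#' @param mitogen_gain,inhibitor_gain ligand-to-C conversion gains.
#' @param p ligand production rate; `k_deg` per-capita consumption rate.
#' @param k_deg per-capita ligand consumption/degradation rate.
#' @param p_D ligand production rate per differentiated cell (recorded for
#'   the two-compartment variant).
#' @param gamma removal rate (1/h) of differentiated cells.
#' @param D_st target differentiated-pool size for `differentiated_pool`
#'   (default `N_st / (tau_ref * gamma)` with `tau_ref = 20 * log(2)` h,
#'   the steady-state division time of the default commitment timer).
#' @param C_basal basal (niche-derived) mitogen level of the
#'   differentiated-pool variant; must lie below `C_crit`.
#' @return An object of class `feedback_spec`.
#' @export
feedback_spec <- function(variant = c("hyperbolic_RD", "linear_DR",
                                      "ligand_mitogen", "ligand_inhibitor",
                                      "differentiated_pool"),
                          C_crit = 0.35, N_st = 100,
                          mitogen_gain = 1, inhibitor_gain = 1,
                          p = 1, k_deg = 1, p_D = 1, gamma = 0.05,
                          D_st = NULL, C_basal = 0.3) {
  variant <- match.arg(variant)
  if (any(c(C_crit, N_st, mitogen_gain, inhibitor_gain, p, k_deg, p_D, gamma) <= 0))
    stop("all feedback rates must be positive", call. = FALSE)
  if (is.null(D_st)) D_st <- N_st / (20 * log(2) * gamma)
  if (C_basal >= C_crit) stop("C_basal must lie below C_crit", call. = FALSE)
  structure(list(variant = variant, C_crit = C_crit, N_st = N_st,
                 mitogen_gain = mitogen_gain, inhibitor_gain = inhibitor_gain,
                 p = p, k_deg = k_deg, p_D = p_D, gamma = gamma, D_st = D_st,
                 C_basal = C_basal),
            class = "feedback_spec")
}

#' Control parameter from the population feedback
#'
#' Evaluates the feedback variant at the perceived population size
#' `alpha * N` (or `alpha * D` for the differentiated-pool variant).
#' `N = 0` falls back to the `N = 1` value with a message; extinction is
#' handled by the simulation driver.
#'
#' @param N live-cell count (or differentiated-pool size for the
#'   `differentiated_pool` variant).
#' @param spec a [feedback_spec()].
#' @param alpha sensing sensitivity (vectorised; 1 = wild type).
#' @return Control parameter `C`, vectorised over `alpha`.
#' @export
feedback_C <- function(N, spec, alpha = 1) {
  if (N < 0) stop("N must be non-negative", call. = FALSE)
  if (N == 0) {
    message("feedback_C: N = 0, using N = 1 fallback")
    N <- 1
  }
  perceived <- pmax(alpha * N, 1e-12)
  switch(spec$variant,
    hyperbolic_RD = spec$C_crit * spec$N_st / perceived,
    linear_DR = spec$C_crit * perceived / spec$N_st,
    ligand_mitogen = spec$mitogen_gain * spec$p / (spec$k_deg * perceived),
    ligand_inhibitor = spec$inhibitor_gain * spec$k_deg * perceived / spec$p,
    differentiated_pool =
      spec$C_basal + (spec$C_crit - spec$C_basal) * perceived / spec$D_st)
}

#' Predicted homeostatic set point
#'
#' Inverts the feedback at the critical value: `N_s = f^{-1}(C_crit)`.
#' Every finite, extended steady-state G1 must sit near the fold, so the
#' population settles where the feedback delivers `C_crit`. For the
#' `differentiated_pool` variant the returned value is the set point of
#' the differentiated pool `D`.
#'
#' @param spec a [feedback_spec()].
#' @param C_crit critical control value (defaults to the spec's anchor).
#' @return The predicted set point (cells).
#' @export
predicted_set_point <- function(spec, C_crit = spec$C_crit) {
  switch(spec$variant,
    hyperbolic_RD = spec$C_crit * spec$N_st / C_crit,
    linear_DR = C_crit * spec$N_st / spec$C_crit,
    ligand_mitogen = spec$mitogen_gain * spec$p / (spec$k_deg * C_crit),
    ligand_inhibitor = C_crit * spec$p / (spec$inhibitor_gain * spec$k_deg),
    differentiated_pool = spec$D_st * (C_crit - spec$C_basal) /
      (spec$C_crit - spec$C_basal))
}

#' Fate topology specification
#'
#' `RD` ("renewal precedes differentiation"): rapid division favours
#' self-renewal; a cell differentiates when its stochastic commitment
#' timer (mean `timer_mean` hours) fires before it divides. `DR`
#' ("differentiation precedes renewal") inverts the rule: division before
#' the timer fires leads to differentiation, after it to renewal.
#'
#' @param kind `"RD"` or `"DR"`.
#' @param timer_mean mean commitment time tau_d (h).
#' @param timer_distribution distribution of the commitment timer;
#'   `"exponential"` (memoryless default), `"deterministic"`, or
#'   `"gamma"` (shape `timer_shape`).
#' @param timer_shape shape parameter when `timer_distribution = "gamma"`.
#' @return An object of class `topology_spec`.
#' @export
topology_spec <- function(kind = c("RD", "DR"), timer_mean = 20,
                          timer_distribution = c("exponential",
                                                 "deterministic", "gamma"),
                          timer_shape = 2) {
  kind <- match.arg(kind)
  timer_distribution <- match.arg(timer_distribution)
  if (timer_mean <= 0) stop("timer_mean must be positive", call. = FALSE)
  structure(list(kind = kind, timer_mean = timer_mean,
                 timer_distribution = timer_distribution,
                 timer_shape = timer_shape),
            class = "topology_spec")
}

# survival function of the commitment timer
.timer_survival <- function(topology, T) {
  switch(topology$timer_distribution,
    exponential = exp(-T / topology$timer_mean),
    deterministic = as.numeric(T < topology$timer_mean),
    gamma = stats::pgamma(T, shape = topology$timer_shape,
                          rate = topology$timer_shape / topology$timer_mean,
                          lower.tail = FALSE))
}

#' Fate of a single division
#'
#' Resolves the competing-risks rule at a division event: under RD a cell
#' dividing before its commitment time self-renews and differentiates
#' otherwise; under DR the rule is inverted. A tie (`age ==
#' commitment_time`) is resolved as the `age >= commitment` branch.
#'
#' @param topology a [topology_spec()].
#' @param age_at_division cell age at the division event (h).
#' @param commitment_time the cell's commitment draw (h).
#' @return `"renew"` or `"differentiate"` (vectorised).
#' @export
assign_fate <- function(topology, age_at_division, commitment_time) {
  if (any(age_at_division < 0) || any(commitment_time < 0))
    stop("times must be non-negative", call. = FALSE)
  before <- age_at_division < commitment_time
  if (topology$kind == "RD") ifelse(before, "renew", "differentiate")
  else ifelse(before, "differentiate", "renew")
}

#' Net self-renewal bias theta(T)
#'
#' `theta(T) = 2 P_R(T) - 1`, with the renewal probability `P_R` given by
#' the competing-risks rule under the commitment-timer distribution. For
#' RD with the exponential timer, `theta(T) = 2 exp(-T / tau_d) - 1`,
#' crossing zero at `T = tau_d log(2)`.
#'
#' @param topology a [topology_spec()].
#' @param T cycle (G1) length in hours, vectorised.
#' @return Bias in `[-1, 1]`.
#' @export
theta_of_T <- function(topology, T) {
  if (any(T < 0)) stop("T must be non-negative", call. = FALSE)
  S <- .timer_survival(topology, T)
  P_R <- if (topology$kind == "RD") S else 1 - S
  2 * P_R - 1
}

#' Per-hour net population growth rate
#'
#' Converts a division of length `T` with net bias `theta` into a
#' continuous growth rate. Returns both the exact discrete-to-continuous
#' form `(1/T) log(1 + theta)` and its linearisation `theta / T` (used by
#' the stability analysis near `theta = 0`).
#'
#' @param T cycle length (h), > 0.
#' @param theta net self-renewal bias in `(-1, 1]`.
#' @return List with `exact` and `linearized` (1/h).
#' @export
growth_rate <- function(T, theta) {
  if (any(T <= 0)) stop("T must be positive", call. = FALSE)
  if (any(theta <= -1) || any(theta > 1))
    stop("theta must lie in (-1, 1]", call. = FALSE)
  list(exact = log1p(theta) / T, linearized = theta / T)
}

#' Stability of the homeostatic set point
#'
#' The feedback chain `N -> C -> T -> theta` (with `dT/dC < 0` from the
#' fold) is stable iff `d(theta)/dT` and `df/dN` share their sign: the RD
#' pairing (both negative) and the DR pairing (both positive) are stable,
#' mixed signs are unstable, and a zero slope is reported as marginal.
#'
#' @param dtheta_dT slope of the bias at the set point.
#' @param df_dN slope of the feedback at the set point.
#' @return `"stable"`, `"unstable"`, or `"marginal"`.
#' @export
stability_check <- function(dtheta_dT, df_dN) {
  if (!is.finite(dtheta_dT) || !is.finite(df_dN))
    stop("slopes must be finite", call. = FALSE)
  if (dtheta_dT == 0 || df_dN == 0) return("marginal")
  if (sign(dtheta_dT) == sign(df_dN)) "stable" else "unstable"
}

#' Mutation specification for mis-sensing mutants
#'
#' At each self-renewing division the daughter's sensitivity `alpha` is,
#' with probability `p_m`, multiplied by a log-normal factor (median 1,
#' log-sd `sigma_mut`) and clipped below at `alpha_min`; otherwise it is
#' inherited unchanged. The parent always retains its own `alpha`.
#'
#' @param p_m mutation probability per division.
#' @param sigma_mut log-standard deviation of the multiplicative effect.
#' @param alpha_min floor on the sensitivity.
#' @param enabled logical switch.
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(p_m = 0.001, sigma_mut = 0.5, alpha_min = 0.03,
                          enabled = TRUE) {
  if (p_m < 0 || p_m > 1) stop("p_m must lie in [0, 1]", call. = FALSE)
  if (sigma_mut < 0) stop("sigma_mut must be non-negative", call. = FALSE)
  if (alpha_min <= 0) stop("alpha_min must be positive", call. = FALSE)
  structure(list(p_m = p_m, sigma_mut = sigma_mut, alpha_min = alpha_min,
                 enabled = enabled), class = "mutation_spec")
}

#' Parameters of an agent-based homeostasis run
#'
#' @param rb an [rb_params()] object (single-cell Rb dynamics).
#' @param feedback a [feedback_spec()].
#' @param topology a [topology_spec()].
#' @param mutation a [mutation_spec()] or `NULL` (mutations off).
#' @param dt time step (h).
#' @param T_baseline mean time (h) of the slow baseline (unregulated)
#'   division process; each cell divides spontaneously with probability
#'   `dt / T_baseline` per step.
#' @param t_max simulated horizon (h).
#' @param N0 initial population size.
#' @param capacity initial storage capacity (cells); default
#'   `max(10 * N_st, 4 * N0)`.
#' @param on_overflow `"grow"` (double the storage) or `"error"`.
#' @param record_every trace recording interval (h).
#' @param seed integer seed for the run.
#' @param D0 initial differentiated-pool size (two-compartment runs).
#' @param warmup warm-up window (h) during which the differentiated pool
#'   is clamped at `D0`, letting the synchronised initial cells establish
#'   a differentiation flux before the pool evolves freely.
#' @return An object of class `population_params`.
#' @export
population_params <- function(rb = rb_params(),
                              feedback = feedback_spec("hyperbolic_RD"),
                              topology = topology_spec("RD"),
                              mutation = NULL,
                              dt = 0.1, T_baseline = 720, t_max = 5000,
                              N0 = 100, capacity = NULL,
                              on_overflow = c("grow", "error"),
                              record_every = 1, seed = 1, D0 = 0,
                              warmup = 40) {
  on_overflow <- match.arg(on_overflow)
  if (is.null(capacity)) capacity <- max(10 * feedback$N_st, 4 * N0, 50)
  if (N0 < 1 || capacity < N0) stop("need capacity >= N0 >= 1", call. = FALSE)
  if (topology$timer_distribution != "exponential")
    stop("the simulation engine draws exponential commitment timers; ",
         "other timer families are available analytically via theta_of_T()",
         call. = FALSE)
  structure(list(rb = rb, feedback = feedback, topology = topology,
                 mutation = mutation, dt = dt, T_baseline = T_baseline,
                 t_max = t_max, N0 = N0, capacity = capacity,
                 on_overflow = on_overflow, record_every = record_every,
                 seed = seed, D0 = D0, warmup = warmup),
            class = "population_params")
}

# map a feedback spec onto the engine's (variant code, scale) pair
.engine_feedback <- function(spec) {
  switch(spec$variant,
    hyperbolic_RD = list(code = 0L, fbA = spec$C_crit * spec$N_st),
    ligand_mitogen = list(code = 0L,
                          fbA = spec$mitogen_gain * spec$p / spec$k_deg),
    linear_DR = list(code = 1L, fbA = spec$C_crit / spec$N_st),
    ligand_inhibitor = list(code = 1L,
                            fbA = spec$inhibitor_gain * spec$k_deg / spec$p),
    differentiated_pool = list(code = 2L, fbA = spec$C_crit))
}

.run_engine <- function(params, use_D = FALSE) {
  fb <- .engine_feedback(params$feedback)
  mut <- params$mutation
  p_m <- if (!is.null(mut) && mut$enabled) mut$p_m else 0
  set.seed(params$seed)
  res <- .pop_engine(
    n0 = as.integer(params$N0), capacity = as.integer(params$capacity),
    grow = params$on_overflow == "grow",
    topology = if (params$topology$kind == "RD") 0L else 1L,
    fb_variant = fb$code, fbA = fb$fbA,
    gamma_D = params$rb$gamma_D, V = params$rb$V, k1 = params$rb$k1,
    k2 = params$rb$k2, sigma = params$rb$sigma, r0 = params$rb$r0,
    r_thresh = params$rb$r_thresh,
    dt = params$dt, t_max = params$t_max,
    tau_d = params$topology$timer_mean, T_baseline = params$T_baseline,
    p_m = p_m,
    sigma_mut = if (is.null(mut)) 0 else mut$sigma_mut,
    alpha_min = if (is.null(mut)) 0.03 else mut$alpha_min,
    use_D = use_D, gamma_pool = params$feedback$gamma, D0 = params$D0,
    warmup = params$warmup, D_st = params$feedback$D_st,
    C_basal = params$feedback$C_basal %||% 0,
    record_every = max(1L, as.integer(round(params$record_every / params$dt))))
  res
}

.make_trace <- function(res, params) {
  n2 <- res$N[res$times >= max(res$times) / 2]
  structure(list(
    times = res$times, N = res$N, mean_alpha = res$mean_alpha, D = res$D,
    renewals = res$renewals, differentiations = res$differentiations,
    age_at_division_sum = res$age_at_division_sum,
    extinct = res$extinct, extinction_time = res$extinction_time,
    final_state = data.frame(age = res$final_age, r = res$final_r,
                             commitment_time = res$final_commit,
                             alpha = res$final_alpha,
                             clone_id = res$final_clone),
    long_run_mean_N = if (length(n2)) mean(n2) else 0,
    params = params), class = "population_trace")
}

#' @export
print.population_trace <- function(x, ...) {
  cat(sprintf("Population trace: %d records over %g h (%s/%s)\n",
              length(x$times), max(x$times),
              x$params$topology$kind, x$params$feedback$variant))
  if (x$extinct) cat(sprintf("  EXTINCT at %.1f h\n", x$extinction_time))
  cat(sprintf("  long-run mean N (second half): %.2f\n", x$long_run_mean_N))
  invisible(x)
}

#' @export
as.data.frame.population_trace <- function(x, ...) {
  data.frame(time_h = x$times, N = x$N, mean_alpha = x$mean_alpha,
             D = x$D, renewals = x$renewals,
             differentiations = x$differentiations)
}

#' Run a homeostasis simulation
#'
#' Full agent-based run from `N0` to `t_max` with the configured feedback
#' and fate topology (compiled stepper). The trace records `N`, mean
#' sensitivity, and per-interval renewal/differentiation event counts;
#' `long_run_mean_N` averages `N` over the second half of the run.
#' Extinction ends the run and is flagged on the trace.
#'
#' @param params a [population_params()] object.
#' @return A `population_trace` object.
#' @examples
#' \donttest{
#' pp <- population_params(t_max = 1000, N0 = 50, seed = 1)
#' tr <- run_homeostasis(pp)
#' tr$long_run_mean_N # near the set point of 100
#' }
#' @export
run_homeostasis <- function(params) {
  .make_trace(.run_engine(params, use_D = FALSE), params)
}

#' Run a mutation-invasion experiment
#'
#' Homeostasis run with mis-sensing mutations enabled; tracks the mean
#' sensitivity `alpha(t)` alongside `N(t)` and summarises the surviving
#' clones. Both topologies drift towards under-sensing mutants
#' (`alpha < 1`, larger `N`); the RD topology drifts faster.
#'
#' @param params a [population_params()] with a [mutation_spec()]
#'   (`p_m > 0`).
#' @return A `population_trace` with an extra `clone_summary` element:
#'   `final_mean_alpha`, `final_N`, and the live clone-size table.
#' @export
run_mutation_experiment <- function(params) {
  if (is.null(params$mutation) || !params$mutation$enabled ||
      params$mutation$p_m <= 0)
    stop("run_mutation_experiment needs mutation enabled with p_m > 0",
         call. = FALSE)
  tr <- .make_trace(.run_engine(params, use_D = FALSE), params)
  fs <- tr$final_state
  clone_sizes <- sort(table(fs$clone_id), decreasing = TRUE)
  tr$clone_summary <- list(
    final_mean_alpha = if (nrow(fs)) mean(fs$alpha) else NA_real_,
    final_N = nrow(fs),
    clone_sizes = clone_sizes)
  tr
}

#' Run a two-compartment (differentiated-pool feedback) simulation
#'
#' Stem cells `N` feed a differentiated pool `D` through differentiation
#' events; `D` decays at rate `gamma` and secretes the mitogenic ligand
#' that sets `C` (so `df/dN > 0` through the chain, requiring the DR fate
#' rule for stability). At steady state the compartments couple through
#' `N_s / T_s = gamma * D_s`.
#'
#' @param params a [population_params()] whose feedback variant is
#'   `differentiated_pool`.
#' @return A `population_trace` with an extra `steady_state` element:
#'   long-run means of `N` and `D`, the measured steady-state cycle
#'   length `T_s` (mean age at fate events over the second half, which
#'   exceeds the sharp-timer value `tau_d log 2` when cycle lengths are
#'   dispersed), the stem-to-differentiated flux `N_s / T_s`, and
#'   `gamma * D_s`.
#' @export
run_two_compartment <- function(params) {
  if (params$feedback$variant != "differentiated_pool")
    stop("run_two_compartment needs the differentiated_pool feedback variant",
         call. = FALSE)
  tr <- .make_trace(.run_engine(params, use_D = TRUE), params)
  second <- tr$times >= max(tr$times) / 2
  N_s <- mean(tr$N[second]); D_s <- mean(tr$D[second])
  # measured steady-state cycle length: mean age at fate events
  n_events <- sum(tr$renewals[second] + tr$differentiations[second])
  T_s <- sum(tr$age_at_division_sum[second]) / n_events
  tr$steady_state <- list(N_s = N_s, D_s = D_s, T_s = T_s,
                          T_s_timer = params$topology$timer_mean * log(2),
                          flux_lhs = N_s / T_s,
                          flux_rhs = params$feedback$gamma * D_s)
  tr
}

#' Advance a population state by one step (reference implementation)
#'
#' A plain-R single step of the agent simulation with the same update
#' order and fate semantics as the compiled engine: feedback, one
#' Euler-Maruyama Rb update per cell, ageing, fate clocks, division with
#' renewal/differentiation bookkeeping, and optional daughter mutation.
#' Useful for audits and for stepping small populations interactively;
#' long runs should use [run_homeostasis()].
#'
#' @param state list with vectors `active` (logical), `age`, `r`,
#'   `commitment_time`, `alpha`, `clone_id`, and scalar `D`; see
#'   [new_population_state()].
#' @param params a [population_params()] object.
#' @return List with the updated `state` and `events`
#'   (`renewals`, `differentiations` counts for the step).
#' @export
step_population <- function(state, params) {
  N <- sum(state$active)
  if (N == 0) return(list(state = state, events = list(renewals = 0L,
                                                       differentiations = 0L)))
  rb <- params$rb; topo <- params$topology$kind
  tau_d <- params$topology$timer_mean
  mut <- params$mutation
  use_D <- params$feedback$variant == "differentiated_pool"
  idx <- which(state$active)
  renew_n <- 0L; diff_n <- 0L
  for (i in idx) {
    size <- if (use_D) state$D else N
    C <- feedback_C(max(size, 1), params$feedback, state$alpha[i])
    ri <- state$r[i]
    ri <- ri + rb_drift(ri, C, rb) * params$dt +
      rb$sigma * ri * sqrt(params$dt) * stats::rnorm(1)
    state$r[i] <- max(ri, 0)
    state$age[i] <- state$age[i] + params$dt
    fate <- NULL
    if (topo == "RD" && state$age[i] >= state$commitment_time[i]) {
      fate <- "differentiate"
    } else {
      divides <- state$r[i] < rb$r_thresh ||
        stats::runif(1) < params$dt / params$T_baseline
      if (divides)
        fate <- assign_fate(params$topology, state$age[i],
                            state$commitment_time[i])
    }
    if (is.null(fate)) next
    if (fate == "differentiate") {
      state$active[i] <- FALSE
      diff_n <- diff_n + 1L
      if (use_D) state$D <- state$D + if (topo == "RD") 1 else 2
    } else {
      state$age[i] <- 0; state$r[i] <- rb$r0
      state$commitment_time[i] <- stats::rexp(1, 1 / tau_d)
      slot <- which(!state$active)[1]
      if (is.na(slot)) {
        if (params$on_overflow == "error")
          stop("population exceeded capacity", call. = FALSE)
        grow_by <- length(state$active)
        state$active <- c(state$active, logical(grow_by))
        state$age <- c(state$age, numeric(grow_by))
        state$r <- c(state$r, numeric(grow_by))
        state$commitment_time <- c(state$commitment_time, numeric(grow_by))
        state$alpha <- c(state$alpha, rep(1, grow_by))
        state$clone_id <- c(state$clone_id, integer(grow_by))
        slot <- which(!state$active)[1]
      }
      a_d <- state$alpha[i]; cl_d <- state$clone_id[i]
      if (!is.null(mut) && mut$enabled && stats::runif(1) < mut$p_m) {
        a_d <- max(a_d * exp(stats::rnorm(1, 0, mut$sigma_mut)), mut$alpha_min)
        cl_d <- max(state$clone_id) + 1L
      }
      state$active[slot] <- TRUE
      state$age[slot] <- 0; state$r[slot] <- rb$r0
      state$commitment_time[slot] <- stats::rexp(1, 1 / tau_d)
      state$alpha[slot] <- a_d; state$clone_id[slot] <- cl_d
      renew_n <- renew_n + 1L
    }
  }
  if (use_D) state$D <- state$D - params$feedback$gamma * state$D * params$dt
  list(state = state,
       events = list(renewals = renew_n, differentiations = diff_n))
}

#' Create a fresh population state for [step_population()]
#'
#' @param params a [population_params()] object.
#' @return A state list with `N0` newborn cells.
#' @export
new_population_state <- function(params) {
  cap <- params$capacity
  state <- list(active = logical(cap), age = numeric(cap), r = numeric(cap),
                commitment_time = numeric(cap), alpha = rep(1, cap),
                clone_id = integer(cap), D = params$D0)
  n0 <- params$N0
  state$active[seq_len(n0)] <- TRUE
  state$r[seq_len(n0)] <- params$rb$r0
  state$commitment_time[seq_len(n0)] <-
    stats::rexp(n0, 1 / params$topology$timer_mean)
  state
}
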