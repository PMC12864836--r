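#' Parameters of the stochastic Rb/E2F G1-S switch
#'
#' Container for the single-cell model of active (unphosphorylated) Rb,
#' \deqn{dr = (1 - (\gamma_D + \gamma_P(r, C)) r)\,dt + \sigma r\,dW,}
#' in which Rb is produced at constant (unit) rate and removed by
#' degradation at rate `gamma_D` and by CycD- and feedback-dependent
#' phosphorylation at rate \eqn{\gamma_P(r, C)} (see [gamma_P()]). The
#' CycD activity `C` is the control parameter of the fold bifurcation that
#' gates the G1-S transition: G1 corresponds to the high-`r` state, and a
#' cell is deemed to enter S phase when `r` first drops below `r_thresh`.
#'
#' Defaults are the reference parameterisation used throughout the package:
#' rates are per hour, concentrations in units where the production rate
#' and `k1` are 1.
#'
#' @param gamma_D degradation/dilution rate of active Rb (1/h).
#' @param V maximal Rb phosphorylation rate (1/h).
#' @param k1 saturation scale of CycD activity (concentration units of `C`).
#' @param k2 scale at which Rb feedback suppresses its own phosphorylation
#'   (concentration units of `r`).
#' @param sigma multiplicative noise intensity (1/sqrt(h)).
#' @param r0 active-Rb level at birth of a cell.
#' @param r_thresh G1/S exit threshold on `r`; must be below `r0`.
#' @return An object of class `rb_params`.
#' @examples
#' p <- rb_params()
#' gamma_P(p$k2, p$k1, p) # half-saturation in both factors: V/4
#' @export
rb_params <- function(gamma_D = 1.0, V = 100, k1 = 1.0, k2 = 0.1,
                      sigma = 0.3, r0 = 4.0, r_thresh = 0.05) {
  p <- list(gamma_D = gamma_D, V = V, k1 = k1, k2 = k2,
            sigma = sigma, r0 = r0, r_thresh = r_thresh)
  vals <- unlist(p)
  if (!all(is.finite(vals)))
    stop("all rb_params fields must be finite", call. = FALSE)
  if (any(vals <= 0))
    stop("all rb_params fields must be strictly positive", call. = FALSE)
  if (r_thresh >= r0)
    stop("r_thresh must be below r0", call. = FALSE)
  structure(p, class = "rb_params")
}

#' @export
print.rb_params <- function(x, ...) {
  cat("Rb/E2F switch parameters:\n")
  cat(sprintf("  gamma_D = %g /h, V = %g /h, k1 = %g, k2 = %g\n",
              x$gamma_D, x$V, x$k1, x$k2))
  cat(sprintf("  sigma = %g /sqrt(h), r0 = %g, r_thresh = %g\n",
              x$sigma, x$r0, x$r_thresh))
  invisible(x)
}

#' Rb phosphorylation rate
#'
#' \deqn{\gamma_P(r, C) = V \frac{C}{1 + C/k_1} \frac{1}{1 + (r/k_2)^2}.}
#' Increasing and saturating in CycD activity `C`; decreasing in `r`
#' (cooperative positive feedback of the E2F/CycE cascade, Hill
#' coefficient 2).
#'
#' @param r active-Rb level(s), non-negative.
#' @param C CycD activity (scalar or vector conformable with `r`),
#'   non-negative.
#' @param params an [rb_params()] object.
#' @return Phosphorylation rate (1/h), vectorised over `r` and `C`.
#' @export
gamma_P <- function(r, C, params = rb_params()) {
  if (any(r < 0) || any(C < 0))
    stop("r and C must be non-negative", call. = FALSE)
  params$V * (C / (1 + C / params$k1)) / (1 + (r / params$k2)^2)
}

#' Deterministic drift of the Rb switch
#'
#' The deterministic part of the Rb dynamics,
#' `1 - (gamma_D + gamma_P(r, C)) * r`.
#'
#' @inheritParams gamma_P
#' @return dr/dt (1/h), vectorised.
#' @export
rb_drift <- function(r, C, params = rb_params()) {
  1 - (params$gamma_D + gamma_P(r, C, params)) * r
}

# d(drift)/dr, analytic (used for stability and fold polishing)
rb_drift_dr <- function(r, C, params) {
  u <- (r / params$k2)^2
  Ceff <- C / (1 + C / params$k1)
  gp <- params$V * Ceff / (1 + u)
  dgp <- -params$V * Ceff * (2 * r / params$k2^2) / (1 + u)^2
  -(params$gamma_D + gp) - r * dgp
}

# d(drift)/dC, analytic
rb_drift_dC <- function(r, C, params) {
  dCeff <- 1 / (1 + C / params$k1)^2
  -r * params$V * dCeff / (1 + (r / params$k2)^2)
}

#' Rb/E2F switch activity proxy
#'
#' Maps the active-Rb level to a bounded switch-activity readout,
#' `1 - tanh(r)`, which lies in (0, 1] and decreases with `r`. Low Rb
#' (high activity) corresponds to E2F de-repression and imminent S entry.
#'
#' @param r active-Rb level(s), non-negative.
#' @return Activity in `[0, 1]`, vectorised.
#' @export
activity_proxy <- function(r) {
  if (any(r < 0)) stop("r must be non-negative", call. = FALSE)
  1 - tanh(r)
}

#' Fixed points of the deterministic Rb switch
#'
#' Finds all non-negative roots of `rb_drift(r, C) = 0` by bracketing sign
#' changes of the drift on `(0, 1/gamma_D]` and polishing each with
#' [stats::uniroot()]. Stability is classified by the sign of the analytic
#' derivative of the drift at the root (`"stable"`, `"unstable"`, or
#' `"marginal"` when |d(drift)/dr| < 1e-10).
#'
#' The root count is 1 (monostable), 3 (bistable window), or 2 exactly at
#' a fold; stabilities alternate along the sorted roots.
#'
#' @param C CycD activity, non-negative scalar.
#' @param params an [rb_params()] object.
#' @param n_grid number of bracketing grid points.
#' @return An object of class `fixed_point_set`: list with `C`, `roots`
#'   (sorted ascending) and `stabilities`.
#' @export
find_fixed_points <- function(C, params = rb_params(), n_grid = 4000) {
  if (length(C) != 1 || C < 0) stop("C must be a non-negative scalar", call. = FALSE)
  # drift(0) = 1 > 0 and drift < 0 for r > 1/gamma_D, so all roots lie in
  # (0, 1/gamma_D]; use a log-spaced grid to resolve the low-r root near k2^2
  r_hi <- 1 / params$gamma_D * (1 + 1e-9)
  grid <- sort(unique(c(
    exp(seq(log(params$k2 * 1e-3), log(r_hi), length.out = n_grid)), r_hi)))
  f <- rb_drift(grid, C, params)
  roots <- numeric(0)
  sgn <- sign(f)
  for (i in seq_len(length(grid) - 1)) {
    if (sgn[i] == 0) next
    if (sgn[i] * sgn[i + 1] < 0) {
      rt <- stats::uniroot(function(r) rb_drift(r, C, params),
                           lower = grid[i], upper = grid[i + 1],
                           tol = 1e-12)$root
      roots <- c(roots, rt)
    } else if (sgn[i + 1] == 0) {
      roots <- c(roots, grid[i + 1])
    }
  }
  roots <- sort(unique(roots))
  d <- rb_drift_dr(roots, C, params)
  stab <- ifelse(abs(d) < 1e-10, "marginal", ifelse(d < 0, "stable", "unstable"))
  structure(list(C = C, roots = roots, stabilities = stab),
            class = "fixed_point_set")
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat(sprintf("Fixed points at C = %g:\n", x$C))
  for (i in seq_along(x$roots))
    cat(sprintf("  r = %.6f (%s)\n", x$roots[i], x$stabilities[i]))
  invisible(x)
}

#' Locate the fold (saddle-node) bifurcations of the Rb switch
#'
#' Scans `C` over `C_range` for changes in the fixed-point count
#' (1 <-> 3), brackets each fold by bisection on the root count, and
#' polishes it by solving the two fold conditions `drift = 0` and
#' `d(drift)/dr = 0` simultaneously with a damped Newton iteration.
#'
#' At the upper fold `C_crit_high` the high-`r` (G1) state annihilates
#' with the unstable intermediate state; above it a cell is committed to
#' the G1-S transition. The lower fold `C_crit_low` bounds the bistable
#' window from below.
#'
#' @param params an [rb_params()] object.
#' @param C_range numeric length-2 search interval for `C`.
#' @param tol bisection tolerance on `C` (the Newton polish is much
#'   tighter).
#' @param n_scan number of scan points over `C_range`.
#' @return An object of class `bifurcation_result`: list with `bistable`
#'   (logical), and when bistable `C_crit_low`, `C_crit_high`,
#'   `r_fold_low`, `r_fold_high`. When no fold exists in range, a result
#'   with `bistable = FALSE` (not an error).
#' @examples
#' bf <- find_bifurcation(rb_params())
#' round(bf$C_crit_high, 2) # 0.35
#' @export
find_bifurcation <- function(params = rb_params(), C_range = c(0, 2),
                             tol = 1e-4, n_scan = 201) {
  Cs <- seq(C_range[1], C_range[2], length.out = n_scan)
  counts <- vapply(Cs, function(C) length(find_fixed_points(C, params)$roots),
                   integer(1))
  # transitions between monostable and bistable
  trans <- which(abs(diff(counts)) == 2)
  if (length(trans) == 0) {
    return(structure(list(bistable = FALSE), class = "bifurcation_result"))
  }
  bisect <- function(lo, hi) {
    # invariant: count differs between lo and hi
    n_lo <- length(find_fixed_points(lo, params)$roots)
    while (hi - lo > tol * 0.01) {
      mid <- (lo + hi) / 2
      if (length(find_fixed_points(mid, params)$roots) == n_lo) lo <- mid
      else hi <- mid
    }
    (lo + hi) / 2
  }
  folds <- vapply(trans, function(i) bisect(Cs[i], Cs[i + 1]), numeric(1))
  C_lo <- min(folds); C_hi <- max(folds)

  polish <- function(C_start, which_fold) {
    # seed from just inside the bistable window, at the midpoint of the
    # pair of roots that merge at this fold
    C_in <- if (which_fold == "high") C_start - 2 * tol else C_start + 2 * tol
    fp <- find_fixed_points(C_in, params)
    r <- if (length(fp$roots) == 3) {
      if (which_fold == "high") mean(fp$roots[2:3]) else mean(fp$roots[1:2])
    } else {
      fp$roots[which.min(abs(rb_drift_dr(fp$roots, C_in, params)))]
    }
    C <- C_start
    for (iter in 1:100) {
      F1 <- rb_drift(r, C, params)
      F2 <- rb_drift_dr(r, C, params)
      h <- max(1e-7, 1e-7 * abs(r))
      J11 <- F2
      J12 <- rb_drift_dC(r, C, params)
      J21 <- (rb_drift_dr(r + h, C, params) - rb_drift_dr(r - h, C, params)) / (2 * h)
      J22 <- (rb_drift_dr(r, C + h, params) - rb_drift_dr(r, C - h, params)) / (2 * h)
      det <- J11 * J22 - J12 * J21
      if (!is.finite(det) || abs(det) < 1e-14) break
      dr <- (F1 * J22 - F2 * J12) / det
      dC <- (F2 * J11 - F1 * J21) / det
      step <- 1
      r_new <- r - step * dr; C_new <- C - step * dC
      if (r_new <= 0 || C_new < 0) { r_new <- max(r_new, 1e-6); C_new <- max(C_new, 0) }
      if (abs(dr) < 1e-12 && abs(dC) < 1e-12) { r <- r_new; C <- C_new; break }
      r <- r_new; C <- C_new
    }
    c(r = r, C = C)
  }
  p_lo <- polish(C_lo, "low"); p_hi <- polish(C_hi, "high")
  structure(list(bistable = TRUE,
                 C_crit_low = unname(p_lo["C"]), C_crit_high = unname(p_hi["C"]),
                 r_fold_low = unname(p_lo["r"]), r_fold_high = unname(p_hi["r"])),
            class = "bifurcation_result")
}

#' @export
print.bifurcation_result <- function(x, ...) {
  if (!x$bistable) {
    cat("No bistability in the searched range of C.\n")
  } else {
    cat(sprintf("Fold bifurcations: C_crit_low = %.6f (r = %.6f), C_crit_high = %.6f (r = %.6f)\n",
                x$C_crit_low, x$r_fold_low, x$C_crit_high, x$r_fold_high))
  }
  invisible(x)
}

#' Simulate a single-cell Rb trajectory
#'
#' Euler-Maruyama integration (Ito interpretation) of the stochastic Rb
#' dynamics from `r0`, with noise term `sigma * r * sqrt(dt) * z`,
#' `z ~ N(0,1)`, and post-step clipping `r <- max(r, 0)`. The trajectory
#' stops at the first sample strictly below `r_thresh` (S entry) or at
#' `t_max` (censored); no sub-step interpolation is applied.
#'
#' @param params an [rb_params()] object.
#' @param C CycD activity: a scalar (constant during G1) or a vector with
#'   one value per time step.
#' @param dt time step (h).
#' @param t_max simulation horizon (h).
#' @param seed optional integer seed.
#' @return An object of class `rb_trajectory`: list with `times`, `r`,
#'   `C`, `exited` (logical) and `exit_time` (h; `NA` if censored).
#' @export
simulate_rb <- function(params = rb_params(), C, dt = 0.05, t_max = 100,
                        seed = NULL) {
  if (dt <= 0 || t_max <= 0) stop("dt and t_max must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_step <- ceiling(t_max / dt)
  Cvec <- if (length(C) == 1) rep(C, n_step) else C
  if (length(Cvec) < n_step) stop("per-step C must cover the horizon", call. = FALSE)
  r <- numeric(n_step + 1)
  r[1] <- params$r0
  exited <- FALSE; exit_time <- NA_real_
  z <- stats::rnorm(n_step)
  for (k in seq_len(n_step)) {
    rk <- r[k]
    rk1 <- rk + rb_drift(rk, Cvec[k], params) * dt +
      params$sigma * rk * sqrt(dt) * z[k]
    rk1 <- max(rk1, 0)
    r[k + 1] <- rk1
    if (rk1 < params$r_thresh) {
      exited <- TRUE; exit_time <- k * dt
      r <- r[seq_len(k + 1)]
      break
    }
  }
  times <- seq(0, by = dt, length.out = length(r))
  structure(list(times = times, r = r, C = C, exited = exited,
                 exit_time = exit_time, dt = dt),
            class = "rb_trajectory")
}

#' @export
as.data.frame.rb_trajectory <- function(x, ...) {
  data.frame(time_h = x$times, r = x$r, activity = activity_proxy(x$r))
}

#' @export
print.rb_trajectory <- function(x, ...) {
  cat(sprintf("Rb trajectory: %d samples, dt = %g h, %s\n",
              length(x$times), x$dt,
              if (x$exited) sprintf("S entry at %.2f h", x$exit_time)
              else "censored (no S entry)"))
  invisible(x)
}
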