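#' Mitogen-condition specification
#'
#' One culture condition of the condition-level G1 analysis: a label, a
#' relative Wnt-pathway activity, and the per-cell CycD control-parameter
#' distribution `Normal(C_mean, C_sd^2)` it maps to.
#'
#' @param label condition name.
#' @param wnt_activity relative Wnt activity (dimensionless, relative to
#'   the lowest condition).
#' @param C_mean mean control parameter for the condition.
#' @param C_sd fixed cell-to-cell standard deviation of `C`.
#' @param n_cells number of cells observed/simulated for the condition.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(label, wnt_activity, C_mean, C_sd = 0.05,
                           n_cells = 100) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (C_sd < 0) stop("C_sd must be non-negative", call. = FALSE)
  structure(list(label = label, wnt_activity = wnt_activity,
                 C_mean = C_mean, C_sd = C_sd, n_cells = n_cells),
            class = "condition_spec")
}

#' Default hESC culture conditions
#'
#' The four reference conditions with their per-condition control
#' parameters and sample sizes: mTeSR1 (`C_mean = 0.5`, n = 114), E8 with
#' the Wnt inhibitor IWP2 (`C_mean = 0.6`, n = 105), E8 (`C_mean = 0.7`,
#' n = 112), and mTeSR1 with added Wnt (`C_mean = 1.5`, n = 104);
#' `C_sd = 0.05` throughout. Relative Wnt activities are expressed as
#' `C_mean / 0.5` (the control parameter is taken proportional to Wnt
#' activity, lowest condition = 1).
#'
#' @return List of four [condition_spec()] objects.
#' @export
default_conditions <- function() {
  list(
    condition_spec("mTeSR1",      1.0, 0.5, 0.05, 114),
    condition_spec("E8+IWP2",     1.2, 0.6, 0.05, 105),
    condition_spec("E8",          1.4, 0.7, 0.05, 112),
    condition_spec("mTeSR1+Wnt",  3.0, 1.5, 0.05, 104))
}

#' Map Wnt activity to the control parameter
#'
#' Linear map `C = scale * activity`. When `scale` is omitted it is
#' calibrated so that the critical value `C_crit` falls at 3/4 of the
#' minimal activity in `ref_activities` (the convention used to anchor
#' the bifurcation to the observed activity range); explicit
#' per-condition `C_mean` values override this mapping when available.
#'
#' @param activity relative Wnt activity, non-negative (vectorised).
#' @param scale multiplicative scale, or `NULL` to calibrate.
#' @param C_crit critical control value used for calibration.
#' @param ref_activities activities whose minimum anchors the
#'   calibration.
#' @return Control parameter values.
#' @export
wnt_to_C <- function(activity, scale = NULL, C_crit = 0.35,
                     ref_activities = activity) {
  if (any(activity < 0)) stop("activity must be non-negative", call. = FALSE)
  if (is.null(scale)) scale <- C_crit / (0.75 * min(ref_activities))
  scale * activity
}

#' Simulate G1 lengths for one condition
#'
#' Draws a per-cell control parameter `C ~ Normal(C_mean, C_sd^2)`
#' (clipped at 0, constant through that cell's G1), integrates the
#' stochastic Rb dynamics by Euler-Maruyama, and records the first
#' passage below `r_thresh` as the G1 length; cells not exiting by
#' `t_max` are censored.
#'
#' @param spec a [condition_spec()].
#' @param rb an [rb_params()] object.
#' @param dt time step (h).
#' @param t_max censoring horizon (h).
#' @param seed optional integer seed.
#' @return A data.frame with `g1_hours` (`NA` when censored), `censored`,
#'   and the per-cell `C`.
#' @export
simulate_condition <- function(spec, rb = rb_params(), dt = 0.05,
                               t_max = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_cells
  C <- pmax(stats::rnorm(n, spec$C_mean, spec$C_sd), 0)
  g1 <- .first_passage_ensemble(C, rb, dt, t_max)
  data.frame(g1_hours = g1, censored = is.na(g1), C = C)
}

# vectorised Euler-Maruyama first-passage times for per-cell constant C
.first_passage_ensemble <- function(C, rb, dt, t_max) {
  n <- length(C)
  r <- rep(rb$r0, n)
  t_exit <- rep(NA_real_, n)
  alive <- rep(TRUE, n)
  n_step <- ceiling(t_max / dt)
  sq <- sqrt(dt)
  for (k in seq_len(n_step)) {
    idx <- which(alive)
    if (!length(idx)) break
    ri <- r[idx]
    ri <- ri + rb_drift(ri, C[idx], rb) * dt +
      rb$sigma * ri * sq * stats::rnorm(length(idx))
    ri <- pmax(ri, 0)
    r[idx] <- ri
    done <- ri < rb$r_thresh
    t_exit[idx[done]] <- k * dt
    alive[idx[done]] <- FALSE
  }
  t_exit
}

#' Summary statistics of a G1-length sample
#'
#' Moments (mean, variance, CV) on the uncensored values plus the
#' box-and-whisker statistics: quartiles by linear interpolation between
#' order statistics (quantile type 7) and whiskers at the farthest data
#' points within 1.5 interquartile ranges of the box. Censored cells are
#' excluded from all statistics but counted.
#'
#' @param g1_hours numeric G1 lengths (h); `NA` = censored.
#' @param censored optional logical vector (defaults to `is.na`).
#' @return An object of class `condition_summary`: one-row data.frame
#'   with `mean_g1`, `var_g1`, `cv`, `q1`, `median`, `q3`,
#'   `whisker_low`, `whisker_high`, `n`, `censored_count`.
#' @export
summarize_condition <- function(g1_hours, censored = is.na(g1_hours)) {
  x <- g1_hours[!censored]
  if (length(x) < 4)
    stop("need at least 4 uncensored values", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  in_lo <- x[x >= q[1] - 1.5 * iqr]
  in_hi <- x[x <= q[3] + 1.5 * iqr]
  m <- mean(x); v <- stats::var(x)
  out <- data.frame(mean_g1 = m, var_g1 = v,
                    cv = sqrt(v) / m,
                    q1 = q[1], median = q[2], q3 = q[3],
                    whisker_low = min(in_lo), whisker_high = max(in_hi),
                    n = length(x), censored_count = sum(censored))
  class(out) <- c("condition_summary", class(out))
  out
}

#' Score the bifurcation model against observed condition summaries
#'
#' Coefficients of determination `R^2 = 1 - SS_res / SS_tot` of the
#' model-predicted condition means and variances against the observed
#' ones (unweighted, across conditions), together with the linear
#' baselines: ordinary least-squares regressions of the observed
#' statistic on Wnt activity, whose in-sample `R^2` is the value a
#' linear-in-activity model of G1 length would report.
#'
#' @param model data.frame with one row per condition: `condition`,
#'   `wnt_activity`, `mean_g1`, `var_g1` (model-predicted).
#' @param observed data.frame with the same columns (observed values),
#'   matched by `condition`.
#' @return An object of class `fit_result`: list with `r2_mean`,
#'   `r2_var`, `r2_mean_linear`, `r2_var_linear`, `n_conditions`.
#' @export
fit_r2 <- function(model, observed) {
  m <- merge(observed, model, by = "condition",
             suffixes = c("_obs", "_mod"))
  if (nrow(m) < 3) stop("need at least 3 matched conditions", call. = FALSE)
  r2_of <- function(obs, pred) {
    ss_tot <- sum((obs - mean(obs))^2)
    if (ss_tot == 0) return(NA_real_)  # undefined: no variance to explain
    1 - sum((obs - pred)^2) / ss_tot
  }
  lin_r2 <- function(obs, act) {
    fit <- stats::lm(obs ~ act)
    r2_of(obs, stats::fitted(fit))
  }
  structure(list(
    r2_mean = r2_of(m$mean_g1_obs, m$mean_g1_mod),
    r2_var = r2_of(m$var_g1_obs, m$var_g1_mod),
    r2_mean_linear = lin_r2(m$mean_g1_obs, m$wnt_activity_obs),
    r2_var_linear = lin_r2(m$var_g1_obs, m$wnt_activity_obs),
    n_conditions = nrow(m)), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Bifurcation-model fit across", x$n_conditions, "conditions:\n")
  cat(sprintf("  mean G1:     R2 = %.3f (linear baseline %.3f)\n",
              x$r2_mean, x$r2_mean_linear))
  cat(sprintf("  variance G1: R2 = %.3f (linear baseline %.3f)\n",
              x$r2_var, x$r2_var_linear))
  invisible(x)
}

#' Simulate and summarise a set of conditions
#'
#' Convenience wrapper: [simulate_condition()] then
#' [summarize_condition()] for each spec, assembled into the data.frame
#' layout [fit_r2()] consumes.
#'
#' @param conditions list of [condition_spec()] objects.
#' @param rb an [rb_params()] object.
#' @param dt,t_max integration settings, as in [simulate_condition()].
#' @param seed integer seed (one stream across all conditions).
#' @return data.frame with one row per condition: `condition`,
#'   `wnt_activity`, the summary columns, and `n_censored`.
#' @export
summarize_conditions <- function(conditions, rb = rb_params(), dt = 0.05,
                                 t_max = 100, seed = 1) {
  set.seed(seed)
  rows <- lapply(conditions, function(sp) {
    sim <- simulate_condition(sp, rb, dt, t_max)
    sm <- summarize_condition(sim$g1_hours, sim$censored)
    cbind(data.frame(condition = sp$label, wnt_activity = sp$wnt_activity),
          as.data.frame(sm))
  })
  do.call(rbind, rows)
}
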