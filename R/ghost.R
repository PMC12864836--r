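#' Activity thresholds for ghost-phase decomposition
#'
#' Three thresholds on the switch-activity scale (`1 - tanh(r)`) decompose
#' a G1 trajectory: crossing `active` marks entry into the intermediate
#' (ghost) region, crossing `high` marks its exit, and crossing `s_entry`
#' (by default the activity at the Rb exit threshold) marks S-phase entry.
#'
#' @param active activity level marking the active state (default 0.4).
#' @param high activity level marking exit from the ghost region
#'   (default 0.7).
#' @param s_entry S-entry activity (default `1 - tanh(r_thresh)` for the
#'   reference `r_thresh = 0.05`).
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(active = 0.4, high = 0.7,
                           s_entry = 1 - tanh(0.05)) {
  if (!(active < high && high < s_entry))
    stop("thresholds must satisfy active < high < s_entry", call. = FALSE)
  structure(list(active = active, high = high, s_entry = s_entry),
            class = "threshold_spec")
}

#' Parameters of a ghost-ensemble simulation
#'
#' Non-interacting cells with per-cell CycD activity drawn from
#' `Normal(C_mean, C_sd^2)` (clipped at 0), positioned just above the
#' fold so trajectories traverse the ghost of the annihilated fixed
#' points.
#'
#' @param n_cells ensemble size.
#' @param t_max horizon (h).
#' @param dt time step (h).
#' @param C_mean mean CycD activity (default `C_crit + 0.008` with the
#'   reference `C_crit = 0.35`).
#' @param C_sd cell-to-cell standard deviation of `C`.
#' @param seed integer seed.
#' @return An object of class `ghost_params`.
#' @export
ghost_params <- function(n_cells = 50000, t_max = 100, dt = 0.05,
                         C_mean = 0.35 + 0.008, C_sd = 0.004, seed = 1) {
  structure(list(n_cells = n_cells, t_max = t_max, dt = dt,
                 C_mean = C_mean, C_sd = C_sd, seed = seed),
            class = "ghost_params")
}

#' Simulate a ghost ensemble with online threshold-crossing capture
#'
#' Vectorised Euler-Maruyama integration of the Rb dynamics for
#' `n_cells` independent cells; records the first crossing time of each
#' activity threshold per cell and retains full activity trajectories for
#' the first `keep` cells (storing all of them would be wasteful).
#'
#' @param params a [ghost_params()] object.
#' @param rb an [rb_params()] object.
#' @param thresholds a [threshold_spec()].
#' @param keep number of cells whose full trajectories are retained.
#' @return An object of class `ghost_ensemble`: list with `phases` (a
#'   data.frame from [classify_phases()] applied to every cell),
#'   `times`, `activity` (matrix, time x kept cells), `C` (per-cell
#'   draws), `params`, `thresholds`.
#' @export
simulate_ghost_ensemble <- function(params = ghost_params(),
                                    rb = rb_params(),
                                    thresholds = threshold_spec(),
                                    keep = 200) {
  set.seed(params$seed)
  n <- params$n_cells
  keep <- min(keep, n)
  C <- pmax(stats::rnorm(n, params$C_mean, params$C_sd), 0)
  if (any(C == 0)) message("simulate_ghost_ensemble: negative C draws clipped at 0")
  n_step <- ceiling(params$t_max / params$dt)
  r <- rep(rb$r0, n)
  t_active <- rep(NA_real_, n); t_high <- rep(NA_real_, n)
  t_s <- rep(NA_real_, n)
  traj <- matrix(NA_real_, nrow = n_step + 1, ncol = keep)
  traj[1, ] <- activity_proxy(r[seq_len(keep)])
  sq <- sqrt(params$dt)
  for (k in seq_len(n_step)) {
    r <- r + rb_drift(r, C, rb) * params$dt +
      rb$sigma * r * sq * stats::rnorm(n)
    r <- pmax(r, 0)
    act <- 1 - tanh(r)
    tk <- k * params$dt
    hit <- is.na(t_active) & act >= thresholds$active
    t_active[hit] <- tk
    hit <- is.na(t_high) & act >= thresholds$high
    t_high[hit] <- tk
    hit <- is.na(t_s) & act >= thresholds$s_entry
    t_s[hit] <- tk
    traj[k + 1, ] <- act[seq_len(keep)]
  }
  phases <- data.frame(
    t_active = t_active, t_high = t_high, t_s = t_s,
    phase1 = t_high - t_active, phase2 = t_s - t_high,
    total_g1 = t_s - t_active,
    censored = is.na(t_s))
  structure(list(phases = phases,
                 times = seq(0, by = params$dt, length.out = n_step + 1),
                 activity = traj, C = C, params = params,
                 thresholds = thresholds),
            class = "ghost_ensemble")
}

#' Phase decomposition of a single trajectory
#'
#' First-crossing times of the switch activity above the `active`,
#' `high`, and `s_entry` thresholds, and the derived phase durations:
#' `phase1 = t_high - t_active` (time in the ghost region),
#' `phase2 = t_s - t_high` (final rise), `total_g1 = t_s - t_active`.
#' Thresholds never crossed are `NA` (censored).
#'
#' @param trajectory an `rb_trajectory` (see [simulate_rb()]), or a list
#'   with `times` and either `activity` or `r`.
#' @param thresholds a [threshold_spec()].
#' @return A one-row data.frame with `t_active`, `t_high`, `t_s`,
#'   `phase1`, `phase2`, `total_g1`, `censored`.
#' @export
classify_phases <- function(trajectory, thresholds = threshold_spec()) {
  act <- if (!is.null(trajectory$activity)) trajectory$activity
         else activity_proxy(trajectory$r)
  times <- trajectory$times
  if (length(act) != length(times))
    stop("trajectory activity and times lengths differ", call. = FALSE)
  first_cross <- function(level) {
    i <- which(act >= level)[1]
    if (is.na(i)) NA_real_ else times[i]
  }
  t_active <- first_cross(thresholds$active)
  t_high <- first_cross(thresholds$high)
  t_s <- first_cross(thresholds$s_entry)
  data.frame(t_active = t_active, t_high = t_high, t_s = t_s,
             phase1 = t_high - t_active, phase2 = t_s - t_high,
             total_g1 = t_s - t_active, censored = is.na(t_s))
}

#' Align trajectories to S entry and average within G1-length bins
#'
#' Shifts every non-censored kept trajectory so its S-entry time is
#' `t = 0`, interpolates linearly on the activity scale onto a common
#' grid, and averages within bins of total G1 length (quartile bins by
#' default). Longer-G1 bins display the longer intermediate-activity
#' plateau that is the ghost-state signature. Empty bins are dropped with
#' a warning.
#'
#' @param ensemble a `ghost_ensemble` from [simulate_ghost_ensemble()].
#' @param bin_edges numeric vector of bin edges on total G1 length, or
#'   `NULL` for quartiles of the kept cells.
#' @param grid_len number of points of the common aligned grid.
#' @return List of per-bin results, each with `bin` (label), `n`,
#'   `times` (aligned, 0 = S entry), `mean_activity`, and
#'   `sample_activity` (one representative path).
#' @export
align_and_bin <- function(ensemble, bin_edges = NULL, grid_len = 200) {
  keep <- ncol(ensemble$activity)
  ph <- ensemble$phases[seq_len(keep), ]
  ok <- which(!ph$censored & !is.na(ph$total_g1))
  if (!length(ok)) stop("no complete trajectories to align", call. = FALSE)
  g1 <- ph$total_g1[ok]
  if (is.null(bin_edges))
    bin_edges <- unique(stats::quantile(g1, probs = seq(0, 1, 0.25)))
  bins <- cut(g1, breaks = bin_edges, include.lowest = TRUE)
  t_span <- max(ph$t_s[ok])
  grid <- seq(-t_span, 0, length.out = grid_len)
  out <- list()
  for (lv in levels(bins)) {
    members <- ok[which(bins == lv)]
    if (!length(members)) {
      warning("empty G1-length bin dropped: ", lv)
      next
    }
    curves <- vapply(members, function(j) {
      shifted <- ensemble$times - ph$t_s[j]
      stats::approx(shifted, ensemble$activity[, j], xout = grid,
                    rule = 1)$y
    }, numeric(grid_len))
    out[[lv]] <- list(bin = lv, n = length(members), times = grid,
                      mean_activity = rowMeans(curves, na.rm = TRUE),
                      sample_activity = curves[, 1])
  }
  out
}

#' Inhibitory-perturbation experiment
#'
#' Cells progress at constant `C = C0` until `t_perturb`, when `C` drops
#' by `dC`. Each cell is then classified: `"proceeds"` if its activity
#' crosses the S-entry threshold after the perturbation;
#' `"reverts"` if it never enters S, its activity exceeded 0.5 just
#' before the perturbation, and its mean activity over the final
#' `revert_window` hours is below the active threshold; `"other"`
#' otherwise. Cells in the ghost region at the time of inhibition have
#' not passed an irreversible commitment point and revert to quiescence.
#'
#' @param n_cells number of cells.
#' @param t_max horizon (h).
#' @param dt time step (h).
#' @param C0 pre-perturbation CycD activity (default the critical value).
#' @param dC perturbation magnitude (applied as `C0 + dC`).
#' @param t_perturb perturbation time (h).
#' @param rb an [rb_params()] object.
#' @param thresholds a [threshold_spec()].
#' @param revert_window averaging window (h) at the end of the run for
#'   the quiescence test.
#' @param seed integer seed.
#' @return List with `labels` (per cell), `counts` (table), `times`,
#'   `activity` (matrix time x cells), and the call parameters.
#' @export
perturbation_experiment <- function(n_cells = 100, t_max = 80, dt = 0.05,
                                    C0 = 0.35, dC = -0.1, t_perturb = 15,
                                    rb = rb_params(),
                                    thresholds = threshold_spec(),
                                    revert_window = 5, seed = 1) {
  set.seed(seed)
  n_step <- ceiling(t_max / dt)
  k_pert <- round(t_perturb / dt)
  r <- rep(rb$r0, n_cells)
  act <- matrix(NA_real_, nrow = n_step + 1, ncol = n_cells)
  act[1, ] <- activity_proxy(r)
  sq <- sqrt(dt)
  for (k in seq_len(n_step)) {
    C <- if (k <= k_pert) C0 else max(C0 + dC, 0)
    r <- r + rb_drift(r, C, rb) * dt + rb$sigma * r * sq * stats::rnorm(n_cells)
    r <- pmax(r, 0)
    act[k + 1, ] <- 1 - tanh(r)
  }
  post <- act[(k_pert + 2):(n_step + 1), , drop = FALSE]
  crossed_after <- apply(post >= thresholds$s_entry, 2, any)
  pre_level <- act[k_pert + 1, ]
  tail_rows <- max(1, n_step + 1 - round(revert_window / dt)):(n_step + 1)
  tail_mean <- colMeans(act[tail_rows, , drop = FALSE])
  labels <- ifelse(crossed_after, "proceeds",
                   ifelse(pre_level > 0.5 & tail_mean < thresholds$active,
                          "reverts", "other"))
  list(labels = labels,
       counts = table(factor(labels, levels = c("proceeds", "reverts", "other"))),
       times = seq(0, by = dt, length.out = n_step + 1),
       activity = act, pre_level = pre_level,
       C0 = C0, dC = dC, t_perturb = t_perturb, seed = seed)
}
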