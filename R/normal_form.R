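#' Exact mean delay of the noisy saddle-node normal form
#'
#' Mean first-passage (G1 delay) time of the critical normal form
#' \deqn{dx = (x^2 + \mu)\,dt + \xi\,dW,}
#' given in closed form by
#' \deqn{T(\mu,\xi) = 2^{1/3}\pi^2 \xi^{-2/3}\left(
#'   \mathrm{Ai}^2[-2^{2/3}\xi^{-4/3}\mu] +
#'   \mathrm{Bi}^2[-2^{2/3}\xi^{-4/3}\mu]\right).}
#' `mu` is the rescaled distance from the bifurcation (negative:
#' sub-critical metastable G1; positive: ghost/critical slowing down
#' regime) and `xi` the noise amplitude at the critical point. The
#' evaluation is done in log space ([airy_sq_log()]) so deeply
#' sub-critical delays that overflow double precision are still available
#' via `log = TRUE`.
#'
#' @param mu rescaled distance(s) from the bifurcation (any sign).
#' @param xi noise amplitude, > 0.
#' @param log if `TRUE` return log of the mean delay.
#' @return Mean delay in rescaled time units (or its log), vectorised.
#' @examples
#' mfpt_exact(0, 1) # about 6.27
#' @export
mfpt_exact <- function(mu, xi, log = FALSE) {
  if (any(xi <= 0)) stop("xi must be positive", call. = FALSE)
  arg <- -2^(2 / 3) * xi^(-4 / 3) * mu
  lg <- (1 / 3) * base::log(2) + 2 * base::log(pi) -
    (2 / 3) * base::log(xi) + airy_sq_log(arg)
  if (log) lg else exp(lg)
}

#' Kramers (exponential) approximation to the sub-critical mean delay
#'
#' Escape-time approximation for the double-well potential
#' \eqn{U(x) = -x^3/3 - \mu x} of the normal form, with barrier
#' \eqn{\Delta U = (4/3)|\mu|^{3/2}}:
#' \deqn{T_K = \frac{\pi}{\sqrt{|\mu|}}
#'   \exp\!\left(\frac{8}{3}\frac{|\mu|^{3/2}}{\xi^2}\right).}
#' Valid for `mu < 0` in the deep-barrier regime
#' \eqn{|\mu|^{3/2}/\xi^2 \gg 1}; the prefactor is the standard
#' double-well (curvature) one.
#'
#' @inheritParams mfpt_exact
#' @return Approximate mean delay (or its log), vectorised.
#' @export
mfpt_kramers <- function(mu, xi, log = FALSE) {
  if (any(mu >= 0)) stop("Kramers approximation requires mu < 0", call. = FALSE)
  if (any(xi <= 0)) stop("xi must be positive", call. = FALSE)
  lg <- base::log(pi) - 0.5 * base::log(abs(mu)) +
    (8 / 3) * abs(mu)^1.5 / xi^2
  if (log) lg else exp(lg)
}

# default absorbing boundaries for empirical first-passage runs: wide
# enough that the potential difference to the well/barrier region exceeds
# the noise scale, so truncation bias is below Monte-Carlo noise
.nf_boundary <- function(mu) max(3, 3 * sqrt(abs(mu)))

#' Empirical mean first-passage time of the normal form
#'
#' Euler-Maruyama ensemble estimate of the mean delay of
#' `dx = (x^2 + mu) dt + xi dW` from `x0` to absorption at `x_absorb`.
#' Default boundaries are `-max(3, 3 sqrt(|mu|))` and
#' `+max(3, 3 sqrt(|mu|))`; paths exceeding the time cap (50x the exact
#' prediction by default) are reported as censored, not dropped silently
#' (censored paths contribute their cap time to the mean, biasing it
#' low -- keep the censored count at zero for quantitative use).
#'
#' @inheritParams mfpt_exact
#' @param n number of paths.
#' @param seed optional integer seed.
#' @param dt integration step (rescaled time).
#' @param x0 starting point (default `-max(3, 3 sqrt(|mu|))`).
#' @param x_absorb absorbing boundary (default `+max(3, 3 sqrt(|mu|))`).
#' @param t_cap hard time cap per path (default 50x the exact mean).
#' @return List with `mean`, `se`, `n`, `censored`, `dt`.
#' @export
mfpt_empirical <- function(mu, xi, n = 2000, seed = NULL, dt = 0.01,
                           x0 = NULL, x_absorb = NULL, t_cap = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (is.null(x0)) x0 <- -.nf_boundary(mu)
  if (is.null(x_absorb)) x_absorb <- .nf_boundary(mu)
  if (x0 >= x_absorb) stop("x0 must be below x_absorb", call. = FALSE)
  if (is.null(t_cap)) t_cap <- 50 * mfpt_exact(mu, xi)
  if (!is.null(seed)) set.seed(seed)
  n_step <- ceiling(t_cap / dt)
  x <- rep(x0, n)
  t_exit <- rep(NA_real_, n)
  alive <- rep(TRUE, n)
  sq <- sqrt(dt)
  for (k in seq_len(n_step)) {
    idx <- which(alive)
    if (!length(idx)) break
    xi_ <- x[idx]
    xi_ <- xi_ + (xi_^2 + mu) * dt + xi * sq * stats::rnorm(length(idx))
    x[idx] <- xi_
    done <- xi_ >= x_absorb
    t_exit[idx[done]] <- k * dt
    alive[idx[done]] <- FALSE
  }
  censored <- sum(is.na(t_exit))
  t_eff <- ifelse(is.na(t_exit), n_step * dt, t_exit)
  list(mean = mean(t_eff), se = stats::sd(t_eff) / sqrt(n),
       n = n, censored = censored, dt = dt)
}

#' Scaling exponent of log T against |mu|
#'
#' Least-squares slope of `log(log T)` on `log |mu|` using the exact mean
#' delay, recovering the super-exponential scaling `log T ~ |mu|^{3/2}` in
#' the deep sub-critical regime. When the regime precondition
#' `min |mu|^{3/2} / xi^2 >= 20` is not met, the result carries a warning
#' flag rather than failing.
#'
#' @param xi noise amplitude.
#' @param mu_grid grid of strictly negative `mu` values.
#' @return List with `exponent`, `regime_ok` (logical), `mu_grid`,
#'   `log_T`.
#' @export
scaling_exponent <- function(xi, mu_grid) {
  if (any(mu_grid >= 0)) stop("mu_grid must be strictly negative", call. = FALSE)
  regime_ok <- min(abs(mu_grid)^1.5) / xi^2 >= 20
  lT <- mfpt_exact(mu_grid, xi, log = TRUE)
  fit <- stats::lm(log(lT) ~ log(abs(mu_grid)))
  list(exponent = unname(stats::coef(fit)[2]), regime_ok = regime_ok,
       mu_grid = mu_grid, log_T = lT)
}

#' Simulate the normal form with constant or time-dependent mu
#'
#' Euler-Maruyama ensemble of `dx = (x^2 + mu(t)) dt + xi dW`, supporting
#' the two G1-lengthening regimes: critical lengthening (constant `mu`
#' near 0, heavy-tailed exit times) and time-dependent driving (`mu(t)`
#' ramped through the fold, tightly clustered exit times).
#'
#' @param mu_fn function of time returning `mu`, or a single number for
#'   constant `mu`.
#' @param xi noise amplitude, >= 0 (0 gives deterministic paths).
#' @param dt integration step.
#' @param t_max horizon; paths not absorbed by then are censored (`NA`).
#' @param n number of paths.
#' @param seed optional integer seed.
#' @param x0,x_absorb start and absorbing boundary (defaults as in
#'   [mfpt_empirical()], using `mu(0)` for the scale).
#' @return List with `exit_times` (length `n`, `NA` = censored), `xi`,
#'   `dt`.
#' @export
simulate_normal_form <- function(mu_fn, xi, dt = 0.01, t_max = 500, n = 500,
                                 seed = NULL, x0 = NULL, x_absorb = NULL) {
  if (is.numeric(mu_fn)) {
    mu_const <- mu_fn
    mu_fn <- function(t) mu_const
  }
  mu0 <- mu_fn(0)
  if (is.null(x0)) x0 <- -.nf_boundary(mu0)
  if (is.null(x_absorb)) x_absorb <- .nf_boundary(mu0)
  if (!is.null(seed)) set.seed(seed)
  n_step <- ceiling(t_max / dt)
  x <- rep(x0, n)
  t_exit <- rep(NA_real_, n)
  alive <- rep(TRUE, n)
  sq <- sqrt(dt)
  for (k in seq_len(n_step)) {
    idx <- which(alive)
    if (!length(idx)) break
    mu_k <- mu_fn((k - 1) * dt)
    xv <- x[idx]
    noise <- if (xi > 0) xi * sq * stats::rnorm(length(idx)) else 0
    xv <- xv + (xv^2 + mu_k) * dt + noise
    x[idx] <- xv
    done <- xv >= x_absorb
    t_exit[idx[done]] <- k * dt
    alive[idx[done]] <- FALSE
  }
  list(exit_times = t_exit, xi = xi, dt = dt)
}

#' Local reduction of the Rb switch to the saddle-node normal form
#'
#' Taylor-expands the Rb drift at the upper fold `(r*, C_crit_high)`:
#' with `a = d(drift)/dC` and `b = (1/2) d^2(drift)/dr^2` evaluated at
#' the fold, the substitution `x = b (r - r*)` (time unchanged) maps the
#' local dynamics onto `dx = (x^2 + mu) dt + xi dW` with
#' `mu = a b (C - C_crit)` and `xi = |b| sigma r*`. The coefficients are
#' reported so delay predictions can be mapped between the physical and
#' rescaled frames; with this choice one rescaled time unit is one hour.
#'
#' @param params an [rb_params()] object (a fold must exist).
#' @return An object of class `nf_reduction`: list with `C_crit`,
#'   `r_fold`, `a`, `b`, `mu_per_C` (= `a*b`), `x_scale` (= `b`),
#'   `time_scale` (= 1), `xi_factor` (= `|b| * sigma * r_fold`).
#' @export
reduce_to_normal_form <- function(params = rb_params()) {
  bf <- find_bifurcation(params)
  if (!bf$bistable) stop("no fold: the switch is monostable over the search range",
                         call. = FALSE)
  r_star <- bf$r_fold_high; C_star <- bf$C_crit_high
  a <- rb_drift_dC(r_star, C_star, params)
  h <- 1e-5 * max(1, abs(r_star))
  b <- (rb_drift_dr(r_star + h, C_star, params) -
          rb_drift_dr(r_star - h, C_star, params)) / (2 * h) / 2
  if (!is.finite(b) || abs(b) < 1e-8)
    stop("degenerate fold: quadratic coefficient vanishes", call. = FALSE)
  structure(list(C_crit = C_star, r_fold = r_star, a = a, b = b,
                 mu_per_C = a * b, x_scale = b, time_scale = 1,
                 xi_factor = abs(b) * params$sigma * r_star),
            class = "nf_reduction")
}

#' @export
print.nf_reduction <- function(x, ...) {
  cat(sprintf("Normal-form reduction at fold (r* = %.4f, C_crit = %.4f):\n",
              x$r_fold, x$C_crit))
  cat(sprintf("  a = ddrift/dC = %.4f, b = (1/2) d2drift/dr2 = %.4f\n", x$a, x$b))
  cat(sprintf("  mu = %.4f * (C - C_crit); xi = %.4f; 1 rescaled time unit = %g h\n",
              x$mu_per_C, x$xi_factor, x$time_scale))
  invisible(x)
}
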