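# shared helpers for the test suite

skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  mean((x - m)^3) / stats::sd(x)^3
}

# independent fixed-point oracle: real non-negative roots of the expanded
# cubic gamma_D r (1 + (r/k2)^2) + V Ceff r - (1 + (r/k2)^2) = 0,
# via the generic polynomial solver
polyroot_fixed_points <- function(C, p) {
  Ceff <- C / (1 + C / p$k1)
  co <- c(1, -(p$gamma_D + p$V * Ceff), 1 / p$k2^2, -p$gamma_D / p$k2^2)
  z <- polyroot(co)
  re <- Re(z)[abs(Im(z)) < 1e-8]
  sort(re[re >= 0])
}

# independent algebraic fold oracle for gamma_D = 1: eliminating the
# control parameter from drift = 0 and d(drift)/dr = 0 gives
# k2/(2) * ... reduces to u^{3/2} = (1/(2 k2)) (u - 1) with u = (r/k2)^2;
# the two roots u > 1 are the fold positions r = k2 sqrt(u)
algebraic_folds <- function(k2 = 0.1, V = 100, k1 = 1) {
  g <- function(u) u^1.5 - (u - 1) / (2 * k2)
  u_low <- stats::uniroot(g, c(1 + 1e-9, 3), tol = 1e-12)$root
  u_high <- stats::uniroot(g, c(3, 1e4), tol = 1e-12)$root
  to_fold <- function(u) {
    r <- k2 * sqrt(u)
    Veff <- (1 + u)^2 / (u - 1)        # V * Ceff at the fold
    Ceff <- Veff / V
    list(r = r, C = Ceff / (1 - Ceff / k1))
  }
  list(low = to_fold(u_low), high = to_fold(u_high))
}

# fake trajectory-like object for classify_phases
make_activity_path <- function(times, activity) {
  list(times = times, activity = activity)
}
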