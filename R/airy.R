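# Airy functions Ai and Bi via Bessel-function identities.
#
# Base R ships modified and ordinary Bessel functions but no Airy pair, so
# the standard identities are used:
#   x > 0, zeta = (2/3) x^{3/2}:
#     Ai(x) = (1/pi) sqrt(x/3) K_{1/3}(zeta)
#     Bi(x) = sqrt(x/3) (I_{-1/3}(zeta) + I_{1/3}(zeta))
#   x < 0, z = -x, zeta = (2/3) z^{3/2}:
#     Ai(-z) = (sqrt(z)/3)  (J_{1/3}(zeta) + J_{-1/3}(zeta))
#     Bi(-z) = sqrt(z/3) (J_{-1/3}(zeta) - J_{1/3}(zeta))
# Near 0 the identities lose accuracy (0/0 limits), so the Maclaurin series
# Ai = c1 f - c2 g, Bi = sqrt(3) (c1 f + c2 g) is used for |x| < 1, with
# f, g the two standard series solutions of w'' = x w.
# For x >= .AIRY_LOG_SWITCH the pair is evaluated in log space with
# exponentially scaled Bessel functions, since Bi overflows around x ~ 290
# and Ai underflows long before.

.AIRY_LOG_SWITCH <- 8

.airy_c1 <- 3^(-2 / 3) / gamma(2 / 3)  # Ai(0)
.airy_c2 <- 3^(-1 / 3) / gamma(1 / 3)  # -Ai'(0)

# Maclaurin series f, g for |x| small; converges rapidly for |x| <= 2
.airy_series <- function(x) {
  f <- rep(1, length(x)); g <- x
  tf <- rep(1, length(x)); tg <- x
  for (k in 1:30) {
    tf <- tf * x^3 / ((3 * k) * (3 * k - 1))
    tg <- tg * x^3 / ((3 * k + 1) * (3 * k))
    f <- f + tf; g <- g + tg
    if (all(abs(tf) < 1e-18 & abs(tg) < 1e-18)) break
  }
  list(Ai = .airy_c1 * f - .airy_c2 * g,
       Bi = sqrt(3) * (.airy_c1 * f + .airy_c2 * g))
}

# log Ai and log Bi for x >= 1 via exponentially scaled Bessel functions
.airy_log_pos <- function(x) {
  zeta <- (2 / 3) * x^1.5
  Ks <- besselK(zeta, 1 / 3, expon.scaled = TRUE)
  Im <- besselI(zeta, -1 / 3, expon.scaled = TRUE)
  Ip <- besselI(zeta, 1 / 3, expon.scaled = TRUE)
  list(logAi = log(Ks / pi) + 0.5 * log(x / 3) - zeta,
       logBi = log(Im + Ip) + 0.5 * log(x / 3) + zeta)
}

.airy_neg <- function(x) {
  z <- -x
  zeta <- (2 / 3) * z^1.5
  Jm <- besselJ(zeta, -1 / 3)
  Jp <- besselJ(zeta, 1 / 3)
  list(Ai = sqrt(z) / 3 * (Jp + Jm),
       Bi = sqrt(z / 3) * (Jm - Jp))
}

#' Airy functions of the first and second kind
#'
#' `airy_ai()` and `airy_bi()` evaluate Ai(x) and Bi(x) through Bessel
#' identities and a Maclaurin series near the origin. `Bi` overflows in
#' double precision near `x = 290`; use [airy_sq_log()] for the
#' overflow-safe log of `Ai^2 + Bi^2` needed by [mfpt_exact()].
#'
#' @param x numeric vector.
#' @return Function values, vectorised.
#' @export
airy_ai <- function(x) {
  out <- numeric(length(x))
  lo <- abs(x) < 1
  out[lo] <- .airy_series(x[lo])$Ai
  pos <- x >= 1
  if (any(pos)) out[pos] <- with(.airy_log_pos(x[pos]), exp(logAi))
  neg <- x <= -1
  if (any(neg)) out[neg] <- .airy_neg(x[neg])$Ai
  out
}

#' @rdname airy_ai
#' @export
airy_bi <- function(x) {
  out <- numeric(length(x))
  lo <- abs(x) < 1
  out[lo] <- .airy_series(x[lo])$Bi
  pos <- x >= 1
  if (any(pos)) out[pos] <- with(.airy_log_pos(x[pos]), exp(logBi))
  neg <- x <= -1
  if (any(neg)) out[neg] <- .airy_neg(x[neg])$Bi
  out
}

#' Overflow-safe log of Ai(x)^2 + Bi(x)^2
#'
#' For `x` beyond the log-space switch-over (8), `Bi^2` dominates and the
#' sum is accumulated as `2 log Bi + log1p(exp(2 log Ai - 2 log Bi))` from
#' exponentially scaled Bessel evaluations, so arbitrarily deep
#' sub-critical arguments of the mean-delay formula remain finite on the
#' log scale.
#'
#' @param x numeric vector.
#' @return `log(Ai(x)^2 + Bi(x)^2)`, vectorised.
#' @export
airy_sq_log <- function(x) {
  out <- numeric(length(x))
  big <- x >= .AIRY_LOG_SWITCH
  if (any(big)) {
    lg <- .airy_log_pos(x[big])
    out[big] <- 2 * lg$logBi + log1p(exp(2 * (lg$logAi - lg$logBi)))
  }
  deep <- x <= -2000
  if (any(deep)) {
    # oscillation envelope: Ai(-z)^2 + Bi(-z)^2 -> 1/(pi sqrt(z)), with
    # relative error O(z^{-3/2}); the Bessel route overflows its argument
    # range long before this matters
    out[deep] <- -log(pi) - 0.5 * log(-x[deep])
  }
  mid <- !big & !deep
  if (any(mid)) {
    xs <- x[mid]
    out[mid] <- log(airy_ai(xs)^2 + airy_bi(xs)^2)
  }
  out
}
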