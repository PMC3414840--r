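# Dimensionless kinetic kernels shared by the steady-state and transient
# solvers.
#
# Conventions fixed throughout the package (unit-checked in the tests):
#   * the spring-energy scale sigma multiplies the squared elongation inside
#     every breakage exponential: k_off = exp(beta^2 * sigma * (L - 1)^2)
#     (in units of k0), so it also sits inside the integrand of G;
#   * the matrix stress is alpha/Phi_m dimensionally, i.e. Gamma * alpha in
#     dimensionless form with Gamma = k0 / (Phi_m * E) -- this makes
#     Gamma*alpha the dimensionless matrix stress;
#   * with expansin action the elongation argument (L - 1) is replaced by
#     (L - f0(L)), both in the breakage rate and inside G.

#' Strain-enhanced crosslink breakage rate
#'
#' Dimensionless Bell-type rupture rate of a crosslink of dimensionless
#' length `L >= 1`: `exp(beta^2 * sigma * e(L)^2)` where the elongation
#' `e(L)` is `L - 1`, or `L - f0(L)` under expansin action. The rate is in
#' units of the unstressed breakage rate `k0` and equals 1 iff the
#' elongation is zero.
#'
#' @param L dimensionless crosslink length(s), `>= 1`.
#' @param p a [wall_params()] object.
#' @return Rate(s) `>= 1` (times `breakage_scale`).
#' @examples
#' breakage_rate(11, wall_params(beta = 0.1))  # exp(1)
#' @export
breakage_rate <- function(L, p) {
  p <- as_wall_params(p)
  if (any(!is.finite(L)) || any(L < 1))
    stop("'L' must be >= 1: crosslinks are never compressed in this flow",
         call. = FALSE)
  e <- elongation_of(L, p)
  p$breakage_scale * exp(p$beta^2 * p$sigma * e^2)
}

# Smallest wall coordinate at which the breakage exponent itself is still
# representable: beta^2*sigma*e(1/z)^2 = cutoff. Below this point G is
# numerically infinite (and the survival fraction is identically zero for
# any physically sensible strain rate).
y_overflow_floor <- function(p, cutoff = 700) {
  bs <- p$beta^2 * p$sigma
  h <- function(z) bs * elongation_of(1 / z, p)^2 - cutoff
  lo <- 1e-14
  if (h(lo) <= 0) return(lo)
  stats::uniroot(h, c(lo, 1), tol = 1e-15)$root
}

#' Cumulative breakage exponent G(y)
#'
#' The kernel `G(y) = int_y^1 exp(beta^2*sigma*((1/z) - 1)^2) / z dz`
#' accumulated by a crosslink advected from the inner face (`y = 1`) to
#' wall coordinate `y`; the steady-state survival fraction is
#' `exp(-G(y)/alpha)`. Under expansin action the elongation argument is
#' `(1/z - f0(1/z))`. The quadrature runs on the log-transformed coordinate
#' `u = log z`, where the integrand is simply the breakage exponential.
#'
#' `G` spans hundreds of orders of magnitude as `y` drops through the
#' scission layer (`y` of order `beta`); values beyond the representable
#' range are returned as `Inf`, which downstream code maps to survival 0.
#'
#' @param y wall coordinate(s) in `(0, 1]`.
#' @param p a [wall_params()] object.
#' @param numerics a [wall_numerics()] object, or `NULL` for defaults.
#' @return `G(y)`, same length as `y`; `G(1) = 0`, strictly decreasing
#'   in `y`, and `G(y) >= log(1/y)`.
#' @export
g_integral <- function(y, p, numerics = NULL) {
  p <- as_wall_params(p)
  num <- as_wall_numerics(numerics)
  if (any(!is.finite(y)) || any(y <= 0) || any(y > 1))
    stop("'y' must lie in (0, 1]", call. = FALSE)
  bs <- p$beta^2 * p$sigma
  f_u <- function(u) {
    L <- exp(-u)
    exp(bs * elongation_of(L, p)^2)
  }
  zs <- y_overflow_floor(p)
  ys <- sort(unique(y), decreasing = TRUE)
  G <- numeric(length(ys))
  acc <- 0
  y_hi <- 1
  for (i in seq_along(ys)) {
    yi <- ys[i]
    if (yi >= 1) next
    if (yi < zs || is.infinite(acc)) {
      G[i] <- Inf
      next
    }
    seg <- stats::integrate(f_u, log(yi), log(y_hi), rel.tol = num$rel_tol,
                            abs.tol = 0,
                            subdivisions = num$subdivisions)$value
    acc <- acc + seg
    if (acc > 1e300) acc <- Inf
    G[i] <- acc
    y_hi <- yi
  }
  G[match(y, ys)]
}

#' Asymptotic approximation of G(y) for beta << 1
#'
#' Piecewise small-`beta` limits of [g_integral()]: the outer form
#' `log(1/y)` for `beta << y <= 1` (the integrand is essentially `1/z`
#' until the scission layer) and the inner form
#' `(y^2/(2*beta^2*sigma)) * exp(beta^2*sigma/y^2)` for `0 < y << beta`,
#' where breakage dominates. The branch switches at `y = beta*sqrt(sigma)`.
#'
#' @inheritParams g_integral
#' @return Approximate `G(y)`.
#' @export
g_asymptotic <- function(y, p) {
  p <- as_wall_params(p)
  if (any(!is.finite(y)) || any(y <= 0) || any(y > 1))
    stop("'y' must lie in (0, 1]", call. = FALSE)
  if (p$beta >= 1)
    stop("asymptotic forms require beta < 1", call. = FALSE)
  bs <- p$beta^2 * p$sigma
  inner <- (y^2 / (2 * bs)) * exp(bs / y^2)
  ifelse(y >= p$beta * sqrt(p$sigma), log(1 / y), inner)
}

#' Crosslink survival fraction exp(-G(y)/alpha)
#'
#' Fused evaluation of the steady-state survival fraction. Works in log
#' space: once `breakage_scale * G(y) / alpha` exceeds the underflow cutoff
#' the result is exactly 0, so the enormous dynamic range of `G` near the
#' outer face never overflows.
#'
#' @param y wall coordinate(s) in `(0, 1]`.
#' @param alpha dimensionless strain rate, `> 0`.
#' @inheritParams g_integral
#' @return Survival fraction(s) in `[0, 1]`.
#' @export
survival_fraction <- function(y, alpha, p, numerics = NULL) {
  p <- as_wall_params(p)
  num <- as_wall_numerics(numerics)
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha > 0)
  s <- p$breakage_scale
  if (s == 0) return(rep(1, length(y)))
  G <- g_integral(y, p, num)
  expo <- s * G / alpha
  out <- numeric(length(y))
  ok <- is.finite(expo) & expo <= num$exp_underflow_cutoff
  out[ok] <- exp(-expo[ok])
  out
}

# Wall coordinate below which the survival fraction is numerically zero for
# the given strain rate: solves breakage_scale * G(y) = cutoff * alpha.
# Stress-type quadratures integrate over [y_cutoff, 1] only; below it the
# integrand is the product of an underflowed exponential and 1/y, i.e.
# exactly 0 in double precision.
y_cutoff <- function(alpha, p, num) {
  s <- p$breakage_scale
  if (s == 0) return(num$y_floor)
  target <- num$exp_underflow_cutoff * alpha / s
  zs <- y_overflow_floor(p)
  g_zs <- g_integral(min(zs * 1.000001, 1), p, num)
  if (!is.finite(g_zs) || g_zs <= target) return(max(zs, num$y_floor))
  r <- stats::uniroot(function(y) g_integral(y, p, num) - target,
                      c(zs * 1.000001, 1), tol = 1e-13)
  max(r$root, num$y_floor)
}
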