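# Steady-state crosslink profiles and stress/strain-rate relations.
#
# In steady state every crosslink deposited at the inner face lies on the
# characteristic L = 1/y, so the profile and all stress resultants reduce to
# quadratures over the wall coordinate weighted by the survival fraction
# exp(-G(y)/alpha). XTH enzyme action (additive coupling) multiplies the
# survivor density by y^((g_xeh+g_xet)/alpha) and, for XET, rescales the
# boundary density to 1/(1-A) through re-deposition of cut crosslinks.

# Elongation part of the stress integrand at wall coordinate y (crosslink
# length L = 1/y): (1/y - 1), or (1/y - f0(1/y)) with expansin action.
stress_elongation <- function(y, p) {
  elongation_of(1 / y, p)
}

# Exponent multiplier and survivor power for the current enzyme coupling:
# additive coupling gives n ~ y^(g/alpha) * exp(-s*G/alpha); multiplicative
# coupling gives n ~ exp(-(1+g)*s*G/alpha).
coupling_terms <- function(p) {
  g <- g_total(p)
  if (p$enzyme_coupling == "multiplicative" && g > 0)
    list(exp_scale = 1 + g, w_power = 0)
  else
    list(exp_scale = 1, w_power = g)
}

# Shared quadrature engine for the steady-state integrals. Returns the
# integral over [y_cutoff, 1] of
#   surv(y)^exp_scale * y^(w_power/alpha) * weight(y) * extra(y)
# where surv = exp(-s*G/alpha). 'extra' optionally multiplies in the
# derivative factor used by phi_eff.
steady_quad <- function(alpha, p, num, weight, deriv = FALSE) {
  ct <- coupling_terms(p)
  s <- p$breakage_scale
  w <- ct$w_power / alpha
  # survival underflows once s*G exceeds 700*alpha/exp_scale
  ylo <- y_cutoff(alpha / ct$exp_scale, p, num)
  # strong enzyme at small alpha: y^w confines all mass to a boundary
  # layer of width ~1/w at the inner face; below exp(-60/w) the integrand
  # is < 1e-26 of the layer mass
  if (w > 50) ylo <- max(ylo, exp(-60 / w))
  f <- function(y) {
    G <- g_integral(y, p, num)
    expo <- ct$exp_scale * s * G / alpha
    surv <- ifelse(is.finite(expo) & expo <= num$exp_underflow_cutoff,
                   exp(-expo), 0)
    base <- surv * y^w * weight(y)
    if (!deriv) return(base)
    # d/dalpha of surv * y^(g/alpha):
    #   surv gains a factor exp_scale*s*G/alpha^2,
    #   y^(g/alpha) gains a factor -(g/alpha^2)*log(y).
    dfac <- ifelse(is.finite(G), ct$exp_scale * s * G / alpha^2, 0) -
      (ct$w_power / alpha^2) * log(y)
    base * dfac
  }
  tryCatch(
    stats::integrate(f, ylo, 1, rel.tol = num$rel_tol, abs.tol = 0,
                     subdivisions = num$subdivisions)$value,
    error = function(e) {
      stop(sprintf(paste0("steady-state quadrature failed at alpha = %g ",
                          "(beta = %g, g_xet = %g, g_xeh = %g): %s"),
                   alpha, p$beta, p$g_xet, p$g_xeh, conditionMessage(e)),
           call. = FALSE)
    })
}

# koff-weighted quadrature used by A under multiplicative coupling.
steady_quad_koff <- function(alpha, p, num, deriv = FALSE) {
  ct <- coupling_terms(p)
  s <- p$breakage_scale
  bs <- p$beta^2 * p$sigma
  ylo <- y_cutoff(alpha / ct$exp_scale, p, num)
  f <- function(y) {
    G <- g_integral(y, p, num)
    expo <- ct$exp_scale * s * G / alpha
    surv <- ifelse(is.finite(expo) & expo <= num$exp_underflow_cutoff,
                   exp(-expo), 0)
    koff <- s * exp(pmin(bs * elongation_of(1 / y, p)^2, 700))
    base <- surv * koff
    if (!deriv) return(base)
    base * ifelse(is.finite(G), ct$exp_scale * s * G / alpha^2, 0)
  }
  stats::integrate(f, ylo, 1, rel.tol = num$rel_tol, abs.tol = 0,
                   subdivisions = num$subdivisions)$value
}

#' XET self-consistency coefficient A
#'
#' Fraction-like coefficient generated by XET re-deposition: cut crosslinks
#' are rejoined unstressed at the inner face, raising the boundary density
#' to `1/(1-A)`. For additive coupling
#' `A = (g_xet/alpha) * int_0^1 exp(-G(y)/alpha) y^((g_xeh+g_xet)/alpha) dy`.
#' The steady state is only self-consistent for `0 <= A < 1`; `A >= 1` is
#' reported as a model-validity error.
#'
#' @param alpha dimensionless strain rate, `> 0`.
#' @param p a [wall_params()] object.
#' @param numerics a [wall_numerics()] object, or `NULL` for defaults.
#' @return `A` in `[0, 1)`; 0 when `g_xet = 0`.
#' @export
xet_coefficient_A <- function(alpha, p, numerics = NULL) {
  p <- as_wall_params(p)
  num <- as_wall_numerics(numerics)
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha > 0)
  if (p$g_xet == 0) return(0)
  J <- if (p$enzyme_coupling == "multiplicative")
    steady_quad_koff(alpha, p, num)
  else
    steady_quad(alpha, p, num, weight = function(y) rep(1, length(y)))
  A <- p$g_xet / alpha * J
  if (A >= 1)
    stop(sprintf(paste0("XET self-consistency violated: A = %.6g >= 1 at ",
                        "alpha = %g (beta = %g, g_xet = %g, g_xeh = %g); ",
                        "no steady state of this form exists"),
                 A, alpha, p$beta, p$g_xet, p$g_xeh), call. = FALSE)
  A
}

#' Steady-state crosslink profile across the wall
#'
#' Crosslink density `n(y)`, length `L = 1/y` and stress density
#' `n * (L - 1)` (or `n * (L - f0(L))` with expansin) at each wall
#' coordinate, for a wall elongating steadily at dimensionless rate
#' `alpha`. Without XET, `n(1) = 1` (deposition boundary condition); with
#' XET, `n(1) = 1/(1-A) >= 1`.
#'
#' @inheritParams xet_coefficient_A
#' @param y_grid wall coordinates in `(0, 1]`; defaults to a log-spaced
#'   grid resolving the scission layer.
#' @return An object of class `crosslink_profile` with fields `alpha`,
#'   `y`, `n`, `L`, `stress_density`, `A` and `params`. `n_total`
#'   (the integral of `n` over the wall) is available via [summary()].
#' @export
steady_profile <- function(alpha, p, numerics = NULL, y_grid = NULL) {
  p <- as_wall_params(p)
  num <- as_wall_numerics(numerics)
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha > 0)
  if (is.null(y_grid)) {
    y_min <- max(num$y_floor, min(p$beta / 100, 0.01))
    y_grid <- exp(seq(log(y_min), 0, length.out = num$n_profile))
  }
  if (any(y_grid <= 0) || any(y_grid > 1))
    stop("'y_grid' must lie in (0, 1]", call. = FALSE)
  y_grid <- sort(y_grid)
  ct <- coupling_terms(p)
  A <- xet_coefficient_A(alpha, p, num)
  G <- g_integral(y_grid, p, num)
  expo <- ct$exp_scale * p$breakage_scale * G / alpha
  surv <- ifelse(is.finite(expo) & expo <= num$exp_underflow_cutoff,
                 exp(-expo), 0)
  n <- surv * y_grid^(ct$w_power / alpha) / (1 - A)
  L <- 1 / y_grid
  structure(
    list(alpha = alpha, y = y_grid, n = n, L = L,
         stress_density = n * stress_elongation(y_grid, p),
         A = A, params = p),
    class = "crosslink_profile")
}

#' @export
print.crosslink_profile <- function(x, ...) {
  cat(sprintf("Steady crosslink profile at alpha = %g (beta = %g)\n",
              x$alpha, x$params$beta))
  cat(sprintf("  %d grid points on y in [%.3g, %.3g]; n(1) = %.6g; A = %.4g\n",
              length(x$y), min(x$y), max(x$y), x$n[length(x$n)], x$A))
  invisible(x)
}

#' @export
as.data.frame.crosslink_profile <- function(x, ...) {
  data.frame(y = x$y, n = x$n, L = x$L, stress_density = x$stress_density)
}

#' @export
summary.crosslink_profile <- function(object, ...) {
  # trapezoidal n_tot = int_0^1 n dy (the recoverable total density)
  y <- object$y; n <- object$n
  n_tot <- sum(diff(y) * (n[-1] + n[-length(n)]) / 2)
  list(alpha = object$alpha, A = object$A, n_boundary = n[length(n)],
       n_total = n_tot)
}

#' Steady-state stress resultant
#'
#' Dimensionless axial stress resultant of the steadily elongating wall,
#' `Sigma_inf = int_0^1 n(y) * e(1/y) dy + Gamma*alpha`, where `n` is the
#' steady crosslink profile and `e` the elongation. Covers the no-enzyme,
#' XTH (with the XET boundary factor `1/(1-A)`) and expansin variants; all
#' reduce to the same integral when the enzyme strengths are zero.
#'
#' @param alpha dimensionless strain rate(s), `> 0`.
#' @inheritParams xet_coefficient_A
#' @return `Sigma_inf(alpha)`, same length as `alpha`.
#' @examples
#' p <- wall_params(beta = 0.1)
#' sigma_infinity(10, p)
#' @export
sigma_infinity <- function(alpha, p, numerics = NULL) {
  p <- as_wall_params(p)
  num <- as_wall_numerics(numerics)
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("'alpha' must be positive and finite", call. = FALSE)
  if (p$breakage_scale == 0 && g_total(p) == 0)
    stop("no steady state exists without breakage: the crosslink stress ",
         "grows without bound", call. = FALSE)
  vapply(alpha, function(a) {
    I <- steady_quad(a, p, num, weight = function(y) stress_elongation(y, p))
    if (p$g_xet > 0) I <- I / (1 - xet_coefficient_A(a, p, num))
    I + p$Gamma * a
  }, numeric(1))
}

#' Effective extensibility
#'
#' Dimensionless effective extensibility
#' `Phi_eff = (d Sigma_inf / d alpha)^(-1)`, the reciprocal local slope of
#' the steady stress/strain-rate relation (the dimensional analogue is
#' `Phi_eff* = (E/k0)^(-1)`-scaled). Evaluated by analytic differentiation
#' under the integral sign (`d/dalpha exp(-G/alpha) = exp(-G/alpha)*G/alpha^2`
#' plus the `A(alpha)` and `y^(g/alpha)` terms where applicable) and,
#' optionally, by central finite differences; with `method = "both"`
#' (default) a relative mismatch beyond `phi_check_tol` is a numerical
#' error.
#'
#' @inheritParams sigma_infinity
#' @param method `"both"` (cross-checked, default), `"analytic"` or `"fd"`.
#' @return `Phi_eff(alpha) > 0`, same length as `alpha`. When `Gamma > 0`,
#'   `Phi_eff <= 1/Gamma`.
#' @export
phi_eff <- function(alpha, p, numerics = NULL,
                    method = c("both", "analytic", "fd")) {
  method <- match.arg(method)
  p <- as_wall_params(p)
  num <- as_wall_numerics(numerics)
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("'alpha' must be positive and finite", call. = FALSE)
  vapply(alpha, function(a) {
    an <- if (method != "fd") dsigma_dalpha(a, p, num) else NA_real_
    fd <- if (method != "analytic") {
      h <- 1e-3 * a
      (sigma_infinity(a + h, p, num) - sigma_infinity(a - h, p, num)) / (2 * h)
    } else NA_real_
    if (method == "both") {
      rel <- abs(an - fd) / max(abs(an), abs(fd), .Machine$double.xmin)
      if (!is.finite(rel) || rel > num$phi_check_tol)
        stop(sprintf(paste0("phi_eff evaluation paths disagree at alpha = ",
                            "%g: analytic slope %.8g vs finite-difference ",
                            "%.8g (relative %.2g)"),
                     a, an, fd, rel), call. = FALSE)
    }
    slope <- if (method == "fd") fd else an
    1 / slope
  }, numeric(1))
}

# Analytic d Sigma_inf / d alpha.
dsigma_dalpha <- function(a, p, num) {
  wfun <- function(y) stress_elongation(y, p)
  I0 <- steady_quad(a, p, num, weight = wfun)
  dI <- steady_quad(a, p, num, weight = wfun, deriv = TRUE)
  if (p$g_xet > 0) {
    A <- xet_coefficient_A(a, p, num)
    if (p$enzyme_coupling == "multiplicative") {
      J_d <- steady_quad_koff(a, p, num, deriv = TRUE)
    } else {
      J_d <- steady_quad(a, p, num, weight = function(y) rep(1, length(y)),
                         deriv = TRUE)
    }
    dA <- -A / a + (p$g_xet / a) * J_d
    dI / (1 - A) + I0 * dA / (1 - A)^2 + p$Gamma
  } else {
    dI + p$Gamma
  }
}

#' Strain rate sustaining a given stress
#'
#' Inverts the steady stress/strain-rate relation: finds `alpha` with
#' `Sigma_inf(alpha) = sigma_target` by a bracketing root-finder
#' (derivative-free). Monotonicity of `Sigma_inf` is verified on 16 probe
#' points before solving, and the bracket expands automatically when the
#' target lies outside it (only upward when `Gamma > 0`, since with
#' `Gamma = 0` the crosslink stress saturates at a plateau).
#'
#' @param sigma_target dimensionless stress resultant, `> 0`.
#' @inheritParams xet_coefficient_A
#' @param bracket initial strain-rate bracket.
#' @return The strain rate `alpha` with `Sigma_inf(alpha) = sigma_target`.
#' @examples
#' \donttest{
#' solve_alpha_for_stress(1, wall_params(beta = 0.1))
#' }
#' @export
solve_alpha_for_stress <- function(sigma_target, p, numerics = NULL,
                                   bracket = c(1e-3, 1e6)) {
  p <- as_wall_params(p)
  num <- as_wall_numerics(numerics)
  stopifnot(length(sigma_target) == 1L, is.finite(sigma_target),
            sigma_target > 0, length(bracket) == 2L, all(bracket > 0),
            bracket[1] < bracket[2])
  probes <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = 16))
  sp <- sigma_infinity(probes, p, num)
  if (any(diff(sp) <= 0))
    stop("Sigma_inf is not strictly increasing on the bracket; refusing ",
         "to root-solve", call. = FALSE)
  lo <- bracket[1]; hi <- bracket[2]
  s_lo <- sp[1]; s_hi <- sp[16]
  while (sigma_target < s_lo && lo > 1e-9) {
    lo <- lo / 100; s_lo <- sigma_infinity(lo, p, num)
  }
  while (sigma_target > s_hi) {
    if (p$Gamma == 0 && hi >= 1e9) {
      stop(sprintf(paste0("target stress %.6g exceeds the attainable ",
                          "crosslink plateau (Sigma_inf(%.3g) = %.6g with ",
                          "Gamma = 0)"), sigma_target, hi, s_hi),
           call. = FALSE)
    }
    if (hi >= 1e12) break
    hi <- hi * 100; s_hi <- sigma_infinity(hi, p, num)
  }
  if (sigma_target < s_lo || sigma_target > s_hi)
    stop(sprintf("target stress %.6g outside attainable range [%.6g, %.6g]",
                 sigma_target, s_lo, s_hi), call. = FALSE)
  f <- function(a) sigma_infinity(a, p, num) - sigma_target
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-11 * max(1, hi * 1e-6))$root
  resid <- abs(f(root)) / max(sigma_target, 1e-300)
  if (resid > 10 * sqrt(num$rel_tol))
    warning(sprintf("root residual %.3g larger than expected", resid))
  root
}

#' Steady stress/extensibility curve over a strain-rate grid
#'
#' Row-wise application of [sigma_infinity()] and [phi_eff()] over a sorted
#' positive strain-rate grid. The result records whether `sigma_inf` is
#' strictly increasing across the grid (`attr(, "monotone")`).
#'
#' @param alpha_grid positive, sorted strain rates.
#' @inheritParams xet_coefficient_A
#' @param phi_method differentiation path forwarded to [phi_eff()]
#'   (`"analytic"` by default for speed; the dual-path check is exercised
#'   pointwise via [phi_eff()]).
#' @return A `data.frame` of class `stress_curve` with columns `alpha`,
#'   `sigma_inf`, `phi_eff`, carrying the parameter set as an attribute.
#' @export
stress_curve <- function(alpha_grid, p, numerics = NULL,
                         phi_method = "analytic") {
  p <- as_wall_params(p)
  num <- as_wall_numerics(numerics)
  if (length(alpha_grid) < 1L || any(!is.finite(alpha_grid)) ||
      any(alpha_grid <= 0))
    stop("'alpha_grid' must be positive and finite", call. = FALSE)
  if (is.unsorted(alpha_grid, strictly = TRUE))
    stop("'alpha_grid' must be strictly increasing", call. = FALSE)
  sig <- sigma_infinity(alpha_grid, p, num)
  phi <- phi_eff(alpha_grid, p, num, method = phi_method)
  out <- data.frame(alpha = alpha_grid, sigma_inf = sig, phi_eff = phi)
  attr(out, "params") <- p
  attr(out, "monotone") <- length(alpha_grid) < 2L || all(diff(sig) > 0)
  class(out) <- c("stress_curve", "data.frame")
  out
}

#' @export
print.stress_curve <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(paste0("Steady stress curve: %d strain rates in [%g, %g], ",
                     "beta = %g, Gamma = %g%s\n"),
              nrow(x), min(x$alpha), max(x$alpha), p$beta, p$Gamma,
              if (isTRUE(attr(x, "monotone"))) "" else "  [NOT monotone]"))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
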