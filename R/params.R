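#' Dimensionless model parameters
#'
#' Bundle of the dimensionless parameters governing crosslink kinetics in the
#' elongating wall. Lengths are scaled on the unstressed crosslink length
#' `L0`, times on the unstressed breakage rate `1/k0`, the wall coordinate
#' `y` on the wall thickness `h` (inner face `y = 1`, outer face `y = 0`) and
#' stress resultants on the crosslink stiffness scale `E = n0*kappa*L0*h`.
#'
#' @param beta crosslink extension parameter (0 < beta <= 1). Crosslinks can
#'   stretch by roughly a factor `1/beta` before the rupture rate explodes;
#'   `beta ~ L0/Lmax`.
#' @param sigma spring-energy scale `kappa*L0^2/(2*kbT)`. Of order unity for
#'   an entropic (Gaussian-chain) tether, hence default 1.
#' @param Gamma matrix-to-crosslink extensibility ratio `k0/(Phi_m*E)`
#'   (>= 0). The pectin matrix contributes a purely viscous stress
#'   `Gamma*alpha`.
#' @param g_xet XET action strength (>= 0): rate (in units of `k0`) at which
#'   crosslinks are cut and immediately rejoined unstressed at the inner
#'   face.
#' @param g_xeh XEH action strength (>= 0): additional pure-scission rate in
#'   units of `k0`.
#' @param g_exp expansin action strength (>= 0): controls the increase of a
#'   crosslink's rest length as it elongates, via `rest_length`.
#' @param rest_length rest-length model used when `g_exp > 0`; see
#'   [rest_length_linear()]. Must be a function `f0(L, g)` with
#'   `1 <= f0 <= L`.
#' @param breakage_scale multiplier on the strain-enhanced breakage rate
#'   (default 1). `0` disables breakage entirely, which is useful for
#'   verification against the exact elastic solution `Sigma(t) = alpha*t`.
#' @param enzyme_coupling `"additive"` (default): enzyme scission adds rates
#'   `g_xeh + g_xet` in units of `k0` to the Bell breakage rate.
#'   `"multiplicative"`: enzyme rates multiply the strain-enhanced rate
#'   instead.
#'
#' @details XTH (`g_xet`/`g_xeh`) and expansin (`g_exp`) modes are analysed
#' separately; supplying both in one parameter set is rejected.
#'
#' @return An object of class `wall_params`.
#' @examples
#' p <- wall_params(beta = 0.1)
#' p_xet <- wall_params(beta = 0.1, g_xet = 100)
#' @export
wall_params <- function(beta, sigma = 1, Gamma = 0, g_xet = 0, g_xeh = 0,
                        g_exp = 0, rest_length = rest_length_linear(),
                        breakage_scale = 1,
                        enzyme_coupling = c("additive", "multiplicative")) {
  enzyme_coupling <- match.arg(enzyme_coupling)
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (beta <= 0 || beta > 1)
    stop("'beta' must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive scalar", call. = FALSE)
  if (!is.numeric(Gamma) || length(Gamma) != 1L || Gamma < 0)
    stop("'Gamma' must be >= 0", call. = FALSE)
  for (nm in c("g_xet", "g_xeh", "g_exp")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || !is.finite(v))
      stop(sprintf("'%s' must be a finite scalar >= 0", nm), call. = FALSE)
  }
  if (g_exp > 0 && (g_xet + g_xeh) > 0)
    stop("XTH (g_xet/g_xeh) and expansin (g_exp) modes cannot be combined ",
         "in a single evaluation", call. = FALSE)
  if (!is.function(rest_length))
    stop("'rest_length' must be a function f0(L, g)", call. = FALSE)
  if (breakage_scale < 0)
    stop("'breakage_scale' must be >= 0", call. = FALSE)
  structure(
    list(beta = beta, sigma = sigma, Gamma = Gamma,
         g_xet = g_xet, g_xeh = g_xeh, g_exp = g_exp,
         rest_length = rest_length, breakage_scale = breakage_scale,
         enzyme_coupling = enzyme_coupling),
    class = "wall_params")
}

#' @export
print.wall_params <- function(x, ...) {
  cat("Dimensionless cell-wall crosslink parameters\n")
  cat(sprintf("  beta  = %g   sigma = %g   Gamma = %g\n",
              x$beta, x$sigma, x$Gamma))
  mode <- if (x$g_exp > 0) "expansin"
          else if (x$g_xet + x$g_xeh > 0) "XTH" else "no enzyme"
  cat(sprintf("  enzyme mode: %s (g_xet = %g, g_xeh = %g, g_exp = %g)\n",
              mode, x$g_xet, x$g_xeh, x$g_exp))
  if (x$breakage_scale != 1)
    cat(sprintf("  breakage rate scaled by %g\n", x$breakage_scale))
  if (x$enzyme_coupling != "additive")
    cat(sprintf("  enzyme coupling: %s\n", x$enzyme_coupling))
  invisible(x)
}

#' Linear expansin rest-length model
#'
#' Default form of the rest-length function `f0(L; g)` describing how
#' expansin unpeels crosslink ends from the microfibrils, relaxing the
#' unstressed length of a crosslink of current length `L`:
#' `f0 = 1 + (g/(1+g))*(L-1)`. It satisfies `1 <= f0 <= L`, reduces to
#' `f0 = 1` (no action) at `g = 0` and approaches full relaxation
#' (`f0 -> L`, no elastic stress) as `g -> Inf`. Any function with the same
#' signature and bounds may be substituted.
#'
#' @return A function `f0(L, g)`.
#' @export
rest_length_linear <- function() {
  function(L, g) 1 + (g / (1 + g)) * (L - 1)
}

# Effective elongation of a crosslink of dimensionless length L >= 1:
# L - 1 without expansin, L - f0(L) with expansin action.
elongation_of <- function(L, p) {
  if (p$g_exp > 0) L - p$rest_length(L, p$g_exp) else L - 1
}

# Total enzyme scission strength (XTH mode)
g_total <- function(p) p$g_xet + p$g_xeh

#' Numerical configuration
#'
#' Tolerances and grid sizes used by the quadrature and root-finding
#' routines. The defaults are adequate for all documented analyses.
#'
#' @param rel_tol relative quadrature tolerance.
#' @param exp_underflow_cutoff once the accumulated breakage exponent
#'   `G(y)/alpha` exceeds this value the survival fraction `exp(-G/alpha)`
#'   is treated as exactly zero (700 is just under the `exp()` underflow
#'   bound for doubles).
#' @param y_floor smallest wall coordinate ever evaluated directly.
#' @param phi_check_tol maximum tolerated relative mismatch between the two
#'   evaluation paths of [phi_eff()].
#' @param n_profile,n_curve default grid sizes for crosslink profiles and
#'   stress curves.
#' @param subdivisions maximum quadrature subdivisions.
#' @return An object of class `wall_numerics`.
#' @export
wall_numerics <- function(rel_tol = 1e-10, exp_underflow_cutoff = 700,
                          y_floor = 1e-12, phi_check_tol = 1e-4,
                          n_profile = 200L, n_curve = 50L,
                          subdivisions = 500L) {
  vals <- c(rel_tol = rel_tol, exp_underflow_cutoff = exp_underflow_cutoff,
            y_floor = y_floor, phi_check_tol = phi_check_tol)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all numerical tolerances must be positive and finite",
         call. = FALSE)
  structure(
    list(rel_tol = rel_tol, exp_underflow_cutoff = exp_underflow_cutoff,
         y_floor = y_floor, phi_check_tol = phi_check_tol,
         n_profile = as.integer(n_profile), n_curve = as.integer(n_curve),
         subdivisions = as.integer(subdivisions)),
    class = "wall_numerics")
}

as_wall_params <- function(p) {
  if (!inherits(p, "wall_params"))
    stop("expected a 'wall_params' object; see wall_params()", call. = FALSE)
  p
}

as_wall_numerics <- function(num) {
  if (is.null(num)) return(wall_numerics())
  if (!inherits(num, "wall_numerics"))
    stop("expected a 'wall_numerics' object; see wall_numerics()",
         call. = FALSE)
  num
}
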