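# Mapping between physical wall parameters and the dimensionless model.
#
# Scalings: n* = n0*n, y* = h*y, L* = L0*L, t* = t/k0, alpha* = k0*alpha,
# Sigma* = E*Sigma with E = n0*kappa*L0*h (the crosslink extensional
# stiffness of the wall), sigma = kappa*L0^2/(2*kbT) and
# Gamma = k0/(Phi_m*E). Units are carried as documented SI conventions, not
# enforced by a unit system; check_dimensional() verifies the derived
# groups are finite and positive.

#' Physical wall parameters
#'
#' Dimensional parameter set for a section of elongating cell wall. Any
#' coherent unit system works; SI is the documented convention.
#'
#' @param n0 deposited crosslink number density per unit wall area (1/m^2).
#' @param kappa crosslink spring stiffness (N/m).
#' @param L0 unstressed crosslink length (m; the mean microfibril spacing,
#'   10--20 nm scale).
#' @param h wall thickness (m).
#' @param k0 unstressed crosslink breakage rate (1/s).
#' @param Phi_m pectin-matrix extensibility (strain rate per stress
#'   resultant, 1/(s N/m)); `1/Phi_m = 4*mu*h` for matrix shear viscosity
#'   `mu`.
#' @param kbT thermal energy (J).
#' @param Lmax fully stretched crosslink length (m), `> L0`; sets
#'   `beta = L0/Lmax` unless `beta` is given explicitly.
#' @param beta explicit crosslink extension parameter; overrides `Lmax`.
#' @param R cell radius (m), optional; used by [turgor_to_stress()].
#' @param P turgor pressure (Pa), optional.
#' @return An object of class `dimensional_params`.
#' @seealso [gaussian_chain_stiffness()] for an entropic-spring `kappa`.
#' @export
dimensional_params <- function(n0, kappa, L0, h, k0, Phi_m, kbT,
                               Lmax = NULL, beta = NULL, R = NULL,
                               P = NULL) {
  req <- c(n0 = n0, kappa = kappa, L0 = L0, h = h, k0 = k0, Phi_m = Phi_m,
           kbT = kbT)
  if (any(!is.finite(req)) || any(req <= 0))
    stop("all physical parameters must be positive and finite",
         call. = FALSE)
  if (!is.null(Lmax) && Lmax <= L0)
    stop("'Lmax' must exceed 'L0'", call. = FALSE)
  structure(
    list(n0 = n0, kappa = kappa, L0 = L0, h = h, k0 = k0, Phi_m = Phi_m,
         kbT = kbT, Lmax = Lmax, beta = beta, R = R, P = P),
    class = "dimensional_params")
}

#' @export
print.dimensional_params <- function(x, ...) {
  cat("Physical cell-wall parameters\n")
  cat(sprintf("  n0 = %g, kappa = %g, L0 = %g, h = %g\n",
              x$n0, x$kappa, x$L0, x$h))
  cat(sprintf("  k0 = %g, Phi_m = %g, kbT = %g\n", x$k0, x$Phi_m, x$kbT))
  if (!is.null(x$Lmax)) cat(sprintf("  Lmax = %g\n", x$Lmax))
  if (!is.null(x$beta)) cat(sprintf("  beta (explicit) = %g\n", x$beta))
  invisible(x)
}

#' Entropic (Gaussian-chain) crosslink stiffness
#'
#' Spring constant of a crosslink modelled as a Gaussian chain of `N_k`
#' rigid links of length `b`: `kappa = 3*kbT/(N_k*b^2)`. With this
#' stiffness the spring-energy scale becomes
#' `sigma = 3*L0^2/(2*N_k*b^2)`, of order unity when the unstressed
#' end-to-end length is comparable to `L0`.
#'
#' @param N_k number of chain links.
#' @param b link length (m).
#' @param kbT thermal energy (J).
#' @return `kappa` (N/m).
#' @export
gaussian_chain_stiffness <- function(N_k, b, kbT) {
  stopifnot(N_k > 0, b > 0, kbT > 0)
  3 * kbT / (N_k * b^2)
}

#' Map physical parameters to the dimensionless model
#'
#' Computes the scales `E = n0*kappa*L0*h`, `sigma = kappa*L0^2/(2*kbT)`
#' and `Gamma = k0/(Phi_m*E)`, and `beta` from `L0/Lmax` (or the explicit
#' override). The returned object carries everything needed to invert the
#' map with [dimensionalize()].
#'
#' @param d a [dimensional_params()] object.
#' @param ... further arguments (enzyme strengths etc.) passed to
#'   [wall_params()].
#' @return An object of class `nondim_map`: a list with `params` (a
#'   [wall_params()]) and `scales` (`E`, `k0`, `L0`, `h` plus the raw
#'   physical parameters).
#' @export
nondimensionalize <- function(d, ...) {
  if (!inherits(d, "dimensional_params"))
    stop("expected a 'dimensional_params' object", call. = FALSE)
  beta <- d$beta
  if (is.null(beta)) {
    if (is.null(d$Lmax))
      stop("supply either 'Lmax' or an explicit 'beta': the extension ",
           "parameter must come from one source", call. = FALSE)
    beta <- d$L0 / d$Lmax
  }
  E <- d$n0 * d$kappa * d$L0 * d$h
  sigma <- d$kappa * d$L0^2 / (2 * d$kbT)
  Gamma <- d$k0 / (d$Phi_m * E)
  structure(
    list(params = wall_params(beta = beta, sigma = sigma, Gamma = Gamma,
                              ...),
         scales = list(E = E, k0 = d$k0, L0 = d$L0, h = d$h,
                       n0 = d$n0, kappa = d$kappa, kbT = d$kbT,
                       Phi_m = d$Phi_m, Lmax = d$Lmax, R = d$R, P = d$P)),
    class = "nondim_map")
}

#' @export
print.nondim_map <- function(x, ...) {
  cat("Nondimensionalised wall model\n")
  cat(sprintf("  E = %g (stress-resultant scale), k0 = %g (rate scale)\n",
              x$scales$E, x$scales$k0))
  print(x$params)
  invisible(x)
}

#' Invert the nondimensionalisation
#'
#' Reconstructs the [dimensional_params()] from a [nondimensionalize()]
#' result; `dimensionalize(nondimensionalize(d))` reproduces `d` to
#' machine precision.
#'
#' @param nd a `nondim_map` object.
#' @return A [dimensional_params()] object.
#' @export
dimensionalize <- function(nd) {
  if (!inherits(nd, "nondim_map"))
    stop("expected a 'nondim_map' object from nondimensionalize()",
         call. = FALSE)
  s <- nd$scales
  dimensional_params(n0 = s$n0, kappa = s$kappa, L0 = s$L0, h = s$h,
                     k0 = s$k0, Phi_m = s$Phi_m, kbT = s$kbT,
                     Lmax = s$Lmax,
                     beta = if (is.null(s$Lmax)) nd$params$beta else NULL,
                     R = s$R, P = s$P)
}

# Consistency check of the derived dimensionless groups.
check_dimensional <- function(nd) {
  s <- nd$scales
  groups <- c(E = s$E,
              sigma = nd$params$sigma,
              Gamma_alpha_unit = s$k0 / (s$Phi_m * s$E))
  if (any(!is.finite(groups)) || any(groups < 0))
    stop("derived scale groups are not finite and non-negative",
         call. = FALSE)
  invisible(groups)
}

#' Dimensional steady stress/strain-rate curve
#'
#' Evaluates the steady-state stress resultant at physical strain rates:
#' `Sigma* = E * Sigma_inf(alpha*/k0)`. In the pre-yield range the
#' dimensional effective extensibility is approximately `k0/E`.
#'
#' @param d a [dimensional_params()] object.
#' @param strain_rates physical strain rates (1/s), `> 0`.
#' @param numerics a [wall_numerics()] object, or `NULL`.
#' @param ... passed to [nondimensionalize()].
#' @return A `data.frame` with columns `strain_rate`, `alpha` (the
#'   dimensionless rate), `sigma` (dimensionless) and `sigma_star`
#'   (dimensional stress resultant, N/m in SI).
#' @export
dimensional_curve <- function(d, strain_rates, numerics = NULL, ...) {
  nd <- nondimensionalize(d, ...)
  check_dimensional(nd)
  if (any(strain_rates <= 0))
    stop("'strain_rates' must be positive", call. = FALSE)
  alpha <- strain_rates / nd$scales$k0
  sig <- sigma_infinity(alpha, nd$params, numerics)
  data.frame(strain_rate = strain_rates, alpha = alpha, sigma = sig,
             sigma_star = nd$scales$E * sig)
}

#' Turgor-generated axial stress resultant
#'
#' For a cylindrical cell of radius `R` under turgor pressure `P`, the
#' axial force `pi*R^2*P` distributed over the perimeter `2*pi*R` gives the
#' axial stress resultant `Sigma* = R*P/2` (the hoop stress resultant,
#' borne by the microfibrils, is `R*P`).
#'
#' @param R cell radius (m).
#' @param P turgor pressure (Pa); may be zero.
#' @return Stress resultant `R*P/2` (N/m).
#' @examples
#' turgor_to_stress(10e-6, 0.5e6)  # 2.5 N/m
#' @export
turgor_to_stress <- function(R, P) {
  stopifnot(all(R > 0), all(P >= 0))
  R * P / 2
}
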