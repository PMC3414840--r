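# Closed-form beta << 1 approximations of the steady stress resultant, the
# scission-layer constant C, and Lockhart (Bingham) parameter extraction.
#
# Notation: alpha0 = 1 + g_xet + g_xeh is the enzyme-raised threshold strain
# rate and L_script = log(1/(C*beta)) the logarithmic yield factor. The
# formatting-degraded printed forms are resolved so that all limits are
# mutually consistent (verified in the tests): the pre-yield slope of the
# saturating form is 1/alpha0 + Gamma, and the post-yield reciprocal
# extensibility is 1/Phi_eff ~ 1/alpha0 + Gamma in dimensionless terms.

alpha0_of <- function(p) 1 + p$g_xet + p$g_xeh

#' Scission-layer approximation of the steady stress resultant
#'
#' Closed form obtained from the sharp-scission-layer approximation
#' `exp(-G(y)/alpha) ~ y^(1/alpha)` on `C*beta <= y <= 1` (zero below):
#' with `a0 = 1 + g_xet + g_xeh` and `q = (C*beta)^((a0+alpha)/alpha)`,
#' ```
#' Sigma_inf ~ alpha / (alpha + a0 - g_xet*(1 - q)) *
#'             ((alpha + a0)/a0 * (1 - (C*beta)^(a0/alpha)) + q - 1) +
#'             Gamma*alpha.
#' ```
#' With all enzyme strengths zero this reduces algebraically to the
#' no-enzyme closed form
#' `alpha*(1 - e^(-L/alpha)) + alpha/(alpha+1)*(e^(-L*(alpha+1)/alpha) - 1)
#'  + Gamma*alpha` with `L = log(1/(C*beta))`.
#'
#' @param alpha dimensionless strain rate(s), `> 0`.
#' @param p a [wall_params()] object (XTH mode or no enzyme).
#' @param C scission-layer constant, `O(1)`, with `0 < C*beta < 1`.
#' @return Approximate `Sigma_inf(alpha)`.
#' @export
sigma_approx_full <- function(alpha, p, C) {
  p <- as_wall_params(p)
  stopifnot(all(alpha > 0), length(C) == 1L, C > 0)
  cb <- C * p$beta
  if (cb <= 0 || cb >= 1)
    stop("'C*beta' must lie in (0, 1)", call. = FALSE)
  if (p$g_exp > 0)
    stop("scission-layer closed form applies to the XTH/no-enzyme model",
         call. = FALSE)
  a0 <- alpha0_of(p)
  q <- cb^((a0 + alpha) / alpha)
  alpha / (alpha + a0 - p$g_xet * (1 - q)) *
    ((alpha + a0) / a0 * (1 - cb^(a0 / alpha)) + q - 1) +
    p$Gamma * alpha
}

#' Limiting saturating and strong-enzyme stress forms
#'
#' Leading-order limits of [sigma_approx_full()] for large
#' `L = log(1/(C*beta))`:
#' * `form = "saturating"`:
#'   `Sigma_inf ~ (alpha/a0)*(1 - e^(-L*a0/alpha)) + Gamma*alpha`
#'   (the no-enzyme case is `a0 = 1`), which interpolates the
#'   piecewise-linear Lockhart limits `Sigma ~ (1/a0 + Gamma)*alpha` for
#'   `1 << alpha << a0*L` and `Sigma ~ L + Gamma*alpha` for
#'   `alpha >> a0*L`;
#' * `form = "strong_enzyme"`: low-strain-rate form for strong enzyme
#'   action, `Sigma_inf ~ alpha^2/(a0*(alpha + 1 + g_xeh)) + Gamma*alpha`,
#'   showing the quadratic-to-linear transition at
#'   `alpha = O(1 + g_xeh)`.
#'
#' @inheritParams sigma_approx_full
#' @param L_script logarithmic yield factor `log(1/(C*beta))`, `> 0`.
#' @param form which limit to evaluate.
#' @return Approximate `Sigma_inf(alpha)`.
#' @export
sigma_approx_limit <- function(alpha, p, L_script,
                               form = c("saturating", "strong_enzyme")) {
  form <- match.arg(form)
  p <- as_wall_params(p)
  stopifnot(all(alpha > 0), length(L_script) == 1L, L_script > 0)
  a0 <- alpha0_of(p)
  if (form == "saturating")
    alpha / a0 * (1 - exp(-L_script * a0 / alpha)) + p$Gamma * alpha
  else
    alpha^2 / (a0 * (alpha + 1 + p$g_xeh)) + p$Gamma * alpha
}

#' Fit the scission-layer constant C
#'
#' Chooses `C` so that [sigma_approx_full()] best matches the full
#' quadrature [sigma_infinity()] over a strain-rate grid, minimising the
#' sum of squared log-residuals (both stress and strain rate span decades).
#' `C` is expected to be `O(1)`; a fitted value outside `(0.1, 10)` is
#' returned with a warning.
#'
#' @param p a [wall_params()] object with `beta <= 0.1` (the approximation
#'   is a small-`beta` construction).
#' @param numerics a [wall_numerics()] object, or `NULL`.
#' @param alpha_fit_grid strain rates used in the fit.
#' @return A list with `C`, `L_script = log(1/(C*beta))` and `rms` (root
#'   mean squared log-residual).
#' @export
fit_C <- function(p, numerics = NULL,
                  alpha_fit_grid = exp(seq(log(1), log(100),
                                           length.out = 25))) {
  p <- as_wall_params(p)
  num <- as_wall_numerics(numerics)
  if (p$beta > 0.1)
    stop("fit_C requires beta <= 0.1", call. = FALSE)
  target <- log(sigma_infinity(alpha_fit_grid, p, num))
  obj <- function(logC) {
    r <- log(sigma_approx_full(alpha_fit_grid, p, exp(logC))) - target
    sum(r^2)
  }
  opt <- stats::optimize(obj, interval = log(c(0.01, min(100, 0.99 / p$beta))),
                         tol = 1e-10)
  C <- exp(opt$minimum)
  if (C <= 0.1 || C >= 10)
    warning(sprintf(paste0("fitted scission-layer constant C = %.4g is ",
                           "outside the expected O(1) range (0.1, 10)"), C))
  list(C = C, L_script = log(1 / (C * p$beta)),
       rms = sqrt(opt$objective / length(alpha_fit_grid)))
}

#' Extract Lockhart (Bingham) parameters from a stress curve
#'
#' Linear regression `Sigma_inf = Y_eff + alpha / phi_post` over the
#' post-yield range of a [stress_curve()]: the intercept is the effective
#' dimensionless yield stress (expected `~ L_script`, i.e. dimensionally
#' `Y ~ E*log(1/(C*beta))`) and the reciprocal slope the post-yield
#' extensibility (expected `~ 1/Gamma`, i.e. matrix-dominated, when
#' `Gamma > 0`). The default fit range is `alpha` in
#' `[5*L_est, 50*L_est]` with `L_est` from [fit_C()]; non-monotone curves
#' are refused.
#'
#' @param curve a [stress_curve()] (or any data frame with columns `alpha`
#'   and `sigma_inf`, in which case `fit_range` must be given).
#' @param numerics a [wall_numerics()] object, or `NULL`.
#' @param fit_range length-2 numeric: strain-rate interval for the linear
#'   fit. Defaults to the rule above.
#' @return An object of class `lockhart_fit`: a list with `Y_eff`,
#'   `phi_post`, `fit_range`, `rms_residual`, `L_script`, `C` and
#'   `n_points`.
#' @export
lockhart_extract <- function(curve, numerics = NULL, fit_range = NULL) {
  num <- as_wall_numerics(numerics)
  if (!all(c("alpha", "sigma_inf") %in% names(curve)))
    stop("'curve' must have columns 'alpha' and 'sigma_inf'", call. = FALSE)
  if (any(diff(curve$sigma_inf) <= 0))
    stop("non-monotone stress curve: fit refused", call. = FALSE)
  C <- NA_real_; L_est <- NA_real_
  if (is.null(fit_range)) {
    p <- attr(curve, "params")
    if (is.null(p))
      stop("'fit_range' must be supplied for curves without attached ",
           "parameters", call. = FALSE)
    fC <- fit_C(p, num)
    C <- fC$C; L_est <- fC$L_script
    lower <- 5 * L_est
    # with a viscous matrix the crosslink plateau still carries slope
    # ~ (L/alpha)^2/2 at alpha = 5L; push the window out until that
    # residual slope is below Gamma/5, so the fitted extensibility is
    # genuinely matrix-dominated
    if (!is.null(p$Gamma) && p$Gamma > 0)
      lower <- max(lower, L_est / sqrt(0.4 * p$Gamma))
    fit_range <- c(lower, 10 * lower)
  }
  sel <- curve$alpha >= fit_range[1] & curve$alpha <= fit_range[2]
  if (sum(sel) < 2L)
    stop(sprintf(paste0("stress curve has %d points in the post-yield fit ",
                        "range [%.3g, %.3g]; need at least 2"),
                 sum(sel), fit_range[1], fit_range[2]), call. = FALSE)
  fit <- stats::lm(sigma_inf ~ alpha, data = as.data.frame(curve)[sel, ])
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0)
    stop("post-yield slope is not positive; fit refused", call. = FALSE)
  structure(
    list(Y_eff = unname(stats::coef(fit)[1]), phi_post = 1 / slope,
         fit_range = fit_range,
         rms_residual = sqrt(mean(stats::resid(fit)^2)),
         L_script = L_est, C = C, n_points = sum(sel)),
    class = "lockhart_fit")
}

#' @export
print.lockhart_fit <- function(x, ...) {
  cat("Lockhart (Bingham) fit of the post-yield stress curve\n")
  cat(sprintf("  yield stress   Y_eff    = %.6g\n", x$Y_eff))
  cat(sprintf("  extensibility  phi_post = %.6g\n", x$phi_post))
  cat(sprintf("  fit range alpha in [%.4g, %.4g] (%d points), rms %.3g\n",
              x$fit_range[1], x$fit_range[2], x$n_points, x$rms_residual))
  if (is.finite(x$L_script))
    cat(sprintf("  scission-layer fit: C = %.4g, L = log(1/(C*beta)) = %.4g\n",
                x$C, x$L_script))
  invisible(x)
}

#' @export
format.lockhart_fit <- function(x, ...) {
  jsonlite::toJSON(
    x[c("Y_eff", "phi_post", "fit_range", "rms_residual", "L_script", "C",
        "n_points")],
    auto_unbox = TRUE, digits = NA, na = "null")
}
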