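# Time-dependent stress under constant strain rate, from an initially
# unstressed wall. The solution along characteristics splits into the
# crosslinks present at t = 0 (confined to y < e^(-alpha*t), all with length
# e^(alpha*t)) and those deposited at the inner face in t > 0 (on L = 1/y in
# e^(-alpha*t) <= y <= 1):
#   Sigma(t) = exp(-G(e^(-alpha*t))/alpha) * (1 - e^(-alpha*t))
#            + int_{e^(-alpha*t)}^1 exp(-G(y)/alpha) (1/y - 1) dy
#            + Gamma * alpha.
# Enzyme analysis is steady-state only, so all transient entry points
# reject parameter sets with nonzero enzyme strengths.

check_no_enzyme <- function(p) {
  if (g_total(p) > 0 || p$g_exp > 0)
    stop("transient analysis supports the enzyme-free model only",
         call. = FALSE)
}

#' Transient stress resultant under constant strain rate
#'
#' Stress resultant `Sigma(t)` of a wall that is unstressed for `t < 0` and
#' stretched at constant dimensionless rate `alpha` for `t > 0`. The stress
#' rises elastically (initial dimensionless stiffness 1, i.e. dimensional
#' stiffness `E`), generally overshoots, and relaxes to the steady value
#' [sigma_infinity()] once the initially present crosslinks have been
#' carried into the scission layer, i.e. for
#' `t >> (1/alpha) * log(1/beta)`.
#'
#' @param t dimensionless time(s) `>= 0` (in units of `1/k0`).
#' @param alpha dimensionless strain rate, `> 0`.
#' @param p a [wall_params()] object with all enzyme strengths zero.
#' @param numerics a [wall_numerics()] object, or `NULL` for defaults.
#' @return `Sigma(t)`, same length as `t`; `Sigma(0) = Gamma*alpha`.
#' @examples
#' p <- wall_params(beta = 0.1)
#' sigma_transient(c(0, 0.2, 2), alpha = 5, p)
#' @export
sigma_transient <- function(t, alpha, p, numerics = NULL) {
  p <- as_wall_params(p)
  num <- as_wall_numerics(numerics)
  check_no_enzyme(p)
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha > 0)
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be >= 0", call. = FALSE)
  vapply(t, function(ti) {
    sum(transient_parts(ti, alpha, p, num)) + p$Gamma * alpha
  }, numeric(1))
}

# The two crosslink contributions (initial cohort, deposited cohort) of the
# transient stress; exposed separately for the region-partition invariant.
transient_parts <- function(ti, alpha, p, num) {
  ym <- exp(-alpha * ti)
  initial <- survival_fraction(ym, alpha, p, num) * (1 - ym)
  ycut <- y_cutoff(alpha, p, num)
  lower <- max(ym, ycut)
  deposited <- if (lower >= 1) 0 else {
    f <- function(y) {
      survival_fraction(y, alpha, p, num) * (1 / y - 1)
    }
    stats::integrate(f, lower, 1, rel.tol = num$rel_tol, abs.tol = 0,
                     subdivisions = num$subdivisions)$value
  }
  c(initial = initial, deposited = deposited)
}

#' Small-stretch expansion of the transient stress
#'
#' Leading-order expansion `Sigma ~ alpha*t - (alpha*t)^2/alpha`, valid for
#' log-stretch `alpha*t << log(1/beta)` (before the initially present
#' crosslinks reach the scission layer): linear elasticity followed by
#' strain softening.
#'
#' @param alpha_t log-stretch value(s) `alpha * t >= 0`.
#' @param alpha dimensionless strain rate.
#' @return Approximate crosslink stress resultant.
#' @export
small_stretch_expansion <- function(alpha_t, alpha) {
  stopifnot(all(alpha_t >= 0), length(alpha) == 1L, alpha > 0)
  alpha_t - alpha_t^2 / alpha
}

#' Transient yield point (stress overshoot)
#'
#' Locates the maximum of the crosslink part of the transient stress over
#' log-stretch `alpha*t` in `(0, 3*log(1/beta)]` -- the transient yield
#' measure. The peak log-stretch is the yield strain measure; it grows with
#' strain rate for small `alpha` and saturates for large `alpha`. A coarse
#' scan is refined by golden-section search ([stats::optimize()]); if no
#' interior maximum exists the boundary is reported with
#' `peak_found = FALSE` rather than a spurious peak. The matrix offset
#' `Gamma*alpha` is constant in time and excluded from the search; the peak
#' total stress is reported alongside.
#'
#' @inheritParams sigma_transient
#' @param n_scan number of coarse-scan points.
#' @return A list with `alpha_t_peak`, `sigma_peak` (crosslink part),
#'   `sigma_peak_total`, `sigma_steady` and `peak_found`.
#' @export
yield_strain <- function(alpha, p, numerics = NULL, n_scan = 200L) {
  p <- as_wall_params(p)
  num <- as_wall_numerics(numerics)
  check_no_enzyme(p)
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha > 0)
  at_max <- 3 * log(1 / p$beta)
  at_grid <- seq(at_max / n_scan, at_max, length.out = n_scan)
  cross <- function(at) sigma_transient(at / alpha, alpha, p, num) -
    p$Gamma * alpha
  vals <- vapply(at_grid, cross, numeric(1))
  i <- which.max(vals)
  if (i == 1L || i == n_scan) {
    return(list(alpha_t_peak = at_grid[i], sigma_peak = vals[i],
                sigma_peak_total = vals[i] + p$Gamma * alpha,
                sigma_steady = sigma_infinity(alpha, p, num),
                peak_found = FALSE))
  }
  opt <- stats::optimize(cross, lower = at_grid[i - 1L],
                         upper = at_grid[i + 1L], maximum = TRUE,
                         tol = 1e-8)
  list(alpha_t_peak = opt$maximum, sigma_peak = opt$objective,
       sigma_peak_total = opt$objective + p$Gamma * alpha,
       sigma_steady = sigma_infinity(alpha, p, num),
       peak_found = TRUE)
}

#' Transient stress trace
#'
#' Samples `Sigma(t)` on a log-spaced grid of log-stretch
#' `alpha*t` in `[1e-3, 3*log(1/beta) + 5]` (resolving both the
#' linear-elastic rise and the relaxation tail) and attaches the overshoot
#' summary and steady-state limit.
#'
#' @inheritParams sigma_transient
#' @param t_grid dimensionless times; defaults to the log-spaced grid above.
#' @param n_t number of default grid points.
#' @return A `data.frame` of class `transient_trace` with columns `t`,
#'   `alpha_t`, `sigma_crosslink`, `sigma_total`; attributes `params`,
#'   `alpha`, `peak` (from [yield_strain()]) and `sigma_steady`.
#' @export
transient_trace <- function(alpha, p, numerics = NULL, t_grid = NULL,
                            n_t = 400L) {
  p <- as_wall_params(p)
  num <- as_wall_numerics(numerics)
  check_no_enzyme(p)
  if (is.null(t_grid)) {
    at <- exp(seq(log(1e-3), log(3 * log(1 / p$beta) + 5),
                  length.out = n_t))
    t_grid <- at / alpha
  }
  t_grid <- sort(t_grid)
  sig <- sigma_transient(t_grid, alpha, p, num)
  out <- data.frame(t = t_grid, alpha_t = alpha * t_grid,
                    sigma_crosslink = sig - p$Gamma * alpha,
                    sigma_total = sig)
  attr(out, "params") <- p
  attr(out, "alpha") <- alpha
  attr(out, "peak") <- yield_strain(alpha, p, num)
  attr(out, "sigma_steady") <- sigma_infinity(alpha, p, num)
  class(out) <- c("transient_trace", "data.frame")
  out
}

#' @export
print.transient_trace <- function(x, ...) {
  pk <- attr(x, "peak")
  cat(sprintf(paste0("Transient stress trace at alpha = %g (beta = %g): ",
                     "%d times\n"),
              attr(x, "alpha"), attr(x, "params")$beta, nrow(x)))
  cat(sprintf("  peak Sigma = %.6g at alpha*t = %.4g%s; steady Sigma = %.6g\n",
              pk$sigma_peak_total, pk$alpha_t_peak,
              if (pk$peak_found) "" else " (boundary, no interior peak)",
              attr(x, "sigma_steady")))
  invisible(x)
}
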