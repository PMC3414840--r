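# Independent verification engines used by the test suite: a stochastic
# discrete-crosslink ensemble and a direct ODE integration along a
# characteristic. Neither shares quadrature code with the closed-form
# solvers they validate.

#' Stochastic discrete-crosslink ensemble simulation
#'
#' Agent-level realisation of the crosslink advection/rupture kinetics: each
#' particle carries a wall position `y`, length `L` and weight `w`
#' representing its contribution to the line density measure `n(y) dy`. Per
#' step of size `dt`, positions advect (`y <- y*exp(-alpha*dt)`), lengths
#' stretch (`L <- L*exp(alpha*dt)`), weights decay by the same factor (the
#' wall also stretches axially, diluting the per-unit-length count), and
#' particles rupture with probability `1 - exp(-I)` where `I` is the
#' integrated Bell-rate hazard over the step (Simpson's rule along the
#' characteristic). New unstressed particles are deposited at the inner
#' face at the deterministic expected rate (fractional counts accumulated
#' across steps; optionally Poisson), stratified over the within-step
#' deposition band so the elastic limit is reproduced exactly. Crosslinks
#' cut by XET action are immediately re-deposited unstressed at the inner
#' face.
#'
#' The ensemble-mean dimensionless stress `sum(w*(L-1))/n_links` converges
#' to [sigma_transient()] / [sigma_infinity()] as `n_links` grows; with
#' `breakage_scale = 0` it equals `alpha*t` exactly (no sampling error:
#' rupture is the only stochastic element). Runs are bit-reproducible for
#' a fixed `(seed, dt)`.
#'
#' @param alpha dimensionless strain rate, `> 0`.
#' @param p a [wall_params()] object (no expansin mode).
#' @param n_links initial particle count (also the deposition density).
#' @param t_end end time; default `(3*log(1/beta) + 10)/alpha`, well past
#'   equilibration.
#' @param dt time step; default `0.02/alpha` so lengths grow 2% per step.
#'   Halved adaptively (up to 10 times) if the step hazard of any particle
#'   still in the statistically relevant band (integrated hazard < 30)
#'   exceeds 0.1; particles beyond hazard 30 die almost surely and do not
#'   constrain the step.
#' @param seed RNG seed (the caller's RNG state is preserved). Replicate
#'   `i` uses `seed + i - 1`.
#' @param sample_every record the stress every this many steps.
#' @param equil_frac fraction of `t_end` treated as equilibration when
#'   averaging the steady tail.
#' @param n_replicates independent replicate runs. The steady estimate is
#'   the mean of the replicate tail means; with several replicates the
#'   standard error comes from their scatter (statistically independent),
#'   otherwise from batch means over the single tail (which are serially
#'   correlated, so multiple replicates are preferred for calibrated
#'   errors).
#' @param poisson_deposition draw per-step deposition counts from a Poisson
#'   distribution instead of the low-variance deterministic rule.
#' @param deposition set `FALSE` to switch off deposition at the inner
#'   face entirely (pure death process; useful for verification).
#' @return A list: `trace` (data frame `t`, `sigma` -- crosslink part plus
#'   `Gamma*alpha` -- of the first replicate), `steady_estimate`,
#'   `steady_se`, `final_state` (data frame `y`, `L`, `w` of the first
#'   replicate), and the settings used.
#' @export
simulate_ensemble <- function(alpha, p, n_links = 10000L, t_end = NULL,
                              dt = NULL, seed = 1L, sample_every = 5L,
                              equil_frac = 0.6, n_replicates = 1L,
                              poisson_deposition = FALSE,
                              deposition = TRUE) {
  p <- as_wall_params(p)
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha > 0, n_links >= 10)
  if (p$g_exp > 0)
    stop("ensemble oracle does not implement expansin mode", call. = FALSE)
  if (is.null(t_end)) t_end <- (3 * log(1 / p$beta) + 10) / alpha
  if (is.null(dt)) dt <- 0.02 / alpha
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)

  bs <- p$beta^2 * p$sigma
  s <- p$breakage_scale
  g_enz <- g_total(p)
  koff <- function(L) s * exp(pmin(bs * (L - 1)^2, 700))
  hazard_cap <- 30  # beyond this survival < 1e-13: certain death

  # Adaptive dt: the per-step survival uses Simpson's rule for the
  # integrated hazard, which is accurate provided log(koff) varies little
  # across a step for particles whose fate is genuinely random (integrated
  # hazard below hazard_cap; longer particles die almost surely and do not
  # constrain the step). The stochastically relevant lengths are where the
  # hazard rate balances the strain rate, bs*(L-1)^2 ~ log(alpha) + O(1).
  n_halve <- 0
  if (s > 0) {
    L_death <- 1 + sqrt((log(max(alpha, 1)) + 3) / bs)
    growth <- function(dtt) 2 * bs * (L_death - 1) * L_death * alpha * dtt
    while (growth(dt) > 0.12 && n_halve < 10) {
      dt <- dt / 2
      n_halve <- n_halve + 1
    }
    if (growth(dt) > 0.12)
      stop("time step still too large after 10 halvings", call. = FALSE)
  }

  n_steps <- ceiling(t_end / dt)
  ea <- exp(-alpha * dt)

  simpson_hazard <- function(L0, dtt) {
    # integral of koff along L(tau) = L0*exp(alpha*tau), tau in [0, dtt]
    Lm <- L0 * exp(alpha * dtt / 2)
    L1 <- L0 * exp(alpha * dtt)
    dtt / 6 * (koff(L0) + 4 * koff(Lm) + koff(L1))
  }

  run_one <- function(rep_seed) {
  set.seed(rep_seed)
  # initial cohort: stratified positions, unstressed lengths
  y <- (seq_len(n_links) - 0.5) / n_links
  L <- rep(1, n_links)
  w <- rep(1, n_links)
  dep_carry <- 0
  t_now <- 0
  ts <- numeric(0); sig <- numeric(0); n_alive <- integer(0)
  for (step in seq_len(n_steps)) {
    # rupture over [t, t+dt] evaluated along each particle's characteristic
    if (s > 0 || g_enz > 0) {
      I <- pmin(simpson_hazard(L, dt) + g_enz * dt, hazard_cap)
      p_die <- -expm1(-I)
      u <- stats::runif(length(L))
      die <- u < p_die
    } else {
      die <- rep(FALSE, length(L))
    }
    # XET-cut particles are re-deposited unstressed at the inner face
    n_xet <- 0L
    if (p$g_xet > 0 && any(die)) {
      tot_rate <- koff(L[die]) + g_enz
      f_xet <- p$g_xet / tot_rate
      xet <- stats::runif(sum(die)) < f_xet
      n_xet <- sum(xet)
      w_xet <- w[die][xet]
    }
    keep <- !die
    y <- y[keep]; L <- L[keep]; w <- w[keep]
    # advect, stretch, dilute
    y <- y * ea; L <- L / ea; w <- w * ea
    if (n_xet > 0L) {
      y <- c(y, rep(1, n_xet)); L <- c(L, rep(1, n_xet))
      w <- c(w, w_xet)
    }
    # deposition at the inner face over the step, stratified in age
    target <- if (deposition) n_links * alpha * dt + dep_carry else 0
    m <- if (!deposition) 0L
         else if (poisson_deposition) stats::rpois(1, n_links * alpha * dt)
         else floor(target)
    if (!poisson_deposition) dep_carry <- target - m
    if (m > 0) {
      age <- dt * (1 - (seq_len(m) - 0.5) / m)
      Ld <- exp(alpha * age)
      if (s > 0 || g_enz > 0) {
        Idep <- pmin(simpson_hazard(rep(1, m), age) + g_enz * age,
                     hazard_cap)
        alive <- stats::runif(m) >= -expm1(-Idep)
      } else alive <- rep(TRUE, m)
      y <- c(y, (1 / Ld)[alive]); L <- c(L, Ld[alive])
      w <- c(w, (1 / Ld)[alive])
    }
    t_now <- step * dt
    if (step %% sample_every == 0L || step == n_steps) {
      ts <- c(ts, t_now)
      sig <- c(sig, sum(w * (L - 1)) / n_links + p$Gamma * alpha)
      n_alive <- c(n_alive, length(L))
    }
  }

  list(trace = data.frame(t = ts, sigma = sig, n_alive = n_alive),
       final_state = data.frame(y = y, L = L, w = w))
  }

  reps <- lapply(seq_len(n_replicates),
                 function(i) run_one(seed + i - 1L))
  first <- reps[[1L]]
  tail_mean <- function(r) {
    mean(r$trace$sigma[r$trace$t >= equil_frac * t_end])
  }
  tms <- vapply(reps, tail_mean, numeric(1))
  if (n_replicates > 1L) {
    est <- mean(tms)
    se <- stats::sd(tms) / sqrt(n_replicates)
  } else {
    tail_vals <- first$trace$sigma[first$trace$t >= equil_frac * t_end]
    nb <- min(10L, max(2L, length(tail_vals) %/% 5L))
    bm <- vapply(split(tail_vals,
                       cut(seq_along(tail_vals), nb, labels = FALSE)),
                 mean, numeric(1))
    est <- mean(tail_vals)
    se <- stats::sd(bm) / sqrt(length(bm))
  }
  list(trace = first$trace,
       steady_estimate = est,
       steady_se = se,
       final_state = first$final_state,
       n_links = n_links, dt = dt, t_end = t_end, seed = seed,
       n_replicates = n_replicates)
}

#' Integrate the survivor fraction along a characteristic
#'
#' Directly integrates `dn/dL = -(n/(alpha*L)) * exp(beta^2*sigma*(L-1)^2)`
#' from `n(1) = 1` with a stiff ODE solver ([deSolve::lsoda()]). Along the
#' steady characteristic `L = 1/y`, the solution must match the closed
#' form `n = exp(-G(1/L)/alpha)`; the test suite requires agreement to
#' 1e-8 relative for `L` up to `1/(2*beta)`.
#'
#' @param alpha dimensionless strain rate, `> 0`.
#' @param p a [wall_params()] object (no-enzyme kinetics).
#' @param L_max largest length integrated to; default `1/(2*beta)`.
#' @param n_out number of output lengths (log-spaced in `L`).
#' @return A `data.frame` with columns `L` and `n`.
#' @export
integrate_characteristic <- function(alpha, p, L_max = NULL, n_out = 50L) {
  p <- as_wall_params(p)
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha > 0)
  if (is.null(L_max)) L_max <- 1 / (2 * p$beta)
  stopifnot(L_max > 1)
  bs <- p$beta^2 * p$sigma
  s <- p$breakage_scale
  Ls <- exp(seq(0, log(L_max), length.out = n_out))
  rhs <- function(L, state, parms) {
    list(-state[1] / (alpha * L) * s * exp(min(bs * (L - 1)^2, 700)))
  }
  sol <- deSolve::lsoda(y = c(n = 1), times = Ls, func = rhs,
                        rtol = 1e-11, atol = 1e-14)
  if (attr(sol, "istate")[1] < 0)
    stop("characteristic ODE integration failed (lsoda istate ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  data.frame(L = sol[, "time"], n = sol[, "n"])
}
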