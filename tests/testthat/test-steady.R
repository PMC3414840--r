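test_that("XET coefficient matches its limits and the frozen quadrature", {
  expect_identical(xet_coefficient_A(3, p_base()), 0)
  expect_identical(xet_coefficient_A(3, p_base(g_xeh = 7)), 0)
  expect_equal(xet_coefficient_A(10, p_base(g_xet = 10)),
               oracle$A_a10_xet10, tolerance = 1e-9)
  # beta -> 0 closed form: A ~ g/(alpha+alpha0) * (1 - (C beta)^((a0+a)/a));
  # the (C beta)^(...) term is negligible here
  p0 <- wall_params(beta = 1e-8, g_xet = 2)
  a <- 5; a0 <- 3
  expect_equal(xet_coefficient_A(a, p0), 2 / (a + a0), tolerance = 1e-4)
})

test_that("steady profile satisfies its boundary and shape invariants", {
  p <- p_base()
  for (a in c(0.5, 5, 50)) {
    pr <- steady_profile(a, p)
    expect_equal(pr$n[length(pr$n)], 1, tolerance = 1e-12)  # n(1) = 1
    expect_true(all(pr$n >= 0))
    expect_true(all(diff(pr$n) >= -1e-12))  # fewer survivors outward
    expect_equal(pr$L, 1 / pr$y)
    expect_true(all(pr$stress_density >= 0))
  }
  # XET raises the boundary density to 1/(1-A)
  px <- p_base(g_xet = 10)
  prx <- steady_profile(10, px)
  expect_equal(prx$n[length(prx$n)], 1 / (1 - prx$A), tolerance = 1e-10)
  expect_gte(prx$n[length(prx$n)], 1)
  # survivor fraction at a single coordinate equals exp(-G/alpha)
  pr1 <- steady_profile(1, p, y_grid = 0.2)
  expect_equal(pr1$n, oracle$n_y02_a1, tolerance = 1e-9)
})

test_that("the small-beta profile is the power law y^(1/alpha)", {
  p0 <- wall_params(beta = 1e-6)
  y <- seq(0.1, 1, length.out = 30)
  for (a in c(0.5, 1, 10)) {
    pr <- steady_profile(a, p0, y_grid = y)
    expect_equal(pr$n, y^(1 / a), tolerance = 5e-5)  # 4 significant figures
  }
})

test_that("steady stress matches the frozen quadrature oracle", {
  p <- p_base()
  expect_equal(sigma_infinity(10, p), oracle$S_a10_b01, tolerance = 1e-9)
  expect_equal(sigma_infinity(c(1, 100), p),
               c(oracle$S_a1_b01, oracle$S_a100_b01), tolerance = 1e-9)
  expect_equal(sigma_infinity(10, p_base(g_xeh = 10)),
               oracle$S_a10_xeh10, tolerance = 1e-9)
  expect_equal(sigma_infinity(10, p_base(g_xet = 10)),
               oracle$S_a10_xet10, tolerance = 1e-9)
  expect_equal(sigma_infinity(2, wall_params(beta = 0.01)),
               oracle$S_a2_b001, tolerance = 1e-9)
  # whole reference curve
  expect_equal(sigma_infinity(oracle$curve_alpha, p), oracle$curve_sigma,
               tolerance = 1e-8)
  # no stretching, no stress
  expect_lt(sigma_infinity(1e-6, p), 1e-4)
  # matrix term adds Gamma*alpha exactly
  pg <- p_base(Gamma = 0.01)
  expect_equal(sigma_infinity(10, pg) - sigma_infinity(10, p), 0.1,
               tolerance = 1e-12)
})

test_that("stress saturates at the logarithmic yield plateau for large alpha", {
  p <- p_base()
  s4 <- sigma_infinity(1e4, p)
  expect_equal(s4, oracle$S_a1e4_b01, tolerance = 1e-8)
  # saturation: two further decades of strain rate add < 5%
  expect_lt((s4 - sigma_infinity(1e2, p)) / s4, 0.16)
  expect_lt((s4 - sigma_infinity(1e3, p)) / s4, 0.05)
  # the plateau sits at the fitted logarithmic factor L = log(1/(C beta)),
  # to the logarithmic accuracy of the scission-layer construction
  fc <- fit_C(p)
  expect_lt(abs(s4 - fc$L_script) / s4, 0.25)
})

test_that("stress is monotone in strain rate and in enzyme strengths", {
  probes <- exp(seq(log(0.01), log(1e4), length.out = 14))
  for (beta in c(0.01, 0.1)) {
    for (Gamma in c(0, 0.01)) {
      for (g in list(c(0, 0), c(10, 0), c(0, 10))) {
        p <- wall_params(beta = beta, Gamma = Gamma, g_xet = g[1],
                         g_xeh = g[2])
        s <- sigma_infinity(probes, p)
        expect_true(all(diff(s) > 0),
                    info = sprintf("beta=%g Gamma=%g gxet=%g gxeh=%g",
                                   beta, Gamma, g[1], g[2]))
      }
    }
  }
  # enzyme softening: Sigma decreases pointwise with each strength
  a <- c(0.5, 5, 50)
  for (gs in list(c(0, 1, 10, 100))) {
    sx <- sapply(gs[[1]], function(g) sigma_infinity(a, p_base(g_xeh = g)))
    expect_true(all(apply(sx, 1, diff) < 0))
    st <- sapply(gs[[1]], function(g) sigma_infinity(a, p_base(g_xet = g)))
    expect_true(all(apply(st, 1, diff) < 0))
    # bond reformation sustains more stress: XET >= XEH at equal strength
    for (g in gs[[1]][-1])
      expect_true(all(sigma_infinity(a, p_base(g_xet = g)) >=
                        sigma_infinity(a, p_base(g_xeh = g))))
  }
})

test_that("the enzyme-general stress form reduces to the no-enzyme integral", {
  # independent in-test evaluation of the XTH form with zero strengths:
  # prefactor 1/(1-A) with A = 0 and survivor power y^0
  p <- p_base()
  num <- wall_numerics()
  for (a in c(0.7, 12)) {
    A <- xet_coefficient_A(a, p)
    expect_identical(A, 0)
    val <- stats::integrate(function(y)
      survival_fraction(y, a, p) * y^(0 / a) * (1 / y - 1),
      wallkinetics:::y_cutoff(a, p, num), 1,
      rel.tol = 1e-11, abs.tol = 0, subdivisions = 500L)$value / (1 - A)
    expect_equal(val, sigma_infinity(a, p), tolerance = 1e-9)
  }
})

test_that("expansin action maps onto a rescaled no-enzyme wall", {
  # with the linear rest-length model, elongation and breakage both scale
  # by 1/(1+g), so Sigma_exp(alpha; beta, g) = Sigma_0(alpha; beta/(1+g))/(1+g)
  for (g in c(0.5, 3)) {
    pe <- wall_params(beta = 0.1, g_exp = g)
    pr <- wall_params(beta = 0.1 / (1 + g))
    for (a in c(1, 10))
      expect_equal(sigma_infinity(a, pe), sigma_infinity(a, pr) / (1 + g),
                   tolerance = 1e-9)
  }
  # g_exp = 0 reproduces the no-enzyme stress exactly
  expect_equal(sigma_infinity(5, wall_params(beta = 0.1, g_exp = 0)),
               sigma_infinity(5, p_base()), tolerance = 1e-12)
  # softening: expansin lowers the stress pointwise
  a <- c(0.5, 5, 50)
  s0 <- sigma_infinity(a, p_base())
  for (g in c(1, 10, 100))
    expect_true(all(sigma_infinity(a, wall_params(beta = 0.1, g_exp = g))
                    <= s0))
})

test_that("multiplicative enzyme coupling behaves qualitatively like additive", {
  a <- c(1, 10)
  s0 <- sigma_infinity(a, p_base())
  sm <- sigma_infinity(a, p_base(g_xeh = 10,
                                 enzyme_coupling = "multiplicative"))
  expect_true(all(sm < s0))
  expect_true(all(diff(sm) > 0))
})

test_that("effective extensibility paths agree and match the oracle slope", {
  p <- p_base()
  # dual-path evaluation (analytic differentiation under the integral vs
  # central differences) runs without mismatch error
  expect_equal(phi_eff(10, p, method = "both"), oracle$phi_fd_a10_b01,
               tolerance = 1e-4)
  expect_equal(phi_eff(10, p, method = "analytic"),
               phi_eff(10, p, method = "fd"), tolerance = 1e-6)
  # with XET (A(alpha) derivative terms in play)
  px <- p_base(g_xet = 10)
  expect_gt(phi_eff(10, px, method = "both"), 0)
  # matrix-dominated limit: Phi_eff -> 1/Gamma
  pg <- p_base(Gamma = 0.01)
  expect_equal(phi_eff(1e5, pg), 100, tolerance = 0.01)
  expect_true(all(phi_eff(c(1, 10, 100), pg) <= 100 + 1e-6))
})

test_that("strain rate can be recovered from a target stress", {
  p <- p_base()
  # pure-matrix model: crosslinks disabled, Sigma = Gamma*alpha is linear
  pm <- wall_params(beta = 0.1, Gamma = 0.05, g_xeh = 1e6)
  a0 <- solve_alpha_for_stress(0.05 * 7, pm, bracket = c(0.1, 1e3))
  expect_equal(a0, 7, tolerance = 1e-4)
  # round trip through the full model
  for (target in c(0.5, 1.5)) {
    a <- solve_alpha_for_stress(target, p)
    expect_equal(sigma_infinity(a, p), target, tolerance = 1e-8)
  }
  # a target above the Gamma = 0 plateau is a range error naming the plateau
  expect_error(solve_alpha_for_stress(50, p), "plateau")
})

test_that("stress curves record monotonicity and propagate parameters", {
  p <- p_base()
  grid <- exp(seq(log(0.5), log(50), length.out = 8))
  cur <- stress_curve(grid, p)
  expect_s3_class(cur, "stress_curve")
  expect_true(attr(cur, "monotone"))
  expect_equal(cur$sigma_inf, sigma_infinity(grid, p), tolerance = 1e-12)
  expect_equal(cur$phi_eff, phi_eff(grid, p, method = "analytic"),
               tolerance = 1e-12)
  # single-point grid equals the pointwise operations
  one <- stress_curve(5, p)
  expect_equal(one$sigma_inf, sigma_infinity(5, p))
  expect_error(stress_curve(c(2, 1), p), "increasing")
  expect_error(stress_curve(numeric(0), p), "positive")
})
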