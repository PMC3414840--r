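---
title: "Crosslink kinetics and emergent yield in the expanding plant cell wall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crosslink kinetics and emergent yield in the expanding plant cell wall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallkinetics)
```

## The model

The growing plant primary cell wall is a composite: stiff cellulose
microfibrils (CMF), oriented in hoops orthogonal to the direction of
elongation, are embedded in a viscous pectin matrix and tethered to one
another by hemicellulose (xyloglucan) crosslinks. `wallkinetics` implements
a transient-network model of this composite. A section of wall of thickness
$h$ elongates at strain rate $\alpha^*$; incompressibility compresses the
wall in the thickness direction, so material deposited at the inner face
($y = 1$ in wall-thickness units) is carried towards the outer face
($y = 0$). A crosslink deposited unstressed (dimensionless length $L = 1$)
at the inner face stretches affinely as it is advected: $L = 1/y$ at steady
state. Crosslinks behave as linear springs and rupture at a strain-enhanced
Bell-type rate,

$$k_\mathrm{off} = k_0\,\exp\!\big(\beta^2\sigma (L-1)^2\big),$$

in units of the unstressed rupture rate $k_0$. Here $\sigma$ is the spring
energy scale ($\kappa L_0^2 / 2 k_b T$, of order one for an entropic
tether, default 1) and $\beta$ is the extension parameter: crosslinks can
stretch by roughly a factor $1/\beta$ before rupture becomes certain
($\beta \sim L_0/L_\mathrm{max}$, small for xyloglucan tethers spanning
10–20 nm CMF gaps and extending to several hundred nm).

Everything the package computes follows from transport along
characteristics. The survivor fraction of a crosslink that has reached
coordinate $y$ is $\exp(-G(y)/\alpha)$, where

$$G(y) = \int_y^1 \exp\!\big(\beta^2\sigma(1/z - 1)^2\big)\,\frac{dz}{z}$$

is the accumulated rupture exposure and $\alpha$ the dimensionless strain
rate ($\alpha^*/k_0$). The steady stress resultant (in units of the wall
extensional stiffness $E = n_0 \kappa L_0 h$) is

$$\Sigma_\infty(\alpha) = \int_0^1 e^{-G(y)/\alpha}\Big(\frac{1}{y} - 1\Big)\,dy
  + \Gamma\alpha,$$

with $\Gamma = k_0/(\Phi_m E)$ the matrix-to-crosslink extensibility ratio;
$\Gamma\alpha$ is the viscous matrix stress. The transient response from an
initially unstressed wall adds the contribution of the crosslinks present
at $t = 0$, which all carry length $e^{\alpha t}$ and occupy
$y < e^{-\alpha t}$.

Three enzyme modes modify the kinetics, each analysed at steady state:

* **XEH** (strength `g_xeh`): pure additional scission at rate
  $g_\mathrm{XEH} k_0$. The survivor density gains a factor
  $y^{g/\alpha}$.
* **XET** (strength `g_xet`): scission plus immediate re-deposition of the
  cut crosslink, unstressed, at the inner face. This raises the boundary
  density to $1/(1-A)$, where the self-consistency coefficient
  $A = (g_\mathrm{XET}/\alpha)\int_0^1 e^{-G/\alpha} y^{g/\alpha} dy$ must
  satisfy $A < 1$ for a steady state to exist; the package raises a
  model-validity error otherwise rather than returning a spurious value.
* **Expansin** (strength `g_exp`): unpeeling of crosslink ends from the
  CMF, modelled as an increase of the rest length via $f_0(L)$ with
  $1 \le f_0 \le L$; both the stress integrand and the rupture exponent
  use the reduced elongation $L - f_0(L)$.

The emergent $\Sigma_\infty(\alpha)$ relation is Bingham-like: a steep
pre-yield rise (slope $\approx 1$, i.e. dimensional stiffness $E$),
followed by saturation of the crosslink stress at the logarithmic plateau
$\mathcal{L} = \log(1/C\beta)$ ($C$ an order-one scission-layer constant),
beyond which only the matrix term grows. Read as a Lockhart law, the yield
stress is $Y \approx E\mathcal{L}$ and the post-yield extensibility is
matrix-dominated, $\Phi \approx \Phi_m$.

## Parameters that matter

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `beta` | extension capacity $L_0/L_\mathrm{max}$ | — (required) | dimensionless |
| `sigma` | spring energy scale $\kappa L_0^2/2k_bT$ | 1 | dimensionless |
| `Gamma` | matrix/crosslink extensibility ratio $k_0/(\Phi_m E)$ | 0 | dimensionless |
| `g_xet`, `g_xeh`, `g_exp` | enzyme strengths (rates per $k_0$) | 0 | dimensionless |
| `alpha` | strain rate $\alpha^*/k_0$ | — | dimensionless |

Typical physiological analyses use $\beta$ between 0.01 and 0.1, $\sigma =
1$ and $\Gamma$ of order $10^{-2}$ or smaller. `nondimensionalize()` maps a
physical parameter set ($n_0, \kappa, L_0, h, k_0, \Phi_m, k_bT$, SI units
by convention) onto these groups and back.

## Numerical choices

* **The kernel $G$** spans hundreds of orders of magnitude across the
  scission layer ($y \lesssim \beta$). It is integrated on the
  log-transformed coordinate $u = \log z$, accumulated over segments for
  vector arguments, and returned as `Inf` once it exceeds the
  representable range. The survival fraction is computed fused with the
  exponent (`exp(-G/alpha)` is exactly 0 beyond the underflow cutoff of
  700, set just below the double-precision limit), so no intermediate
  value ever overflows.
* **Stress quadratures** run over $[y_\mathrm{cut}, 1]$, where
  $y_\mathrm{cut}$ solves $G(y) = 700\,\alpha$; below this point the
  integrand is identically zero in double precision. With strong enzyme
  action at small $\alpha$ the survivor power $y^{g/\alpha}$ instead
  confines all mass to a boundary layer of width $\alpha/g$ at the inner
  face, and the lower limit is raised to $\exp(-60\alpha/g)$.
* **Effective extensibility** $\Phi_\mathrm{eff} =
  (d\Sigma_\infty/d\alpha)^{-1}$ is evaluated by two independent routes —
  analytic differentiation under the integral sign (including the
  $A(\alpha)$ and $y^{g/\alpha}$ terms) and central finite differences
  with $h = 10^{-3}\alpha$ — and the default method cross-checks them at
  $10^{-4}$ relative tolerance, raising an error on mismatch.
* **Root solving** (`solve_alpha_for_stress()`) verifies monotonicity on
  16 log-spaced probes before bracketing; with $\Gamma = 0$ a target above
  the crosslink plateau is reported as a range error naming the plateau
  rather than diverging.
* **Transient peak search** scans $\alpha t \in (0, 3\log(1/\beta)]$
  coarsely and refines by golden-section search; a maximum on the scan
  boundary is reported with `peak_found = FALSE` rather than as a peak.
  The matrix offset $\Gamma\alpha$, constant in time, is excluded from the
  search and reported alongside.
* **Quadrature tolerances** default to $10^{-10}$ relative; all frozen
  reference values in the test suite were computed with an independent
  adaptive quadrature at $10^{-12}$–$10^{-13}$ before the package
  numerics were written.

## Verification oracles

Two independent engines validate the closed-form/quadrature solutions and
are part of the public interface:

* `integrate_characteristic()` integrates $dn/dL = -(n/\alpha L)
  \exp(\beta^2\sigma(L-1)^2)$ directly with a stiff ODE solver; it matches
  $\exp(-G(1/L)/\alpha)$ to better than $10^{-8}$ relative.
* `simulate_ensemble()` evolves discrete crosslink particles: exact
  advection and stretching per step, stochastic rupture with the
  integrated hazard computed by Simpson's rule along each characteristic,
  and deterministic stratified deposition (a Poisson mode exists behind a
  flag). Particle weights decay as $e^{-\alpha t}$, accounting for the
  axial dilution of the per-unit-length count, which makes the
  breakage-free ensemble reproduce $\Sigma = \alpha t$ exactly — a useful
  end-to-end check with no sampling noise. The step-size rule requires the
  hazard rate to change little across a step for particles whose fate is
  genuinely stochastic (integrated hazard below 30); particles beyond that
  band die almost surely, so the locally enormous rupture rates inside the
  scission layer do not force the step to zero. Steady-state estimates
  average the equilibrated tail; standard errors come from independent
  replicates (`n_replicates`), since tail batch means within a single run
  are serially correlated and understate the error.

## Design choices where the design was open

* **Expansin rest-length function.** Only the constraint
  $1 \le f_0 \le L$ is fixed by the model statement. The package default
  is $f_0(L; g) = 1 + \tfrac{g}{1+g}(L-1)$: it is linear, reduces to no
  action at $g = 0$, and approaches complete stress relaxation as
  $g \to \infty$. It sits behind a function argument (`rest_length`) so
  any admissible form can be substituted. A convenient consequence used in
  the tests: with this form the expansin wall is exactly a no-enzyme wall
  with $\beta \mapsto \beta/(1+g)$ and stress scaled by $1/(1+g)$.
* **Enzyme coupling.** Additive rate terms ($k_0(g_\mathrm{XEH} +
  g_\mathrm{XET})$) are the default; the multiplicative alternative
  ($k_\mathrm{off}(g_\mathrm{XEH}+g_\mathrm{XET})$) is available via
  `enzyme_coupling = "multiplicative"` and behaves qualitatively alike.
  Combining XTH and expansin in one parameter set is rejected rather than
  guessed: the two mechanisms are formulated as separate model variants.
* **Scission-layer constant.** `fit_C()` chooses $C$ by least squares on
  log stress over $\alpha \in [1, 100]$. The closed-form plateau
  $\mathcal{L} = \log(1/C\beta)$ then *overestimates* the plateau the full
  numerics actually reach at accessible strain rates (the saturation is
  logarithmic, so a constant fitted on the yield knee necessarily differs
  from one fitted to the plateau). The package
  records the independently fitted values and does not force agreement;
  the fitted yield stress `Y_eff` sits about 35% below the knee-fitted
  $\mathcal{L}$ at $\beta = 0.1$, and within ~10% of a plateau-fitted
  $\mathcal{L}$.
* **Post-yield fit window.** `lockhart_extract()` regresses over $\alpha
  \in [5\mathcal{L}, 50\mathcal{L}]$ by default. With $\Gamma > 0$ the
  residual crosslink slope at $5\mathcal{L}$ (about
  $(\mathcal{L}/\alpha)^2/2$) still exceeds $\Gamma$ for small $\Gamma$,
  which would contaminate the extensibility estimate; the window is
  therefore pushed out to where that residual slope falls below
  $\Gamma/5$, i.e. $\alpha \ge \mathcal{L}/\sqrt{0.4\,\Gamma}$. On a
  $\beta = 0.1$, $\Gamma = 0.01$ curve this recovers
  $\Phi_\mathrm{post} \approx 1/\Gamma$ within a few percent.

## What the ensemble generator does and does not emulate

The discrete ensemble realises exactly the kinetics of the continuum
model: affine advection, length-dependent rupture, boundary deposition and
XET re-deposition. It does *not* emulate features of real walls that the
continuum model itself omits — crosslink formation within the wall
interior, nonlinear (strain-stiffening) tether elasticity, fibre
reorientation, wall curvature, pectin chemorheology (PME/calcium), or
Brownian fluctuations of the tethers. Agreement between the ensemble and
the quadrature therefore validates the numerics, not the biology;
conclusions about real walls inherit all the modelling assumptions above.

## Worked example

```{r example}
p <- wall_params(beta = 0.1, Gamma = 0)
# strain rate sustained at unit stress, without and with XET action
solve_alpha_for_stress(1, p)
solve_alpha_for_stress(1, wall_params(beta = 0.1, g_xet = 100))
# transient overshoot at high strain rate
yield_strain(100, p)[c("alpha_t_peak", "sigma_peak")]
```

The computations above use the study conditions of the package's
acceptance checks ($\beta = 0.1$, $\sigma = 1$, $\Gamma = 0$): XET action
at strength 100 raises the strain rate sustained at unit stress roughly
forty-fold, and at $\alpha = 100$ the transient stress peaks near a
log-stretch of 3.1.

## Problem sizes

The shipped analyses are deliberately modest: stress curves use 40–50
log-spaced strain rates; transient traces 400 times; the ensemble
verification points use 5000 particles with 8–10 replicates, which
resolves the steady stress to a relative standard error of a few parts in
$10^4$. All scale linearly if finer resolution is wanted.

## Known limitations

* The transient solver covers constant strain rate from an unstressed
  initial state; creep under fixed load and step-load viscoelasticity are
  out of scope.
* Enzyme action is steady-state only, spatially homogeneous, and one
  family at a time.
* Whether $A \ge 1$ (no XET steady state) is reachable for physically
  sensible parameters is reported, not resolved: the solver raises a
  diagnostic error when it happens.
* The Lockhart parameters extracted at finite $\beta$ identify the
  yield stress only to logarithmic accuracy, as discussed above.
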