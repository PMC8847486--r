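---
title: "Modeling circadian clocks and designing antithetic integral feedback controllers"
author: "clockAIF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling circadian clocks and designing AIF controllers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clockAIF)
```

## The modeling framework

`clockAIF` represents gene circuits as *extended S-Systems*: every species
$X_i$ obeys a power-law ODE with three kinds of terms,

$$\frac{dX_i}{dt} = \alpha_i \prod_{j=1}^{n_i^P}
\Big(\sum_k b_{i,j,k} X_k\Big)^{g_{i,j}}
\;-\; \sum_{j=1}^{n_i^D} \beta_{i,j} X_i \prod_k X_k^{h_{i,j,k}}
\;+\; \sum_{j=1}^{n_i^L} \gamma_{i,j} U_{i,j}.$$

Production is a rate constant times a product of power-law factors; each
factor's base is a sum of species selected by a Boolean membership vector,
and the sign of the exponent $g_{i,j}$ sets the regulation type (positive
= activation, negative = inhibition). This lets one structure express both
activation and repression without switching nonlinearities. Every
degradation term is proportional to $X_i$ itself, optionally modulated by
power-law cofactors — which is how the package encodes negative regulation
acting through clearance (e.g. a complex that promotes degradation of its
own component). Light-coupled terms are additive, gated by a square wave
$L(t)$ with photoperiod $P_H$ ($L = 1$ iff $0 \le t \bmod 24 < P_H$, dawn
at $t = 0$), with an optional power-law species factor; a term vanishes
identically when its gate is closed. The classic power-law form (one
single-species factor per regulator, no light terms) is the special case,
and the test suite verifies the reduction against a direct evaluation of
that form.

Units are fixed to nM and hours throughout and carried as labels only.

### Numerical policy

* **Nonnegativity.** States are clipped to a floor of $10^{-9}$ nM before
  any power evaluation: non-integer powers of negative numbers are
  undefined, and concentrations are physically nonnegative. Recorded
  values that undershoot zero are clipped to 0 and counted in the
  trajectory metadata, so silent excursions are visible.
* **Solver.** `deSolve::lsoda` (adaptive step, automatic stiff/non-stiff
  switching), rtol $10^{-6}$, atol $10^{-9}$; the two controller species
  get atol $10^{-12}$ because at large sequestration rates they
  equilibrate at very small concentrations. Integration is restarted at
  every dawn and dusk with the light level frozen per segment, so the
  discontinuous forcing is seen exactly rather than smoothed through.
* **Windows.** All windows are half-open $[t_0, t_1)$; dawn is lit, dusk
  is dark. Entrainment simulations discard two transient days by default
  and flag (not fail) runs whose day-over-day mismatch exceeds 1% of each
  species' amplitude.

## The packaged clocks and what they stand in for

Five clock designs ship with the package — JL2005 and JD2016 (plant),
HU2001 (insect), SB2004 (mammal), AD2015 (fungus) — each with design
metadata naming the control target, the positive regulator lost under
perturbation, and the target's linear degradation rate $\gamma_P$
(1.2875, 0, 0.5238, 1.5816 and 0.2749 h$^{-1}$ respectively; the JD2016
target HYP, a hypocotyl-growth output, has no degradation and is a pure
integrator).

The shipped network parameterisations are **synthetic stand-ins**, as the
file names state. Each is a compact three-species, light-entrained
power-law circuit: a driver species (named after the lost regulator)
relaxing between a dark and a light level, a delayed auxiliary complex,
and the target gene produced from a power of the driver and degraded
linearly at $\gamma_P$ plus, for the oscillatory clocks, through an
auxiliary-complex cofactor term that deepens the trough between peaks.
The target's production scale and exponent were calibrated once, at
package construction time (`inst/scripts/make-clock-configs.R`), so that
the entrained target profile reproduces the published profile extremes
$(\mu_{\min}, \mu_{\max})$ recorded in the design metadata, to well within
0.5%. HU2001 additionally keeps the negative regulation of PER by the
PER/TIM complex as a degradation cofactor, so that perturbing the
CLK/CYC input leaves that regulation intact; JL2005 keeps a direct light
term on the target, so the perturbed plant still shows light-driven
peaks; JD2016's PIF driver accumulates in darkness through light-gated
degradation and HYP integrates it monotonically.

What these stand-ins do establish: the entrained reference profiles, the
design quantities derived from them ($\mu_{\min}$, hence $\bar\eta$), and
every structural property of the closed loop. What they do not establish:
behavior tied to the detailed kinetics of the original literature models —
they are driven (entrained) oscillators that do not free-run in constant
darkness, their perturbed plants are nearly linear in the target, and
quantities such as *which* actuation rate attains a given tracking error
are parameterisation-specific. Test results on the stand-ins transfer to
real clock models only at the level of the design procedure, not of
individual tuned values.

## Parameter estimation

The estimation module fits extended S-System parameters to time series by
the normalized least-squares objective

$$J(\Theta) = \frac{1}{N_L N_G} \sum_{i=1}^{N_G} \sum_{j=1}^{N_L}
\left(\frac{X_i(t_j) - \hat X_i(t_j,\Theta)}{M_i}\right)^2,
\qquad M_i = \max_j X_i(t_j),$$

minimized by Nelder–Mead with seeded multi-start. The training protocol
generates four days of 12L:12D data and keeps the final two days of hourly
samples ($N_L = 49$ per species), so fitting happens on the limit cycle.
Design choices worth knowing:

* the model is simulated from the first training sample (no free initial
  state);
* rates are optimized in log space, exponents through a sign-preserving
  log-magnitude transform with the sign frozen by the network topology, so
  the optimizer cannot turn an activation into an inhibition;
* a failed simulation returns a finite penalty ($10^6$) instead of
  crashing the simplex;
* restarts jitter the start point in transformed space (sd 0.3) under the
  supplied seed; there is no hidden entropy.

The two-gene fixture generator (`makeToyProblem`) draws a light-driven
activator–repressor pair, and recovery from 20%-perturbed starts is the
package's accuracy check: across ten seeded fixtures the pooled median
relative parameter error is a few percent with every objective below
$10^{-4}$ (2500 simplex iterations per fit; the acceptance suite uses the
first three seeds to stay within its runtime envelope).

## The controller and the design procedure

The antithetic controller couples an actuator $Z_1$ and a sensor $Z_2$
through mutual sequestration at rate $\eta$; $\theta_1 z_1$ replaces the
target's lost production (always as an additive actuation term on the
target species), $\theta_2$ sets the sensing gain and $\gamma_C$ the
controller degradation. With $\gamma_C = 0$ the difference $z_1 - z_2$ is
an exact running integral of the tracking error — the package exposes this
as a diagnostic (`integralResidual`, trapezoidal quadrature on the output
grid; use a grid step of about 0.005 h if you want the identity resolved
to $10^{-4}$, since the quadrature error scales with the square of the
step). The closed loop starts with the plant on its unperturbed entrained
cycle at dawn, the controller empty ($z_1 = z_2 = 0$), and perturbation
and controller engaging together at $t = 0$; tracking error is the mean
square deviation from the reference over hourly samples $t = 1..96$ h.

The automated procedure (`designController`) runs five steps: load and
perturb the clock; set $\eta = 10\bar\eta$ — for the degradation-free
JD2016 target, where $\bar\eta$ is undefined, run a coarse $\eta$ sweep
and take ten times the grid value at the largest drop in
$\log_{10}$(MSE); fix $\theta_2 = 1$ (any detuning inflates the error
roughly as $(1 - 1/\theta_2)^2 \mu^2$, an order of magnitude or more);
choose $\gamma_C$ by policy; and log-sweep $\theta_1$, selecting the
smallest value within 1% of the minimal MSE (weaker actuation is
biologically cheaper).

Two design decisions deserve explanation:

* **The sequestration rate stays fixed during the $\theta_1$ sweep**
  (`etaRule = "fixed"`, the default): $\eta$ is chosen once from the
  bound at $\theta_1 = \theta_2 = 1$ and the sweep then explores
  actuation alone. The alternative rule (`"track"`), which re-evaluates
  $\eta = 10\bar\eta(\theta_1, \theta_2)$ at every swept point, makes the
  loop arbitrarily accurate at large gains (the bound grows as
  $\theta_1^2$) and therefore has no interior optimum to find; with the
  fixed rule the sweep exhibits the trade-off actually being tuned — at
  non-zero $\gamma_C$ the error first falls with gain and then rises
  again as the sensor species, forced to scale like
  $\theta_1/(\eta\gamma_P)$, leaks appreciable flux through its own
  degradation.
* **The auto policy for $\gamma_C$ picks the largest degradation on the
  grid $\{0, 0.5, 1, 1.5, 2, 3, 5\}$ whose MSE stays at or below 0.3**:
  degradation only ever costs accuracy, so the design question is how
  much of it the application can tolerate, and the scan is run at the
  zero-degradation actuation optimum. A small *improvement* from mild
  degradation can occur when the actuation is aggressive ($\gamma_C$
  damps controller-induced overshoot) — the trend tests therefore assert
  monotone growth from $\gamma_C = 0.5$ upward rather than across the
  first step.

Sweep grids: 25 log-spaced points over 0.1–10 h$^{-1}$ for
$\gamma_C = 0$, 31 points over 0.1–$10^5$ h$^{-1}$ otherwise (about five
per decade — enough to locate optima on curves this smooth at a fraction
of the cost of a dense grid). Runs are deterministic; failed grid points
are recorded as missing, not fatal.

## Problem sizes used by the shipped checks

Reference extraction simulates 2 transient + 4 recorded days at 0.1 h
sampling; closed-loop runs cover 96 h recorded at 0.5 h (0.005 h for the
integral-identity diagnostic, over 24 h); sweeps use the grids above;
estimation checks use two-gene fixtures with 49 hourly samples per
species. These sizes resolve every quantity the package reports while
keeping a full test run in the tens of minutes on a single core.

## Known limitations

* The stand-in clocks are entrained oscillators, not free-running ones;
  constant-dark or constant-light behavior of the originals is out of
  scope, as are stochastic (low-copy-number) effects on sequestration,
  delay terms and temperature entrainment.
* $\bar\eta$ is a time-scale-separation bound derived for a one-species
  linear plant; for the embedded nonlinear plants it is a design
  heuristic, which is precisely why the tenfold rule and the MSE sweeps
  exist.
* Periodic extension of a reference beyond its window assumes exact 24 h
  periodicity; it is forbidden for the non-periodic JD2016 output, whose
  closed-loop runs are limited to the 96 h reference window.
* The light-coupling dialect is a gate times an optional power-law
  factor; smooth (twilight) light profiles are not representable.
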