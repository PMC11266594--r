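---
title: "Modelling VOC biofiltration: biofilm kinetics, column coupling and the Elman surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling VOC biofiltration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofiltervoc)
```

## The model

A biofilter removes volatile organic compounds (VOCs) from a contaminated
air stream by passing it through a packed bed whose particles are coated
with a thin microbial biofilm.  This package models the simultaneous
steady-state biodegradation of a hydrophilic compound (methanol) and a
hydrophobic one (alpha-pinene), coupled by inhibition: methanol suppresses
the pinene-degrading community by the factor

$$\alpha = \frac{1}{1 + (C_m / K_i)^2},$$

where $C_m$ is the methanol concentration and $K_i$ the inhibition
constant (`inhibition_factor()`).

**Biofilm phase.**  Within the film (depth $X^* \in [0,1]$, interface at
$X^* = 0$, impermeable support at $X^* = 1$) diffusion balances
Michaelis-Menten consumption.  In dimensionless form,

$$\frac{d^2 S_m^*}{dX^{*2}} = \phi \, \frac{S_m^*}{1 + \beta S_m^*},
\qquad
\frac{d^2 S_p^*}{dX^{*2}} = \alpha \phi_1 \, \frac{S_p^*}{1 + \beta_1 S_p^*},$$

with $S^*(0) = 1$ and $S^{*\prime}(1) = 0$.  The Thiele-type modulus
$\phi = (X \mu_{\max}/Y)\,\delta^2 / (D_e K)$ compares maximal reaction to
diffusion; the saturation parameter $\beta = S_i / K$ is the interface
concentration relative to half-saturation.  Two limits close the model in
analytic form: *unsaturated* (first-order) kinetics for $\beta \to 0$,
solved by $\cosh(\sqrt{\phi}(1-x))/\cosh\sqrt{\phi}$, and *saturated*
(zero-order) kinetics for $\beta S^* \gg 1$, solved by a parabola with,
when the demand $d = \phi/\beta$ exceeds 2, a free boundary at the
penetration depth $x_p = \sqrt{2/d}$ beyond which the substrate is
depleted.

**Gas phase.**  Plug flow along the dimensionless bed height
$h^* \in [0,1]$ with mass transfer into the film:

$$\frac{dC_m^*}{dh^*} = A \left(\frac{dS_m^*}{dX^*}\right)_{X^*=0},
\qquad
\frac{dC_p^*}{dh^*} = \alpha A_1 \left(\frac{dS_p^*}{dX^*}\right)_{X^*=0},$$

with $C^*(0) = 1$.  Because the interface gradient is negative, both
profiles decline; writing the balance with this sign is the only
convention compatible with the dimensional plug-flow equations and with
monotone removal, and it is the one implemented.  Removal efficiency is
$1 - C^*(1)$.

### Assumptions inherited from the model

Radial gradients, axial dispersion and start-up transients are neglected
(plug flow, rectangular film geometry); biomass density is constant in
time; methanol and pinene are the only active substrates and are degraded
by distinct communities.  Temperature and pH effects are out of scope.

The inhibition factor deserves one caution: parameter sweeps in the
source literature use constant values such as $\alpha = 1.34$ even though
the defining expression is bounded by 1.  The package therefore keeps two
separate entry points — a constant $\alpha > 0$ supplied directly in
`biofilm_params()`, and the bounded dynamic route via
`inhibition_factor()` / `gamma` in the column model — and never mixes
them silently.

## Numerical design

**Biofilm solver** (`solve_biofilm_bvp()`).  Second-order central
differences on a uniform grid, Neumann closure by a ghost node at
$X^* = 1$, and a damped Newton iteration on the tridiagonal system
(Thomas elimination; residual tolerance $10^{-12}$, initial guess
$S^* \equiv 1$, step halving on residual growth).  The problem is solved
at `n_grid` and `2 n_grid − 1` points and Richardson-extrapolated, which
raises the profile and flux accuracy to fourth order: at the default
`n_grid = 1001` the solution is converged to well below $10^{-10}$, and
doubling the grid changes it only at round-off level.  The interface flux
is computed from the exact discrete conservation identity — for the
converged difference solution the one-sided interface slope equals minus
the trapezoidal quadrature of the reaction term — and then extrapolated,
so flux and profile honour mass conservation by construction.  The choice
of a Richardson-extrapolated direct discretization over shooting keeps
the scheme robust in the stiff, nearly-depleted regimes (large $\phi$,
small $\beta$) where initial-value integration of the unstable growing
mode loses digits; a high-accuracy shooting solver is retained in the
test suite as an independent oracle.

The zero-order regime is evaluated from its closed form rather than
iterated: the parabola satisfies the central-difference equations exactly,
and the free-boundary case keeps value and slope continuous at $x_p$,
which a clamped iteration would not.

**Column solver** (`solve_column()`).  Classical fourth-order Runge-Kutta
with `n_h = 101` points by default; the integration is repeated at halved
step and the difference recorded (`step_error`, typically below
$10^{-8}$).  In `local` coupling the film problem is rescaled at each
height — saturation parameter $\beta C^*(h^*)$, flux scaled by $C^*$ —
which follows exactly from the substitution $s = S/C^*$ in the film
equation; for first- and zero-order kinetics the local flux has a closed
form and no inner solve is needed.  The `as_printed` coupling freezes the
inlet flux and yields a linear decline clamped at zero; it is retained
because the column equations are sometimes written with a constant flux
term, but `local` is the default since only it produces the flattening
concentration profiles expected physically.

## The Elman surrogate

The surrogate is an Elman recurrent network: one hidden layer of
$N = 60$ logistic neurons whose previous activations are fed back through
a context layer, and a logistic output unit,

$$h(t) = \sigma(w^{h,i} x(t) + w^{h,c} c(t-1) + b_h), \quad
c(t) = h(t), \quad
y(t) = \sigma(w^{o,h} h(t) + b_o).$$

Biases are included for both layers; without the output bias even a
constant target would be unlearnable.  Profiles are presented in
ascending $X^*$ order with zero initial context, and `enn_predict()`
rejects unsorted queries because the context makes the output
order-dependent.  Since targets lie in $(0,1]$, the boundary value
$S^*(0) = 1$ is representable only asymptotically; a converged surrogate
prints values like 0.9999x there, which is inherent to the logistic
output, not a defect.

**Training** (`enn_train()`).  The dataset is the reference profile
sampled at 1001 uniform points, split 701/150/150 into train, validation
and test by a seeded permutation with largest-remainder rounding.
Training is Levenberg-Marquardt on the mean-square error: solve
$(J^\top J + \mu I)\,\Delta w = J^\top e$, accept if the training MSE
decreases ($\mu \leftarrow 0.1\mu$), otherwise sharpen the damping
($\mu \leftarrow 10\mu$).  With 3781 parameters and 701 residuals the
update is computed in residual space through the identity
$\Delta w = J^\top (J J^\top + \mu I)^{-1} e$, which reduces the
factorization from $3781^2$ to $701^2$.

The Jacobian is *teacher-forced*: the context sequence is recomputed by
every forward pass but treated as exogenous when differentiating, the
classical truncation for Elman networks that keeps $J^\top J$ well-posed
without backpropagation through time.  Two consequences shaped the
optimizer design:

* **Initialization.**  All weights start uniform on $[-0.5, 0.5]$, with
  the context block scaled by $1/\sqrt{N}$.  Unscaled context weights sum
  sixty $O(1)$ terms into every hidden pre-activation, saturating the
  units and making the teacher-forced Jacobian a poor local model; the
  scaling keeps the context drive comparable to a single input weight.
* **Fractional steps.**  A rejected full step is retried at 1/2 and 1/4
  length before $\mu$ is increased.  With an inexact Jacobian, raising
  $\mu$ turns the step toward the inexact gradient, which can fail even
  for arbitrarily small steps; a shortened Gauss-Newton step often still
  descends.

Stopping tests, in order: gradient $\infty$-norm below $10^{-7}$; no
acceptable step with $\mu$ up to $10^{10}$; validation degradation — the
validation MSE exceeding its best by more than a relative $10^{-6}$ on
`val_patience = 6` consecutive accepted steps (a plateau at the optimum
does not stop training, since the noiseless target cannot be overfitted
in the usual sense); or 2000 epochs.  The weights with the best
validation MSE are returned, and a fixed seed makes the whole run
bit-reproducible.

With these choices a typical training on the $\phi = \beta = 10$ profile
stops after some tens of epochs with a test-split mean absolute deviation
in the $10^{-5}$–$10^{-3}$ range depending on the seed; stalled basins at
a few $10^{-3}$ exist, which is why multi-run statistics are reported.

## Evaluation statistics

`metric_report()` computes MSE, mean absolute deviation (MAD), Theil's
inequality coefficient (TIC — scale-invariant, 0 for perfect agreement)
and Nash-Sutcliffe efficiency with its complement (NSE/ENSE).  NSE
defaults to the classical form
$1 - \sum (\hat y - y)^2 / \sum (y - \bar y)^2$, for which the
mean-of-reference predictor scores exactly 0; the variant that pairs a
$1/M$-scaled numerator with the prediction's deviations from the
reference mean, as the statistic is sometimes printed, is available via
`variant = "printed_form"` but is undefined at the mean predictor and is
not the default.  `aggregate_runs()` summarises repeated trainings by
minimum, mean and sample standard deviation (ddof = 1, the conservative
choice for a small number of runs; run count and per-run point count are
deliberately distinct quantities).

## Scale of the shipped computations

The defaults reproduce the benchmark tables at desk scale: film solves at
1001 grid points (about 0.1 s each), column integrations at 101 heights,
surrogate trainings on 1001-point datasets that converge in tens of LM
epochs (seconds to a few tens of seconds each), and ten-run statistics
for the stochastic summaries.  The test suite exercises smaller networks
and coarser grids wherever a property does not depend on size.

## What the generated data does and does not show

All reference data are generated by the package's own deterministic
solvers; they are noise-free and infinitely smooth samples of the exact
model.  Passing tests therefore demonstrate correctness of the numerics
and the trainability of the surrogate on clean profiles — they do not
demonstrate robustness to measurement noise, to model misspecification,
or to experimental biofilter data, none of which the model itself
represents.  Known limitations worth restating: the constant-$\alpha$
path accepts physically questionable values above 1 by design; the
`as_printed` column coupling is a deliberately literal reading kept for
comparison; and the surrogate's logistic output cannot reach the
interface boundary value exactly.
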