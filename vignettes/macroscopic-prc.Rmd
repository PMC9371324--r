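---
title: "Macroscopic phase-resetting curves of renewal spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macroscopic phase-resetting curves of renewal spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A network of `N` all-to-all coupled spiking neurons is described at the
single-cell level by a renewal (escape-rate) process: a neuron whose last
spike happened `r` milliseconds ago ("age" `r`) and which receives total
input `h(t)` fires in `[t, t + dt)` with probability `S(h, r) dt`. The
hazard `S` encodes refractoriness and intrinsic noise; the package ships the
standard textbook forms (`hazard_model()`), all of the type
`S(h, r) = exp(h) f(r)` or close variants: a hard threshold
`exp(h) H(r - T_ref)`, its softened version
`exp(h) H(r - T_ref)(1 - exp(-(r - T_ref)/tau))` where `tau` acts as an
effective noise level, a linear ramp, saturating `tanh` forms, and the
hazard of a gamma interspike-interval density. Hazards and ISI densities
are equivalent descriptions (`hazard_to_isi()`, `isi_to_hazard()`,
`dS_dh_from_isi()`); the quotient formulas dividing by the survivor
function are evaluated with a configurable survivor floor (default `1e-8`)
below which the hazard is held at its last reliable value, because the
quotient becomes numerically meaningless once essentially the whole
probability mass has fired.

Units: time in ms, rates in 1/ms, inputs in mV entering `exp(h)`
dimensionlessly.

Each spike feeds back through an exponentially filtered synaptic current,
`tau_s dIs/dt = -Is + Js A(t)`, `h = I_ext + Is`, where `A(t)` is the
population activity. In the large-`N` limit the network is described by the
refractory-density (age-structured von Foerster) equation for the age
density `q(t, r)`:

```
dq/dt + dq/dr = -S(h, r) q,    q(t, 0) = A(t) = \int S(h, r) q(t, r) dr.
```

For sufficiently strong coupling and drive the stationary (asynchronous)
state destabilises and a collective limit-cycle oscillation emerges. The
package computes the phase-resetting curve of that *macroscopic* rhythm
(mPRC) from the adjoint of the linearised dynamics around the mean-field
limit cycle: the normalised adjoint pair `(Z_q, Z_Is)` satisfies
`int Z_q dq/dt dr + Z_Is dIs/dt = 2*pi/T` at every phase, and `Z_Is(theta)`
is the phase shift (radians) per mV of instantaneous displacement of the
synaptic current — the mPRC, since input from outside the circuit arrives
through the synapses.

## Numerical design

**Forward solver.** The transport equation is integrated along
characteristics on an age grid `r_j = j dt` (`dt` = age step = time step),
with first-order decay `1 - dt S`. Two design points deserve comment:

* *Conservation.* The boundary cell receives exactly the probability mass
  fired during the step, `q_1^{n+1} = A^n = dt sum_j S_j^n q_j^n`
  (rectangle sums throughout). Under this bookkeeping the discrete mass is
  conserved to machine precision apart from the (tracked) leak past the
  grid end. Evaluating the activity sum at the new time instead, or giving
  the boundary node a half trapezoid weight, books the influx one step
  ahead of the outflux and lets the mass wobble by `O(dt * A)` within each
  cycle — a 6% transient error at `dt = 0.05` through a synchronised
  volley, against `< 1e-3` for the conservative form.
* *Stability.* The decay factor may transiently go negative where the
  hazard saturates (`dt S > 1`), which remains contractive; the solver
  aborts only at the true stability boundary `dt S >= 2` and warns in
  between. With hard-threshold hazards in strongly synchronised regimes
  this matters: `exp(h)` can exceed 50/ms at the volley peak.

The age grid is truncated at `r_max = 1.25 T_ref` by default — by that age
essentially the whole population has fired in the regimes of interest —
and leaked mass is monitored.

**Age truncation and initialisation.** Runs start from a truncated
Gaussian age profile (mean `T_ref/2`, sd `T_ref/6`) normalised under the
scheme's quadrature, and the synaptic current at 0.

**Limit cycle.** After a transient, the period is estimated from upward
crossings of `Is` through its running mean (the Poincare section that also
anchors phase 0); one period is resampled onto `M = round(T/dt)` samples
by linear interpolation and *periodised*: the residual end-to-end gap
(reported as the `defect`) is distributed linearly across the period so
that the stored cycle wraps exactly. Oscillation detection treats a
decaying ringing amplitude (stable-focus transient) and a relative
amplitude below `1e-3` as "no oscillation"; the secondary Floquet modes of
these networks are weakly damped (multipliers `0.98-0.997` per period), so
classification close to the bifurcation needs long transients.

**Adjoint solver.** One backward period of the adjoint equations is a
linear map of the section state; the periodic adjoint is its
unit-eigenvalue eigenvector. Plain backward cycling (power iteration)
stalls at the weakly damped spectrum, so the eigenvector is extracted by a
small restarted Arnoldi eigensolve whose matrix-vector product is one
backward period, after deflating the exactly known trivial solution
(`Z_q` constant, `Z_Is = 0` — the conserved-mass functional, which pairs
to zero with any input-driven perturbation). Convergence is measured on
the direction of the section state because the discrete dual eigenvalue is
`1 + O(dt)`; the recorded trace is Floquet-corrected by dividing out that
uniform tilt.

Two backward steps are provided. The default (`scheme = "transpose"`) is
the *discrete adjoint*: the exact transpose of the forward scheme's
linearised step, whose pairing with the cycle's own secant tangent is
conserved essentially exactly — the normalisation bracket is then flat to
0.07% on the soft-threshold benchmark and to ~2% even for the
near-singular hard-threshold volley. The direct first-order
discretisation of the continuous adjoint equations
(`scheme = "characteristics"`, with nearest-node extrapolation at the
oldest age and trapezoid age sums) is retained and agrees with the
transpose on the mPRC to a fraction of a percent; its bracket however
inherits an `O(dt)` inconsistency that concentrates at sharp volleys
(17% locally at `dt = 0.005` for the hard threshold), which is why it is
not the default. Normalisation rescales by the mean bracket and errors
out if the bracket changes sign or deviates more than 10% from constancy.

**Resolution defaults.** Forward exploration uses `dt = 0.05` ms; cycles
feeding the adjoint use `dt = 0.005` ms. Unit tests run the pipeline at
`dt = 0.02` and the validation suite at `dt = 0.005`; the hard-threshold
(`tau = 0`) benchmark uses a 4000 ms transient because its weakly damped
modes decay slowest. These sizes keep the full test suite in the
minutes range on one CPU.

## Direct-perturbation validation

`perturb_meanfield()` measures phase shifts by running paired trajectories
from the same on-cycle state and comparing late Poincare-crossing times
(positive = advance). Where the pulse enters matters:

* a pulse injected through the synaptic drive
  (`tau_s dIs/dt = ... + tau_s p(t)`, route `"synaptic"`) displaces `Is`
  by its charge, so the shift per unit charge converges to `Z_Is` — this
  is the protocol that validates the adjoint mPRC, and it mirrors how
  activity from another circuit enters the equations;
* a pulse added to the external current (route `"iext"`) acts on `h`
  unfiltered; the adjoint pairing shows the corresponding sensitivity is
  `Z_h = Z_Is/tau_s - dZ_Is/dt`, *not* `Z_Is`. The package verifies this
  identity numerically (correlation with `Z_h` ~ 0.97 versus ~ 0.1 with
  `Z_Is` itself on the benchmark). Published protocols that pulse the
  external current and overlay the result on `Z_Is` rely on the two
  shapes being similar, which holds only when the derivative term is
  small.

Because the measured shift integrates the PRC over the pulse, finite-pulse
measurements are compared against the adjoint curve at the pulse centre
(or its pulse average); with 1 ms pulses of 0.4 mV/ms the 16-point sweep
correlates with the adjoint mPRC at r > 0.998 and halving the amplitude
halves the shift within a few percent.

**Spiking network.** `perturb_spiking()` applies the pulse to `h` of every
neuron in paired (common-seed) stochastic simulations and reads phases
from peaks of the Gaussian-smoothed (sd `T/20`) population activity. The
stochastic simulator itself evaluates the hazard at the midpoint age
`r + dt/2` and, on firing, draws the exact within-step event time and
restarts the age at the residual — these renewal processes are so regular
(ISI CV ~ 1.5%) that the `O(dt)` bias of the naive per-step rule (about
-1.9% on the stationary rate at `dt = 0.1`) would otherwise dominate every
statistical comparison. The naive rule is kept as `scheme = "simple"`.
Even so, a small systematic excess rate of order `1/N` remains in
recurrent networks (synaptic-current fluctuations rectified by the convex
`exp(h)` rate — about +0.07% at `N = 5000`), so stationary-rate
comparisons against the `N -> infinity` mean field are accurate to a
fraction of a percent but *not* to within the (tiny) standard errors of
long averages; the validation suite states this expectation precisely and
the corresponding check documents the discrepancy rather than hiding it.

## Stability analysis

Linearising around the asynchronous state gives a characteristic function
`C(lambda)` whose roots are the eigenvalues of the linearised operator;
`C(0) = 0` always (mass conservation). `characteristic_general()`
evaluates the quadrature form for any hazard (with the inner integral
simplified through `q_inf = A_inf exp(-cumhaz)`, which removes all
large-exponential intermediate terms); for the hard threshold the closed
form `C(lambda) = lambda - Js lambda kappa(lambda) A_inf + e^h -
e^{h - lambda T_ref}` is available, and the two are related *exactly* by
`C_closed = (e^{h_inf} + lambda) C_general` — the package asserts this
identity at random complex points. The Hopf line `C(i omega) = 0` is
traced in the `(I_ext, Js)` plane by warm-started 2-D Newton with the
steady state recomputed self-consistently at each coupling; the rightmost
eigenvalue is approximated by multi-start damped Newton (a heuristic — no
argument-principle counting — documented as such).

## Phase locking of two coupled circuits

For two identical circuits coupled symmetrically with strength `eps*Gs`
(folded into one number, since only the product appears) and conduction
delay `d`, the weakly-coupled-oscillator reduction gives
`dtheta/dt = G(theta) = H(theta - d) - H(-theta - d)` with
`H(theta) = (eps Gs / T) \int Z_Is(s) A(s - theta) ds`. `interaction_H()`
computes `H` as a circular cross-correlation on the cycle grid,
`g_function()` locates the zeros of `G` (stable when the slope is
negative; zeros closer than two grid steps are merged and flagged), and
`delay_bifurcation()` sweeps the delay. `simulate_coupled()` validates the
prediction on finite stochastic networks; because the locking flow is slow
(`|G| ~ 1e-3` ms/ms at `eps Gs = 0.2`), the two circuits start with a
quarter-period age offset — starting exactly in-phase on an unstable
in-phase state would look locked for thousands of milliseconds — and the
empirical lag is the circular mean of matched activity-peak differences
over the last half of the run.

## Worked example

```{r, eval = FALSE}
library(mprcnet)

hz <- hazard_model("exp_relax", T_ref = 10, tau = 5)
fit <- network_prc(hz, I_ext = 2, J_s = 15, tau_s = 10, dt = 0.005)
summary(fit)
plot(fit)

# locking prediction for two circuits coupled with eps*Gs = 0.2 mV ms
H <- interaction_H(fit$mprc, fit$cycle$A, fit$cycle$T, 0.2)
g_function(H, d = 4.5)      # anti-phase stable at this delay
```

## What the simulations do and do not show

The stochastic generator realises exactly the model class the mean-field
theory assumes: homogeneous all-to-all coupling, exponential synapses,
renewal neurons with the specified hazard. Agreement between the spiking
simulations and the theory therefore validates the solvers, not the
biological realism of the model: heterogeneity, sparse connectivity,
conductance synapses, adaptation (non-renewal memory) and
excitatory-inhibitory structure are all outside the present scope.
Limitations worth keeping in mind: everything is first-order in `dt`
(hard-threshold volleys converge slowly); the Hopf line is only traced for
the hard-threshold hazard (no closed form otherwise); the rightmost-root
search is heuristic; and the weak-coupling reduction is first order in
`eps*Gs`, so predicted lags drift for strong cross-coupling.
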