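---
title: "Methods: MSD theory for the focal-adhesion centroid jump process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSD theory for the focal-adhesion centroid jump process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centroidMSD)
```

## The process

The package models amoeboid cell motion as a discrete-time jump process.
A cell has `n` focal adhesions (FAs), each attached or detached; the
binary vector $\psi$ and the FA positions $v_i$ together with positive
spring weights $\alpha_i$ determine the centroid through the force
balance $\sum_i \alpha_i \psi_i (v_i - c) = 0$, i.e. $c$ is the weighted
mean of the attached sites. One FA switches state per binding event: with
$k$ attached, each attached FA detaches with probability
$p_k = 1/(k + (n-k)r)$ and each detached FA attaches with probability
$r\,p_k$, so that the per-event probabilities total one. An attaching FA
is placed at a random outreach $\eta \sim \nu$ from the current centroid;
a detached FA keeps its position until it reattaches; if every FA is
detached the centroid does not move. The process is space- and
time-homogeneous, and the attachment count is an autonomous birth--death
chain whose stationary distribution $\pi_k$ is available in closed form
(`stationary_distribution`).

This jump process is the large-spring-constant limit of a force-based
ODE model in which attached springs drag the cell body; only the jump
process is implemented here. "Time" is measured in binding events
throughout, so the MSD lag $\tau$ is an event shift, not a physical time.

## Parameters

* `n` (count, default none): total number of FAs. The analytic formulas
  are exact integer/binomial expressions; values up to a few dozen are
  numerically unproblematic in double precision.
* `r` (dimensionless, $>0$): propensity of a detached FA to switch
  relative to an attached one. Large `r` keeps the cell nearly fully
  attached; small `r` nearly fully detached.
* `nu` (`outreach_distribution`): outreach law in polar form. Defaults:
  length uniform on $[0, 10]$ length units, angle uniform on
  $[-30^\circ, 30^\circ]$ measured counter-clockwise from the positive
  $x$-axis. The angle interval is accepted in degrees at every interface
  and converted internally; the reference axis only affects the direction
  of the drift $E_\nu[\eta]$, not $E_\nu[\|\eta\|^2]$. Uniform and
  degenerate laws are supported: they cover the study conditions and have
  exact moments, which the MSD theory needs.
* `events`, `burn_in` (counts): recorded and discarded binding events.
  The burn-in default of 10,000 events reaches the stationary
  attachment-count occupancy (total variation $< 0.01$) for $n \le 10$
  over $r \in [0.25, 100]$ with a wide margin.
* `weights` ($\alpha_i$, default all 1): the simulator supports unequal
  spring weights, but every analytic operation rejects them -- the
  displacement algebra below assumes the plain mean.

## Sequential configurations and the AMSD

An attach event that brings the count from $k-1$ to $k$ displaces the
centroid by exactly $\eta/k$, whatever the configuration. Detach
displacements depend on the whole configuration, which is where the
approximation enters: a configuration is *sequential* if it has a
creation story that attaches one FA at a time at outreaches
$\eta_2, \dots, \eta_k$ from the successively updated centroids
(`build_sequential_state`). For such configurations the $k$ possible
detach displacements are explicit linear combinations of the
$\eta_m/m$ (`detach_possibilities`), each equal to $(c_k - v_d)/(k-1)$
for the detaching site $d$ — a property the tests exploit as a geometric
brute-force oracle.

Squaring, dropping the cross terms between distinct outreaches, and
summing over the $k$ possibilities gives the per-state detach expectation
(`detach_sum_expectation`); the cross terms vanish exactly for an
isotropic angle law and are deliberately ignored otherwise, mirroring the
way the closed form is assembled. Weighting attach terms with the full
stationary probabilities $\pi_k r p_k (n-k)$ and detach terms with
$\pi_k p_k$ — i.e. *pretending every configuration is sequential* —
yields the closed-form one-lag estimate `amsd`. For $n \le 2$ every
configuration is sequential and the AMSD is exact
(`exact_msd_small_n`); the identity `amsd(2, r, nu) ==
exact_msd_small_n(2, r, nu)` holds for all `r` and is tested on a grid.

## Bounds

The probability that the count reached $k$ by a history *identical* to a
creation story (no detachment ever) and then detaches is
$P_k^d = \pi_0\, k\, r^k p_0 \cdots p_k\, n!/(n-k)!$
(`sequential_path_probability`). Crediting detach events only with this
probability — and zero for every unknown value — gives the lower bound
`lower_bound_msd`; it keeps the AMSD's attach part and satisfies
$LB \le AMSD$ term by term.

For the upper bound, the extremal placement puts every FA at maximal
outreach $\eta_{max}$ from its predecessors along one direction. The
resulting placement recurrence
$x_t = (x_{t-1} + \dots + x_{t-n+2})/(n-1) + \eta_{max}$ has the unique
fixed point $x^* = \eta_{max}(n-1)$, and all roots of its characteristic
polynomial $(n-1)\lambda^{n-2} = \lambda^{n-3} + \dots + 1$ lie strictly
inside the unit circle with exactly one positive real root
(`characteristic_roots`), so the fixed point attracts and the worst-case
displacement $\eta_{max}(n-1)/k$ is approached in the limit. Charging
that displacement, squared, to all non-sequential detach probability
$\max(0,\, k \pi_k p_k - P_k^d)$ yields `upper_bound_msd`. The bound is
deliberately coarse — a rare worst case carried with a large
probability — but it is a genuine bound, and the simulated MSD stays
below it in every test.

## MSD as a function of the lag

For a process that is space- and time-homogeneous and a sum of i.i.d.
jumps, $MSD(\tau) = \tau\,\mathrm{Var} + \tau^2 \|E\|^2$. The centroid
jumps are *not* independent (the attachment count correlates successive
displacements), so `msd_of_tau` applies this quadratic form with the
AMSD as the $\tau = 1$ value and `mean_jump` as the drift, as an
approximation: exact at $\tau = 1$ by construction, linear in $\tau$ for
an isotropic outreach, and upward-bending when the outreach is biased.
At $\tau = 50$ the curve flattens monotonically both in $n$ (at fixed
$r = 10$) and in $r$ (at fixed $n = 5$), the qualitative signature that
adhesiveness suppresses motility.

## What the simulator emulates, and what it does not

The simulator *is* the data generator for all empirical checks: there is
no external data. It reproduces the study conditions — default $\nu$ as
above, initial FAs equally spaced on a circle of uniform random radius
in $[0, 10]$ with all FAs attached, a burn-in, then $10^5$–$10^6$
recorded events (desk scale; the reference figures used up to $10^7$,
and the comparisons here carry sampling-error tolerances accordingly).
It does not emulate features of real cell tracks: physical time between
events, spatially heterogeneous substrates, correlated outreaches,
three-dimensional motion, or measurement noise. Passing tests therefore
validate the mathematics of the model, not its biological fidelity.

## Numerical and design choices

* **Draw order.** Each event consumes uniforms in a fixed order:
  event type, FA selection, then (attach only) outreach length and angle.
  Degenerate laws still consume their draw. FA selection maps one
  uniform to an index (`floor(u*m) + 1`). The C++ event loop uses R's
  RNG stream and long-double centroid accumulation so that it reproduces
  the pure-R `step_event` bitwise — a tested invariant, and the reason
  trajectories are bit-reproducible from a seed across both code paths.
* **Stationary grouping of $\pi_k$.** The closed form is implemented as
  $r^{k-1}\binom{n-1}{k-1}[k+(n-k)r]\big/\big(2(1+r)^{n-1}k\big)$, the
  grouping fixed by requiring exact agreement with the enumerated
  $n = 2$ and $n = 5$ state tables and with birth--death stationarity.
* **Detach expectation as a sum.** `detach_sum_expectation` is the *sum*
  over the $k$ detach possibilities, not their average; each possibility
  carries the per-FA probability $p_k$ in the assembly. The $k = 2$
  reduction ($E_\nu[\|\eta\|^2]/2$) pins this convention down.
* **Constructive bounds.** `lower_bound_msd` and `upper_bound_msd` are
  assembled from their probabilistic ingredients (attach part,
  $P_k^d/k$ times the detach sum, worst-case remainder) rather than from
  a single typeset formula; the assembly preserves $LB \le AMSD \le UB$
  term by term and reproduces the exact $n = 2$, $r = 1$ values
  $275/24$ and $175/12$.
* **Ensemble averages and periodicity.** The attachment count flips
  parity at every event, so from a deterministic start the count at a
  *fixed* event index never mixes parities, and ensemble statistics at
  fixed lag are parity-biased no matter how long the burn-in. Time
  averages are unaffected. For ensemble estimates the
  `steady_state_count` initialisation draws the initial count from
  $\pi$, which the count chain then preserves exactly at every
  subsequent event.
* **Degenerate inputs.** $k = 0$ forces an attachment, $k = n$ a
  detachment; a detachment from $k = 1$ leaves the centroid in place and
  contributes zero to every MSD expression; `events = 0` yields an empty
  trajectory that still round-trips through the CSV format.
* **Exact arithmetic in tests.** Where a property is an algebraic
  identity (probability normalisation; the aggregate detach probability
  $\sum_k \pi_k k p_k = 1/2$), the tests verify the equivalent integer
  binomial identity $\sum_k a^{k-1} b^{n-k}\binom{n-1}{k-1} =
  (a+b)^{n-1}$ for rational $r = a/b$, which doubles represent exactly
  below $2^{53}$.

## Known limitations

* The AMSD is an approximation whose error is smallest when
  configurations are nearly sequential (small `r`, or small `n`). Across
  the tested grid ($n = 2..10$, $r \in \{0.25, 1, 10\}$, $10^6$ events)
  the relative error against the simulated MSD grows from under 1%
  ($n = 2$, any `r`; small `n` at `r = 0.25`) to roughly 10% at
  mid-range `r` and larger `n` — approximation bias, not sampling error.
  The acceptance suite records this honestly rather than loosening the
  comparison.
* `msd_of_tau` inherits the independence assumption of the quadratic lag
  law; for $\tau > 1$ it is an estimate, with no error bound supplied.
* The upper bound grows like $\eta_{max}^2 (n-1)^2$ and is far from the
  simulated MSD for moderate `n`; its value is the proof of existence
  and the worst-case machinery, not tightness.
* Closed-form moments restrict $\nu$ to uniform or degenerate length and
  angle laws; other laws would need numerical quadrature, which the
  constructor deliberately rejects rather than silently approximating.
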