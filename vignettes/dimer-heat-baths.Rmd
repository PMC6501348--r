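---
title: "Multi-resolution dimer models in short-range and long-range heat baths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution dimer models in short-range and long-range heat baths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerbath)
```

## The model

The solute is a dimer: two monomers of equal mass $M$ at positions
$\mathbf X_1, \mathbf X_2$, joined by a harmonic spring
$\Phi(R) = k (R - \ell_0)^2/2$ acting on the separation
$R = |\mathbf X_2 - \mathbf X_1|$. Everything is in dimensionless units;
there is no unit-conversion layer. The macroscopic reference description of
the solvent is a pair of Langevin equations, one per monomer, with friction
$\gamma$ and velocity-noise amplitude $\gamma\sqrt{2D}$ per component, so
the stationary velocity variance is $D\gamma$ per component and the thermal
energy is fixed by the Einstein–Smoluchowski relation $k_BT = M D \gamma$
(temperature is *not* a free parameter anywhere in the package).

Three equilibrium statistics of the centre of mass
$\bar{\mathbf X} = (\mathbf X_1 + \mathbf X_2)/2$ serve as benchmarks,
because they are closed-form for the Langevin dimer:

* the velocity autocorrelation function
  $C_d(\tau) = \tfrac13\langle \bar{\mathbf V}(t+\tau)\cdot
  \bar{\mathbf V}(t)\rangle = (D\gamma/2)e^{-\gamma\tau}$
  (`analytic_vacf()`),
* the diffusion constant $D_d = \int_0^\infty C_d = D/2$
  (`analytic_dimer_diffusion()`),
* the mean length $L_d \approx \ell_0(1 + 2MD\gamma/(k\ell_0^2))$, first
  order in $\varepsilon = MD\gamma/(k\ell_0^2)$ (`analytic_mean_length()`;
  a warning fires at $\varepsilon > 0.1$, a threshold we chose since the
  derivation only assumes $\varepsilon \ll 1$).

The two explicit solvents below converge to this Langevin description in
the appropriate limits ($\mu \to \infty$, and $\bar\omega \to \infty$ with
growing oscillator counts), which is what the estimators and the test suite
check quantitatively.

## Short-range bath: collision MD in a co-moving frame

The first solvent is a gas of point particles of mass $m = M/\mu$ that
interact with the monomers (balls of radius $r_0$) only through elastic,
frictionless collisions: tangential velocity components are unchanged and
the normal components undergo the $\mu$-weighted exchange of
`elastic_collision()`, which conserves momentum and kinetic energy exactly.

For the gas to reproduce friction $\gamma$ and diffusion $D$ on a single
monomer, its Maxwell–Boltzmann velocity scale and spatial Poisson density
must be calibrated as
$$
\sigma_\mu = \sqrt{(\mu+1)D\gamma}, \qquad
\lambda_\mu = \frac{3}{8 r_0^2}\sqrt{\frac{(\mu+1)\gamma}{2\pi D}} .
$$
The density follows from the free-molecular (Epstein) drag on a sphere with
the reduced-mass collision rule, $\gamma M = \tfrac83\sqrt{2\pi}\,
\lambda_\mu m_r \sigma_\mu r_0^2$ with $m_r = m\mu/(\mu+1)$. Because the
printed source for this constant is easy to mistranscribe, the package
treats the calibration as an *operational* contract and verifies it
directly: `measure_collision_friction()` holds a monomer at constant
velocity in the gas, accumulates collision impulses, and recovers
$\gamma$ within 10% — this oracle is part of the test suite.

### The co-moving frame

Simulating the gas in all of space is impossible, so the gas is explicit
only inside a cubic frame of side $L$ that moves with the dimer (anchored
at the centre of mass, or on the individual monomers for the two-bath and
mixed variants). One step of `step_comoving()` performs:

1. free flight of monomers and gas;
2. overlap detection and rewind: a particle whose free-flight endpoint lies
   inside a monomer is rewound to the exact quadratic contact time, the
   elastic exchange applied, and both bodies replayed for the remaining
   fraction of the step;
3. a forward-Euler spring kick on the monomer velocities;
4. frame recentring and deletion of particles that left the box;
5. stochastic boundary insertion.

Insertion is where the statistical mechanics lives. The expected number of
gas particles crossing one face in a step,
$p_{in} = \lambda_\mu L^2\Delta t\,(\sigma_\mu/\sqrt{2\pi}\,
e^{-V^2/2\sigma_\mu^2} - \tfrac V2\,\mathrm{erfc}(V/\sigma_\mu\sqrt2))$
with $V$ the frame velocity along the face's inward normal, is used as a
per-face Bernoulli probability; the run aborts if the total over six faces
exceeds 0.1, because the scheme inserts at most one particle per step. The
inserted particle's penetration depth follows the erfc-tail law
$p(z;\beta) \propto \mathrm{erfc}(z+\beta)$ with
$\beta = V/(\sigma_\mu\sqrt2)$, sampled *exactly* by the
acceptance–rejection scheme of `erfc_tail_sample()` (exponential proposal
with mean $a_1(\beta)$, envelope scaled by $a_2(\beta)$; acceptance
probability $2/\pi \approx 63.7\%$ at $\beta = 0$, or $86.3\%$ with the
tuned pair $a_1 = 0.532$, $a_2 = 0.814$). Its velocity component along the
inward normal is a Gaussian conditioned to reach that depth within the
step (`truncated_gaussian_velocity_sample()`). Finally, because six
half-space influx calculations over-count edges and corners, a proposal
whose back-propagated origin has $j$ coordinates outside the box is kept
with probability $1/j$ (`overcount_acceptance()`).

The single strongest test of this machinery is equilibrium maintenance: an
*empty* frame, static or dragged at constant velocity, must hold the
particle count Poisson($\lambda_\mu L^3$) and the velocities
Maxwell–Boltzmann indefinitely. The suite runs $10^5$ steps of
`simulate_bath_frame()` and applies $\chi^2$ and Kolmogorov–Smirnov tests
at the 1% level.

### Numerical choices and edge cases

* **Several collisions in one step.** The algorithm is derived assuming at
  most one collision per step, and at the standard parameters a collision
  occurs in only $\sim 0.3\%$ of steps per monomer. But over $10^7$ steps,
  steps in which *two different* particles overlap monomers are certain to
  occur, so treating them as a fatal error would make the prescribed runs
  impossible. The engine instead resolves distinct particles independently
  (earliest contact first) and counts such steps in
  `multi_collision_steps`. A collision replay can also shift a monomer by
  $O(\Delta V\,\Delta t)$ and leave an untouched grazing particle
  marginally inside it at the next step's start; such shallow, approaching
  overlaps are resolved as immediate contacts, while a particle found
  *deep* inside a monomer — which genuinely indicates a broken
  configuration — raises an error.
* **Departed particles never return.** This is a known bias of the moving
  frame, not corrected here (a particle that leaves a frame anchored on an
  accelerating monomer could re-enter in reality). It is the mechanism the
  original analysis offers for the few-percent distortion of the mixed
  model's VACF at $L = 0.32$; in this implementation the $[0,1]$
  Green–Kubo integral comes out a few percent *below* $D/2$ at that frame
  size and within a percent of it at $L = 0.48$, so the sign of the bias
  is an implementation detail of the frame bookkeeping, not a property of
  the method.
* **Insertion overlapping a monomer.** Unspecified upstream; we reject such
  insertions, consistently with how initialization culls overlaps, and
  count them (`overlap_culled_insertions`; at standard parameters this is
  rare because faces sit $2r_0$ from the anchored monomer).
* **Monomer–monomer excluded volume is not enforced** — the model defines
  no monomer–monomer collision; presets keep $\ell_0 \ge 2.25\,r_0$ so
  overlap is rare and shallow.
* **One-bath frame size.** With $L = 0.72$ the influx bound $6p_{in}\le0.1$
  forces $\Delta t \le 2.5\times10^{-7}$; the `short_range_one_bath` preset
  uses that step rather than the $10^{-6}$ of the smaller frames.

### Mixed resolution

`simulate_short_range(mode = "mixed")` keeps monomer 1 in the collision
gas (frame anchored on it) while monomer 2 follows an Euler–Maruyama
Langevin step with the shared spring force. This is the configuration whose
VACF and Green–Kubo diffusion constant are compared against the Langevin
closed forms.

## Long-range bath: Kac–Zwanzig oscillators

The second solvent couples each monomer to $N_i$ harmonic oscillators with
frequencies drawn i.i.d. Exponential(mean $\bar\omega$) and couplings
chosen so that eliminating the oscillators yields a generalized Langevin
equation with the Lorentzian memory kernel
$\kappa(\tau) = (2\gamma/\pi)\,\bar\omega/(\bar\omega^2\tau^2+1)$,
$\int_0^\infty\kappa = \gamma$ (`friction_kernel()`). The kernel integral
is frequency-draw independent *by construction*: the coupling sum rules
$m\sum_j \alpha_j^2\omega_j^2 = 2\gamma\bar\omega/\pi$ (per monomer,
two-bath) and $\sum_j k_j\alpha_j^2 = \gamma\bar\omega/\pi$ (shared) hold
exactly, and the tests assert them to machine precision. The GLE itself is
never integrated — the oscillators are explicit, evolved together with the
monomers by synchronized velocity Verlet (`step_verlet_full()`), which is
time-reversible and conserves energy to the usual bounded drift (checked
at $10^{-4}$ relative over $10^4$ steps).

Oscillator initial conditions are thermal: velocities
$\mathcal N(0, k_BT/m)$ and positions Gaussian about the instantaneous
potential minimum with variance $k_BT/\text{stiffness}$. "Maxwell–
Boltzmann" alone does not pin down the positions; we chose equilibrium
about the minimum because it makes the fluctuation–dissipation property —
the autocovariance of the summed bath force on a pinned monomer equals
$k_BT\,\kappa(\tau)$ per component — hold from $t = 0$, and the suite
verifies exactly that ensemble identity. (Our direct calculation gives the
factor $k_BT$, not $2k_BT$; the test asserts the computed factor.)

Three coupling topologies share one integrator:

* **two_bath** — independent oscillator sets per monomer; the dimer
  statistics approach the Langevin predictions, and the mean length matches
  the first-order $L_d$ formula within its confidence interval;
* **shared** — one set coupled identically to both monomers
  ($k_j = m\omega_j^2/2$). The bath coordinates then cancel exactly from
  the separation dynamics, leaving
  $M\ddot{\mathbf R} = -2\Phi'(R)\hat{\mathbf R} - (\gamma\bar\omega/\pi)
  \mathbf R$, i.e. a *shortened* effective rest length
  $2k\pi\ell_0/(2k\pi + \gamma\bar\omega)$
  (`effective_rest_length_one_bath()`); simulations land on it to
  $\sim10^{-5}$ absolute;
* **split** — one nominal bath whose two halves couple exclusively to one
  monomer each; statistically identical to two_bath, demonstrating that a
  "single" heat bath can either shorten or extend the dimer depending on
  the coupling choice.

Extreme frequencies from the exponential tail are retained, never
truncated (truncation would bias $\kappa(0)$); the default step adapts
instead: $\Delta t = \min(10^{-3}/\bar\omega,\, 0.1/\omega_{\max})$, with a
hard error at $\Delta t\,\omega_{\max} > 1$. The mixed-resolution variant
(`mode = "mixed"`) integrates monomer 2 by the BBK acceleration
$-\Phi'(R)/M\,\hat{\mathbf R} - \gamma\mathbf V_2 +
\gamma\sqrt{2D/\Delta t}\,\xi$ inside the same half-kick structure, with a
fresh $\xi$ per acceleration evaluation. Whether the shared-mode bath uses
exactly $N$ oscillators or a Poisson count is unspecified upstream; we use
exactly $N$.

## Estimators

`estimate_vacf()` is the direct overlapping-origin time average on the
trajectory's sampling grid (recording every $10^{-3}$ time units by
default — decoupled from $\Delta t$, which can be $10^{-6}$). It uses the
raw product $\langle \bar V(t+\tau)\cdot\bar V(t)\rangle$ as defined, not
the demeaned autocovariance; on a run of production span $T$ the
unsubtracted sample mean inflates every lag by
$O(2 D_d/T)$ per component, so Green–Kubo estimates need
$T \gtrsim 50$ for percent-level work — the reason the acceptance runs are
longer than the shortest runs the tests use.
`diffusion_from_vacf()` integrates it by the trapezoidal rule over
$[0, 1]$, the interval used for all reported $D_d$ values;
`diffusion_from_msd()` provides the independent mean-squared-displacement
route, and `fit_exponential_vacf()` recovers $(D, \gamma)$ jointly by
Levenberg–Marquardt. Mean lengths come with two-sided 99% confidence
intervals from 20 batch means — the upstream analysis does not state its
CI construction, so batch means (autocorrelation-aware, simple, and
assumption-light) is our choice, with the burn-in defaulting to the first
half of the run as in the published protocol.

## What the tests do and do not show

The simulations in the test suite and the acceptance script are scaled-down
versions of the published protocols: the Langevin benchmark runs the full
$T = 200$, but the short-range mixed model runs $T = 20$ in the tests and
$T = 100$ in the acceptance script, at $\Delta t = 10^{-6}$ (the full
protocol is $T = 500$, about $5\times10^8$ steps), and the long-range mixed
model uses $N_1 = 10^3$ oscillators over $T = 20$ (tests) or $T = 100$
(script) rather than $N_1 = 10^5$ over $T = 10^3$. At these sizes the
Green–Kubo estimates carry confidence intervals of several percent, so the
checks assert consistency with $D/2$ within those intervals rather than
the third decimal place. Similarly, the thermal extension of the dimer at
$k = 10^6$ is $\sim 6\times10^{-5}$ — below desk-scale resolving power for
the collision bath — so positivity of the extension is demonstrated on the
routes where it is resolvable (Langevin and split-oscillator runs, plus a
softer-spring Langevin run against the quadrature mean of the stationary
length density), while the stiff-spring collision runs assert coverage of
the prediction by their confidence intervals.

The synthetic gas and oscillator baths are exactly the models being
studied, not approximations of real solvents: passing tests show that the
multi-resolution machinery reproduces the *Langevin limit* of these
idealized baths, not that any particular physical solvent behaves this
way.

## Reproducibility

Every simulator takes an integer `seed` and draws all randomness —
including inside the compiled loops — from R's generator, so a
configuration plus a seed reproduces a run bit for bit. A single stream is
used per run (sub-stream bookkeeping would only matter for comparing runs
that share some but not all draws, which nothing here does). Trajectories
serialize to CSV with a JSON metadata sidecar carrying the model tag,
parameters and seed; estimators are pure functions of the saved series.
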