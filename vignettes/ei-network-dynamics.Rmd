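---
title: "Mean-field theory of fluctuating activity in excitatory-inhibitory networks"
author: "eichaos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field theory of fluctuating activity in excitatory-inhibitory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eichaos)
```

## The model

`eichaos` analyses sparsely connected networks of excitatory and inhibitory
rate units,

$$\dot x_i(t) = -x_i(t) + \sum_{j=1}^N J_{ij}\,\phi(x_j(t)) + I,$$

where $x_i$ is the input current to unit $i$, $\phi$ a monotone positive
transfer function, and $J_{ij}$ a sparse random matrix in which every
excitatory synapse has strength $J$ and every inhibitory synapse $-gJ$.  In
the reference ensemble each neuron receives exactly $C$ inputs, a fraction
$f$ of them excitatory ($C_E = fC$, $C_I = (1-f)C$), so that excitatory and
inhibitory neurons see statistically identical inputs.  Time is rescaled so
the current time constant is one; all rate-model quantities are unitless.
The default transfer function is threshold-linear with offset $\gamma$ and
saturation $\phi_{max}$:
$\phi(x) = \min(\max(\gamma + x, 0), \phi_{max})$.

Defaults follow the standard choices for this model class: $\gamma = 0.5$,
$f = 0.8$, $I = 0$, and inhibition dominance $g > C_E/C_I$ so that the net
recurrent feedback $J(C_E - gC_I)$ is negative.  Autapses are not excluded:
the ensemble places each row's connections uniformly over all columns, so
self-connections occur with probability of order $C/N$; excluding them would
change the ensemble the theory describes.

## Stability of the fixed point and the first critical coupling

The homogeneous fixed point solves $x_0 = J(C_E - gC_I)\phi(x_0) + I$
(`solve_fixed_point()`).  Its stability is governed by the spectrum of the
gain-scaled connectivity: a densely filled disk of radius
$r = \phi'(x_0)\,J\sqrt{C_E + g^2 C_I}$ plus an outlier at
$\phi'(x_0)\,J(C_E - gC_I)$ carried by the non-zero row mean
(`spectrum_summary()`, `empirical_eigenvalues()`).  In the
inhibition-dominated regime the outlier is negative, and the first
instability is the disk edge crossing one, at the critical coupling
$J_C$ solved by `critical_coupling_Jc()`.  With $\gamma > 0$ and $I = 0$
the fixed point sits on the unit-gain branch for every $J$, so
$J_C = 1/\sqrt{C_E + g^2 C_I}$ exactly.

## Self-consistent statistics of the fluctuating state

Above $J_C$ the network settles into deterministic, irregular fluctuations.
The mean-field description replaces the recurrent input by a Gaussian
process, turning the network into identical Langevin units whose first two
moments must be computed self-consistently.  With
$[\cdot]$ denoting Gaussian averages over $x \sim \mathcal N(\mu, \Delta_0)$,
the stationary state obeys

$$\mu = J(C_E - gC_I)\,[\phi] + I,$$

together with an energy balance for the lagged autocovariance
$\Delta(\tau)$, which evolves like a classical particle,
$\ddot\Delta = -\partial V/\partial\Delta$, in the potential

$$V(\Delta, \Delta_0) = -\tfrac{\Delta^2}{2}
  + J^2(C_E + g^2 C_I)\left\{[\Phi\Phi](\Delta) - \Delta\,[\phi]^2\right\},$$

where $[\Phi\Phi](\Delta)$ is the double Gaussian average of the
antiderivative $\Phi$ of $\phi$ and the $-\Delta[\phi]^2$ term is the trace
of the perfectly homogeneous in-degree.  Note that the variance prefactor
$J^2(C_E + g^2C_I)$ multiplies *both* terms in the brace: integrating the
force equation term by term fixes this, and the uncoupled white-noise limit
(below) provides an independent check — with the prefactor on only the
first term, an uncoupled network driven by white noise of amplitude
$\Delta_{ext}$ would not recover the stationary variance
$\Delta_0 = \Delta_{ext}$ of the unit-time-constant filter.

The physical solution decays from $\Delta_0$ to zero at rest, which pins
$\Delta_0$ through $V(\Delta_0, \Delta_0) = V(0, \Delta_0)$.
`solve_dmf()` solves the mean equation and this balance jointly (the mean
is re-solved inside every variance evaluation, making the search
one-dimensional), and `autocorrelation_trajectory()` integrates the
particle motion for the full $\Delta(\tau)$.

Two consequences shape the phenomenology.  First, because rates are
positive, the mean and the variance are coupled: fluctuations raise the
mean firing rate well above its fixed-point value, and this elevation is
the experimentally accessible signature of the fluctuating state.  Second,
the decay timescale of $\Delta(\tau)$ diverges as $J \downarrow J_C$
(critical slowing down).

### Near-threshold behaviour

With $\gamma = 0.5$ the threshold kink sits a finite distance
$\gamma + x_0$ from the fixed point, so the nonlinear correction in the
energy balance turns on like $\exp\{-(\gamma+x_0)^2/2\Delta_0\}$.  The
variance branch is continuous at $J_C$ but rises logarithmically steeply:
$\Delta_0$ at $1.001\,J_C$ is already a few percent of its value at
$1.5\,J_C$, and the relaxation rate scales like $\sqrt{J - J_C}$ rather
than linearly.  The tests assert these (correct) qualitative properties
instead of linear-onset rules of thumb.

## The second critical coupling and the three regimes

With the saturation removed ($\phi_{max} = \infty$) the fluctuating
solution survives only up to a second coupling $J_D$: beyond it, the
positive tail of the Gaussian feeds back faster than inhibition can
stabilise, $\mu \to -\infty$ and $\Delta_0 \to \infty$ with a fixed ratio
$k = \mu/\sqrt{\Delta_0}$.  Substituting this ansatz into the mean equation
gives $k = J(C_E - gC_I)\,a_1(k)$, and the leading $\Delta_0^2$ order of the
energy balance turns existence of a finite variance into

$$J_D^2 (C_E + g^2 C_I)\left\{\tfrac{a_4(k) - a_2(k)^2}{4} - a_1(k)^2\right\}
 = \tfrac12, \qquad a_j(k) = E\!\left[\max(k+z,0)^j\right].$$

`divergence_coupling_Jd()` solves this pair; the result is cross-checked in
the test suite by bisecting the divergence classifier of `solve_dmf()`
(which scans the energy balance up to $\Delta_0 = 10^8$ before declaring
divergence), and the two agree to well under a percent.  The offset
$\gamma$ drops out at leading order, so $J_D$ depends only on $(g, C, f)$.

This yields three regimes, tabulated by `classify_regime()` and
`phase_diagram()`:

* $J < J_C$ — stable homogeneous fixed point;
* $J_C < J < J_D$ — *inhibition-stabilized* fluctuations: the statistics
  are essentially independent of $\phi_{max}$ (the package verifies
  $\Delta_0$ changes by well under 5% between $\phi_{max}=8$ and $\infty$);
* $J > J_D$ — *bound-stabilized* fluctuations: the mean rate and the
  fluctuation amplitude $\sqrt{\Delta_0}$ grow linearly with
  $\phi_{max}$, and the unbounded network runs away.

For purely inhibitory networks ($C_E = 0$) the recurrent input is strictly
non-positive and run-away activity is impossible; a $J_D$ predicted there
would be an artifact of the Gaussian approximation's positive tail, so
`divergence_coupling_Jd()` refuses such parameters with a dedicated error
class rather than returning a number.

## Noise, spiking interactions, and heterogeneous in-degree

**External white noise** of autocovariance $2\Delta_{ext}\delta(\tau)$
enters the particle picture purely as initial kinetic energy:
$\dot\Delta(0^+) = -\Delta_{ext}$.  The transition is smoothed — the
variance is positive at all couplings — while the feedback amplification
above $J_C$ and the location of $J_D$ are unchanged.  Weak noise preserves
an interior maximum of the fluctuation timescale near $J_C$; strong noise
removes it.

**Poisson spiking interactions** (units exchange spikes drawn from
inhomogeneous Poisson processes of rate $\phi(x_j)$, `simulate_rate_poisson()`)
reduce, at the mean-field level, to self-consistent white noise of
amplitude $\Delta_{ext} = J^2(C_E + g^2C_I)[\phi] / (2\bar\tau)$, updated
inside the same solve.  The printed sign of the delta term in the source
derivation is a typographical slip; the noise variance is positive, as in
the external-noise case.  Larger rate time constants $\bar\tau$ filter the
spiking noise away and recover the deterministic statistics.

**Stochastic in-degree** (each synapse present independently with
probability $C/N$, `build_stochastic_indegree()`) introduces quenched
disorder: the stationary state is heterogeneous with variance
$\Delta_0 = J^2(C_E + g^2C_I)[\phi^2]$, and the potential loses its
$-\Delta[\phi]^2$ term, so the particle comes to rest at a non-zero
$\Delta_\infty$ — the across-unit variance of time-averaged inputs.  In
`solve_dmf_stochastic_indegree()` the static branch sits exactly at a
stationary point of the potential; when it destabilises, the fluctuating
pair $(\Delta_0, \Delta_\infty)$ is found by scanning $\Delta_0$ just
*below* the static root and matching $V(\Delta_0) = V(\Delta_\infty)$ at
the smaller stationary point.  Near the instability no such pair exists
and the solver returns the static branch; this matches simulation, where
the temporal component only becomes appreciable well above the static
instability.

## General two-population networks (discrete time)

When excitatory and inhibitory neurons receive statistically different
inputs (block connectivity, `block_params()` / `build_block()`), the
continuous-time self-consistency involves two coupled autocorrelation
functions and loses the potential analogy; solving it is computationally
prohibitive, so the package follows the discrete-time route: for
$x(t+1) = J\phi(x(t))$ the stochastic input is unfiltered and the
stationary statistics reduce to four algebraic equations for
$(\mu_E, \mu_I, \Delta_0^E, \Delta_0^I)$, solved by damped fixed-point
iteration in `solve_dmf_discrete_two_pop()` (damping 0.3, residual
tolerance $10^{-11}$).  Discrete time adds a caveat: a strongly negative
real outlier can lose stability before the bulk radius does, producing a
period-2 homogeneous oscillation; the solver warns whenever
$|\mathrm{Re}\,\xi_\pm| \ge r$.

## LIF transfer function and spiking networks

To connect with integrate-and-fire networks the transfer function can be
replaced by the first-passage (Siegert) rate of an LIF neuron,
$F(\mu_0 + \tau_m x,\, \sigma)$, evaluated overflow-safely through the
scaled complementary error function ($\mathrm{erfcx}$) with a
log-asymptotic branch deep below threshold (`lif_F()`).  Because a
time-varying input variance is not tractable in the mean-field equations,
$\sigma$ is pinned to $\sigma^2 = \tau_m J^2 (C_E + g^2 C_I)\bar\phi$ for a
reference rate $\bar\phi$ (default 0.02/ms).  `solve_dmf_lif()` then runs
the same machinery; since every moment evaluation would otherwise trigger
hundreds of Siegert integrals, the rate is tabulated once per solve on a
monotone spline with constant/linear extension.  The upper bound of this
transfer function is $1/\tau_{rp}$, so the refractory period plays the
role of $\phi_{max}$: at intermediate coupling the predicted rates
saturate as $\tau_{rp} \to 0$, at strong coupling they grow like
$1/\tau_{rp}$.

`simulate_lif()` integrates the spiking network itself ($\tau_m$ = 20 ms,
$V_{th}$ = 20 mV, $V_r$ = 10 mV, $\mu_0$ = 24 mV, delay 1.1 ms): exact
exponential membrane decay between grid points, delta synapses delivered as
voltage jumps of the PSP amplitude $J_{ij}$ through a ring buffer with
bit-exact delays (the delay must be a multiple of the step), threshold
detection at grid points, reset and refractory clamp with inputs discarded
during the clamp.  The weak-coupling population rate is compared against
the self-consistent asynchronous rate `lif_fixed_point()`, in which both
the mean and the variance of the input are slaved to the rate.

## Numerical choices

* **Gaussian moments.**  For the threshold-linear function all four
  moments $[\phi], [\phi^2], [\Phi], [\Phi^2]$ use exact censored-normal
  closed forms (truncated-normal moment recurrences), cross-checked against
  adaptive quadrature to $10^{-8}$ in the tests.  Double averages use the
  closed-form inner expectation and a 101-node Gauss–Hermite outer rule
  (the outer integrand is smooth); endpoints $\Delta \in \{0, \Delta_0\}$
  are returned exactly.  Non-threshold-linear transfer functions fall back
  to 201-node Gauss–Hermite with panelwise Gauss–Legendre antiderivatives.
* **Variance search.**  The energy gap behaves like
  $c(J)\,\Delta_0^2$ near zero, so the geometric scan starts at
  $\Delta_0 = 10^{-6}$ — safely above the double-precision cancellation
  noise of the moment differences — and classifies the state divergent if
  no sign change occurs up to $10^8$.
* **Autocorrelation integration.**  Classical RK4 with $d\tau = 0.01$
  (0.02 in scans), the smooth $C(\Delta)$ splined once per trajectory;
  integration stops below $10^{-4}\Delta_0$ and the energy-conservation
  residual (verified $< 10^{-4}\Delta_0$) bounds quadrature and ODE error
  jointly.  A turnaround high on the potential raises an error; a
  turnaround after the decay merely truncates the trace (residual
  numerical energy near the flat hill top).
* **Simulators.**  Heun's method (deterministic) or Euler–Maruyama with
  $\sqrt{2\Delta_{ext}\,dt}$ increments (noisy), default $dt = 0.05$;
  initial currents $\mathcal N(0, 0.1^2)$ and LIF potentials uniform in
  $[V_r, V_{th}]$ to avoid artificial synchrony; transients of 50 time
  units (rate) or a few hundred ms (LIF) are discarded before statistics.
  Poisson interactions draw per-step spike counts from
  $\mathrm{Poisson}(\phi(x_j)\,dt)$ with step size restricted by
  $\phi_{max}\,dt/\bar\tau < 0.1$.  All randomness flows through R's RNG,
  so a seed makes runs bit-reproducible; trajectories are flagged divergent
  and truncated once $|x| > 10^{12}$.
* **Estimators.**  Variances and lagged covariances use the biased ($1/T$)
  normalisation; the empirical variance is reported as its decomposition
  into a temporal part and the across-unit variance of time means (the
  quenched part), whose sum is the total by construction — this covers
  both reasonable readings of "the" empirical autocovariance and exposes
  exactly the quantity the stochastic-in-degree theory predicts.  The
  fluctuation timescale is the full width at half maximum of
  $\Delta(\tau)$, doubled from the positive-lag half since the function is
  even.

## What the simulations do and do not establish

The simulators generate data from precisely the ensembles the theory
describes (plus finite $N$, finite $C$ and discretisation).  Agreement
between the two therefore validates the self-consistency machinery, not
the biological realism of the model: real cortical networks have
conductance synapses, synaptic time constants, structured connectivity and
non-threshold-linear transfer — all outside scope here.

Problem sizes were chosen so the whole suite runs comfortably on one CPU:
simulations use $N$ = 2000–10000 with $C$ = 100–125 (the LIF network is a
$C/N$-preserving scale-down of the usual $N = 20000$, $C = 500$ setting),
horizons of a few hundred time units (rate) or 1.5 s (LIF), and three
connectivity seeds where realization averaging matters.

## Known limitations

* **Gaussian closure error.**  The single-unit input distribution is
  skewed when inhibition dominates strongly (negative tail from
  $-gJ$ synapses acting on positive rates).  At $g = 5$ this makes the
  theory overestimate the mid-coupling variance: around
  $1.5$–$2.5\,J_C$ the predicted $\Delta_0$ exceeds the simulated one by
  roughly a fifth, an offset that does not shrink with $N$ (checked up to
  $N = 16000$) and is shared by two independent solution routes of the
  same equations.  Mean currents and mean rates stay within a few percent.
  The `gaussian_equivalent` ensemble exists to separate this entry-level
  non-Gaussianity from moment-matching effects.
* **Purely inhibitory networks** are described less accurately overall,
  and the divergence analysis does not apply (see above).
* **Near $J_D$** the variance is hypersensitive to any perturbation, so
  comparisons there are made on robust functionals (existence/divergence,
  noise-energy shares) rather than on $\Delta_0$ itself.
* **Finite-size synchrony.**  Population-averaged fluctuations decay like
  $1/N$; at small $N$ or small refractory periods the spiking network
  shows residual synchrony that the mean-field description ignores.

## Configuration format

The command-line front end (`inst/cli/eichaos.R`) reads scan
configurations as YAML, the natural configuration format in the R
toolchain, and writes a JSON manifest with the resolved options and seed
next to every output so runs can be reproduced exactly.
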