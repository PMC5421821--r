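# eichaos

Dynamical mean-field theory and fast simulators for intrinsically generated
fluctuating activity ("rate chaos") in sparsely connected
excitatory-inhibitory networks.

## The problem

A random recurrent network of rate units

    dx_i/dt = -x_i + sum_j J_ij phi(x_j) + I

with segregated excitatory and inhibitory populations (every excitatory
synapse `J`, every inhibitory synapse `-g*J`, exactly `C` inputs per neuron,
a fraction `f` of them excitatory) is the canonical bridge between the
classical theory of rate chaos and biologically constrained spiking
networks.  Because firing rates are positive, the mean and the variance of
the activity are coupled, and the network traverses three regimes as the
coupling `J` grows:

1. **fixed point** below `J_C = 1/(phi'(x0) sqrt(C_E + g^2 C_I))`, where the
   bulk spectral radius of the linearised connectivity crosses one;
2. **inhibition-stabilized fluctuations** for `J_C < J < J_D`: chaotic
   activity whose statistics barely depend on the saturation bound
   `phi_max`, stabilised by rate positivity plus dominant inhibition;
3. **bound-stabilized fluctuations** above `J_D`: the mean rate and the
   fluctuation amplitude `sqrt(Delta_0)` grow linearly with `phi_max`, and
   the unbounded network runs away.

The package solves the self-consistent mean-field equations for the mean
input `mu`, the variance `Delta_0` and the full autocovariance
`Delta(tau)` — for the deterministic network, with external white noise,
with self-consistent Poisson spiking noise, for binomial (stochastic)
in-degree, for general two-population block connectivity (discrete time),
and for an LIF (Siegert) transfer function — and verifies every prediction
against compiled network simulators (continuous rate, Poisson-spiking rate,
discrete map, and a spiking leaky integrate-and-fire network with delta
synapses and transmission delays).

Intended users: computational neuroscientists studying recurrent network
dynamics, and anyone needing a tested reference implementation of
self-consistent Gaussian moment equations for sparse EI ensembles.

## Worked example

```r
library(eichaos)

p  <- network_params(J = 0.2, g = 5, C = 100, f = 0.8, N = 4000)
tf <- threshold_linear(gamma = 0.5, phi_max = 2)

solve_fixed_point(p, tf)        # -0.4  (input current; rate phi(-0.4) = 0.1)
Jc <- critical_coupling_Jc(p, tf)
Jd <- divergence_coupling_Jd(p)
c(Jc, Jd)                       # 0.04152274 0.10566839

p$J <- 1.5 * Jc
sol <- solve_dmf(p, tf)
sol
#> DMF solution [fluctuating]: mu = -0.34585, Delta0 = 0.228596,
#>   Delta_inf = 0, mean rate = 0.397954
```

Above `J_C` the self-consistent variance is positive and the mean firing
rate (0.398) sits well above the fixed-point rate at the same coupling —
the mean-rate elevation that signals intrinsically generated fluctuations.
A matched simulation reproduces these statistics:

```r
W  <- build_fixed_indegree(p, seed = 1)
tr <- simulate_rate(W, tf, T = 400, dt = 0.05, seed = 2)
current_stats(tr, discard = 50, tf = tf)[c("mean_current", "delta0_emp", "mean_rate")]
#> $mean_current  -0.3294   $delta0_emp  0.1774   $mean_rate  0.268
```

Mean current and rate agree with the theory to a few percent; the simulated
variance sits somewhat below the Gaussian-closure prediction at
mid-coupling (a known limitation discussed in the vignette).  Classifying
regimes and scanning the phase plane:

```r
classify_regime(network_params(J = 0.08, g = 5, C = 100, N = 4000))
#> [1] "inhibition_stabilized"   (attr Jc = 0.0415, Jd = 0.1057)
phase_diagram(p, g_values = c(4.5, 5, 6), C_values = 100)
```

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/eichaos.R", package="eichaos"))')" \
    classify --J 0.08 --g 5 --C 100 --out out/
```

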