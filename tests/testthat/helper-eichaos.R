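# Shared fixtures: the reference parameter set used throughout the paper's
# single-statistics analysis (g = 5, C = 100, f = 0.8, gamma = 0.5).

tl_bounded <- function(phi_max = 2) threshold_linear(gamma = 0.5, phi_max = phi_max)
tl_unbounded <- function() threshold_linear(gamma = 0.5, phi_max = Inf)

ref_params <- function(J = 0.2, g = 5, C = 100, N = 2000, f = 0.8, I = 0) {
  network_params(J = J, g = g, C = C, f = f, N = N, I = I)
}

Jc_ref <- function(g = 5, C = 100, f = 0.8) 1 / sqrt(f * C + g^2 * (1 - f) * C)

# rate_trajectory wrapper for surrogate data matrices (units x frames)
surrogate_traj <- function(X, dt = 1) {
  eichaos:::new_rate_trajectory(times = dt * (seq_len(ncol(X)) - 1),
                                currents = X, dt = dt, seed = 0L,
                                divergent = FALSE)
}

# spike_data wrapper for surrogate spike trains
surrogate_spikes <- function(neuron, time, N, duration) {
  structure(list(spikes = data.frame(neuron = neuron, time = time),
                 N = N, duration = duration, params = NULL, seed = 0L),
            class = "spike_data")
}
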