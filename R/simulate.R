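#' LIF network simulation parameters
#'
#' Cell and synapse constants of the spiking leaky integrate-and-fire
#' network: membrane time constant, threshold and reset, refractory period,
#' synaptic transmission delay, and the constant suprathreshold drive
#' `mu_0`.  A warning is emitted when `tau_rp >= delay`, a configuration
#' known to produce spurious synchronization.
#'
#' @param tau_m membrane time constant (ms).
#' @param V_th spike threshold (mV).
#' @param V_r reset potential (mV).
#' @param tau_rp absolute refractory period (ms).
#' @param delay synaptic transmission delay (ms).
#' @param mu_0 constant external drive (mV).
#' @return An object of class `"lif_params"`.
#' @export
lif_params <- function(tau_m = 20, V_th = 20, V_r = 10, tau_rp = 0.5,
                       delay = 1.1, mu_0 = 24) {
  if (V_th <= V_r) stop("'V_th' must exceed 'V_r'")
  stopifnot(tau_m > 0, tau_rp >= 0, delay > 0)
  if (tau_rp >= delay)
    warning("refractory period >= synaptic delay: expect spurious synchronization")
  structure(list(tau_m = tau_m, V_th = V_th, V_r = V_r, tau_rp = tau_rp,
                 delay = delay, mu_0 = mu_0),
            class = "lif_params")
}

new_rate_trajectory <- function(times, currents, dt, seed, divergent,
                                extra = list()) {
  structure(c(list(times = times, currents = currents, dt = dt, seed = seed,
                   divergent = divergent), extra),
            class = "rate_trajectory")
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat(sprintf("rate_trajectory: %d units, %d frames (t in [%g, %g], dt = %g)%s\n",
              nrow(x$currents), ncol(x$currents), x$times[1],
              x$times[length(x$times)], x$dt,
              if (x$divergent) " [DIVERGENT]" else ""))
  invisible(x)
}

csc_slots <- function(conn) {
  W <- methods::as(conn$weights, "CsparseMatrix")
  list(p = W@p, i = W@i, x = W@x, n = nrow(W))
}

default_keep <- function(n_steps, max_frames = 2000L) {
  max(1L, ceiling(n_steps / max_frames))
}

#' Simulate the continuous-time rate network
#'
#' Integrates `x' = -x + W phi(x) + I` (plus optional additive white noise
#' with autocovariance `2 delta_ext delta(tau)`), using Heun's method for
#' deterministic dynamics and Euler-Maruyama with `sqrt(2 delta_ext dt)`
#' increments when noise is present.  Initial currents are drawn
#' `N(0, 0.1^2)` unless supplied.  If any current exceeds `1e12` in
#' magnitude the run is flagged divergent and the trajectory truncated.
#'
#' @param conn a `connectivity_matrix`.
#' @param tf transfer function (the compiled path supports
#'   [threshold_linear()]; other transfer functions fall back to a plain R
#'   integrator).
#' @param I external input current.
#' @param noise a [noise_spec()] of kind `"none"` or `"white"`.
#' @param T simulated time (unitless, time constant 1).
#' @param dt integration step (must be <= 0.1).
#' @param seed RNG seed (initial conditions and noise).
#' @param keep_every store every `keep_every`-th step (default: aim for
#'   about 2000 stored frames).
#' @param x0 optional initial currents.
#' @return A `"rate_trajectory"`: stored `times`, an `N x frames` matrix of
#'   `currents`, `dt`, `seed` and a `divergent` flag.
#' @export
simulate_rate <- function(conn, tf, I = 0, noise = noise_spec("none"),
                          T = 200, dt = 0.05, seed = 1, keep_every = NULL,
                          x0 = NULL) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  if (dt > 0.1) stop("'dt' must be <= 0.1")
  if (!noise$kind %in% c("none", "white"))
    stop("simulate_rate() supports noise of kind 'none' or 'white'; use simulate_rate_poisson() for spiking interactions")
  S <- csc_slots(conn)
  n_steps <- round(T / dt)
  keep_every <- keep_every %||% default_keep(n_steps)
  set.seed(seed)
  if (is.null(x0)) x0 <- stats::rnorm(S$n, 0, 0.1)
  delta_ext <- if (noise$kind == "white") noise$delta_ext else 0
  if (inherits(tf, "threshold_linear")) {
    r <- .sim_rate_cpp(S$p, S$i, S$x, S$n, tf$gamma, tf$phi_max, I, delta_ext,
                       x0, n_steps, dt, as.integer(keep_every))
  } else {
    r <- sim_rate_r(S, tf, I, delta_ext, x0, n_steps, dt, keep_every)
  }
  new_rate_trajectory(r$times, r$currents, dt * keep_every, seed, r$divergent)
}

# reference R integrator for non-threshold-linear transfer functions
sim_rate_r <- function(S, tf, I, delta_ext, x0, n_steps, dt, keep_every) {
  W <- Matrix::sparseMatrix(i = S$i + 1L, p = S$p, x = S$x, dims = c(S$n, S$n))
  x <- x0
  n_keep <- n_steps %/% keep_every
  out <- matrix(0, S$n, n_keep + 1)
  times <- numeric(n_keep + 1)
  out[, 1] <- x
  kept <- 0L
  divergent <- FALSE
  noise_sd <- sqrt(2 * delta_ext * dt)
  for (s in seq_len(n_steps)) {
    f1 <- -x + as.vector(W %*% tf_value(tf, x)) + I
    if (delta_ext > 0) {
      x <- x + dt * f1 + noise_sd * stats::rnorm(S$n)
    } else {
      xm <- x + dt * f1
      f2 <- -xm + as.vector(W %*% tf_value(tf, xm)) + I
      x <- x + dt / 2 * (f1 + f2)
    }
    if (max(abs(x)) > 1e12) { divergent <- TRUE; break }
    if (s %% keep_every == 0) {
      kept <- kept + 1L
      out[, kept + 1] <- x
      times[kept + 1] <- s * dt
    }
  }
  list(currents = out[, 1:(kept + 1), drop = FALSE],
       times = times[1:(kept + 1)], divergent = divergent)
}

#' Simulate the rate network with Poisson spiking interactions
#'
#' Units interact through spikes instead of rates:
#' `tau_bar x' = -x + sum_j W_ij chi_j(t)` where `chi_j` is an inhomogeneous
#' Poisson spike train of rate `phi(x_j(t))`.  Spike counts per step are
#' drawn as `Poisson(phi(x_j) dt)` (thinning of the inhomogeneous process
#' on the integration grid) and each spike adds `W_ij / tau_bar` to the
#' target currents.  Larger `tau_bar` filters the spiking noise more
#' strongly, bringing the statistics back toward the deterministic rate
#' model.
#'
#' @inheritParams simulate_rate
#' @param tau_bar time constant of the rate dynamics.
#' @param record_spikes store individual spike times (set `FALSE` for long
#'   runs where only the currents matter).
#' @return A `"rate_trajectory"` with additional fields `spikes` (a
#'   data.frame `neuron`/`time`, 1-based ids, if recorded) and
#'   `spike_count` (per-unit totals).
#' @export
simulate_rate_poisson <- function(conn, tf, tau_bar = 1, T = 200, dt = 0.02,
                                  seed = 1, keep_every = NULL,
                                  record_spikes = FALSE, x0 = NULL) {
  stopifnot(inherits(conn, "connectivity_matrix"),
            inherits(tf, "threshold_linear"))
  if (is.finite(tf$phi_max) && tf$phi_max * dt / tau_bar >= 0.1)
    stop("'dt' too large: phi_max * dt / tau_bar must be < 0.1")
  S <- csc_slots(conn)
  n_steps <- round(T / dt)
  keep_every <- keep_every %||% default_keep(n_steps)
  set.seed(seed)
  if (is.null(x0)) x0 <- stats::rnorm(S$n, 0, 0.1)
  r <- .sim_rate_poisson_cpp(S$p, S$i, S$x, S$n, tf$gamma, tf$phi_max,
                             tau_bar, x0, n_steps, dt,
                             as.integer(keep_every), record_spikes)
  spikes <- if (record_spikes)
    data.frame(neuron = r$spike_id + 1L, time = r$spike_t) else NULL
  new_rate_trajectory(r$times, r$currents, dt * keep_every, seed, r$divergent,
                      extra = list(spikes = spikes, spike_count = r$spike_count,
                                   tau_bar = tau_bar, T = n_steps * dt))
}

#' Simulate the discrete-time rate map
#'
#' Iterates `x(t+1) = W phi(x(t))`: dynamics with no current filtering,
#' used for the two-population mean-field analysis where the continuous-time
#' equations are intractable.
#'
#' @inheritParams simulate_rate
#' @param T_steps number of map iterations.
#' @return A `"rate_trajectory"` whose `times` are the iteration indices.
#' @export
simulate_discrete <- function(conn, tf, T_steps = 500, seed = 1, x0 = NULL) {
  stopifnot(inherits(conn, "connectivity_matrix"),
            inherits(tf, "threshold_linear"))
  S <- csc_slots(conn)
  set.seed(seed)
  if (is.null(x0)) x0 <- stats::rnorm(S$n, 0, 0.1)
  r <- .sim_discrete_cpp(S$p, S$i, S$x, S$n, tf$gamma, tf$phi_max, x0,
                         as.integer(T_steps))
  new_rate_trajectory(0:(ncol(r$currents) - 1), r$currents, 1, seed,
                      r$divergent)
}

#' Simulate the spiking LIF network
#'
#' Exact exponential membrane update between grid points; a presynaptic
#' spike at `t` adds the post-synaptic potential amplitude `W_ij` (mV) to
#' `V_i` at `t + delay` (delta synapses, implemented with a ring buffer).
#' Threshold crossings are detected at grid points, followed by reset to
#' `V_r` and a refractory clamp of `tau_rp` during which inputs are
#' discarded.  Initial potentials are drawn uniformly in `[V_r, V_th]`.
#'
#' @param conn a `connectivity_matrix` whose weights are PSP amplitudes in
#'   mV.
#' @param lif an [lif_params()] object.
#' @param T simulated time (ms).
#' @param dt time step (ms, must be <= 0.05); `delay` must be an integer
#'   multiple of `dt` (bit-exact delay semantics).
#' @param seed RNG seed.
#' @param noise_sd optional white-noise amplitude `sigma` (mV) matching the
#'   diffusion approximation `tau_m V' = -V + mu_0 + sigma sqrt(tau_m) xi`.
#' @param V0 optional initial potentials.
#' @return An object of class `"spike_data"`: a data.frame `spikes`
#'   (`neuron` 1-based, `time` in ms), the network size `N`, `duration`,
#'   `params` and `seed`.
#' @export
simulate_lif <- function(conn, lif = lif_params(), T = 1000, dt = 0.05,
                         seed = 1, noise_sd = 0, V0 = NULL) {
  stopifnot(inherits(conn, "connectivity_matrix"), inherits(lif, "lif_params"))
  if (dt > 0.05) stop("'dt' must be <= 0.05 ms")
  delay_steps <- lif$delay / dt
  if (abs(delay_steps - round(delay_steps)) > 1e-9)
    stop("'delay' must be an integer multiple of 'dt'")
  delay_steps <- as.integer(round(delay_steps))
  if (delay_steps < 1) stop("'delay' must be at least one time step")
  S <- csc_slots(conn)
  n_steps <- round(T / dt)
  set.seed(seed)
  if (is.null(V0)) V0 <- stats::runif(S$n, lif$V_r, lif$V_th)
  r <- .sim_lif_cpp(S$p, S$i, S$x, S$n, lif$tau_m, lif$V_th, lif$V_r,
                    lif$tau_rp, lif$mu_0, noise_sd, V0, n_steps, dt,
                    delay_steps)
  structure(list(spikes = data.frame(neuron = r$spike_id + 1L,
                                     time = r$spike_t),
                 N = S$n, duration = n_steps * dt, params = lif, seed = seed,
                 V_end = r$V),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  rate <- nrow(x$spikes) / x$N / (x$duration / 1000)
  cat(sprintf("spike_data: %d neurons, %d spikes over %g ms (mean rate %.2f Hz)\n",
              x$N, nrow(x$spikes), x$duration, rate))
  invisible(x)
}

#' Write spikes as a two-column CSV
#'
#' @param spikes a `"spike_data"` object.
#' @param file output path; columns `neuron_id` (0-based) and `time_ms`.
#' @return `file`, invisibly.
#' @export
write_spikes <- function(spikes, file) {
  stopifnot(inherits(spikes, "spike_data"))
  utils::write.csv(data.frame(neuron_id = spikes$spikes$neuron - 1L,
                              time_ms = spikes$spikes$time),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
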