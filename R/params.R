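#' Parameters of the single-statistics excitatory-inhibitory ensemble
#'
#' Defines the sparse two-population random network in which every neuron
#' receives exactly (or on average) `C` incoming connections, a fraction `f`
#' of them excitatory with strength `J` and the rest inhibitory with strength
#' `-g * J`.  With this column structure excitatory and inhibitory neurons
#' receive statistically identical inputs, which is what makes the mean-field
#' equations solvable with a single mean and a single autocorrelation.
#'
#' @param J synaptic strength of excitatory synapses (unitless; mV for the
#'   spiking LIF network).
#' @param g ratio of inhibitory to excitatory synaptic strength (> 0).
#' @param C number of incoming connections per neuron.
#' @param f fraction of incoming connections that are excitatory; `f * C`
#'   must be an integer for the fixed in-degree ensemble.
#' @param N network size (only used by the connectivity builders and
#'   simulators; the mean-field equations are independent of `N`).
#' @param I constant external input current.
#'
#' @return An object of class `"network_params"`: a list with fields `J`, `g`,
#'   `C`, `f`, `N`, `I` and the derived in-degrees `C_E = f * C`,
#'   `C_I = (1 - f) * C`.
#'
#' @details The network is called inhibition dominated when `g > C_E / C_I`,
#'   i.e. when the net row sum `J * (C_E - g * C_I)` of the connectivity is
#'   negative; [is_inhibition_dominated()] tests this.  All mean-field
#'   couplings enter through the two combinations `C_E - g * C_I` (mean) and
#'   `C_E + g^2 * C_I` (variance).
#'
#' @examples
#' p <- network_params(J = 0.2, g = 5, C = 100, N = 2000)
#' is_inhibition_dominated(p)
#' @export
network_params <- function(J, g, C, f = 0.8, N = 1000L, I = 0) {
  stopifnot(is.numeric(J), length(J) == 1L, is.finite(J))
  if (!is.numeric(g) || length(g) != 1L || g < 0)
    stop("'g' must be a single non-negative number")
  if (!is.numeric(C) || length(C) != 1L || C < 1 || C != round(C))
    stop("'C' must be a positive integer")
  if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1)
    stop("'f' must lie in [0, 1]")
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer")
  if (C > N)
    stop("in-degree 'C' cannot exceed network size 'N'")
  p <- list(J = as.numeric(J), g = as.numeric(g), C = as.integer(C),
            f = as.numeric(f), N = as.integer(N), I = as.numeric(I),
            C_E = f * C, C_I = (1 - f) * C)
  class(p) <- "network_params"
  p
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "EI network parameters: J = %g, g = %g, C = %d (C_E = %g, C_I = %g), f = %g, N = %d, I = %g\n",
    x$J, x$g, x$C, x$C_E, x$C_I, x$f, x$N, x$I))
  cat(sprintf("  inhibition dominated: %s\n", is_inhibition_dominated(x)))
  invisible(x)
}

#' Is the network inhibition dominated?
#'
#' @param params a [network_params()] object.
#' @return `TRUE` when `g > C_E / C_I`, so that the net row sum of the
#'   connectivity (and hence the outlier eigenvalue) is negative.  Purely
#'   inhibitory networks (`C_E = 0`) are inhibition dominated for any `g > 0`.
#' @export
is_inhibition_dominated <- function(params) {
  stopifnot(inherits(params, "network_params"))
  if (params$C_I == 0) return(FALSE)
  params$g > params$C_E / params$C_I
}

# Mean and variance couplings J*(C_E - g*C_I), J^2*(C_E + g^2*C_I).
coupling_mean <- function(params) params$J * (params$C_E - params$g * params$C_I)
coupling_var <- function(params) params$J^2 * (params$C_E + params$g^2 * params$C_I)

#' Parameters of the block (general two-population) ensemble
#'
#' Generalises [network_params()] to networks in which excitatory and
#' inhibitory neurons receive statistically different inputs.  The synaptic
#' matrix is organised in four sparse blocks: every row of an excitatory
#' (resp. inhibitory) neuron contains exactly `C_E` entries `J * j_E`
#' (resp. `J * j_I`) in the excitatory columns and `C_I` entries
#' `-J * g_E * j_E` (resp. `-J * g_I * j_I`) in the inhibitory columns.
#'
#' @param j_E,j_I output strength factors of synapses onto excitatory and
#'   inhibitory neurons (> 0).
#' @param g_E,g_I relative inhibition onto the excitatory and inhibitory
#'   population.
#' @param C_E,C_I excitatory and inhibitory in-degrees (identical for all
#'   rows).
#' @param N_E,N_I population sizes.
#' @param J global coupling scale.
#'
#' @return An object of class `"block_params"`.  When `j_E = j_I = 1` and
#'   `g_E = g_I`, the ensemble reduces exactly to the single-statistics
#'   ensemble of [network_params()].
#' @export
block_params <- function(j_E, j_I, g_E, g_I, C_E, C_I, N_E, N_I, J = 1) {
  vals <- c(j_E = j_E, j_I = j_I, g_E = g_E, g_I = g_I)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("block strengths 'j_E', 'j_I', 'g_E', 'g_I' must be positive")
  near_int <- function(x) abs(x - round(x)) < 1e-9
  stopifnot(near_int(C_E), near_int(C_I), C_E >= 0, C_I >= 0,
            near_int(N_E), near_int(N_I))
  C_E <- round(C_E); C_I <- round(C_I)
  if (C_E > N_E) stop("'C_E' cannot exceed 'N_E'")
  if (C_I > N_I) stop("'C_I' cannot exceed 'N_I'")
  b <- list(j_E = j_E, j_I = j_I, g_E = g_E, g_I = g_I,
            C_E = as.integer(C_E), C_I = as.integer(C_I),
            N_E = as.integer(N_E), N_I = as.integer(N_I), J = as.numeric(J))
  class(b) <- "block_params"
  b
}

#' @export
print.block_params <- function(x, ...) {
  cat(sprintf("Block EI parameters: J = %g, j_E = %g, j_I = %g, g_E = %g, g_I = %g\n",
              x$J, x$j_E, x$j_I, x$g_E, x$g_I))
  cat(sprintf("  C_E = %d, C_I = %d, N_E = %d, N_I = %d\n",
              x$C_E, x$C_I, x$N_E, x$N_I))
  invisible(x)
}

#' Convert single-statistics parameters to block parameters
#'
#' @param params a [network_params()] object.
#' @return The equivalent [block_params()] object with `j_E = j_I = 1` and
#'   `g_E = g_I = g`; population sizes are `f * N` and `(1 - f) * N` (rounded).
#' @export
as_block_params <- function(params) {
  stopifnot(inherits(params, "network_params"))
  N_E <- round(params$f * params$N)
  block_params(j_E = 1, j_I = 1, g_E = params$g, g_I = params$g,
               C_E = params$C_E, C_I = params$C_I,
               N_E = N_E, N_I = params$N - N_E, J = params$J)
}

#' Noise specification for rate dynamics and mean-field solvers
#'
#' @param kind `"none"` for deterministic dynamics, `"white"` for additive
#'   external white noise with autocovariance `2 * delta_ext * delta(tau)`,
#'   or `"poisson_spiking"` for interactions through Poisson spikes, which at
#'   the mean-field level act as self-consistent white noise of amplitude
#'   `J^2 * (C_E + g^2 C_I) * [phi] / (2 * tau_bar)`.
#' @param delta_ext white-noise amplitude (>= 0); ignored unless
#'   `kind = "white"`.
#' @param tau_bar time constant of the rate dynamics in the spiking model
#'   (> 0); larger values filter the spiking noise more strongly.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(kind = c("none", "white", "poisson_spiking"),
                       delta_ext = 0, tau_bar = 1) {
  kind <- match.arg(kind)
  if (delta_ext < 0) stop("'delta_ext' must be non-negative")
  if (tau_bar <= 0) stop("'tau_bar' must be positive")
  structure(list(kind = kind, delta_ext = as.numeric(delta_ext),
                 tau_bar = as.numeric(tau_bar)),
            class = "noise_spec")
}
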