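#' Empirical statistics of simulated activity
#'
#' Estimators that make simulated trajectories comparable with the
#' mean-field predictions: the mean input current, the decomposition of the
#' total input variance into a temporal part and a quenched (across-unit)
#' part, the population-averaged lagged autocovariance, and spike-train
#' summaries.
#'
#' @name stats-module
#' @keywords internal
NULL

traj_window <- function(traj, discard) {
  keep <- traj$times >= discard
  if (sum(keep) < 2) stop("trajectory too short after discarding the transient")
  traj$currents[, keep, drop = FALSE]
}

#' Current statistics of a rate trajectory
#'
#' Computes, after discarding a transient, the mean input current and the
#' variance decomposition
#' `delta0_emp = mean_i var_t(x_i) + var_i(mean_t(x_i))`:
#' the first term is the temporal fluctuation variance, the second
#' (`delta_inf_emp`) the quenched variance of per-unit time averages, which
#' vanishes for fixed in-degree ensembles but not for heterogeneous ones.
#' Variances use the biased (1/T) normalisation, matching the lag
#' estimator.
#'
#' @param traj a `"rate_trajectory"`.
#' @param discard transient length to drop (same time units as
#'   `traj$times`).
#' @param tf optional transfer function: when supplied, `mean_rate` is the
#'   average of `phi(x)` over the retained window.
#' @return A list with `mean_current`, `delta0_emp`, `delta_inf_emp`,
#'   `delta_temporal_emp` and (optionally) `mean_rate`.
#' @export
current_stats <- function(traj, discard = 50, tf = NULL) {
  stopifnot(inherits(traj, "rate_trajectory"))
  X <- traj_window(traj, discard)
  Tn <- ncol(X)
  m_i <- rowMeans(X)
  v_i <- rowMeans(X^2) - m_i^2           # biased temporal variances
  d_inf <- mean(m_i^2) - mean(m_i)^2     # across-unit variance of means
  out <- list(mean_current = mean(m_i),
              delta_temporal_emp = mean(v_i),
              delta_inf_emp = d_inf,
              delta0_emp = mean(v_i) + d_inf,
              n_frames = Tn)
  if (!is.null(tf)) out$mean_rate <- mean(tf_value(tf, X))
  out
}

# per-row biased autocovariance up to max_lag via FFT, rows demeaned
row_autocov_fft <- function(X, max_lag) {
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  m <- stats::nextn(2 * n, 2)
  pad <- matrix(0, nrow(X), m)
  pad[, seq_len(n)] <- Xc
  ft <- stats::mvfft(t(pad))
  ac <- Re(stats::mvfft(ft * Conj(ft), inverse = TRUE)) / m
  # ac is m x N; biased normalisation 1/n
  t(ac[seq_len(max_lag + 1), , drop = FALSE]) / n
}

#' Empirical input-current autocorrelation
#'
#' The population-averaged lagged autocovariance
#' `Delta_hat(tau) = mean_i cov_t(x_i(t), x_i(t + tau)) + delta_inf_emp`,
#' where the per-unit covariances subtract per-unit time means (biased 1/T
#' normalisation) and the quenched component is added back so that
#' `Delta_hat(0)` equals the total variance `delta0_emp` of
#' [current_stats()].  Both components are also returned separately.
#'
#' @param traj a `"rate_trajectory"`.
#' @param max_lag largest lag, in time units (must not exceed half of the
#'   retained window).
#' @param discard transient to drop.
#' @return A list with `lags`, `delta_hat`, `delta_temporal` (the lagged
#'   temporal component), `delta_inf_emp`, and the normalised trace
#'   `delta_normalized = delta_hat / delta_hat[1]`.
#' @export
autocorrelation_empirical <- function(traj, max_lag = 20, discard = 50) {
  stopifnot(inherits(traj, "rate_trajectory"))
  X <- traj_window(traj, discard)
  dt <- traj$dt
  L <- floor(max_lag / dt)
  if (L > ncol(X) / 2) stop("'max_lag' exceeds half of the usable window")
  ac <- row_autocov_fft(X, L)
  temporal <- colMeans(ac)
  m_i <- rowMeans(X)
  d_inf <- mean(m_i^2) - mean(m_i)^2
  delta_hat <- temporal + d_inf
  list(lags = dt * (0:L), delta_hat = delta_hat, delta_temporal = temporal,
       delta_inf_emp = d_inf,
       delta_normalized = delta_hat / delta_hat[1])
}

#' Fluctuation timescale as full width at half maximum
#'
#' Linear-interpolated lag at which a decaying autocorrelation trace first
#' falls to half its zero-lag value, doubled (the autocorrelation is even
#' in the lag).  Scale invariant.
#'
#' @param lags non-negative lag grid.
#' @param delta_trace autocorrelation values on `lags`; `delta_trace[1]`
#'   must be positive.
#' @return The FWHM (same units as `lags`); `Inf` when the trace never
#'   falls below half.
#' @examples
#' tau <- seq(0, 20, 0.01)
#' timescale_fwhm(tau, exp(-tau))  # 2 * log(2)
#' @export
timescale_fwhm <- function(lags, delta_trace) {
  if (delta_trace[1] <= 0) stop("'delta_trace' must start positive")
  half <- delta_trace[1] / 2
  below <- which(delta_trace < half)
  if (!length(below)) return(Inf)
  i <- below[1]
  if (i == 1) return(0)
  t_half <- lags[i - 1] + (lags[i] - lags[i - 1]) *
    (delta_trace[i - 1] - half) / (delta_trace[i - 1] - delta_trace[i])
  2 * t_half
}

spike_count_matrix <- function(spikes, bin) {
  breaks <- seq(0, spikes$duration + bin, by = bin)
  n_bins <- length(breaks) - 1L
  cnt <- matrix(0L, spikes$N, n_bins)
  if (nrow(spikes$spikes)) {
    b <- pmin(pmax(ceiling(spikes$spikes$time / bin), 1L), n_bins)
    tab <- table(factor(spikes$spikes$neuron, levels = seq_len(spikes$N)), b)
    cnt[, as.integer(colnames(tab))] <- as.integer(tab)
  }
  cnt[, seq_len(floor(spikes$duration / bin)), drop = FALSE]
}

#' Instantaneous firing rates by Gaussian filtering
#'
#' Convolves each neuron's spike train with a normalised Gaussian kernel
#' (default SD 50 ms) sampled on a bin grid.  The kernel integrates to one,
#' so a single spike contributes unit area; output is in spikes/s.
#'
#' @param spikes a `"spike_data"` object.
#' @param filter_sd kernel standard deviation (ms).
#' @param bin sampling bin (ms).
#' @return A list with `times` (bin centres, ms) and `rates`
#'   (neurons x bins matrix, spikes/s).
#' @export
instantaneous_rates <- function(spikes, filter_sd = 50, bin = 1) {
  stopifnot(inherits(spikes, "spike_data"))
  if (spikes$duration < 10 * filter_sd)
    warning("duration is shorter than 10 filter widths; edge effects will be strong")
  cnt <- spike_count_matrix(spikes, bin)
  half <- ceiling(4 * filter_sd / bin)
  kt <- (-half:half) * bin
  kernel <- stats::dnorm(kt, sd = filter_sd)
  kernel <- kernel / sum(kernel)           # unit mass per spike
  n <- ncol(cnt)
  m <- stats::nextn(n + length(kernel), 2)
  padK <- numeric(m); padK[seq_along(kernel)] <- kernel
  padX <- matrix(0, nrow(cnt), m)
  padX[, seq_len(n)] <- cnt
  ftK <- stats::fft(padK)
  ftX <- stats::mvfft(t(padX))
  sm <- Re(stats::mvfft(ftX * ftK, inverse = TRUE)) / m
  rates <- t(sm[half + seq_len(n), , drop = FALSE])
  list(times = (seq_len(n) - 0.5) * bin,
       rates = rates / bin * 1000)         # counts/ms -> spikes/s
}

#' Spike-train autocorrelation
#'
#' Per-neuron binned spike-count autocovariance (biased, per-unit means
#' subtracted), averaged over neurons; the zero-lag bin (dominated by the
#' point-process variance) is reported separately.
#'
#' @param spikes a `"spike_data"` object.
#' @param bin bin width (ms).
#' @param max_lag largest lag (ms).
#' @return A list with `lags` (> 0, ms), `values`, and `zero_lag`.
#' @export
spike_autocorrelation <- function(spikes, bin = 1, max_lag = 50) {
  stopifnot(inherits(spikes, "spike_data"))
  cnt <- spike_count_matrix(spikes, bin)
  L <- floor(max_lag / bin)
  if (L > ncol(cnt) / 2) stop("'max_lag' exceeds half of the recording")
  ac <- row_autocov_fft(cnt, L)
  avg <- colMeans(ac)
  list(lags = bin * (1:L), values = avg[-1], zero_lag = avg[1])
}

#' Synchrony index of a spiking network
#'
#' Standard deviation over time of the population-averaged spiking rate
#' (1 ms bins by default), normalised by the square root of the mean firing
#' rate.  For `N` independent Poisson neurons the index scales as
#' `1 / sqrt(N * bin)`; excess values indicate correlations and
#' finite-size synchrony.
#'
#' @param spikes a `"spike_data"` object (duration of at least 1 s
#'   recommended).
#' @param bin bin width (ms).
#' @param discard initial transient to drop (ms).
#' @return The synchrony index (scalar, in `sqrt(Hz) / sqrt(Hz)` units,
#'   i.e. `sqrt(s)`-free); 0 when no spikes were fired.
#' @export
synchrony_index <- function(spikes, bin = 1, discard = 0) {
  stopifnot(inherits(spikes, "spike_data"))
  cnt <- spike_count_matrix(spikes, bin)
  if (discard > 0) cnt <- cnt[, -(seq_len(floor(discard / bin))), drop = FALSE]
  pop <- colMeans(cnt) / (bin / 1000)      # population rate, Hz per neuron
  mr <- mean(pop)
  if (mr <= 0) return(0)
  stats::sd(pop) / sqrt(mr)
}
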