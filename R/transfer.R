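#' Threshold-linear transfer function
#'
#' The piecewise-linear current-to-rate map used throughout the rate-network
#' analysis: zero below `-gamma`, linear with unit gain in between, saturated
#' at `phi_max` above `phi_max - gamma`.  An infinite `phi_max` is a
#' first-class value; it is required by the analysis of the divergence
#' coupling, where the upper bound is removed.
#'
#' @param gamma offset of the threshold (default 0.5), so that
#'   `phi(0) = gamma`.
#' @param phi_max saturation value (`Inf` for an unbounded rectified-linear
#'   unit).
#' @return An object of class `c("threshold_linear", "transfer_function")`.
#' @seealso [phi()], [gaussian_moments()], [lif_transfer()]
#' @export
threshold_linear <- function(gamma = 0.5, phi_max = Inf) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (!(is.numeric(phi_max) && length(phi_max) == 1L && phi_max > 0))
    stop("'phi_max' must be a positive number (possibly Inf)")
  structure(list(gamma = gamma, phi_max = phi_max),
            class = c("threshold_linear", "transfer_function"))
}

#' @export
print.threshold_linear <- function(x, ...) {
  cat(sprintf("threshold-linear transfer: gamma = %g, phi_max = %g\n",
              x$gamma, x$phi_max))
  invisible(x)
}

#' Effective rate transfer function of a leaky integrate-and-fire neuron
#'
#' Wraps the first-passage (Siegert) input-output function `F(mu, sigma)` of
#' an LIF neuron into a transfer function usable by the mean-field solvers:
#' a rate unit with current `x` fires at `F(mu_0 + tau_m * x, sigma)`, where
#' `sigma` is held fixed at an effective value (see [solve_dmf_lif()]).
#'
#' Units: membrane quantities in mV, time constants in ms, rates in 1/ms.
#'
#' @param tau_m membrane time constant (ms).
#' @param V_th spike threshold (mV).
#' @param V_r reset potential (mV).
#' @param tau_rp absolute refractory period (ms); its inverse bounds the rate.
#' @param sigma effective input noise standard deviation (mV).
#' @param mu_0 constant external drive (mV) added to the recurrent input.
#' @return An object of class `c("lif_transfer", "transfer_function")`.
#' @export
lif_transfer <- function(tau_m = 20, V_th = 20, V_r = 10, tau_rp = 0.5,
                         sigma = 1, mu_0 = 24) {
  if (V_th <= V_r) stop("'V_th' must exceed 'V_r'")
  stopifnot(tau_m > 0, tau_rp >= 0, sigma >= 0)
  structure(list(tau_m = tau_m, V_th = V_th, V_r = V_r, tau_rp = tau_rp,
                 sigma = sigma, mu_0 = mu_0),
            class = c("lif_transfer", "transfer_function"))
}

#' @export
print.lif_transfer <- function(x, ...) {
  cat(sprintf(
    "LIF transfer: tau_m = %g ms, V_th = %g mV, V_r = %g mV, tau_rp = %g ms, sigma = %g mV, mu_0 = %g mV\n",
    x$tau_m, x$V_th, x$V_r, x$tau_rp, x$sigma, x$mu_0))
  invisible(x)
}

#' Transfer function value, derivative and antiderivative
#'
#' `phi()` evaluates the current-to-rate map, `phi_prime()` its derivative
#' (for the threshold-linear function the derivative is 0 or 1; at the two
#' kinks the right-derivative is returned), and `Phi()` its antiderivative,
#' normalised so that `Phi(-gamma) = 0` for the threshold-linear function
#' (and `Phi(0) = 0` for the LIF transfer, where only differences of `Phi`
#' ever enter the theory).
#'
#' @param x input current(s).
#' @param tf a transfer-function object ([threshold_linear()] or
#'   [lif_transfer()]).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' tf <- threshold_linear(gamma = 0.5, phi_max = 2)
#' phi(c(-1, 0, 10), tf)
#' Phi(0.5, threshold_linear(0.5, Inf))  # (gamma + 0.5)^2 / 2
#' @export
phi <- function(x, tf) tf_value(tf, x)

#' @rdname phi
#' @export
phi_prime <- function(x, tf) tf_deriv(tf, x)

#' @rdname phi
#' @export
Phi <- function(x, tf) tf_antideriv(tf, x)

tf_value <- function(tf, x) UseMethod("tf_value")
tf_deriv <- function(tf, x) UseMethod("tf_deriv")
tf_antideriv <- function(tf, x) UseMethod("tf_antideriv")

#' @export
tf_value.threshold_linear <- function(tf, x) {
  pmin(pmax(tf$gamma + x, 0), tf$phi_max)
}

#' @export
tf_deriv.threshold_linear <- function(tf, x) {
  u <- tf$gamma + x
  as.numeric(u >= 0 & u < tf$phi_max)
}

#' @export
tf_antideriv.threshold_linear <- function(tf, x) {
  u <- tf$gamma + x
  M <- tf$phi_max
  out <- numeric(length(u))
  mid <- u > 0 & u <= M
  out[mid] <- u[mid]^2 / 2
  if (is.finite(M)) {
    hi <- u > M
    out[hi] <- M * u[hi] - M^2 / 2
  }
  out
}

#' @export
tf_value.lif_transfer <- function(tf, x) {
  lif_F(tf$mu_0 + tf$tau_m * x, tf$sigma^2, tf)
}

#' @export
tf_deriv.lif_transfer <- function(tf, x, h = 1e-4) {
  (tf_value(tf, x + h) - tf_value(tf, x - h)) / (2 * h)
}

#' @export
tf_antideriv.lif_transfer <- function(tf, x) {
  # Only differences of Phi enter the mean-field equations, so the reference
  # point is arbitrary; integrate the (smooth, monotone) rate from 0.
  vapply(x, function(xx) {
    if (xx == 0) return(0)
    if (xx > 0)
      stats::integrate(function(u) tf_value(tf, u), 0, xx,
                       rel.tol = 1e-9, abs.tol = 1e-12)$value
    else
      -stats::integrate(function(u) tf_value(tf, u), xx, 0,
                        rel.tol = 1e-9, abs.tol = 1e-12)$value
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Siegert first-passage rate of the LIF neuron
# ---------------------------------------------------------------------------

# erfcx(x) = exp(x^2) * erfc(x), overflow safe via pracma for moderate x and
# the asymptotic series for large x.
erfcx_safe <- function(x) {
  out <- numeric(length(x))
  big <- x > 25
  out[!big] <- pracma::erfcx(x[!big])
  if (any(big)) {
    xb <- x[big]
    out[big] <- (1 - 1 / (2 * xb^2) + 3 / (4 * xb^4)) / (xb * sqrt(pi))
  }
  out
}

#' Mean firing rate of an LIF neuron driven by white noise
#'
#' Evaluates the stationary first-passage (Siegert) rate
#' `F = 1 / (tau_rp + tau_m * sqrt(pi) * int_{(V_r - mu)/sigma}^{(V_th - mu)/sigma} erfcx(-u) du)`
#' of a leaky integrate-and-fire neuron receiving a white-noise current of
#' mean `mu` and noise variance `sigma_sq`.  The integrand is evaluated with
#' the scaled complementary error function so that strongly supra- and
#' sub-threshold inputs do not overflow; far sub-threshold rates are returned
#' on a log-asymptotic branch.  In the noiseless limit `sigma -> 0` the
#' deterministic rate `1 / (tau_rp + tau_m * log((mu - V_r)/(mu - V_th)))`
#' (0 below threshold) is returned.
#'
#' @param mu mean input (mV); vectorised.
#' @param sigma_sq input noise variance (mV^2).
#' @param tf an [lif_transfer()] object (provides `tau_m`, `V_th`, `V_r`,
#'   `tau_rp`).
#' @return Firing rate(s) in 1/ms, non-decreasing in `mu` and bounded by
#'   `1/tau_rp`.
#' @export
lif_F <- function(mu, sigma_sq, tf) {
  stopifnot(inherits(tf, "lif_transfer"))
  if (sigma_sq < 0) stop("'sigma_sq' must be non-negative")
  sigma <- sqrt(sigma_sq)
  vapply(mu, function(m) lif_F_scalar(m, sigma, tf), numeric(1))
}

lif_F_scalar <- function(mu, sigma, tf) {
  tau_m <- tf$tau_m; tau_rp <- tf$tau_rp
  if (sigma < 1e-12) {
    if (mu <= tf$V_th) return(0)
    return(1 / (tau_rp + tau_m * log((mu - tf$V_r) / (mu - tf$V_th))))
  }
  a <- (tf$V_r - mu) / sigma
  b <- (tf$V_th - mu) / sigma
  if (b > 25) {
    # deeply sub-threshold: integral dominated by the upper limit,
    # int erfcx(-u) du ~ exp(b^2)/b; return the log-asymptotic rate
    log_int <- b^2 - log(b)
    return(exp(-(log_int + log(tau_m * sqrt(pi)))))
  }
  val <- stats::integrate(function(u) erfcx_safe(-u), a, b,
                          rel.tol = 1e-10, abs.tol = 1e-14)$value
  1 / (tau_rp + tau_m * sqrt(pi) * val)
}

# ---------------------------------------------------------------------------
# Gaussian moments
# ---------------------------------------------------------------------------

# Truncated standard-normal raw moments I_k = int_a^b z^k dnorm(z) dz,
# k = 0..4, with b possibly Inf.  Used by the closed-form censored moments.
trunc_norm_I <- function(a, b) {
  da <- stats::dnorm(a); db <- if (is.finite(b)) stats::dnorm(b) else 0
  pa <- stats::pnorm(a); pb <- if (is.finite(b)) stats::pnorm(b) else 1
  b0 <- if (is.finite(b)) b else 0  # b^k * dnorm(b) -> 0 for b = Inf
  I0 <- pb - pa
  I1 <- da - db
  I2 <- I0 + a * da - b0 * db
  I3 <- 2 * I1 + a^2 * da - b0^2 * db
  I4 <- 3 * I2 + a^3 * da - b0^3 * db
  list(I0 = I0, I1 = I1, I2 = I2, I3 = I3, I4 = I4,
       K0 = 1 - pb, K1 = db, K2 = (1 - pb) + b0 * db)
}

# E[phi], E[phi^2], E[Phi], E[Phi^2] of the threshold-linear function under
# x ~ N(mu, s^2), in closed censored-normal form.  With u = gamma + x the
# function is clip(u, 0, M) and its antiderivative 0 / u^2/2 / M*u - M^2/2.
tl_moments <- function(mu, s, gamma, M) {
  m <- gamma + mu
  if (s < 1e-14) {
    u <- min(max(m, 0), M)
    Phi_v <- if (m <= 0) 0 else if (m <= M) m^2 / 2 else M * m - M^2 / 2
    return(list(phi = u, phi_sq = u^2, Phi = Phi_v, Phi_sq = Phi_v^2))
  }
  a <- -m / s
  b <- if (is.finite(M)) (M - m) / s else Inf
  tn <- trunc_norm_I(a, b)
  e1 <- m * tn$I0 + s * tn$I1
  e2 <- m^2 * tn$I0 + 2 * m * s * tn$I1 + s^2 * tn$I2
  e4 <- m^4 * tn$I0 + 4 * m^3 * s * tn$I1 + 6 * m^2 * s^2 * tn$I2 +
    4 * m * s^3 * tn$I3 + s^4 * tn$I4
  phi_m <- e1
  phi_sq <- e2
  Phi_m <- e2 / 2
  Phi_sq <- e4 / 4
  if (is.finite(M)) {
    # censored (saturated) upper tail
    u1 <- m * tn$K0 + s * tn$K1
    u2 <- m^2 * tn$K0 + 2 * m * s * tn$K1 + s^2 * tn$K2
    phi_m <- phi_m + M * tn$K0
    phi_sq <- phi_sq + M^2 * tn$K0
    Phi_m <- Phi_m + M * u1 - M^2 / 2 * tn$K0
    Phi_sq <- Phi_sq + M^2 * u2 - M^3 * u1 + M^4 / 4 * tn$K0
  }
  list(phi = phi_m, phi_sq = phi_sq, Phi = Phi_m, Phi_sq = Phi_sq)
}

# Cached Gauss-Hermite rule mapped to N(0,1): E f(z) ~ sum w_i f(x_i).
.gh_env <- new.env(parent = emptyenv())
gh_rule <- function(n = 101L) {
  key <- as.character(n)
  if (is.null(.gh_env[[key]])) {
    r <- pracma::gaussHermite(n)
    .gh_env[[key]] <- list(z = r$x * sqrt(2), w = r$w / sqrt(pi))
  }
  .gh_env[[key]]
}

#' Gaussian moments of a transfer function
#'
#' Moments of `phi(mu + sqrt(delta0) * z)` and of its antiderivative
#' `Phi(mu + sqrt(delta0) * z)` under a standard normal `z`.  These four
#' numbers are the building blocks of every mean-field self-consistency
#' equation: the mean rate, the equal-time rate variance, and the potential
#' energies entering the variance equation.
#'
#' For the threshold-linear function exact censored-normal closed forms are
#' used; for other transfer functions (LIF) the integrals are computed by
#' Gauss-Hermite quadrature on a cubic-spline representation of the
#' (pre-integrated) transfer function.
#'
#' @param mu mean input current.
#' @param delta0 input-current variance (>= 0).
#' @param tf transfer function object.
#' @return A list with fields `mean_phi`, `mean_phi_sq`, `mean_Phi`,
#'   `mean_Phi_sq`.
#' @examples
#' gaussian_moments(0, 0, threshold_linear(0.5, 2))  # degenerate: phi(0) = 0.5
#' @export
gaussian_moments <- function(mu, delta0, tf) {
  if (delta0 < 0) stop("'delta0' must be non-negative")
  if (inherits(tf, "threshold_linear")) {
    m <- tl_moments(mu, sqrt(delta0), tf$gamma, tf$phi_max)
    return(list(mean_phi = m$phi, mean_phi_sq = m$phi_sq,
                mean_Phi = m$Phi, mean_Phi_sq = m$Phi_sq))
  }
  gaussian_moments_quad(mu, delta0, tf)
}

gaussian_moments_quad <- function(mu, delta0, tf, n = 201L) {
  if (delta0 < 1e-14) {
    pv <- tf_value(tf, mu); Pv <- tf_antideriv(tf, mu)
    return(list(mean_phi = pv, mean_phi_sq = pv^2,
                mean_Phi = Pv, mean_Phi_sq = Pv^2))
  }
  gh <- gh_rule(n)
  x <- mu + sqrt(delta0) * gh$z
  pv <- tf_value(tf, x)
  Pv <- tf_antideriv_grid(tf, x)
  list(mean_phi = sum(gh$w * pv), mean_phi_sq = sum(gh$w * pv^2),
       mean_Phi = sum(gh$w * Pv), mean_Phi_sq = sum(gh$w * Pv^2))
}

# Antiderivative evaluated at a sorted batch of points by cumulative
# Gauss-Legendre panels between consecutive points (avoids one integrate()
# call per node for expensive transfer functions).
tf_antideriv_grid <- function(tf, x) {
  if (inherits(tf, "threshold_linear")) return(tf_antideriv(tf, x))
  o <- order(x)
  xs <- x[o]
  # 5-point Gauss-Legendre per panel
  gl_x <- c(-0.9061798459, -0.5384693101, 0, 0.5384693101, 0.9061798459)
  gl_w <- c(0.2369268851, 0.4786286705, 0.5688888889, 0.4786286705, 0.2369268851)
  pts <- c(0, xs)
  vals <- numeric(length(xs))
  acc <- 0
  # integral from 0 to xs[1], then panel increments
  for (k in seq_along(xs)) {
    lo <- if (k == 1) 0 else xs[k - 1]
    hi <- xs[k]
    h <- (hi - lo) / 2
    mid <- (hi + lo) / 2
    acc <- acc + h * sum(gl_w * tf_value(tf, mid + h * gl_x))
    vals[k] <- acc
  }
  out <- numeric(length(x))
  out[o] <- vals
  out
}

# ---------------------------------------------------------------------------
# Double Gaussian averages
# ---------------------------------------------------------------------------

# E_z [ (E_y f(mu + sqrt(delta) z + sqrt(delta0 - delta) y))^2 ] for
# f = phi or Phi.  The inner average is a censored-normal closed form for
# the threshold-linear function (quadrature otherwise); the outer integrand
# is smooth, so a modest Gauss-Hermite rule suffices.
double_gaussian_sq <- function(mu, delta0, delta, tf, what = c("phi", "Phi"),
                               n_outer = 101L) {
  what <- match.arg(what)
  if (delta < 0 || delta > delta0 + 1e-12)
    stop("'delta' must lie in [0, delta0]")
  delta <- min(delta, delta0)
  mom0 <- gaussian_moments(mu, delta0, tf)
  if (delta >= delta0 - 1e-14)
    return(if (what == "phi") mom0$mean_phi_sq else mom0$mean_Phi_sq)
  if (delta <= 1e-14)
    return(if (what == "phi") mom0$mean_phi^2 else mom0$mean_Phi^2)
  gh <- gh_rule(n_outer)
  mu_in <- mu + sqrt(delta) * gh$z
  s_in <- sqrt(delta0 - delta)
  if (inherits(tf, "threshold_linear")) {
    h <- vapply(mu_in, function(mi) {
      m <- tl_moments(mi, s_in, tf$gamma, tf$phi_max)
      if (what == "phi") m$phi else m$Phi
    }, numeric(1))
  } else {
    h <- vapply(mu_in, function(mi) {
      gm <- gaussian_moments_quad(mi, s_in^2, tf, n = 101L)
      if (what == "phi") gm$mean_phi else gm$mean_Phi
    }, numeric(1))
  }
  sum(gh$w * h^2)
}

#' Lagged rate correlation under the Gaussian ansatz
#'
#' The rate autocorrelation `C(tau)` implied by jointly Gaussian currents
#' with mean `mu`, variance `delta0` and lagged covariance `delta`:
#' `C = E_z [ (E_y phi(mu + sqrt(delta) z + sqrt(delta0 - delta) y))^2 ]`.
#' It interpolates continuously and monotonically between `[phi]^2` at
#' `delta = 0` (independent samples) and `[phi^2]` at `delta = delta0`
#' (equal times).
#'
#' @param mu mean input current.
#' @param delta0 equal-time current variance.
#' @param delta lagged current covariance, in `[0, delta0]` (the theory is
#'   solved on the monotone non-negative branch of the autocorrelation).
#' @param tf transfer function.
#' @return The rate correlation (a scalar).
#' @export
rate_correlation <- function(mu, delta0, delta, tf) {
  if (delta0 < 0) stop("'delta0' must be non-negative")
  if (delta < 0 || delta > delta0 + 1e-12)
    stop("'delta' must lie in [0, delta0]")
  double_gaussian_sq(mu, delta0, delta, tf, what = "phi")
}

# ---------------------------------------------------------------------------
# Tabulated transfer functions
# ---------------------------------------------------------------------------

# Spline tabulation of an expensive transfer function (used by the LIF
# mean-field solvers, where every Gaussian moment would otherwise trigger
# hundreds of Siegert integrals).  Outside the table the value is extended
# as a constant and the antiderivative linearly, which is exact once the
# rate has saturated (or vanished).
tf_tabulate <- function(tf, lo, hi, n = 2001L) {
  x <- seq(lo, hi, length.out = n)
  v <- tf_value(tf, x)
  fun <- stats::splinefun(x, v, method = "monoH.FC")
  # cumulative antiderivative on the same grid (trapezoid on a fine grid)
  dx <- x[2] - x[1]
  cum <- c(0, cumsum((v[-1] + v[-n]) / 2 * dx))
  Phi0 <- stats::approx(x, cum, xout = 0)$y
  Phi_fun <- stats::splinefun(x, cum - Phi0, method = "monoH.FC")
  structure(list(base = tf, lo = lo, hi = hi, fun = fun, Phi_fun = Phi_fun,
                 v_lo = v[1], v_hi = v[n],
                 Phi_lo = cum[1] - Phi0, Phi_hi = cum[n] - Phi0),
            class = c("tabulated_transfer", "transfer_function"))
}

#' @export
tf_value.tabulated_transfer <- function(tf, x) {
  out <- tf$fun(pmin(pmax(x, tf$lo), tf$hi))
  out[x < tf$lo] <- tf$v_lo
  out[x > tf$hi] <- tf$v_hi
  out
}

#' @export
tf_deriv.tabulated_transfer <- function(tf, x) {
  out <- tf$fun(pmin(pmax(x, tf$lo), tf$hi), deriv = 1)
  out[x < tf$lo | x > tf$hi] <- 0
  pmax(out, 0)
}

#' @export
tf_antideriv.tabulated_transfer <- function(tf, x) {
  out <- tf$Phi_fun(pmin(pmax(x, tf$lo), tf$hi))
  lo <- x < tf$lo; hi <- x > tf$hi
  out[lo] <- tf$Phi_lo + tf$v_lo * (x[lo] - tf$lo)
  out[hi] <- tf$Phi_hi + tf$v_hi * (x[hi] - tf$hi)
  out
}
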