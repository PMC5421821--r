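#' Dynamical mean-field solvers
#'
#' The mean-field description replaces the recurrent input of every unit by
#' a self-consistent Gaussian process, reducing the network to coupled
#' equations for the mean input current `mu` and the input autocovariance
#' `Delta(tau)`.  For the single-statistics ensemble the stationary problem
#' collapses to two equations: the mean equation
#' `mu = J (C_E - g C_I) [phi] + I` and an energy balance for the particle
#' analogy of the autocorrelation dynamics, which fixes the equal-time
#' variance `Delta_0`.
#'
#' @name dmf
#' @keywords internal
NULL

stop_no_convergence <- function(msg, last = NULL) {
  stop(structure(class = c("eichaos_no_convergence", "error", "condition"),
                 list(message = msg, call = sys.call(-1), last = last)))
}

new_dmf_solution <- function(regime, mu, delta0, delta_inf, mean_rate,
                             residuals, noise = noise_spec("none"),
                             delta_ext_eff = 0, extra = list()) {
  structure(c(list(regime = regime, mu = mu, delta0 = delta0,
                   delta_inf = delta_inf, mean_rate = mean_rate,
                   converged = all(abs(residuals) < 1e-6),
                   residuals = residuals, noise = noise,
                   delta_ext_eff = delta_ext_eff,
                   tau_grid = NULL, delta_trace = NULL), extra),
            class = "dmf_solution")
}

#' @export
print.dmf_solution <- function(x, ...) {
  cat(sprintf("DMF solution [%s]: mu = %.6g, Delta0 = %.6g, Delta_inf = %.6g, mean rate = %.6g\n",
              x$regime, x$mu, x$delta0, x$delta_inf, x$mean_rate))
  if (!is.null(x$residuals))
    cat(sprintf("  residuals: %s\n", paste(format(x$residuals, digits = 3), collapse = ", ")))
  invisible(x)
}

# root of f on an expanding bracket around `start`
expand_uniroot <- function(f, lower, upper, max_expand = 60, tol = 1e-12) {
  flo <- f(lower); fhi <- f(upper)
  n <- 0
  while (flo * fhi > 0 && n < max_expand) {
    span <- upper - lower
    lower <- lower - span
    upper <- upper + span
    flo <- f(lower); fhi <- f(upper)
    n <- n + 1
  }
  if (flo * fhi > 0)
    stop_no_convergence("no sign change found while bracketing root")
  stats::uniroot(f, c(lower, upper), tol = tol)$root
}

#' Homogeneous fixed point of the rate dynamics
#'
#' Solves `x0 = J (C_E - g C_I) phi(x0) + I`.  For inhibition-dominated
#' networks with a monotone transfer function the solution is unique; in
#' general the root reached by bracketed root finding started around `I` is
#' returned.
#'
#' @param params a [network_params()] object.
#' @param tf transfer function.
#' @return The fixed-point input current `x0` (a scalar).
#' @examples
#' p <- network_params(J = 0.2, g = 5, C = 100)
#' solve_fixed_point(p, threshold_linear(0.5, 2))  # = -0.4 (linear branch)
#' @export
solve_fixed_point <- function(params, tf) {
  k <- coupling_mean(params)
  f <- function(x) x - k * tf_value(tf, x) - params$I
  expand_uniroot(f, params$I - 1, params$I + 1)
}

radius_at <- function(params, tf, J) {
  p <- params; p$J <- J
  x0 <- solve_fixed_point(p, tf)
  g0 <- tf_deriv(tf, x0)
  g0 * J * sqrt(params$C_E + params$g^2 * params$C_I)
}

#' Critical coupling of the fixed-point instability
#'
#' The smallest coupling `J` at which the bulk spectral radius
#' `phi'(x0(J)) * J * sqrt(C_E + g^2 C_I)` of the linearised dynamics
#' crosses unity, with the fixed point `x0` re-solved at every candidate
#' `J`.  For an inhibition-dominated threshold-linear network with
#' `0 < gamma` the fixed point sits on the unit-gain branch and the critical
#' coupling is simply `1 / sqrt(C_E + g^2 C_I)`.
#'
#' @param params a [network_params()] object (the `J` field is ignored).
#' @param tf transfer function.
#' @param J_max upper end of the search interval.
#' @return The critical coupling, or `NA` (with a warning) when the gain at
#'   the fixed point vanishes throughout the search range so that no
#'   instability of this type occurs.
#' @export
critical_coupling_Jc <- function(params, tf, J_max = 10) {
  if (!is_inhibition_dominated(params) && params$C_I > 0)
    warning("network is not inhibition dominated: the outlier eigenvalue may cross unity before the bulk radius")
  f <- function(J) radius_at(params, tf, J) - 1
  Js <- exp(seq(log(1e-6), log(J_max), length.out = 200))
  vals <- vapply(Js, f, numeric(1))
  idx <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (!length(idx)) {
    if (all(vals < 0)) {
      warning("bulk radius stays below 1 over the search range (zero gain at the fixed point): no transition")
      return(NA_real_)
    }
    stop_no_convergence("could not bracket the critical coupling")
  }
  stats::uniroot(f, c(Js[idx[1]], Js[idx[1] + 1]), tol = 1e-12)$root
}

# mean equation mu = J*(C_E - g C_I)*[phi](mu, delta0) + I at fixed delta0
solve_mu_given_delta0 <- function(params, tf, delta0) {
  k <- coupling_mean(params)
  f <- function(m) m - k * gaussian_moments(m, delta0, tf)$mean_phi - params$I
  expand_uniroot(f, params$I - 1 - abs(k), params$I + 1)
}

# effective white-noise amplitude entering the kinetic term of the energy
# balance: Delta_dot(0+) = -delta_ext_eff
effective_delta_ext <- function(params, noise, mean_phi) {
  switch(noise$kind,
         none = 0,
         white = noise$delta_ext,
         poisson_spiking = coupling_var(params) * mean_phi / (2 * noise$tau_bar))
}

# energy gap V(Delta0, Delta0) + kinetic - V(0, Delta0); a positive value
# means the particle still overshoots Delta = 0, the self-consistent
# variance is the root
energy_gap <- function(params, tf, noise, delta0) {
  mu <- solve_mu_given_delta0(params, tf, delta0)
  gm <- gaussian_moments(mu, delta0, tf)
  dext <- effective_delta_ext(params, noise, gm$mean_phi)
  gap <- coupling_var(params) *
    (gm$mean_Phi_sq - gm$mean_Phi^2 - delta0 * gm$mean_phi^2) +
    dext^2 / 2 - delta0^2 / 2
  list(gap = gap, mu = mu, gm = gm, dext = dext)
}

#' Solve the stationary mean-field equations (fixed in-degree)
#'
#' Jointly solves the mean equation and the energy balance
#' `V(Delta_0, Delta_0) + Delta_ext^2 / 2 = V(0, Delta_0)` for the
#' single-statistics fixed in-degree ensemble, optionally with external
#' white noise or self-consistent Poisson spiking noise.  Below the critical
#' coupling (and without noise) the solution is the fixed point with
#' `Delta_0 = 0`; above it the positive-variance root is returned.  With an
#' unbounded transfer function and coupling beyond the divergence point no
#' finite root exists and the solution is flagged `"divergent"`.
#'
#' @param params a [network_params()] object.
#' @param tf transfer function.
#' @param noise a [noise_spec()].
#' @param delta0_max largest variance scanned before declaring divergence.
#' @return A `"dmf_solution"`: regime, `mu`, `delta0`, `delta_inf` (always 0
#'   for the fixed in-degree ensemble), `mean_rate`, residuals and the
#'   effective noise amplitude `delta_ext_eff`.
#' @export
solve_dmf <- function(params, tf, noise = noise_spec("none"),
                      delta0_max = 1e8) {
  stopifnot(inherits(params, "network_params"), inherits(noise, "noise_spec"))
  Jc <- suppressWarnings(critical_coupling_Jc(params, tf))
  gap_f <- function(d0) energy_gap(params, tf, noise, d0)$gap
  if (noise$kind == "none" && !is.na(Jc) && params$J <= Jc) {
    x0 <- solve_fixed_point(params, tf)
    return(new_dmf_solution("fixed_point", mu = x0, delta0 = 0, delta_inf = 0,
                            mean_rate = tf_value(tf, x0),
                            residuals = c(mu = 0, energy = 0), noise = noise))
  }
  # scan a geometric grid for the sign change of the energy gap; the floor
  # sits well above the double-precision cancellation noise of the moment
  # differences (the gap scales as Delta0^2 near the transition)
  scale0 <- 1e-6
  grid <- scale0 * 1.25^(0:round(log(delta0_max / scale0) / log(1.25)))
  prev <- gap_f(grid[1])
  root <- NA_real_
  if (prev <= 0 && noise$kind == "none") {
    # no fluctuating branch emerges (at or below threshold)
    x0 <- solve_fixed_point(params, tf)
    return(new_dmf_solution("fixed_point", mu = x0, delta0 = 0, delta_inf = 0,
                            mean_rate = tf_value(tf, x0),
                            residuals = c(mu = 0, energy = 0), noise = noise))
  }
  for (i in 2:length(grid)) {
    cur <- gap_f(grid[i])
    if (prev > 0 && cur <= 0) {
      root <- stats::uniroot(gap_f, c(grid[i - 1], grid[i]),
                             tol = min(1e-12, grid[i - 1] * 1e-9))$root
      break
    }
    prev <- cur
  }
  if (is.na(root)) {
    if (is.finite(tf$phi_max %||% Inf))
      stop_no_convergence("no self-consistent variance found for a bounded transfer function",
                          last = list(delta0_max = delta0_max, gap = prev))
    return(new_dmf_solution("divergent", mu = -Inf, delta0 = Inf,
                            delta_inf = 0, mean_rate = Inf,
                            residuals = c(mu = NA, energy = NA), noise = noise))
  }
  eg <- energy_gap(params, tf, noise, root)
  res <- c(mu = eg$mu - coupling_mean(params) * eg$gm$mean_phi - params$I,
           energy = eg$gap)
  new_dmf_solution("fluctuating", mu = eg$mu, delta0 = root, delta_inf = 0,
                   mean_rate = eg$gm$mean_phi, residuals = res, noise = noise,
                   delta_ext_eff = eg$dext)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Self-consistent potential of the autocorrelation dynamics
#'
#' The autocorrelation obeys `Delta'' = -dV/dDelta` with
#' `V(Delta, Delta_0) = -Delta^2/2 + J^2 (C_E + g^2 C_I) * {[Phi Phi](Delta)
#'  - Delta [phi]^2}`, where `[Phi Phi]` is the double Gaussian average of
#' the antiderivative.  For the stochastic in-degree ensemble the
#' `-Delta [phi]^2` term (a trace of the perfectly homogeneous in-degree)
#' is absent.
#'
#' @param delta lagged covariance, in `[0, delta0]`.
#' @param delta0 equal-time variance.
#' @param mu mean input current.
#' @param params a [network_params()] object.
#' @param tf transfer function.
#' @param scheme `"fixed_in_degree"` (default) keeps the `-Delta [phi]^2`
#'   term; `"stochastic_in_degree"` drops it.
#' @return The potential value (a scalar).
#' @export
potential_V <- function(delta, delta0, mu, params, tf,
                        scheme = c("fixed_in_degree", "stochastic_in_degree")) {
  scheme <- match.arg(scheme)
  PP <- double_gaussian_sq(mu, delta0, delta, tf, what = "Phi")
  v <- -delta^2 / 2 + coupling_var(params) * PP
  if (scheme == "fixed_in_degree") {
    mp <- gaussian_moments(mu, delta0, tf)$mean_phi
    v <- v - coupling_var(params) * delta * mp^2
  }
  v
}

#' Integrate the autocorrelation trajectory
#'
#' Integrates `Delta''(tau) = Delta - J^2 (C_E + g^2 C_I) {C(Delta) -
#' [phi]^2}` from `Delta(0) = Delta_0` with initial velocity
#' `-delta_ext_eff` (0 for deterministic dynamics), using a classical
#' fourth-order Runge-Kutta scheme.  The self-consistent solution lies on
#' the separatrix that decays monotonically to 0, so integration stops once
#' `Delta` falls below `stop_frac * Delta_0` (or raises an error if the
#' trajectory grows, which signals an inconsistent `(mu, Delta_0)` input).
#'
#' @param sol a `"dmf_solution"` in the fluctuating regime.
#' @param params,tf network parameters and transfer function used for `sol`.
#' @param tau_max hard cap on the integration horizon (chosen adaptively up
#'   to this value).
#' @param dtau time step.
#' @param stop_frac stop once `Delta < stop_frac * Delta_0`.
#' @return `sol` with `tau_grid`, `delta_trace` and an
#'   `energy_residual` field attached.
#' @export
autocorrelation_trajectory <- function(sol, params, tf, tau_max = 1000,
                                       dtau = 0.01, stop_frac = 1e-4) {
  stopifnot(inherits(sol, "dmf_solution"))
  if (sol$regime != "fluctuating")
    stop("autocorrelation_trajectory() requires a fluctuating solution")
  mu <- sol$mu; d0 <- sol$delta0
  K <- coupling_var(params)
  mp2 <- gaussian_moments(mu, d0, tf)$mean_phi^2
  # spline the (smooth) rate correlation once; the integration then costs
  # only spline evaluations
  dg <- seq(0, d0, length.out = 81)
  Cg <- vapply(dg, function(d) double_gaussian_sq(mu, d0, d, tf, what = "phi"),
               numeric(1))
  Cs <- stats::splinefun(dg, Cg, method = "monoH.FC")
  force_fn <- function(d) {
    dc <- min(max(d, 0), d0)
    dc - K * (Cs(dc) - mp2)
  }
  n_max <- ceiling(tau_max / dtau)
  delta <- numeric(n_max + 1)
  y <- c(d0, -sol$delta_ext_eff)
  delta[1] <- d0
  n_used <- n_max
  grew <- FALSE
  for (i in seq_len(n_max)) {
    k1 <- c(y[2], force_fn(y[1]))
    y2 <- y + dtau / 2 * k1
    k2 <- c(y2[2], force_fn(y2[1]))
    y3 <- y + dtau / 2 * k2
    k3 <- c(y3[2], force_fn(y3[1]))
    y4 <- y + dtau * k3
    k4 <- c(y4[2], force_fn(y4[1]))
    y <- y + dtau / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    delta[i + 1] <- y[1]
    if (y[1] < stop_frac * d0) { n_used <- i; break }
    # turnaround after the decay (residual numerical energy near the flat
    # hill top) ends the useful trace; a turnaround high up signals an
    # inconsistent (mu, Delta0) input
    if (y[2] > 0) {
      n_used <- i
      grew <- y[1] > 0.5 * d0
      break
    }
  }
  if (grew)
    stop_no_convergence("autocorrelation trajectory grows: inconsistent (mu, Delta0) input")
  tau <- dtau * (0:n_used)
  trace <- pmax(delta[1:(n_used + 1)], 0)
  V0 <- potential_V(d0, d0, mu, params, tf)
  Ve <- potential_V(trace[n_used + 1], d0, mu, params, tf)
  E0 <- V0 + sol$delta_ext_eff^2 / 2
  Ee <- Ve + y[2]^2 / 2
  sol$tau_grid <- tau
  sol$delta_trace <- trace
  sol$energy_residual <- abs(E0 - Ee)
  sol
}

# ---------------------------------------------------------------------------
# Divergence coupling (unbounded transfer function)
# ---------------------------------------------------------------------------

# raw moments a_j(k) = E[ max(k + z, 0)^j ], z ~ N(0,1)
rectified_moments <- function(k) {
  P <- stats::pnorm(k); D <- stats::dnorm(k)
  list(a1 = k * P + D,
       a2 = (1 + k^2) * P + k * D,
       a4 = (k^4 + 6 * k^2 + 3) * P + (k^3 + 5 * k) * D)
}

# self-consistent divergence-ansatz ratio k = mu / sqrt(Delta0) at coupling J
divergence_k <- function(params, J) {
  km <- J * (params$C_E - params$g * params$C_I)
  f <- function(k) k - km * rectified_moments(k)$a1
  stats::uniroot(f, c(-80, 0), tol = 1e-13)$root
}

#' Divergence coupling of the unbounded network
#'
#' For an unbounded threshold-linear transfer function the fluctuating
#' solution ceases to exist beyond a second coupling `J_D`: the mean drifts
#' to `-Inf` and the variance to `+Inf` with a fixed ratio
#' `k = mu / sqrt(Delta_0)`.  Substituting this scaling ansatz into the
#' mean equation gives a self-consistency condition for `k(J)`; inserting it
#' into the leading (quadratic in `Delta_0`) order of the energy balance
#' turns the existence of a finite variance into a sign condition whose zero
#' crossing defines `J_D`:
#' `J_D^2 (C_E + g^2 C_I) {(a4 - a2^2)/4 - a1^2} = 1/2`,
#' where `a_j(k) = E[max(k + z, 0)^j]` are rectified Gaussian moments.
#' The result does not depend on the threshold offset `gamma`, which drops
#' out at leading order.
#'
#' @param params a [network_params()] object; must have `C_E > 0` (for a
#'   purely inhibitory network the Gaussian approximation would predict a
#'   spurious divergence, see Details) and be inhibition dominated.
#' @return `J_D` (a scalar), strictly larger than the critical coupling.
#'
#' @details For `C_E = 0` the recurrent input is strictly non-positive and
#'   cannot drive run-away activity; a divergence predicted in that case is
#'   an artifact of the Gaussian approximation (whose positive tail
#'   introduces fictitious positive feedback).  The function therefore
#'   refuses purely inhibitory parameters with an error of class
#'   `"eichaos_gaussian_artifact_error"`.
#' @export
divergence_coupling_Jd <- function(params) {
  stopifnot(inherits(params, "network_params"))
  if (params$C_E == 0)
    stop(structure(class = c("eichaos_gaussian_artifact_error", "error", "condition"),
                   list(message = paste(
                     "purely inhibitory network (C_E = 0): a divergence coupling would be",
                     "an artifact of the Gaussian approximation and is not computed"),
                     call = sys.call())))
  if (!is_inhibition_dominated(params))
    stop("divergence_coupling_Jd() requires an inhibition-dominated network")
  gap <- function(J) {
    k <- divergence_k(params, J)
    a <- rectified_moments(k)
    J^2 * (params$C_E + params$g^2 * params$C_I) *
      ((a$a4 - a$a2^2) / 4 - a$a1^2) - 0.5
  }
  Jc <- 1 / sqrt(params$C_E + params$g^2 * params$C_I)
  lo <- Jc * (1 + 1e-6)
  glo <- gap(lo)
  hi <- lo
  repeat {
    hi <- hi * 1.3
    ghi <- gap(hi)
    if (glo * ghi <= 0) break
    if (hi > 1e4 * Jc)
      stop_no_convergence("could not bracket the divergence coupling")
    glo <- ghi; lo <- hi
  }
  stats::uniroot(gap, c(lo, hi), tol = 1e-13)$root
}

# ---------------------------------------------------------------------------
# Stochastic in-degree
# ---------------------------------------------------------------------------

#' Mean-field solution for the stochastic in-degree ensemble
#'
#' With binomial in-degrees the frozen heterogeneity of the total input
#' produces a quenched variance that persists in the stationary state.
#' Below the instability the solution is static:
#' `Delta_0 = J^2 (C_E + g^2 C_I) [phi^2]` together with the mean equation
#' (and `Delta_inf = Delta_0`).  Above it, `(mu, Delta_0, Delta_inf)` solve
#' the mean equation, the energy balance of the potential without the
#' homogeneous `-Delta [phi]^2` term, and the stationarity condition
#' `Delta_inf = J^2 (C_E + g^2 C_I) C(Delta_inf)`.
#'
#' @param params a [network_params()] object.
#' @param tf transfer function.
#' @return A `"dmf_solution"`; the temporal fluctuation amplitude is
#'   `delta0 - delta_inf` (0 in the static regime).
#' @export
solve_dmf_stochastic_indegree <- function(params, tf) {
  stopifnot(inherits(params, "network_params"))
  K <- coupling_var(params)
  if (params$J == 0) {
    return(new_dmf_solution("fixed_point", mu = params$I, delta0 = 0,
                            delta_inf = 0,
                            mean_rate = tf_value(tf, params$I),
                            residuals = c(mu = 0, static = 0)))
  }
  static_resid <- function(d0) {
    mu <- solve_mu_given_delta0(params, tf, d0)
    d0 - K * gaussian_moments(mu, d0, tf)$mean_phi_sq
  }
  d_static <- expand_uniroot(static_resid, 0, max(1, K), tol = 1e-12)
  mu_s <- solve_mu_given_delta0(params, tf, d_static)
  gm_s <- gaussian_moments(mu_s, d_static, tf)
  static_sol <- new_dmf_solution("fixed_point", mu = mu_s, delta0 = d_static,
                                 delta_inf = d_static,
                                 mean_rate = gm_s$mean_phi,
                                 residuals = c(mu = 0,
                                               static = static_resid(d_static)))
  # Fluctuating branch.  The static variance sits exactly at a stationary
  # point of the potential; when it destabilises, the decaying solution has
  # Delta_0 slightly below the static root and comes to rest at the smaller
  # stationary point Delta_inf (a hill of V).  For a candidate Delta_0, find
  # the smallest interior root of Delta = K * C(Delta), then require the
  # energy balance V(Delta_0) = V(Delta_inf).
  dinf_given_d0 <- function(d0) {
    mu <- solve_mu_given_delta0(params, tf, d0)
    ri <- function(di) di - K * double_gaussian_sq(mu, d0, di, tf, what = "phi")
    dis <- seq(d0 * 1e-4, d0 * 0.9999, length.out = 80)
    rv <- vapply(dis, ri, numeric(1))
    sgn <- which(rv[-1] * rv[-length(rv)] < 0)
    if (!length(sgn)) return(list(dinf = NA_real_, mu = mu))
    list(dinf = stats::uniroot(ri, dis[c(sgn[1], sgn[1] + 1)],
                               tol = 1e-12)$root, mu = mu)
  }
  outer_resid <- function(d0) {
    di <- dinf_given_d0(d0)
    if (is.na(di$dinf)) return(NA_real_)
    gm <- gaussian_moments(di$mu, d0, tf)
    PP <- double_gaussian_sq(di$mu, d0, di$dinf, tf, what = "Phi")
    (d0^2 - di$dinf^2) / 2 - K * (gm$mean_Phi_sq - PP)
  }
  fr <- seq(0.5, 0.9999, length.out = 70)
  root <- NA_real_
  prev <- NA_real_
  for (i in seq_along(fr)) {
    cur <- outer_resid(fr[i] * d_static)
    if (!is.na(prev) && !is.na(cur) && prev * cur <= 0) {
      root <- stats::uniroot(function(d) outer_resid(d),
                             d_static * fr[c(i - 1, i)], tol = 1e-11)$root
      break
    }
    prev <- cur
  }
  if (is.na(root)) return(static_sol)   # no fluctuating branch at this J
  di <- dinf_given_d0(root)
  gm <- gaussian_moments(di$mu, root, tf)
  res <- c(mu = di$mu - coupling_mean(params) * gm$mean_phi - params$I,
           energy = outer_resid(root),
           dinf = di$dinf - K * double_gaussian_sq(di$mu, root, di$dinf, tf, "phi"))
  new_dmf_solution("fluctuating", mu = di$mu, delta0 = root,
                   delta_inf = di$dinf, mean_rate = gm$mean_phi,
                   residuals = res)
}

# ---------------------------------------------------------------------------
# Discrete-time two-population DMF
# ---------------------------------------------------------------------------

block_fixed_point <- function(block, tf, tol = 1e-12, max_iter = 10000) {
  J <- block$J
  Tmap <- function(x) {
    pE <- tf_value(tf, x[1]); pI <- tf_value(tf, x[2])
    c(J * block$j_E * (block$C_E * pE - block$g_E * block$C_I * pI),
      J * block$j_I * (block$C_E * pE - block$g_I * block$C_I * pI))
  }
  x <- c(0, 0)
  alpha <- 0.3
  for (i in seq_len(max_iter)) {
    xn <- (1 - alpha) * x + alpha * Tmap(x)
    if (max(abs(xn - x)) < tol) return(xn)
    x <- xn
  }
  # fall back to direct residual minimisation
  obj <- function(x) sum((x - Tmap(x))^2)
  o <- stats::optim(x, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 5000))
  if (o$value > 1e-16 * (1 + sum(x^2)))
    stop_no_convergence("block fixed point iteration did not converge", last = o)
  o$par
}

#' Discrete-time mean-field solution for general two-population networks
#'
#' For the discrete map `x(t+1) = J phi(x(t))` the stochastic process
#' replacing the recurrent input is not filtered, so the stationary
#' statistics obey four algebraic equations for the per-population means and
#' variances: the means follow the block mean matrix applied to
#' `([phi_E], [phi_I])` and the variances the block variance matrix applied
#' to the per-population rate variances.  Solved by damped fixed-point
#' iteration.
#'
#' @param block a [block_params()] object.
#' @param tf transfer function.
#' @return A list of class `"two_pop_dmf_solution"` with fields `regime`,
#'   `mu_E`, `mu_I`, `delta0_E`, `delta0_I`, `mean_rate_E`, `mean_rate_I`,
#'   the fixed point `x0` and the predicted spectrum.  A warning is emitted
#'   when the outlier eigenvalues are large enough (relative to the bulk
#'   radius) that a period-doubling instability may precede the transition
#'   to chaos.
#' @export
solve_dmf_discrete_two_pop <- function(block, tf) {
  stopifnot(inherits(block, "block_params"))
  x0 <- block_fixed_point(block, tf)
  gains <- c(tf_deriv(tf, x0[1]), tf_deriv(tf, x0[2]))
  spec <- spectrum_summary(block, gains)
  if (any(abs(Re(spec$predicted_outliers)) >= spec$predicted_radius) &&
      spec$predicted_radius > 0)
    warning("outlier eigenvalues are not dominated by the bulk radius: a period-doubling bifurcation may precede the transition to chaos")
  J <- block$J
  mom <- function(mu, d0) gaussian_moments(mu, d0, tf)
  update <- function(s) {
    mE <- mom(s[1], s[3]); mI <- mom(s[2], s[4])
    vE <- mE$mean_phi_sq - mE$mean_phi^2
    vI <- mI$mean_phi_sq - mI$mean_phi^2
    c(J * block$j_E * (block$C_E * mE$mean_phi - block$g_E * block$C_I * mI$mean_phi),
      J * block$j_I * (block$C_E * mE$mean_phi - block$g_I * block$C_I * mI$mean_phi),
      J^2 * block$j_E^2 * (block$C_E * vE + block$g_E^2 * block$C_I * vI),
      J^2 * block$j_I^2 * (block$C_E * vE + block$g_I^2 * block$C_I * vI))
  }
  if (spec$predicted_radius < 1) {
    mE <- tf_value(tf, x0[1]); mI <- tf_value(tf, x0[2])
    out <- list(regime = "fixed_point", mu_E = x0[1], mu_I = x0[2],
                delta0_E = 0, delta0_I = 0, mean_rate_E = mE, mean_rate_I = mI,
                x0 = x0, spectrum = spec, residual = 0)
    class(out) <- "two_pop_dmf_solution"
    return(out)
  }
  # damped iteration from a perturbed fixed point; the chaotic branch is the
  # attracting fixed point of the damped update above the instability
  s <- c(x0[1], x0[2], 0.1, 0.1)
  alpha <- 0.3
  res <- Inf
  for (i in seq_len(20000)) {
    sn <- (1 - alpha) * s + alpha * update(s)
    sn[3:4] <- pmax(sn[3:4], 0)
    res <- max(abs(sn - s))
    s <- sn
    if (res < 1e-11) break
  }
  if (res > 1e-8)
    stop_no_convergence("two-population discrete DMF iteration did not converge",
                        last = s)
  mE <- mom(s[1], s[3]); mI <- mom(s[2], s[4])
  out <- list(regime = "fluctuating", mu_E = s[1], mu_I = s[2],
              delta0_E = s[3], delta0_I = s[4],
              mean_rate_E = mE$mean_phi, mean_rate_I = mI$mean_phi,
              x0 = x0, spectrum = spec, residual = res)
  class(out) <- "two_pop_dmf_solution"
  out
}

#' @export
print.two_pop_dmf_solution <- function(x, ...) {
  cat(sprintf("two-population discrete DMF [%s]:\n", x$regime))
  cat(sprintf("  E: mu = %.5g, Delta0 = %.5g, rate = %.5g\n",
              x$mu_E, x$delta0_E, x$mean_rate_E))
  cat(sprintf("  I: mu = %.5g, Delta0 = %.5g, rate = %.5g\n",
              x$mu_I, x$delta0_I, x$mean_rate_I))
  invisible(x)
}

# ---------------------------------------------------------------------------
# LIF transfer function DMF
# ---------------------------------------------------------------------------

#' Mean-field solution for the rate model with an LIF transfer function
#'
#' Runs the same stationary machinery as [solve_dmf()] with the
#' threshold-linear function replaced by the LIF first-passage rate
#' `F(mu_0 + tau_m x, sigma)`, where the input noise is pinned to the
#' effective value `sigma^2 = tau_m J^2 (C_E + g^2 C_I) * phi_bar`
#' determined by a reference rate `phi_bar`.  The upper bound of this
#' transfer function is the inverse refractory period, so the role played
#' by `phi_max` in the threshold-linear analysis is taken over by
#' `1 / tau_rp`.
#'
#' @param params a [network_params()] object (`J` in mV).
#' @param lif an [lif_transfer()] object; its `sigma` field is overwritten
#'   by the effective value.
#' @param phi_bar reference rate (1/ms) fixing the effective noise.
#' @return A `"dmf_solution"` (rates in 1/ms) with the effective transfer
#'   function attached as `tf_eff` and the critical coupling as `Jc`.
#' @export
solve_dmf_lif <- function(params, lif, phi_bar = 0.02) {
  stopifnot(inherits(params, "network_params"), inherits(lif, "lif_transfer"))
  make_tf <- function(J) {
    s2 <- lif$tau_m * J^2 * (params$C_E + params$g^2 * params$C_I) * phi_bar
    lif_transfer(tau_m = lif$tau_m, V_th = lif$V_th, V_r = lif$V_r,
                 tau_rp = lif$tau_rp, sigma = sqrt(s2), mu_0 = lif$mu_0)
  }
  radius <- function(J) {
    p <- params; p$J <- J
    tfJ <- make_tf(J)
    x0 <- solve_fixed_point(p, tfJ)
    tf_deriv(tfJ, x0) * J * sqrt(params$C_E + params$g^2 * params$C_I)
  }
  Jc <- tryCatch({
    f <- function(J) radius(J) - 1
    lo <- 1e-4; hi <- 5
    while (f(hi) < 0 && hi < 100) hi <- hi * 2
    stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  }, error = function(e) NA_real_)
  tf_eff <- make_tf(params$J)
  # tabulate the Siegert rate over a generous input range: the spline makes
  # every Gaussian moment cheap (the rate is constant-extended outside)
  mu_lo <- lif$V_th - 30 * max(tf_eff$sigma, 1) - 60
  mu_hi <- lif$V_th + 2000
  tf_tab <- tf_tabulate(tf_eff, (mu_lo - lif$mu_0) / lif$tau_m,
                        (mu_hi - lif$mu_0) / lif$tau_m)
  if (!is.na(Jc) && params$J <= Jc) {
    x0 <- solve_fixed_point(params, tf_eff)
    sol <- new_dmf_solution("fixed_point", mu = x0, delta0 = 0, delta_inf = 0,
                            mean_rate = tf_value(tf_eff, x0),
                            residuals = c(mu = 0, energy = 0))
  } else {
    # the LIF rate is bounded by 1/tau_rp, so the bounded-transfer scan of
    # solve_dmf applies; mark divergence through the scan cap for tau_rp = 0
    sol <- solve_dmf_general(params, tf_tab)
  }
  sol$tf_eff <- tf_eff
  sol$Jc <- Jc
  sol
}

# solve_dmf body for a generic (non threshold-linear) transfer function:
# identical scan, but bounds/divergence are decided by the scan cap alone
solve_dmf_general <- function(params, tf, noise = noise_spec("none"),
                              delta0_max = 1e8) {
  gap_f <- function(d0) energy_gap(params, tf, noise, d0)$gap
  scale0 <- 1e-6
  grid <- scale0 * 1.25^(0:round(log(delta0_max / scale0) / log(1.25)))
  prev <- gap_f(grid[1])
  if (prev <= 0 && noise$kind == "none") {
    x0 <- solve_fixed_point(params, tf)
    return(new_dmf_solution("fixed_point", mu = x0, delta0 = 0, delta_inf = 0,
                            mean_rate = tf_value(tf, x0),
                            residuals = c(mu = 0, energy = 0), noise = noise))
  }
  root <- NA_real_
  for (i in 2:length(grid)) {
    cur <- gap_f(grid[i])
    if (prev > 0 && cur <= 0) {
      root <- stats::uniroot(gap_f, c(grid[i - 1], grid[i]), tol = 1e-11)$root
      break
    }
    prev <- cur
  }
  if (is.na(root))
    return(new_dmf_solution("divergent", mu = -Inf, delta0 = Inf,
                            delta_inf = 0, mean_rate = Inf,
                            residuals = c(mu = NA, energy = NA), noise = noise))
  eg <- energy_gap(params, tf, noise, root)
  new_dmf_solution("fluctuating", mu = eg$mu, delta0 = root, delta_inf = 0,
                   mean_rate = eg$gm$mean_phi,
                   residuals = c(mu = 0, energy = eg$gap), noise = noise,
                   delta_ext_eff = eg$dext)
}

#' Self-consistent asynchronous fixed point of the LIF network
#'
#' Solves the classical self-consistency of the asynchronous state of a
#' sparse LIF network: the population rate `nu` satisfies
#' `nu = F(mu_0 + tau_m J (C_E - g C_I) nu, sigma(nu))` with
#' `sigma^2(nu) = tau_m J^2 (C_E + g^2 C_I) nu`.  This is the fixed point of
#' the LIF rate model with both the mean and the variance of the input
#' determined by the rate itself, and it is the mean-field prediction
#' against which the spiking simulations are compared at weak coupling.
#'
#' @param params a [network_params()] object (`J` in mV).
#' @param lif an [lif_transfer()] object (its `sigma` field is ignored).
#' @return A list with `rate` (1/ms), `mu` (mV) and `sigma` (mV).
#' @export
lif_fixed_point <- function(params, lif) {
  km <- params$C_E - params$g * params$C_I
  K <- params$C_E + params$g^2 * params$C_I
  h <- function(nu) {
    mu <- lif$mu_0 + lif$tau_m * params$J * km * nu
    s2 <- lif$tau_m * params$J^2 * K * nu
    nu - lif_F(mu, s2, lif)
  }
  hi <- if (lif$tau_rp > 0) 1 / lif$tau_rp else 2
  nu <- stats::uniroot(h, c(0, hi), tol = 1e-13)$root
  list(rate = nu,
       mu = lif$mu_0 + lif$tau_m * params$J * km * nu,
       sigma = sqrt(lif$tau_m * params$J^2 * K * nu))
}
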