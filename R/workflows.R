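#' Classify the dynamical regime of a parameter set
#'
#' Locates the coupling of a threshold-linear EI network relative to the two
#' critical couplings: below `J_C` the homogeneous fixed point is stable;
#' between `J_C` and `J_D` the network fluctuates but stays bounded even
#' without an upper bound on the rates (fluctuations stabilised by
#' inhibition and the positivity constraint); above `J_D` a finite
#' stationary state exists only thanks to the saturation bound.
#'
#' @param params a [network_params()] object (its `J` field is the coupling
#'   being classified).
#' @param tf a [threshold_linear()] transfer function (only `gamma` is
#'   used: the classification is defined through the unbounded limit).
#' @return One of `"fixed_point"`, `"inhibition_stabilized"`,
#'   `"bound_stabilized"`, with attributes `Jc` and `Jd`.
#' @export
classify_regime <- function(params, tf = threshold_linear()) {
  stopifnot(inherits(params, "network_params"),
            inherits(tf, "threshold_linear"))
  Jc <- critical_coupling_Jc(params, tf)
  if (!is.na(Jc) && params$J < Jc)
    return(structure("fixed_point", Jc = Jc, Jd = NA_real_))
  Jd <- divergence_coupling_Jd(params)
  structure(if (params$J < Jd) "inhibition_stabilized" else "bound_stabilized",
            Jc = Jc, Jd = Jd)
}

#' Phase diagram over network parameters
#'
#' Tabulates the two critical couplings over a grid of inhibition ratios
#' and/or in-degrees (all other parameters fixed).
#'
#' @param params a [network_params()] template.
#' @param g_values,C_values grids (either may be a scalar).
#' @param tf transfer function (threshold-linear).
#' @return A data.frame with one row per `(g, C)` and columns `g`, `C`,
#'   `Jc`, `Jd`, `Jd_over_Jc`.
#' @export
phase_diagram <- function(params, g_values = params$g, C_values = params$C,
                          tf = threshold_linear()) {
  grid <- expand.grid(g = g_values, C = C_values)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    p <- network_params(J = params$J, g = grid$g[r], C = grid$C[r],
                        f = params$f, N = params$N, I = params$I)
    Jc <- critical_coupling_Jc(p, tf)
    Jd <- tryCatch(divergence_coupling_Jd(p), error = function(e) NA_real_)
    data.frame(g = grid$g[r], C = grid$C[r], Jc = Jc, Jd = Jd,
               Jd_over_Jc = Jd / Jc)
  })
  do.call(rbind, rows)
}

#' Side-by-side comparison of theory and simulation over a coupling scan
#'
#' For each coupling in `J_values` solves the stationary mean-field
#' equations and (optionally) runs matched network simulations, reporting
#' predicted and empirical mean current, variance and mean rate together
#' with pass/fail flags at the stated relative tolerance.
#'
#' @param params a [network_params()] template (its `J` is replaced by each
#'   grid value; `N` sets the simulated size).
#' @param J_values coupling grid.
#' @param tf transfer function (threshold-linear).
#' @param noise a [noise_spec()] passed to both solver and simulator.
#' @param seeds connectivity/initial-condition seeds for the simulations;
#'   use `integer(0)` to skip simulation and report theory only.
#' @param T,dt simulation horizon and step.
#' @param discard transient dropped before computing statistics.
#' @param tol relative tolerance for the pass/fail flags.
#' @return A data.frame with one row per coupling; when simulations are run
#'   it carries empirical columns, absolute relative errors and a logical
#'   `pass`.  The attribute `all_pass` summarises the run.
#' @export
run_comparison <- function(params, J_values, tf, noise = noise_spec("none"),
                           seeds = 1:3, T = 300, dt = 0.05, discard = 50,
                           tol = 0.1) {
  rows <- lapply(J_values, function(J) {
    p <- params; p$J <- J
    sol <- solve_dmf(p, tf, noise)
    row <- data.frame(J = J, regime = sol$regime, mu = sol$mu,
                      delta0 = sol$delta0, rate = sol$mean_rate)
    if (length(seeds) && sol$regime != "divergent") {
      st <- vapply(seeds, function(s) {
        W <- build_fixed_indegree(p, seed = s)
        tr <- simulate_rate(W, tf, I = p$I, noise = noise, T = T, dt = dt,
                            seed = s + 1000L)
        cs <- current_stats(tr, discard = discard, tf = tf)
        c(cs$mean_current, cs$delta0_emp, cs$mean_rate)
      }, numeric(3))
      emp <- rowMeans(st)
      row$mu_emp <- emp[1]; row$delta0_emp <- emp[2]; row$rate_emp <- emp[3]
      scale_mu <- max(abs(sol$mu), 0.05)
      row$err_mu <- abs(emp[1] - sol$mu) / scale_mu
      row$err_delta0 <- if (sol$delta0 > 1e-6)
        abs(emp[2] - sol$delta0) / sol$delta0 else emp[2]
      row$err_rate <- abs(emp[3] - sol$mean_rate) / max(sol$mean_rate, 1e-3)
      row$pass <- row$err_mu < tol & row$err_rate < tol &
        (if (sol$delta0 > 1e-6) row$err_delta0 < tol else emp[2] < 1e-3)
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "all_pass") <- if ("pass" %in% names(out)) all(out$pass) else NA
  out
}
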