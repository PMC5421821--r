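test_that("homogeneous fixed point has its closed-form limits", {
  tf <- tl_bounded(2)
  p0 <- ref_params(J = 0)
  expect_equal(solve_fixed_point(p0, tf), 0)
  p0$I <- 0.7
  expect_equal(solve_fixed_point(p0, tf), 0.7)
  # exact balance g = C_E / C_I cancels the recurrent term
  pb <- ref_params(J = 0.3, g = 4, I = 0.2)
  expect_equal(solve_fixed_point(pb, tf), 0.2, tolerance = 1e-9)
  # inhibition-dominated linear branch: x0 = J*k*gamma / (1 - J*k)
  p <- ref_params(J = 0.2, g = 5)
  expect_equal(solve_fixed_point(p, tf), -0.4, tolerance = 1e-10)
  expect_equal(phi(solve_fixed_point(p, tf), tf), 0.1, tolerance = 1e-10)
})

test_that("critical coupling matches the unit-gain closed form and shrinks with C", {
  tf <- tl_bounded(2)
  expect_equal(critical_coupling_Jc(ref_params(g = 5), tf), 1 / sqrt(580),
               tolerance = 1e-9)
  expect_equal(critical_coupling_Jc(ref_params(g = 4.5), tf), 1 / sqrt(485),
               tolerance = 1e-9)
  Jc_C <- vapply(c(100, 200, 400),
                 function(C) critical_coupling_Jc(ref_params(C = C), tf),
                 numeric(1))
  expect_true(all(diff(Jc_C) < 0))
})

test_that("stationary solver returns the fixed point below Jc and the noise-filter limit", {
  tf <- tl_bounded(2)
  Jc <- Jc_ref()
  pb <- ref_params(J = 0.9 * Jc)
  sb <- solve_dmf(pb, tf)
  expect_equal(sb$regime, "fixed_point")
  expect_equal(sb$mu, solve_fixed_point(pb, tf))
  expect_equal(sb$delta0, 0)
  # uncoupled network with white noise: Delta0 = Delta_ext exactly
  p0 <- ref_params(J = 0)
  sn <- solve_dmf(p0, tf, noise_spec("white", delta_ext = 0.13))
  expect_equal(sn$delta0, 0.13, tolerance = 1e-8)
  expect_equal(sn$mu, 0, tolerance = 1e-10)
})

test_that("variance branch is continuous at Jc and raises the mean rate", {
  tf <- tl_bounded(2)
  Jc <- Jc_ref()
  d0 <- vapply(c(1.001, 1.02, 1.1, 1.5),
               function(r) solve_dmf(ref_params(J = r * Jc), tf)$delta0,
               numeric(1))
  expect_true(all(diff(d0) > 0))
  expect_lt(d0[1], 0.04 * d0[4])
  # fluctuations raise the mean rate above the fixed-point value
  p2 <- ref_params(J = 2 * Jc)
  s2 <- solve_dmf(p2, tf)
  expect_gt(s2$mean_rate, phi(solve_fixed_point(p2, tf), tf))
})

test_that("potential is consistent with the rate-correlation force", {
  tf <- tl_bounded(2)
  Jc <- Jc_ref()
  p <- ref_params(J = 1.5 * Jc)
  sol <- solve_dmf(p, tf)
  K <- p$J^2 * (p$C_E + p$g^2 * p$C_I)
  mp2 <- gaussian_moments(sol$mu, sol$delta0, tf)$mean_phi^2
  # -dV/dDelta equals Delta - J^2 K (C(Delta) - [phi]^2)
  for (d in c(0.2, 0.5, 0.8) * sol$delta0) {
    h <- 1e-5
    dV <- (potential_V(d + h, sol$delta0, sol$mu, p, tf) -
             potential_V(d - h, sol$delta0, sol$mu, p, tf)) / (2 * h)
    force <- d - K * (rate_correlation(sol$mu, sol$delta0, d, tf) - mp2)
    expect_lt(abs(-dV - force), 1e-5 * max(1, abs(force)))
  }
  # derivative vanishes at Delta = 0 (homogeneous in-degree)
  h <- 1e-6
  dV0 <- (potential_V(h, sol$delta0, sol$mu, p, tf) -
            potential_V(0, sol$delta0, sol$mu, p, tf)) / h
  expect_lt(abs(dV0), 1e-4)
  # below Jc the potential is concave with its maximum at 0
  pb <- ref_params(J = 0.8 * Jc)
  x0 <- solve_fixed_point(pb, tf)
  dg <- seq(0, 0.5, length.out = 21)
  Vg <- vapply(dg, function(d) potential_V(d, 0.5, x0, pb, tf), numeric(1))
  expect_equal(which.max(Vg), 1L)
  expect_true(all(diff(Vg, differences = 2) < 1e-10))
})

test_that("autocorrelation trajectory decays with conserved energy", {
  tf <- tl_bounded(2)
  p <- ref_params(J = 1.5 * Jc_ref())
  sol <- solve_dmf(p, tf)
  st <- autocorrelation_trajectory(sol, p, tf, dtau = 0.01)
  expect_equal(st$delta_trace[1], sol$delta0)
  n <- length(st$delta_trace)
  expect_lt(st$delta_trace[n], 1.1e-4 * sol$delta0)
  expect_true(all(diff(st$delta_trace) < 1e-10))
  expect_lt(st$energy_residual, 1e-4 * sol$delta0)
  # requesting a trajectory for a fixed point is an error
  sb <- solve_dmf(ref_params(J = 0.5 * Jc_ref()), tf)
  expect_error(autocorrelation_trajectory(sb, p, tf), "fluctuating")
})

test_that("fluctuation timescale diverges approaching the critical coupling", {
  tf <- tl_bounded(2)
  Jc <- Jc_ref()
  fw <- vapply(c(1.02, 1.08, 1.2), function(r) {
    p <- ref_params(J = r * Jc)
    st <- autocorrelation_trajectory(solve_dmf(p, tf), p, tf, dtau = 0.02)
    timescale_fwhm(st$tau_grid, st$delta_trace)
  }, numeric(1))
  expect_true(all(diff(fw) < 0))
  expect_gt(fw[1] / fw[3], 3)
})

test_that("divergence coupling is consistent with the solver's classifier", {
  p <- ref_params(g = 5)
  Jd <- divergence_coupling_Jd(p)
  Jc <- Jc_ref()
  expect_gt(Jd, Jc)
  tfu <- tl_unbounded()
  mid <- ref_params(J = (Jc + Jd) / 2)
  expect_equal(solve_dmf(mid, tfu)$regime, "fluctuating")
  lo <- ref_params(J = 0.98 * Jd)
  hi <- ref_params(J = 1.02 * Jd)
  expect_equal(solve_dmf(lo, tfu)$regime, "fluctuating")
  expect_equal(solve_dmf(hi, tfu)$regime, "divergent")
  # Jd grows with the inhibition ratio
  Jd_g <- vapply(c(4.5, 5, 6), function(g)
    divergence_coupling_Jd(ref_params(g = g)), numeric(1))
  expect_true(all(diff(Jd_g) > 0))
  # purely inhibitory networks are refused with the artifact error
  pin <- network_params(J = 0.1, g = 1, C = 100, f = 0, N = 1000, I = 1)
  expect_error(divergence_coupling_Jd(pin),
               class = "eichaos_gaussian_artifact_error")
})

test_that("variance saturates with phi_max below Jd and scales above it", {
  Jc <- Jc_ref(); p <- ref_params()
  Jd <- divergence_coupling_Jd(p)
  pm <- ref_params(J = (Jc + Jd) / 2)
  d8 <- solve_dmf(pm, tl_bounded(8))$delta0
  dI <- solve_dmf(pm, tl_unbounded())$delta0
  expect_lt(abs(d8 - dI) / dI, 0.05)
  pd <- ref_params(J = 1.5 * Jd)
  sd_vals <- vapply(c(2, 4, 8, 16), function(M)
    sqrt(solve_dmf(pd, tl_bounded(M))$delta0), numeric(1))
  r2 <- summary(stats::lm(sd_vals ~ c(2, 4, 8, 16)))$r.squared
  expect_gt(r2, 0.99)
})

test_that("spiking noise contributes weakly near the divergence coupling", {
  # near Jd the total variance is dominated by the intrinsic feedback; the
  # spiking-noise kinetic term contributes only a small share of the energy
  # balance (the variance itself is hypersensitive to any perturbation close
  # to the divergence, so the share is the meaningful measure)
  p <- ref_params()
  Jd <- divergence_coupling_Jd(p)
  pj <- ref_params(J = 0.9 * Jd)
  tfu <- tl_unbounded()
  s_spk <- solve_dmf(pj, tfu, noise_spec("poisson_spiking", tau_bar = 1))
  expect_lt(s_spk$delta_ext_eff^2 / s_spk$delta0^2, 0.1)
})

test_that("purely inhibitory fluctuations barely raise the mean rate", {
  tf <- tl_bounded(2)
  pin <- network_params(J = 0.1, g = 1, C = 100, f = 0, N = 1000, I = 1)
  Jci <- critical_coupling_Jc(pin, tf)
  pin$J <- 1.5 * Jci
  si <- solve_dmf(pin, tf)
  elev_in <- si$mean_rate / phi(solve_fixed_point(pin, tf), tf) - 1
  pei <- ref_params(J = 1.5 * Jc_ref())
  se <- solve_dmf(pei, tf)
  elev_ei <- se$mean_rate / phi(solve_fixed_point(pei, tf), tf) - 1
  expect_gt(si$delta0, 0)
  expect_gt(elev_ei / elev_in, 5)
})

test_that("stochastic in-degree solver: limits and quenched structure", {
  tf <- tl_bounded(2)
  p0 <- ref_params(J = 0)
  s0 <- solve_dmf_stochastic_indegree(p0, tf)
  expect_equal(s0$mu, 0)
  expect_equal(s0$delta0, 0)
  # static branch solves Delta0 = J^2 K [phi^2]
  ps <- ref_params(J = 0.5 * Jc_ref())
  ss <- solve_dmf_stochastic_indegree(ps, tf)
  K <- ps$J^2 * 580
  expect_equal(ss$delta0,
               K * gaussian_moments(ss$mu, ss$delta0, tf)$mean_phi_sq,
               tolerance = 1e-8)
  expect_equal(ss$delta0, ss$delta_inf)
  # strong coupling: temporal fluctuations on top of quenched disorder
  pf <- ref_params(J = 2.2 * Jc_ref())
  sf <- solve_dmf_stochastic_indegree(pf, tf)
  expect_equal(sf$regime, "fluctuating")
  expect_gt(sf$delta0, sf$delta_inf)
  expect_gt(sf$delta_inf, 0)
})

test_that("two-population discrete theory reduces to single statistics", {
  tf <- tl_bounded(1)
  # equal populations, weak inhibition dominance (no period doubling)
  b <- block_params(j_E = 1, j_I = 1, g_E = 4.2, g_I = 4.2, C_E = 80, C_I = 20,
                    N_E = 800, N_I = 200, J = 0.055)
  sol <- solve_dmf_discrete_two_pop(b, tf)
  expect_equal(sol$mu_E, sol$mu_I, tolerance = 1e-9)
  expect_equal(sol$delta0_E, sol$delta0_I, tolerance = 1e-9)
  # oracle: direct damped iteration of the reduced two-equation system
  km <- 0.055 * (80 - 4.2 * 20); K <- 0.055^2 * (80 + 4.2^2 * 20)
  s <- c(0, 0.05)
  for (i in 1:5000) {
    gm <- gaussian_moments(s[1], s[2], tf)
    s <- 0.7 * s + 0.3 * c(km * gm$mean_phi,
                           K * (gm$mean_phi_sq - gm$mean_phi^2))
  }
  expect_equal(sol$mu_E, s[1], tolerance = 1e-6)
  expect_equal(sol$delta0_E, s[2], tolerance = 1e-6)
  # fixed-point branch matches the two-population fixed-point equations
  blo <- block_params(j_E = 0.1, j_I = 0.15, g_E = 4.5, g_I = 4.2,
                      C_E = 80, C_I = 20, N_E = 800, N_I = 200, J = 0.2)
  slo <- solve_dmf_discrete_two_pop(blo, tf)
  expect_equal(slo$regime, "fixed_point")
  expect_equal(slo$mu_E,
               0.2 * 0.1 * (80 * phi(slo$mu_E, tf) - 4.5 * 20 * phi(slo$mu_I, tf)),
               tolerance = 1e-8)
  # strong inhibition makes the outlier dominate the bulk: the negative
  # real outlier then loses stability first, so the solver must warn
  bw <- block_params(j_E = 1, j_I = 1, g_E = 6, g_I = 6, C_E = 80, C_I = 20,
                     N_E = 800, N_I = 200, J = 0.05)
  expect_warning(solve_dmf_discrete_two_pop(bw, tf), "period-doubling")
})

test_that("LIF-transfer theory: uncoupled limit and refractory-period regimes", {
  p0 <- network_params(J = 1e-8, g = 5, C = 100, N = 1000)
  lt <- lif_transfer(tau_rp = 0.5)
  s0 <- solve_dmf_lif(p0, lt, phi_bar = 0.02)
  expect_equal(s0$mean_rate, lif_F(24, 0, lt), tolerance = 1e-4)
  # below Jc the solution is the self-consistent fixed point of the rate map
  p <- network_params(J = 0.3, g = 5, C = 100, N = 1000)
  s <- solve_dmf_lif(p, lt, phi_bar = 0.02)
  expect_equal(s$regime, "fixed_point")
  expect_equal(s$mu, p$J * (80 - 5 * 20) * s$mean_rate, tolerance = 1e-6)
  # refractory-period sensitivity separates the two fluctuating regimes:
  # intermediate coupling saturates as tau_rp -> 0, strong coupling grows
  rate_at <- function(J, trp) {
    pj <- network_params(J = J, g = 5, C = 100, N = 1000)
    solve_dmf_lif(pj, lif_transfer(tau_rp = trp), phi_bar = 0.02)$mean_rate
  }
  ratio_mid <- rate_at(0.75, 0.1) / rate_at(0.75, 0.5)
  ratio_strong <- rate_at(1.2, 0.1) / rate_at(1.2, 0.5)
  expect_lt(ratio_mid, 1.15)
  expect_gt(ratio_strong, 1.5)
})
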