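test_that("rate network converges to the homogeneous fixed point below Jc", {
  tf <- tl_bounded(2)
  p <- ref_params(J = 0.5 * Jc_ref(), N = 1000)
  W <- build_fixed_indegree(p, seed = 1)
  tr <- simulate_rate(W, tf, T = 100, dt = 0.05, seed = 2)
  x0 <- solve_fixed_point(p, tf)
  expect_false(tr$divergent)
  expect_lt(max(abs(tr$currents[, ncol(tr$currents)] - x0)), 1e-6)
})

test_that("simulators are bit-reproducible given matrix and seed", {
  tf <- tl_bounded(2)
  p <- ref_params(J = 2 * Jc_ref(), N = 500)
  W <- build_fixed_indegree(p, seed = 3)
  t1 <- simulate_rate(W, tf, T = 20, dt = 0.05, seed = 9)
  t2 <- simulate_rate(W, tf, T = 20, dt = 0.05, seed = 9)
  expect_identical(t1$currents, t2$currents)
  n1 <- simulate_rate(W, tf, noise = noise_spec("white", 0.1), T = 20,
                      dt = 0.05, seed = 9)
  n2 <- simulate_rate(W, tf, noise = noise_spec("white", 0.1), T = 20,
                      dt = 0.05, seed = 9)
  expect_identical(n1$currents, n2$currents)
  s1 <- simulate_lif(W, lif_params(), T = 200, dt = 0.05, seed = 4)
  s2 <- simulate_lif(W, lif_params(), T = 200, dt = 0.05, seed = 4)
  expect_identical(s1$spikes, s2$spikes)
})

test_that("halving the step leaves the empirical variance nearly unchanged", {
  tf <- tl_bounded(2)
  p <- ref_params(J = 2 * Jc_ref(), N = 2000)
  W <- build_fixed_indegree(p, seed = 1)
  # long window so that chaotic sampling variability sits well below the
  # discretisation tolerance being checked
  d0 <- vapply(c(0.05, 0.025), function(dt) {
    tr <- simulate_rate(W, tf, T = 2000, dt = dt, seed = 5)
    current_stats(tr, discard = 100)$delta0_emp
  }, numeric(1))
  expect_lt(abs(d0[2] / d0[1] - 1), 0.02)
})

test_that("unbounded dynamics diverge above Jd and stay bounded below", {
  tfu <- tl_unbounded()
  Jd <- divergence_coupling_Jd(ref_params())
  pd <- ref_params(J = 1.6 * Jd, N = 2000)
  Wd <- build_fixed_indegree(pd, seed = 1)
  trd <- simulate_rate(Wd, tfu, T = 200, dt = 0.05, seed = 2)
  expect_true(trd$divergent)
  pb <- ref_params(J = 0.7 * Jd, N = 2000)
  Wb <- build_fixed_indegree(pb, seed = 1)
  trb <- simulate_rate(Wb, tfu, T = 100, dt = 0.05, seed = 2)
  expect_false(trb$divergent)
  expect_true(all(is.finite(trb$currents)))
})

test_that("Poisson spiking counts are consistent with the instantaneous rates", {
  tf <- tl_bounded(2)
  p <- ref_params(J = 1.6 * Jc_ref(), N = 1000)
  W <- build_fixed_indegree(p, seed = 2)
  tr <- simulate_rate_poisson(W, tf, tau_bar = 1, T = 60, dt = 0.02, seed = 3,
                              keep_every = 1, record_spikes = TRUE)
  # total spike count vs integral of phi(x) dt over the run
  expected <- sum(phi(tr$currents[, -ncol(tr$currents)], tf)) * 0.02
  total <- sum(tr$spike_count)
  expect_lt(abs(total - expected) / sqrt(expected), 4)
  expect_equal(nrow(tr$spikes), total)
  # slowing the rate dynamics reduces the spiking-noise variance
  d0 <- vapply(c(1, 4), function(tb) {
    trb <- simulate_rate_poisson(W, tf, tau_bar = tb, T = 80 * tb, dt = 0.02,
                                 seed = 4)
    current_stats(trb, discard = 20 * tb)$delta0_emp
  }, numeric(1))
  expect_gt(d0[1], d0[2])
})

test_that("discrete map contracts to the fixed point at weak coupling", {
  tf <- tl_bounded(1)
  b <- block_params(j_E = 0.1, j_I = 0.15, g_E = 4.5, g_I = 4.2,
                    C_E = 80, C_I = 20, N_E = 800, N_I = 200, J = 0.2)
  W <- build_block(b, seed = 1)
  tr1 <- simulate_discrete(W, tf, T_steps = 300, seed = 2)
  tr2 <- simulate_discrete(W, tf, T_steps = 300, seed = 3)
  last1 <- tr1$currents[, 301]; last2 <- tr2$currents[, 301]
  expect_lt(max(abs(last1 - last2)), 1e-10)
  sol <- solve_dmf_discrete_two_pop(b, tf)
  expect_lt(max(abs(last1[1:800] - sol$mu_E)), 1e-8)
})

test_that("an isolated suprathreshold LIF neuron fires at the closed-form rate", {
  W <- as_connectivity(matrix(0, 1, 1))
  lp <- lif_params(tau_rp = 0.5, delay = 1, mu_0 = 24)
  sp <- simulate_lif(W, lp, T = 5000, dt = 0.01, seed = 1)
  isi_pred <- 0.5 + 20 * log((24 - 10) / (24 - 20))
  n_expected <- floor((5000 - isi_pred) / isi_pred)
  expect_lt(abs(nrow(sp$spikes) - n_expected), 2)
  isis <- diff(sp$spikes$time)
  expect_lt(max(abs(isis - mean(isis))), 0.011)  # periodic up to grid rounding
  expect_lt(abs(mean(isis) / isi_pred - 1), 0.01)
})

test_that("refractory period is enforced and delays are bit-exact", {
  p <- ref_params(J = 1, g = 5, C = 100, N = 400)
  W <- build_fixed_indegree(p, seed = 1)
  lp <- lif_params(tau_rp = 2, delay = 2.5, mu_0 = 24)
  sp <- simulate_lif(W, lp, T = 2000, dt = 0.05, seed = 2)
  by_n <- split(sp$spikes$time, sp$spikes$neuron)
  min_isi <- min(vapply(by_n[lengths(by_n) > 1], function(t) min(diff(t)), 1e9))
  expect_gte(min_isi, 2 + 0.05 - 1e-9)
  # delay must be a multiple of dt
  expect_error(simulate_lif(W, lif_params(delay = 1.1), T = 10, dt = 0.04),
               "multiple")
})

test_that("a presynaptic spike deposits exactly its PSP amplitude after the delay", {
  # neuron 1 starts above threshold and spikes at the first step; neuron 2 is
  # passive.  Ending the run exactly at the arrival step isolates the jump.
  Wmat <- matrix(0, 2, 2); Wmat[2, 1] <- 0.37
  W <- as_connectivity(Wmat)
  dt <- 0.05; delay <- 1
  lp0 <- lif_params(tau_rp = 0.5, delay = delay, mu_0 = 0)
  V0 <- c(25, 15)
  sp_on <- simulate_lif(W, lp0, T = delay + dt, dt = dt, seed = 1, V0 = V0)
  W0 <- as_connectivity(matrix(0, 2, 2))
  sp_off <- simulate_lif(W0, lp0, T = delay + dt, dt = dt, seed = 1, V0 = V0)
  expect_equal(nrow(sp_on$spikes), 1L)
  expect_equal(sp_on$V_end[2] - sp_off$V_end[2], 0.37, tolerance = 1e-12)
})

test_that("lif parameter validation warns about synchrony-prone settings", {
  expect_warning(lif_params(tau_rp = 1.5, delay = 1.1), "synchronization")
  expect_error(lif_params(V_th = 5, V_r = 10), "exceed")
})
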