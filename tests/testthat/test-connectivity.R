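test_that("fixed in-degree rows carry exactly the prescribed synapses", {
  p <- ref_params(J = 0.2, g = 5, C = 100, N = 2000)
  W <- build_fixed_indegree(p, seed = 1)
  rs <- Matrix::rowSums(W$weights)
  expect_equal(max(abs(rs - 0.2 * (80 - 5 * 20))), 0, tolerance = 1e-12)
  # per-row counts of excitatory and inhibitory entries
  pos <- Matrix::rowSums(W$weights > 0)
  neg <- Matrix::rowSums(W$weights < 0)
  expect_true(all(pos == 80) && all(neg == 20))
  # Dale's law by column
  pop <- W$population
  expect_true(all(W$weights[, pop == "E"]@x >= 0))
  expect_true(all(W$weights[, pop == "I"]@x <= 0))
})

test_that("builders are deterministic given the seed", {
  p <- ref_params(N = 500)
  for (build in list(build_fixed_indegree, build_stochastic_indegree,
                     build_gaussian_equivalent)) {
    W1 <- build(p, seed = 7)
    W2 <- build(p, seed = 7)
    W3 <- build(p, seed = 8)
    expect_identical(W1$weights, W2$weights)
    expect_false(identical(W1$weights, W3$weights))
  }
})

test_that("invalid degree configurations are rejected", {
  expect_error(network_params(J = 1, g = 5, C = 600, N = 500), "exceed")
  p_frac <- network_params(J = 1, g = 5, C = 100, f = 0.777, N = 500)
  expect_error(build_fixed_indegree(p_frac, seed = 1), "integer")
})

test_that("stochastic in-degree rows are binomial", {
  p <- ref_params(J = 1, g = 5, C = 100, N = 2000)
  W <- build_stochastic_indegree(p, seed = 3)
  deg <- Matrix::rowSums(W$weights != 0)
  # mean within 3 standard errors
  se <- sqrt(100 * (1 - 100 / 2000) / 2000)
  expect_lt(abs(mean(deg) - 100), 3 * se)
  # variance close to C(1 - C/N)
  expect_lt(abs(var(deg) / (100 * (1 - 100 / 2000)) - 1), 0.15)
  # p = 1 gives a dense matrix
  pd <- ref_params(J = 1, g = 5, C = 200, N = 200)
  Wd <- build_stochastic_indegree(pd, seed = 1)
  expect_equal(length(Wd$weights@x), 200 * 200)
})

test_that("block builder honours per-population strengths and reduces", {
  b <- block_params(j_E = 0.1, j_I = 0.15, g_E = 4.5, g_I = 4.2,
                    C_E = 80, C_I = 20, N_E = 800, N_I = 200, J = 0.4)
  W <- build_block(b, seed = 2)
  rs <- Matrix::rowSums(W$weights)
  expect_equal(rs[1:800], rep(0.4 * 0.1 * (80 - 4.5 * 20), 800))
  expect_equal(rs[801:1000], rep(0.4 * 0.15 * (80 - 4.2 * 20), 200))
  # reduction to the single-statistics ensemble
  p <- ref_params(J = 0.3, N = 1000)
  br <- as_block_params(p)
  Wr <- build_block(br, seed = 5)
  expect_equal(sort(unique(Wr$weights@x)), c(-1.5, 0.3))
  expect_true(all(Matrix::rowSums(Wr$weights != 0) == 100))
})

test_that("gaussian-equivalent entries match the target moments", {
  p <- ref_params(J = 0.2, g = 5, C = 100, N = 800)
  W <- build_gaussian_equivalent(p, seed = 4)
  x <- as.vector(as.matrix(W$weights))
  m_t <- 0.2 * (80 - 100) / 800
  v_t <- 0.04 * (80 + 25 * 20) / 800
  expect_lt(abs(mean(x) - m_t), 3 * sqrt(v_t / length(x)))
  expect_lt(abs(var(x) / v_t - 1), 3 * sqrt(2 / length(x)))
})

test_that("predicted spectrum matches algebra and one realization", {
  b <- as_block_params(ref_params(J = 1, g = 5, C = 100, N = 1500))
  s <- spectrum_summary(b, gains = c(1, 1))
  expect_equal(s$predicted_radius, sqrt(580), tolerance = 1e-12)
  expect_equal(sort(Re(s$predicted_outliers)), c(-20, 0), tolerance = 1e-9)
  expect_error(spectrum_summary(b, gains = c(-1, 1)), "non-negative")
  s0 <- spectrum_summary(b, gains = c(0, 0))
  expect_equal(s0$predicted_radius, 0)
  expect_equal(Mod(s0$predicted_outliers), c(0, 0))
  # empirical eigenvalues of one realization
  W <- build_fixed_indegree(ref_params(J = 1, g = 5, C = 100, N = 1500), seed = 1)
  ev <- empirical_eigenvalues(W)
  r_emp <- bulk_radius(ev, outliers = -20)
  expect_lt(abs(r_emp / sqrt(580) - 1), 0.05)
  # the outlier is pinned by the exact row sums
  expect_lt(min(Mod(ev - (-20))), 0.5)
})

test_that("block spectrum prediction matches an eigendecomposition", {
  b <- block_params(j_E = 0.1, j_I = 0.15, g_E = 4.5, g_I = 4.2,
                    C_E = 80, C_I = 20, N_E = 1200, N_I = 300, J = 0.4)
  s <- spectrum_summary(b, gains = c(1, 1))
  W <- build_block(b, seed = 9)
  ev <- empirical_eigenvalues(W, gains = c(1, 1))
  r_emp <- bulk_radius(ev, outliers = s$predicted_outliers, outlier_tol = 0.3)
  expect_lt(abs(r_emp / s$predicted_radius - 1), 0.05)
  # outliers within absolute 0.5
  for (o in s$predicted_outliers) expect_lt(min(Mod(ev - o)), 0.5)
})

test_that("coordinate-text export writes entries and a JSON sidecar", {
  p <- ref_params(N = 200)
  W <- build_fixed_indegree(p, seed = 1)
  f <- tempfile(fileext = ".coo")
  write_connectivity(W, f)
  lines <- readLines(f)
  expect_equal(length(lines) - 1L, length(W$weights@x))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$scheme, "fixed_in_degree")
  expect_equal(meta$seed, 1L)
  first <- as.numeric(strsplit(lines[2], " ")[[1]])
  expect_true(first[1] >= 0 && first[2] >= 0)  # 0-based indices
})
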