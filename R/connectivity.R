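#' Random connectivity ensembles
#'
#' Builders for the sparse synaptic matrices studied by the mean-field
#' theory.  All builders return a `"connectivity_matrix"` object: a list with
#' a sparse `weights` matrix (class [Matrix::dgCMatrix-class]), the
#' generation `scheme`, the per-column `population` labels (`"E"` or `"I"`),
#' the `seed` and the generating parameters.  Columns carry the population
#' identity: excitatory columns contain only non-negative entries, inhibitory
#' columns only non-positive ones (Dale's law).  By default the first
#' `f * N` columns are excitatory; `shuffle = TRUE` interleaves the labels
#' at random.  Self-connections are not excluded: the ensemble places each
#' row's `C` connections uniformly over all columns, so autapses occur with
#' probability of order `C / N`.
#'
#' @name connectivity
#' @keywords internal
NULL

new_connectivity <- function(weights, scheme, population, seed, params) {
  structure(list(weights = weights, scheme = scheme,
                 population = population, seed = seed, params = params),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("connectivity_matrix: %d x %d, scheme = %s, nnz = %d, seed = %d\n",
              d[1], d[2], x$scheme, length(x$weights@x), x$seed))
  invisible(x)
}

# sample exactly k column indices per row from cols, uniformly without
# replacement, row by row (deterministic order given the seed)
sample_rows <- function(n_rows, cols, k) {
  idx <- matrix(0L, nrow = k, ncol = n_rows)
  for (r in seq_len(n_rows)) idx[, r] <- cols[sample.int(length(cols), k)]
  idx
}

#' Fixed in-degree EI connectivity
#'
#' Every row receives exactly `C_E = f * C` excitatory entries of value `J`
#' and `C_I = (1 - f) * C` inhibitory entries of value `-g * J`, with the
#' positions drawn uniformly without replacement within each population.
#' Every row sum therefore equals `J * (C_E - g * C_I)` exactly.
#'
#' @param params a [network_params()] object; `f * C` must be integral.
#' @param seed integer RNG seed (the build is deterministic given the seed).
#' @param shuffle interleave E/I column labels at random instead of using the
#'   first `f * N` columns as excitatory.
#' @return A `connectivity_matrix` (see [connectivity]).
#' @examples
#' W <- build_fixed_indegree(network_params(0.2, 5, 100, N = 500), seed = 1)
#' range(Matrix::rowSums(W$weights))  # exactly J * (C_E - g * C_I)
#' @export
build_fixed_indegree <- function(params, seed, shuffle = FALSE) {
  stopifnot(inherits(params, "network_params"))
  check_integral_degrees(params)
  N <- params$N
  pop <- make_population(N, params$f, shuffle, seed)
  e_cols <- which(pop == "E"); i_cols <- which(pop == "I")
  C_E <- as.integer(round(params$C_E)); C_I <- as.integer(round(params$C_I))
  set.seed(seed)
  je <- if (C_E > 0) sample_rows(N, e_cols, C_E) else matrix(0L, 0, N)
  ji <- if (C_I > 0) sample_rows(N, i_cols, C_I) else matrix(0L, 0, N)
  i_all <- c(rep(seq_len(N), each = C_E), rep(seq_len(N), each = C_I))
  j_all <- c(as.integer(je), as.integer(ji))
  x_all <- c(rep(params$J, N * C_E), rep(-params$g * params$J, N * C_I))
  W <- Matrix::sparseMatrix(i = i_all, j = j_all, x = x_all, dims = c(N, N))
  new_connectivity(W, "fixed_in_degree", pop, seed, params)
}

check_integral_degrees <- function(params) {
  if (abs(params$C_E - round(params$C_E)) > 1e-9)
    stop("f * C must be an integer for fixed in-degree ensembles")
}

make_population <- function(N, f, shuffle, seed) {
  n_E <- round(f * N)
  pop <- rep(c("E", "I"), c(n_E, N - n_E))
  if (shuffle) {
    set.seed(seed + 1L)
    pop <- sample(pop)
  }
  pop
}

#' Stochastic (binomial) in-degree EI connectivity
#'
#' Each entry of an excitatory column independently equals `J` with
#' probability `C / N` (inhibitory column: `-g * J`), so row in-degrees are
#' Binomial with mean `C` and variance `C * (1 - C/N)`.  This is the
#' heterogeneous ensemble whose quenched in-degree disorder produces a
#' non-zero asymptotic variance in the mean-field solution.
#'
#' @inheritParams build_fixed_indegree
#' @return A `connectivity_matrix`.
#' @export
build_stochastic_indegree <- function(params, seed, shuffle = FALSE) {
  stopifnot(inherits(params, "network_params"))
  N <- params$N
  p <- params$C / N
  if (p > 1) stop("in-degree 'C' cannot exceed network size 'N'")
  pop <- make_population(N, params$f, shuffle, seed)
  set.seed(seed)
  # column-wise Bernoulli draws: per-entry probability C/N in both
  # populations, so mean row in-degrees are C_E = f*C and C_I = (1-f)*C
  # because the column counts are f*N and (1-f)*N
  rows <- vector("list", N)
  for (j in seq_len(N)) rows[[j]] <- which(stats::runif(N) < p)
  nnz_col <- lengths(rows)
  j_all <- rep.int(seq_len(N), nnz_col)
  i_all <- unlist(rows, use.names = FALSE)
  x <- ifelse(pop[j_all] == "E", params$J, -params$g * params$J)
  W <- Matrix::sparseMatrix(i = i_all, j = j_all, x = x, dims = c(N, N))
  new_connectivity(W, "stochastic_in_degree", pop, seed, params)
}

#' Block two-population connectivity
#'
#' The general ensemble in which excitatory and inhibitory neurons receive
#' statistically different inputs: each row of an E neuron holds `C_E`
#' entries `J * j_E` in the E columns and `C_I` entries `-J * g_E * j_E` in
#' the I columns; rows of I neurons use `j_I` and `g_I`.  With
#' `j_E = j_I = 1` and `g_E = g_I` the distribution is identical to
#' [build_fixed_indegree()].
#'
#' @param block a [block_params()] object.
#' @param seed integer RNG seed.
#' @return A `connectivity_matrix` with `N_E + N_I` rows; the first `N_E`
#'   rows/columns are the excitatory population.
#' @export
build_block <- function(block, seed) {
  stopifnot(inherits(block, "block_params"))
  N <- block$N_E + block$N_I
  pop <- rep(c("E", "I"), c(block$N_E, block$N_I))
  e_cols <- seq_len(block$N_E); i_cols <- block$N_E + seq_len(block$N_I)
  set.seed(seed)
  je <- if (block$C_E > 0) sample_rows(N, e_cols, block$C_E) else matrix(0L, 0, N)
  ji <- if (block$C_I > 0) sample_rows(N, i_cols, block$C_I) else matrix(0L, 0, N)
  row_j <- ifelse(pop == "E", block$j_E, block$j_I)
  row_g <- ifelse(pop == "E", block$g_E, block$g_I)
  i_all <- c(rep(seq_len(N), each = block$C_E), rep(seq_len(N), each = block$C_I))
  x_exc <- rep(block$J * row_j, each = block$C_E)
  x_inh <- rep(-block$J * row_g * row_j, each = block$C_I)
  W <- Matrix::sparseMatrix(i = i_all, j = c(as.integer(je), as.integer(ji)),
                            x = c(x_exc, x_inh), dims = c(N, N))
  new_connectivity(W, "block", pop, seed, block)
}

#' Gaussian-equivalent dense connectivity
#'
#' A dense i.i.d. Gaussian matrix whose entry mean `J (C_E - g C_I) / N` and
#' variance `J^2 (C_E + g^2 C_I) / N` match the sparse EI ensemble.  Used to
#' probe which deviations from the mean-field theory stem from the
#' non-Gaussian (sparse, sign-constrained) entry distribution rather than
#' from the matched first two moments.
#'
#' @inheritParams build_fixed_indegree
#' @return A `connectivity_matrix` whose `weights` are dense (stored sparse
#'   for interface uniformity).  Population labels are not meaningful for
#'   this ensemble and are set to `"E"`.
#' @export
build_gaussian_equivalent <- function(params, seed) {
  stopifnot(inherits(params, "network_params"))
  N <- params$N
  m <- coupling_mean(params) / N
  s <- sqrt(coupling_var(params) / N)
  set.seed(seed)
  W <- Matrix::Matrix(matrix(stats::rnorm(N * N, mean = m, sd = s), N, N),
                      sparse = TRUE)
  new_connectivity(methods::as(W, "CsparseMatrix"), "gaussian_equivalent",
                   rep("E", N), seed, params)
}

#' Predicted spectrum of the linearised block ensemble
#'
#' Predicts the stability-relevant spectrum of the gain-scaled connectivity
#' `S_ij = phi'(x0) * J_ij`: the radius of the densely filled disk is the
#' square root of the leading eigenvalue of the 2x2 block variance matrix,
#' and the (up to two) outlier eigenvalues are the eigenvalues of the 2x2
#' block mean matrix.  For the single-statistics ensemble these reduce to
#' `r = phi'(x0) J sqrt(C_E + g^2 C_I)` and a single outlier
#' `phi'(x0) J (C_E - g C_I)` (the second eigenvalue of the rank-one mean
#' matrix is 0 and is not an outlier).
#'
#' @param block a [block_params()] object (use [as_block_params()] for
#'   single-statistics parameters).
#' @param gains length-2 vector `c(phi'_E, phi'_I)` of the transfer gains at
#'   the fixed point of each population; must be non-negative.
#' @return A list of class `"spectrum_summary"` with `predicted_radius` and
#'   `predicted_outliers` (complex, length 2).
#' @export
spectrum_summary <- function(block, gains) {
  stopifnot(inherits(block, "block_params"), length(gains) == 2L)
  if (any(gains < 0)) stop("'gains' must be non-negative")
  gE <- gains[1]; gI <- gains[2]
  J <- block$J
  Sigma <- J^2 * rbind(
    c(gE^2 * block$C_E * block$j_E^2, gI^2 * block$C_I * block$g_E^2 * block$j_E^2),
    c(gE^2 * block$C_E * block$j_I^2, gI^2 * block$C_I * block$g_I^2 * block$j_I^2))
  M <- J * rbind(
    c(gE * block$C_E * block$j_E, -gI * block$C_I * block$g_E * block$j_E),
    c(gE * block$C_E * block$j_I, -gI * block$C_I * block$g_I * block$j_I))
  ev_S <- eigen(Sigma, only.values = TRUE)$values
  r <- sqrt(max(0, max(Re(ev_S))))
  outliers <- eigen(M, only.values = TRUE)$values
  structure(list(predicted_radius = r,
                 predicted_outliers = as.complex(outliers)),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("predicted bulk radius: %g\n", x$predicted_radius))
  cat("predicted outliers:", format(x$predicted_outliers), "\n")
  invisible(x)
}

#' Empirical eigenvalues of a realised connectivity matrix
#'
#' Dense eigendecomposition of (optionally gain-scaled) weights; intended
#' for moderate sizes (N up to a few thousand).
#'
#' @param conn a `connectivity_matrix`.
#' @param gains optional length-2 vector of population gains used to scale
#'   rows (E rows by `gains[1]`, I rows by `gains[2]`).
#' @return Complex vector of eigenvalues.
#' @export
empirical_eigenvalues <- function(conn, gains = NULL) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  W <- as.matrix(conn$weights)
  if (!is.null(gains)) {
    scale_row <- ifelse(conn$population == "E", gains[1], gains[2])
    W <- W * scale_row
  }
  eigen(W, only.values = TRUE)$values
}

#' Empirical bulk spectral radius
#'
#' Largest eigenvalue modulus after removing eigenvalues that fall within
#' `outlier_tol` of the predicted outlier locations (the isolated
#' eigenvalues carried by the non-zero mean of the ensemble).
#'
#' @param eigenvalues complex eigenvalues (from [empirical_eigenvalues()]).
#' @param outliers predicted outlier positions to exclude (complex).
#' @param outlier_tol absolute exclusion distance.
#' @return The bulk radius (a scalar).
#' @export
bulk_radius <- function(eigenvalues, outliers = NULL, outlier_tol = 1) {
  ev <- eigenvalues
  if (!is.null(outliers) && length(outliers)) {
    for (o in outliers) {
      if (!length(ev)) break
      d <- Mod(ev - o)
      if (min(d) < outlier_tol) ev <- ev[-which.min(d)]
    }
  }
  max(Mod(ev))
}

#' Export a connectivity matrix as coordinate text plus JSON sidecar
#'
#' Writes the non-zero entries as whitespace-separated `row col value`
#' triplets with 0-based indices (one header comment line carrying the
#' dimensions), and a `<file>.json` sidecar with the scheme, seed and
#' generating parameters.
#'
#' @param conn a `connectivity_matrix`.
#' @param file output path for the coordinate text.
#' @return `file`, invisibly.
#' @export
write_connectivity <- function(conn, file) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  W <- methods::as(conn$weights, "TsparseMatrix")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%% coordinate real general %d %d %d",
                     nrow(W), ncol(W), length(W@x)), con)
  writeLines(sprintf("%d %d %.17g", W@i, W@j, W@x), con)
  sidecar <- paste0(file, ".json")
  params <- conn$params
  class(params) <- NULL
  jsonlite::write_json(list(scheme = conn$scheme, seed = conn$seed,
                            dims = dim(conn$weights), params = params),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Wrap an arbitrary weight matrix as a connectivity object
#'
#' Mainly useful for small hand-built circuits (single- or two-neuron
#' oracles) and for feeding externally generated matrices to the
#' simulators.
#'
#' @param weights a square matrix (dense or sparse).
#' @param population optional per-column `"E"`/`"I"` labels; inferred from
#'   column signs when omitted (columns with any negative entry are `"I"`).
#' @param seed seed recorded in the object (not used for generation).
#' @return A `connectivity_matrix` with scheme `"custom"`.
#' @export
as_connectivity <- function(weights, population = NULL, seed = 0L) {
  W <- methods::as(Matrix::Matrix(weights, sparse = TRUE), "CsparseMatrix")
  if (nrow(W) != ncol(W)) stop("'weights' must be square")
  if (is.null(population)) {
    neg <- Matrix::colSums(W < 0) > 0
    population <- ifelse(neg, "I", "E")
  }
  new_connectivity(W, "custom", population, as.integer(seed), NULL)
}
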