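# Shared fixture builders; everything is generated in code.

# A tiny gl_matrix from an explicit list of likelihood triples.
# triples: list over individuals, each a list over sites of length-3 vectors.
gl_from_triples <- function(triples, ids = NULL) {
  n <- length(triples)
  m <- length(triples[[1]])
  lik <- array(0, dim = c(n, m, 3))
  for (i in seq_len(n)) for (j in seq_len(m))
    lik[i, j, ] <- triples[[i]][[j]]
  if (is.null(ids)) ids <- paste0("chr1_", 100 * seq_len(m))
  gl_matrix(lik, parse_marker_ids(ids, rep("0", m), rep("1", m)))
}

# Random valid likelihood array (not normalized) for round-trip tests.
random_gl <- function(n, m, seed = 1) {
  set.seed(seed)
  lik <- array(runif(n * m * 3, 0.01, 1), dim = c(n, m, 3))
  gl_matrix(lik, parse_marker_ids(paste0("chr", sample(1:3, m, TRUE), "_",
                                         sample(1e6, m)),
                                  rep("A", m), rep("C", m)))
}

# Exact per-site HWE log-likelihood, used as the grid-search oracle for
# the EM allele-frequency estimate (independent of the EM code path).
loglik_at_f <- function(gl, j, f) {
  l <- gl$likelihoods
  sum(log(l[, j, 1] * (1 - f)^2 + l[, j, 2] * 2 * f * (1 - f) +
            l[, j, 3] * f^2))
}

grid_search_af <- function(gl, j, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(f) loglik_at_f(gl, j, f), 0)
  grid[which.max(ll)]
}

# Small simulated dataset for structural tests.
small_dataset <- function(seed = 1, ...) {
  args <- list(n_individuals = 60, n_sites = 800, fst = 0.05,
               depth_mean = 6, error_rate = 0.01, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  make_dataset(do.call(sim_config, args))
}
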