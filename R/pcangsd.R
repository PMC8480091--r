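#' Posterior genotype probabilities for one observation
#'
#' Bayes rule combining a genotype-likelihood triple with a
#' Binomial(2, pi) prior given the individual allele frequency:
#' \deqn{P(G = g | X, \pi) \propto P(X | G = g)\,\mathrm{Binom}(g; 2, \pi).}
#' An uninformative (equal) triple returns the prior; a certain triple
#' returns itself.
#'
#' @param gl_triple numeric length-3 vector of likelihoods for genotypes
#'   0, 1, 2 (any positive scale).
#' @param pi individual allele frequency in (0, 1).
#' @return length-3 vector of posterior probabilities summing to 1.
#' @export
genotype_posteriors <- function(gl_triple, pi) {
  stopifnot(length(gl_triple) == 3L, all(gl_triple >= 0),
            pi > 0, pi < 1)
  if (sum(gl_triple) <= 0)
    stop("invalid likelihood triple: all three genotype likelihoods are zero")
  prior <- c((1 - pi)^2, 2 * pi * (1 - pi), pi^2)
  w <- gl_triple * prior
  w / sum(w)
}

#' Posterior genotype dosages
#'
#' Expected minor-allele count \eqn{E[G_{ij} | X_{ij}, \hat\pi_{ij}] =
#' \sum_g g\, P(G_{ij} = g | X_{ij}, \hat\pi_{ij})} for every individual
#' and site. Missing observations (equal triples) yield exactly
#' \eqn{2\hat\pi_{ij}}: missing data are imputed from the population
#' structure captured by the individual allele frequencies.
#'
#' @param gl a [gl_matrix()].
#' @param pi N x M matrix of individual allele frequencies in (0, 1).
#' @return N x M matrix of dosages in \[0, 2\].
#' @export
posterior_dosage <- function(gl, pi) {
  pi <- as.matrix(pi)
  stopifnot(nrow(pi) == n_ind(gl), ncol(pi) == n_sites(gl))
  w0 <- gl_slice(gl, 1) * (1 - pi)^2
  w1 <- gl_slice(gl, 2) * 2 * pi * (1 - pi)
  w2 <- gl_slice(gl, 3) * pi^2
  (w1 + 2 * w2) / (w0 + w1 + w2)
}

#' Standardize posterior dosages under the Binomial model
#'
#' \deqn{y_{ij} = \frac{E[G_{ij} | X_{ij}, \hat\pi_{ij}] - 2\hat f_j}
#'   {\sqrt{2 \hat f_j (1 - \hat f_j)}}}
#' centering and scaling by the population allele frequency, so that under
#' Hardy-Weinberg and no structure every column has mean 0 and variance 1
#' in expectation.
#'
#' @param dosage N x M dosage matrix.
#' @param f length-M population allele frequencies strictly inside (0, 1).
#' @return N x M standardized matrix.
#' @export
standardize_dosage <- function(dosage, f) {
  stopifnot(length(f) == ncol(dosage))
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop("standardization requires allele frequencies strictly in (0, 1); ",
         "run site_filter() first")
  sweep(sweep(dosage, 2, 2 * f, "-"), 2, sqrt(2 * f * (1 - f)), "/")
}

#' Truncated singular value decomposition
#'
#' Top-K singular triplets of the standardized dosage matrix; U holds the
#' individual coordinates (population structure), V the variant weights,
#' S the singular values. For N <= M the decomposition is obtained from
#' the eigendecomposition of the N x N Gram matrix, which is exact and
#' fast at scan dimensions. A deterministic sign convention is applied:
#' each component is flipped so that the entry of U with the largest
#' absolute value is positive (ties broken by lowest index).
#'
#' @param y N x M numeric matrix.
#' @param K number of components, 1 <= K < min(N - 1, M).
#' @return list of class `"svd_factors"` with `U` (N x K), `d` (length K,
#'   descending), `V` (M x K), `K`.
#' @export
truncated_svd <- function(y, K) {
  y <- as.matrix(y)
  n <- nrow(y); m <- ncol(y)
  if (K < 1 || K >= min(n - 1, m))
    stop("K must satisfy 1 <= K < min(N - 1, M); got K = ", K)
  if (n <= m) {
    e <- eigen(tcrossprod(y), symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(K)], 0))
    U <- e$vectors[, seq_len(K), drop = FALSE]
    V <- crossprod(y, U) %*% diag(1 / d, K)
  } else {
    s <- svd(y, nu = K, nv = K)
    d <- s$d[seq_len(K)]
    U <- s$u
    V <- s$v
  }
  for (k in seq_len(K)) {
    piv <- which.max(abs(U[, k]))
    if (U[piv, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  structure(list(U = U, d = d, V = V, K = K), class = "svd_factors")
}

#' Update individual allele frequencies from the factorization
#'
#' Inverts the standardization on the rank-K reconstruction
#' \eqn{\hat Y = U S V^T}:
#' \deqn{\hat\pi_{ij} = \mathrm{clip}\left(
#'   \frac{\hat Y_{ij} \sqrt{2 \hat f_j (1 - \hat f_j)} + 2 \hat f_j}{2},
#'   \epsilon, 1 - \epsilon\right)}
#' so the Binomial priors stay non-degenerate. Zero reconstruction (no
#' structure) returns the population frequency.
#'
#' @param factors an `svd_factors` object.
#' @param f length-M population allele frequencies.
#' @param clip_lo clipping bound (default 1e-4).
#' @return N x M matrix of individual allele frequencies.
#' @export
update_ind_afs <- function(factors, f, clip_lo = 1e-4) {
  yhat <- factors$U %*% (factors$d * t(factors$V))
  pi <- sweep(sweep(yhat, 2, sqrt(2 * f * (1 - f)), "*"), 2, 2 * f, "+") / 2
  pmin(pmax(pi, clip_lo), 1 - clip_lo)
}

#' Fit individual allele frequencies by iterated dosage/SVD updates
#'
#' The iterative estimation loop: starting from \eqn{\hat\pi_{ij} =
#' \hat f_j}, alternate posterior dosage computation, Binomial
#' standardization, truncated SVD and allele-frequency update until the
#' root-mean-square change of \eqn{\hat\pi} falls below `tol`, then run
#' one final dosage/standardize/SVD pass with the converged frequencies.
#' The returned factors feed both selection statistics.
#'
#' @param gl a [gl_matrix()] restricted to filtered (variable) sites.
#' @param f length-M allele frequencies for those sites.
#' @param K number of principal components.
#' @param tol convergence threshold on RMS change of pi (default 1e-5).
#' @param max_iter iteration cap (default 100).
#' @param clip_lo clipping bound for pi (default 1e-4).
#' @return list of class `"pcsel_fit"`: `factors` (svd_factors), `pi`,
#'   `y` (standardized dosages), `f`, `n_iter`, `converged`,
#'   `rmse_trace`.
#' @export
fit_individual_afs <- function(gl, f, K, tol = 1e-5, max_iter = 100,
                               clip_lo = 1e-4) {
  n <- n_ind(gl); m <- n_sites(gl)
  stopifnot(length(f) == m)
  if (K >= n - 1) stop("K must be smaller than N - 1")
  pi <- matrix(rep(f, each = n), nrow = n)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    e <- posterior_dosage(gl, pi)
    y <- standardize_dosage(e, f)
    fac <- truncated_svd(y, K)
    pi_new <- update_ind_afs(fac, f, clip_lo)
    rmse <- sqrt(mean((pi_new - pi)^2))
    trace <- c(trace, rmse)
    pi <- pi_new
    if (rmse < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("individual allele-frequency iteration did not converge in ",
            max_iter, " iterations (last RMS change ",
            signif(trace[length(trace)], 3), ")")
  e <- posterior_dosage(gl, pi)
  y <- standardize_dosage(e, f)
  fac <- truncated_svd(y, K)
  structure(list(factors = fac, pi = pi, y = y, f = f,
                 n_iter = it, converged = converged, rmse_trace = trace),
            class = "pcsel_fit")
}

#' @export
print.pcsel_fit <- function(x, ...) {
  cat(sprintf("pcsel_fit: %d individuals x %d sites, K = %d\n",
              nrow(x$pi), ncol(x$pi), x$factors$K))
  cat(sprintf("  %d iterations, converged: %s\n", x$n_iter, x$converged))
  invisible(x)
}
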