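#' Estimate per-site allele frequencies from genotype likelihoods by EM
#'
#' Maximizes, for every site j, the Hardy-Weinberg likelihood
#' \deqn{\ell_j(f) = \sum_i \log \sum_g P(X_{ij} | G = g)\,
#'   \mathrm{Binom}(g; 2, f)}
#' over the minor-allele frequency f by expectation-maximization: the
#' E-step computes the posterior expected dosage of every individual under
#' a Binomial(2, f) prior, the M-step sets f to the mean dosage divided
#' by two. With certain (hard-genotype) likelihoods this reduces exactly
#' to the sample allele proportion.
#'
#' Sites where every individual is missing carry no information; their
#' frequency is returned as NA and they are excluded downstream.
#'
#' @param gl a [gl_matrix()].
#' @param tol convergence threshold on the per-site frequency change.
#' @param max_iter iteration cap.
#' @param f_init initial frequency for every site.
#' @return numeric vector of length M of minor-allele frequency estimates
#'   in \[0, 1\], NA for all-missing sites.
#' @export
estimate_af_em <- function(gl, tol = 1e-6, max_iter = 200, f_init = 0.25) {
  n <- n_ind(gl)
  if (n < 2L) stop("allele-frequency estimation requires at least 2 individuals")
  stopifnot(tol > 0)
  l0 <- gl_slice(gl, 1)
  l1 <- gl_slice(gl, 2)
  l2 <- gl_slice(gl, 3)
  m <- n_sites(gl)
  f <- rep(f_init, m)
  active <- rep(TRUE, m)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    fa <- f[active]
    p0 <- rep((1 - fa)^2, each = n)
    p1 <- rep(2 * fa * (1 - fa), each = n)
    p2 <- rep(fa^2, each = n)
    w0 <- l0[, active, drop = FALSE] * p0
    w1 <- l1[, active, drop = FALSE] * p1
    w2 <- l2[, active, drop = FALSE] * p2
    eg <- (w1 + 2 * w2) / (w0 + w1 + w2)
    fn <- colMeans(eg) / 2
    done <- abs(fn - fa) < tol
    f[active] <- fn
    active[active] <- !done
  }
  all_missing <- colSums(!gl_is_missing(gl)) == 0L
  f[all_missing] <- NA_real_
  f
}

# Per-site HWE log-likelihood at frequency f (recycled along sites).
site_loglik <- function(gl, f) {
  l0 <- gl_slice(gl, 1)
  l1 <- gl_slice(gl, 2)
  l2 <- gl_slice(gl, 3)
  n <- n_ind(gl)
  fr <- rep(f, length.out = n_sites(gl))
  p0 <- rep((1 - fr)^2, each = n)
  p1 <- rep(2 * fr * (1 - fr), each = n)
  p2 <- rep(fr^2, each = n)
  # normalize each triple by its max so logs stay bounded; the scale
  # cancels in all likelihood-ratio differences
  sc <- pmax(l0, l1, l2)
  colSums(log((l0 * p0 + l1 * p1 + l2 * p2) / sc))
}

#' Likelihood-ratio test for a site being variable
#'
#' Compares the maximized Hardy-Weinberg likelihood at the estimated
#' frequency against the better of the two monomorphic models (f = 0 and
#' f = 1): \eqn{LRT_j = 2[\ell_j(\hat f_j) - \max(\ell_j(0), \ell_j(1))]},
#' clamped at zero, with an upper-tail chi-square (1 df) p-value. Mirrors
#' the SNP-calling test applied to low-coverage data before scanning.
#'
#' @param gl a [gl_matrix()].
#' @param f allele-frequency vector from [estimate_af_em()].
#' @return data.frame with columns `lrt` and `pval` (length M); NA
#'   frequencies give lrt = 0, pval = 1.
#' @export
snp_lrt <- function(gl, f) {
  stopifnot(length(f) == n_sites(gl))
  f_safe <- ifelse(is.na(f), 0, f)
  ll_hat <- site_loglik(gl, f_safe)
  ll_0 <- site_loglik(gl, 0)
  ll_1 <- site_loglik(gl, 1)
  lrt <- pmax(0, 2 * (ll_hat - pmax(ll_0, ll_1)))
  lrt[is.na(f)] <- 0
  data.frame(lrt = lrt,
             pval = stats::pchisq(lrt, df = 1, lower.tail = FALSE))
}

#' Minor-allele-frequency and SNP filtering of sites
#'
#' Retains site j iff `maf_min < f_j < 1 - maf_min` (strict on both
#' sides, so f exactly at the threshold is excluded) and, when LRT
#' p-values are supplied, `lrt_p_j < snp_p`. Excluded sites carry a
#' reason code: `monomorphic` (NA frequency), `below-maf`, or
#' `failed-lrt`.
#'
#' @param f allele-frequency vector.
#' @param lrt_p optional vector of SNP-test p-values; NULL in genotype /
#'   known-sites mode.
#' @param maf_min minor-allele-frequency threshold (default 0.05).
#' @param snp_p SNP-test p-value threshold (default 1e-6).
#' @return list with logical `keep` (length M) and character `reasons`
#'   (NA for retained sites).
#' @export
site_filter <- function(f, lrt_p = NULL, maf_min = 0.05, snp_p = 1e-6) {
  stopifnot(maf_min > 0, maf_min < 1, snp_p > 0, snp_p < 1)
  m <- length(f)
  reasons <- rep(NA_character_, m)
  reasons[is.na(f)] <- "monomorphic"
  low <- !is.na(f) & !(f > maf_min & f < 1 - maf_min)
  reasons[low] <- "below-maf"
  if (!is.null(lrt_p)) {
    stopifnot(length(lrt_p) == m)
    fail <- is.na(reasons) & !(lrt_p < snp_p)
    reasons[fail] <- "failed-lrt"
  }
  keep <- is.na(reasons)
  if (!any(keep))
    stop("no sites retained after allele-frequency and SNP filtering")
  list(keep = keep, reasons = reasons)
}
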