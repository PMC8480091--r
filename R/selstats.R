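# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Per-component variant-weight selection statistic
#'
#' Normalizes the variant weights of each principal component so they are
#' standard normal under neutral drift: \eqn{d_{jk} = v_{jk} \sqrt{M}},
#' with \eqn{d_{jk}^2 \sim \chi^2_1}. Because each column of V has unit
#' norm, \eqn{\sum_j d_{jk}^2 = M} exactly for every component. Reported
#' without genomic control.
#'
#' @param factors an `svd_factors` object from [truncated_svd()].
#' @return list of class `"s1_result"` with M x K matrices `d`, `chi2`,
#'   `pvals`.
#' @export
s1_statistic <- function(factors) {
  m <- nrow(factors$V)
  d <- factors$V * sqrt(m)
  chi2 <- d^2
  pvals <- chisq_pvalues(chi2, df = 1)
  structure(list(d = d, chi2 = chi2, pvals = pvals), class = "s1_result")
}

#' Regression z-scores of sites on the principal components
#'
#' For every site, the standardized dosage column is modeled as
#' \eqn{y_j = U \beta_j + \epsilon_j}. Because U has orthonormal columns
#' the least-squares coefficients come directly from the factorization,
#' \eqn{\beta_j = S V_{j,}}, with no refit. The z-score divides by the
#' residual standard error \eqn{\sqrt{(y_j - \hat y_j)^T (y_j - \hat y_j)
#' / (N - K)}}, shared by all K coefficients of the site.
#'
#' Sites whose residual is exactly zero (the column lies in the span of U)
#' have undefined z-scores; their rows are returned as NA and recorded in
#' the `"degenerate"` attribute so the scan can flag them instead of
#' crashing.
#'
#' @param y N x M standardized dosage matrix.
#' @param factors matching `svd_factors`.
#' @return M x K matrix of z-scores with logical attribute `"degenerate"`.
#' @export
s2_zscores <- function(y, factors) {
  n <- nrow(y); m <- ncol(y); K <- factors$K
  if (n <= K) stop("z-scores require N > K")
  beta <- sweep(factors$V, 2, factors$d, "*")      # M x K, beta_j = S V_j
  yhat <- factors$U %*% (factors$d * t(factors$V))
  rss <- colSums((y - yhat)^2)
  se <- sqrt(rss / (n - K))
  degen <- se <= 0 | !is.finite(se)
  z <- beta / se
  z[degen, ] <- NA_real_
  attr(z, "degenerate") <- degen
  z
}

#' Squared robust Mahalanobis distances of z-score rows
#'
#' Location and scatter are estimated by the reweighted minimum-
#' covariance-determinant estimator: a raw MCD fit (support fraction
#' 0.75, fixed internal seed for reproducibility) followed by one
#' reweighting step that refits mean and covariance on the rows whose
#' raw distance falls below the 97.5% chi-square quantile and rescales
#' by the normal-consistency factor of that truncation. Each row's
#' squared Mahalanobis distance to the robust center is returned; under
#' neutrality the distances are approximately chi-square with K degrees
#' of freedom. If the robust scatter estimate is singular or fails, the
#' classical mean/covariance is used with a warning; a singular
#' classical covariance is a fatal error. Rows with NA (degenerate
#' sites) are excluded from estimation and returned as NA.
#'
#' @param z M x K matrix of z-scores.
#' @param robust use the MCD estimator (default TRUE); FALSE gives the
#'   classical mean/covariance distance.
#' @param support_fraction fraction of rows the MCD fits (default 0.75).
#' @param seed RNG seed for the MCD subsampling.
#' @return length-M vector of squared distances.
#' @export
robust_mahalanobis <- function(z, robust = TRUE, support_fraction = 0.75,
                               seed = 42L) {
  z <- as.matrix(z)
  m <- nrow(z); K <- ncol(z)
  ok <- stats::complete.cases(z)
  if (robust && sum(ok) <= 5 * K)
    stop("too few sites (", sum(ok), ") to estimate a robust scatter for K = ",
         K)
  est <- NULL
  if (robust) {
    est <- tryCatch(
      with_local_seed(seed, {
        raw <- MASS::cov.rob(z[ok, , drop = FALSE], method = "mcd",
                             quantile.used = floor(support_fraction *
                                                     sum(ok)))
        # reweighting step: refit on rows inside the 97.5% quantile of
        # the raw distances, with the normal-consistency rescaling of
        # the truncated covariance
        d_raw <- stats::mahalanobis(z[ok, , drop = FALSE], raw$center,
                                    raw$cov)
        w <- d_raw <= stats::qchisq(0.975, K)
        cdelta <- 0.975 / stats::pchisq(stats::qchisq(0.975, K), K + 2)
        zw <- z[ok, , drop = FALSE][w, , drop = FALSE]
        list(center = colMeans(zw), cov = stats::cov(zw) * cdelta)
      }),
      error = function(e) NULL)
    if (!is.null(est) && !is.finite(determinant(as.matrix(est$cov))$modulus))
      est <- NULL
    if (is.null(est))
      warning("robust scatter estimation failed or was singular; ",
              "falling back to classical mean/covariance")
  }
  if (is.null(est)) {
    est <- list(center = colMeans(z[ok, , drop = FALSE]),
                cov = stats::cov(z[ok, , drop = FALSE]))
    if (!is.finite(determinant(as.matrix(est$cov))$modulus))
      stop("collinear z-scores: classical covariance is singular")
  }
  d2 <- rep(NA_real_, m)
  d2[ok] <- stats::mahalanobis(z[ok, , drop = FALSE], est$center, est$cov)
  d2
}

#' Genomic inflation factor and corrected statistics
#'
#' \eqn{\lambda} is the median of the observed chi-square statistics
#' divided by the median of the null chi-square distribution with `df`
#' degrees of freedom; the corrected statistics divide by \eqn{\lambda},
#' forcing their median onto the null median.
#'
#' @param stats non-negative chi-square statistics (NAs ignored for the
#'   median).
#' @param df degrees of freedom of the intended null.
#' @return list with `lambda` and `corrected`.
#' @export
genomic_inflation <- function(stats, df) {
  stopifnot(df >= 1, length(stats) >= 1)
  med <- stats::median(stats, na.rm = TRUE)
  if (!is.finite(med) || med <= 0)
    stop("degenerate statistics: median is not positive")
  lambda <- med / stats::qchisq(0.5, df = df)
  list(lambda = lambda, corrected = stats / lambda)
}

# Upper-tail chi-square p-values, log-safe; underflow maps to the
# smallest positive representable double, never 0.
chisq_pvalues <- function(stats, df) {
  p <- stats::pchisq(stats, df = df, lower.tail = FALSE)
  p[!is.na(p) & p <= 0] <- .Machine$double.xmin
  if (is.matrix(stats) && !is.matrix(p)) p <- matrix(p, nrow = nrow(stats))
  p
}

#' P-values and Bonferroni significance calls
#'
#' Upper-tail chi-square p-values with a family-wise Bonferroni threshold
#' `alpha / M_tests` over the retained (tested) sites; a site is
#' significant iff its p-value is strictly below the threshold.
#'
#' @param stats chi-square statistics (vector or matrix).
#' @param df degrees of freedom.
#' @param alpha family-wise error target (default 0.05).
#' @param M_tests number of tests; defaults to the number of statistics.
#' @return list with `pvals`, `threshold`, `significant`.
#' @export
pvalues_and_bonferroni <- function(stats, df, alpha = 0.05,
                                   M_tests = length(stats)) {
  stopifnot(alpha > 0, alpha < 1, M_tests >= 1)
  p <- chisq_pvalues(stats, df)
  thr <- alpha / M_tests
  list(pvals = p, threshold = thr, significant = !is.na(p) & p < thr)
}
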