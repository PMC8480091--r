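#' Run a full PCA-based selection scan on genotype likelihoods
#'
#' End-to-end pipeline: EM allele-frequency estimation, SNP
#' likelihood-ratio testing (skipped in genotype / known-sites mode),
#' minor-allele-frequency filtering, iterative individual-allele-frequency
#' fitting with truncated SVD, then the requested selection statistics.
#' The per-component variant-weight statistic (S1) is reported without
#' genomic control; the robust-Mahalanobis statistic (S2) is always
#' corrected by the genomic inflation factor.
#'
#' @param gl a [gl_matrix()], or an N x M hard-genotype dosage matrix
#'   (0/1/2/NA) which is converted with [genotypes_to_gl()] and analysed
#'   in genotype mode (no SNP test).
#' @param K number of principal components to fit and test.
#' @param which which statistics to compute: "both", "s1" or "s2".
#' @param alpha family-wise error target for Bonferroni calls.
#' @param maf_min minor-allele-frequency threshold (strict).
#' @param snp_p SNP likelihood-ratio p-value threshold; set NULL to skip
#'   the SNP test (done automatically for genotype input).
#' @param tol,max_iter convergence controls of the iterative fit.
#' @param robust use the robust (MCD) scatter for S2 (default TRUE).
#' @param seed seed for the MCD subsampling.
#' @return list of class `"pcsel_scan"`: `markers`, `maf` (retained
#'   sites), `mask` (full-length filter with reasons), `fit`, and the
#'   requested `s1` / `s2` components with p-values, Bonferroni
#'   threshold and significance flags; `s2` additionally carries
#'   `lambda_gc` and a `degenerate` flag vector.
#' @export
run_scan <- function(gl, K = 1, which = c("both", "s1", "s2"),
                     alpha = 0.05, maf_min = 0.05, snp_p = 1e-6,
                     tol = 1e-5, max_iter = 100, robust = TRUE,
                     seed = 42L) {
  which <- match.arg(which)
  if (is.matrix(gl) || is.data.frame(gl)) {
    gl <- genotypes_to_gl(as.matrix(gl))
    snp_p <- NULL
  }
  f_all <- estimate_af_em(gl)
  lrt_p <- if (is.null(snp_p)) NULL else snp_lrt(gl, f_all)$pval
  mask <- site_filter(f_all, lrt_p, maf_min = maf_min,
                      snp_p = if (is.null(snp_p)) 1e-6 else snp_p)
  glk <- gl_subset_sites(gl, mask$keep)
  f <- f_all[mask$keep]
  fit <- fit_individual_afs(glk, f, K = K, tol = tol, max_iter = max_iter)
  m_tests <- sum(mask$keep)
  out <- list(markers = glk$markers, maf = f, mask = mask, fit = fit,
              alpha = alpha, n_tests = m_tests, K = K)
  if (which %in% c("both", "s1")) {
    s1 <- s1_statistic(fit$factors)
    bon <- pvalues_and_bonferroni(s1$chi2, df = 1, alpha = alpha,
                                  M_tests = m_tests)
    s1$pvals <- bon$pvals
    s1$threshold <- bon$threshold
    s1$significant <- bon$significant
    out$s1 <- s1
  }
  if (which %in% c("both", "s2")) {
    z <- s2_zscores(fit$y, fit$factors)
    degen <- attr(z, "degenerate")
    mahal <- robust_mahalanobis(z, robust = robust, seed = seed)
    if (any(degen)) {
      mx <- max(mahal[is.finite(mahal)], 0)
      mahal[degen] <- mx
    }
    gc <- genomic_inflation(mahal, df = K)
    bon <- pvalues_and_bonferroni(gc$corrected, df = K, alpha = alpha,
                                  M_tests = m_tests)
    out$s2 <- list(z = z, mahal = mahal, lambda_gc = gc$lambda,
                   mahal_corrected = gc$corrected, pvals = bon$pvals,
                   threshold = bon$threshold, significant = bon$significant,
                   degenerate = degen)
  }
  class(out) <- "pcsel_scan"
  out
}

#' @export
print.pcsel_scan <- function(x, ...) {
  cat(sprintf("pcsel_scan: %d sites retained of %d read, K = %d\n",
              x$n_tests, length(x$mask$keep), x$K))
  excl <- table(x$mask$reasons[!x$mask$keep])
  if (length(excl))
    cat("  excluded:", paste(names(excl), excl, sep = " = ",
                             collapse = ", "), "\n")
  if (!is.null(x$s1))
    cat(sprintf("  S1: %d Bonferroni-significant site-component pairs\n",
                sum(x$s1$significant)))
  if (!is.null(x$s2))
    cat(sprintf("  S2: lambda_gc = %.3f, %d Bonferroni-significant sites\n",
                x$s2$lambda_gc, sum(x$s2$significant)))
  invisible(x)
}

#' Flatten a scan result to a per-site table
#'
#' @param x a `pcsel_scan` object.
#' @param ... unused.
#' @return data.frame with one row per retained site.
#' @export
as.data.frame.pcsel_scan <- function(x, ...) {
  df <- data.frame(chrom = x$markers$chrom, pos = x$markers$pos,
                   id = x$markers$id, maf = x$maf,
                   stringsAsFactors = FALSE)
  if (!is.null(x$s1)) {
    for (k in seq_len(x$K)) {
      df[[paste0("s1_d_pc", k)]] <- x$s1$d[, k]
      df[[paste0("s1_chi2_pc", k)]] <- x$s1$chi2[, k]
      df[[paste0("s1_pval_pc", k)]] <- x$s1$pvals[, k]
      df[[paste0("s1_sig_pc", k)]] <- x$s1$significant[, k]
    }
  }
  if (!is.null(x$s2)) {
    df$s2_mahal <- x$s2$mahal
    df$s2_chi2 <- x$s2$mahal_corrected
    df$s2_pval <- x$s2$pvals
    df$s2_sig <- x$s2$significant
    df$s2_degenerate <- x$s2$degenerate
  }
  df
}

#' Manhattan plot of a selection scan
#'
#' @param x a `pcsel_scan` object.
#' @param statistic "s1" (a given PC) or "s2".
#' @param pc which component when `statistic = "s1"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_manhattan <- function(x, statistic = c("s1", "s2"), pc = 1, ...) {
  statistic <- match.arg(statistic)
  if (statistic == "s1") {
    p <- x$s1$pvals[, pc]; thr <- x$s1$threshold
    main <- sprintf("S1 statistic, PC%d", pc)
  } else {
    p <- x$s2$pvals; thr <- x$s2$threshold
    main <- "S2 robust Mahalanobis statistic"
  }
  graphics::plot(seq_along(p), -log10(p), pch = 16, cex = 0.4,
                 xlab = "site index", ylab = expression(-log[10](p)),
                 main = main, ...)
  graphics::abline(h = -log10(thr), col = "red")
  invisible(x)
}

#' QQ plot of scan p-values against the uniform expectation
#'
#' @inheritParams plot_manhattan
#' @export
plot_qq <- function(x, statistic = c("s1", "s2"), pc = 1, ...) {
  statistic <- match.arg(statistic)
  p <- if (statistic == "s1") x$s1$pvals[, pc] else x$s2$pvals
  p <- sort(p[!is.na(p)])
  expd <- -log10(stats::ppoints(length(p)))
  graphics::plot(expd, -log10(p), pch = 16, cex = 0.4,
                 xlab = "expected -log10(p)", ylab = "observed -log10(p)",
                 ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}
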