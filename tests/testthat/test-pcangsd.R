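test_that("genotype posteriors follow Bayes rule with a Binomial prior", {
  # uninformative data returns the prior
  expect_equal(genotype_posteriors(c(1, 1, 1) / 3, 0.3),
               c(0.49, 0.42, 0.09), tolerance = 1e-12)
  # hand computation: prior (0.25, 0.5, 0.25) x gl (0.1, 0.6, 0.3)
  expect_equal(genotype_posteriors(c(0.1, 0.6, 0.3), 0.5),
               c(0.0625, 0.75, 0.1875), tolerance = 1e-12)
  # certain observation is unchanged by any prior
  expect_equal(genotype_posteriors(c(1, 0, 0), 0.9), c(1, 0, 0))
  expect_error(genotype_posteriors(c(0, 0, 0), 0.5), "zero")
  # posteriors sum to one over random inputs
  set.seed(1)
  for (i in 1:50) {
    p <- genotype_posteriors(runif(3, 0, 5), runif(1, 0.01, 0.99))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("posterior dosages impute missing data and stay in [0, 2]", {
  gl <- gl_from_triples(list(list(c(1, 1, 1) / 3, c(0.1, 0.6, 0.3),
                                  c(0, 1, 0))))
  pi <- matrix(c(0.3, 0.5, 0.7), nrow = 1)
  d <- posterior_dosage(gl, pi)
  expect_equal(d[1, 1], 0.6)      # missing -> 2 * pi
  expect_equal(d[1, 2], 1.125)    # continues the Bayes hand computation
  expect_equal(d[1, 3], 1)        # certain genotype is returned exactly
  gl2 <- random_gl(10, 50, seed = 2)
  d2 <- posterior_dosage(gl2, matrix(runif(500, 0.01, 0.99), 10))
  expect_true(all(d2 >= 0 & d2 <= 2))
})

test_that("standardization applies the Binomial scaling and guards f", {
  expect_equal(standardize_dosage(matrix(1.125), 0.5)[1, 1],
               0.125 / sqrt(0.5), tolerance = 1e-9)
  expect_equal(standardize_dosage(matrix(2), 0.05)[1, 1], 6.16441,
               tolerance = 1e-5)
  expect_equal(standardize_dosage(matrix(0.8), 0.4)[1, 1], 0)
  expect_error(standardize_dosage(matrix(1), 1), "0, 1")
})

test_that("truncated SVD matches the dense decomposition and is orthonormal", {
  set.seed(6)
  y <- matrix(rnorm(20 * 50), 20)
  fac <- truncated_svd(y, 3)
  dense <- svd(y)
  expect_equal(fac$d, dense$d[1:3], tolerance = 1e-8)
  recon <- fac$U %*% (fac$d * t(fac$V))
  recon_dense <- dense$u[, 1:3] %*% diag(dense$d[1:3]) %*% t(dense$v[, 1:3])
  expect_lt(max(abs(recon - recon_dense)), 1e-8)
  expect_equal(crossprod(fac$U), diag(3), tolerance = 1e-8)
  expect_equal(crossprod(fac$V), diag(3), tolerance = 1e-8)
  # sign convention: dominant entry of each U column is positive
  for (k in 1:3) expect_gt(fac$U[which.max(abs(fac$U[, k])), k], 0)

  # exact recovery of a rank-1 matrix
  y1 <- outer(rnorm(15), rnorm(30))
  f1 <- truncated_svd(y1, 1)
  expect_lt(norm(f1$U %*% (f1$d * t(f1$V)) - y1, "F"), 1e-8)

  expect_error(truncated_svd(y, 25), "K must")
})

test_that("individual allele frequencies invert the standardization", {
  f <- c(0.2, 0.5, 0.8)
  fac <- structure(list(U = matrix(0, 4, 1), d = 1,
                        V = matrix(0, 3, 1), K = 1),
                   class = "svd_factors")
  pi <- update_ind_afs(fac, f)
  expect_equal(pi, matrix(rep(f, each = 4), 4))     # no structure -> f
  fac$U <- matrix(-100, 4, 1)
  fac$V <- matrix(1, 3, 1)
  expect_true(all(update_ind_afs(fac, f) == 1e-4))  # clipped at the bound
})

test_that("structureless certain genotypes converge immediately", {
  set.seed(9)
  f_true <- runif(500, 0.1, 0.9)
  geno <- matrix(rbinom(50 * 500, 2, rep(f_true, each = 50)), 50)
  gl <- genotypes_to_gl(geno)
  f <- estimate_af_em(gl)
  mask <- site_filter(f, maf_min = 0.05)
  fit <- fit_individual_afs(gl_subset_sites(gl, mask$keep), f[mask$keep],
                            K = 1)
  # dosages of certain genotypes do not depend on pi, so the second
  # iteration reproduces the first exactly
  expect_lte(fit$n_iter, 2)
  expect_true(fit$converged)
  # pi stays near f up to the rank-1 noise floor ~ s1 / sqrt(NM)
  expect_lt(sqrt(mean(sweep(fit$pi, 2, fit$f)^2)), 0.1)
})

test_that("the iterative fit converges with a decaying change trace", {
  d <- small_dataset(seed = 4, fst = 0.1, admixture_mode = "discrete")
  f <- estimate_af_em(d$gl)
  mask <- site_filter(f, snp_lrt(d$gl, f)$pval)
  fit <- fit_individual_afs(gl_subset_sites(d$gl, mask$keep),
                            f[mask$keep], K = 1)
  expect_true(fit$converged)
  tr <- fit$rmse_trace
  expect_lt(tr[length(tr)], 1e-5)
  # decay after the first step, allowing small wiggles near the pi
  # clipping boundary
  if (length(tr) > 2)
    expect_true(all(diff(tr[-1]) <= 0.5 * tr[2]))
  expect_lt(tr[length(tr)], tr[2])
})

test_that("PC1 separates two simulated populations perfectly", {
  cfg <- sim_config(n_individuals = 100, n_sites = 2000, fst = 0.1,
                    depth_mean = 6, error_rate = 0.01,
                    admixture_mode = "discrete", seed = 14)
  d <- make_dataset(cfg)
  f <- estimate_af_em(d$gl)
  mask <- site_filter(f, snp_lrt(d$gl, f)$pval)
  fit <- fit_individual_afs(gl_subset_sites(d$gl, mask$keep),
                            f[mask$keep], K = 1)
  grp <- d$truth$admixture[, 1] > 0.5
  side <- fit$factors$U[, 1] > 0
  expect_true(all(side == grp) || all(side == !grp))
})

test_that("allele relabeling negates a site's variant weights only", {
  d <- small_dataset(seed = 4, fst = 0.1, admixture_mode = "discrete")
  gl <- d$gl
  gl2 <- gl
  gl2$likelihoods[, 5, ] <- gl2$likelihoods[, 5, 3:1]
  f1 <- estimate_af_em(gl); f2 <- estimate_af_em(gl2)
  expect_equal(f2[5], 1 - f1[5], tolerance = 1e-6)
  m1 <- site_filter(f1, snp_lrt(gl, f1)$pval)
  m2 <- site_filter(f2, snp_lrt(gl2, f2)$pval)
  expect_equal(m1$keep, m2$keep)
  fit1 <- fit_individual_afs(gl_subset_sites(gl, m1$keep), f1[m1$keep], K = 1)
  fit2 <- fit_individual_afs(gl_subset_sites(gl2, m2$keep), f2[m2$keep], K = 1)
  j <- sum(m1$keep[1:5])
  expect_equal(fit2$factors$V[j, ], -fit1$factors$V[j, ], tolerance = 1e-6)
  expect_equal(fit2$factors$V[-j, ], fit1$factors$V[-j, ], tolerance = 1e-6)
  s1a <- s1_statistic(fit1$factors); s1b <- s1_statistic(fit2$factors)
  expect_equal(s1b$chi2, s1a$chi2, tolerance = 1e-6)
})

test_that("high-depth factors agree with true-genotype factors", {
  cfg <- sim_config(n_individuals = 80, n_sites = 1500, fst = 0.05,
                    depth_mean = 30, error_rate = 0.005, seed = 16)
  d <- make_dataset(cfg)
  f <- estimate_af_em(d$gl)
  mask <- site_filter(f, snp_lrt(d$gl, f)$pval)
  fit_gl <- fit_individual_afs(gl_subset_sites(d$gl, mask$keep),
                               f[mask$keep], K = 1)
  geno <- d$truth$genotypes[, mask$keep]
  glg <- genotypes_to_gl(geno)
  fg <- estimate_af_em(glg)
  fit_g <- fit_individual_afs(glg, fg, K = 1)
  expect_gt(abs(cor(fit_gl$factors$U[, 1], fit_g$factors$U[, 1])), 0.99)
  expect_gt(abs(cor(fit_gl$factors$V[, 1], fit_g$factors$V[, 1])), 0.99)
})

test_that("individual allele frequencies track the simulated truth", {
  cfg <- sim_config(n_individuals = 80, n_sites = 1500, fst = 0.1,
                    depth_mean = 8, error_rate = 0.01,
                    admixture_mode = "discrete", seed = 17)
  d <- make_dataset(cfg)
  f <- estimate_af_em(d$gl)
  mask <- site_filter(f, snp_lrt(d$gl, f)$pval)
  fit <- fit_individual_afs(gl_subset_sites(d$gl, mask$keep),
                            f[mask$keep], K = 1)
  expect_gt(cor(as.vector(fit$pi),
                as.vector(d$truth$true_pi[, mask$keep])), 0.9)
})
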