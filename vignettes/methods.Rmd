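---
title: "Methods: PCA-based selection scans from genotype likelihoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PCA-based selection scans from genotype likelihoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`pcselscan` scans diallelic sites for allele-frequency differentiation
in excess of genetic drift along inferred axes of population structure,
taking genotype likelihoods rather than called genotypes as input. The
major and minor allele are assumed known, genotypes follow a
Binomial(2, π) model given the individual allele frequency π, and sites
are treated as independent (no linkage modeling).

The estimation loop alternates four steps until the individual allele
frequencies stabilize:

1. posterior genotype dosage
   $E[G_{ij} \mid X_{ij}, \hat\pi_{ij}] = \sum_g g\,P(G_{ij}=g \mid X_{ij},
   \hat\pi_{ij})$ with posterior
   $\propto P(X_{ij}\mid g)\,\mathrm{Binom}(g; 2, \hat\pi_{ij})$;
2. standardization
   $y_{ij} = (E[G_{ij}\mid\cdot] - 2\hat f_j)/\sqrt{2\hat f_j(1-\hat f_j)}$,
   where $\hat f_j$ is the population allele frequency — the population
   frequency, not $\hat\pi_{ij}$, is used in both the centering and the
   denominator;
3. truncated SVD $\hat Y = U S V^\top$ of the $N\times M$ matrix $y$;
4. update $\hat\pi_{ij} = \mathrm{clip}((\hat Y_{ij}\sqrt{2\hat f_j(1-\hat
   f_j)} + 2\hat f_j)/2,\ \epsilon,\ 1-\epsilon)$.

The loop is initialized at $\hat\pi_{ij} = \hat f_j$ and, after
convergence, one final dosage/standardize/SVD pass is run so the
returned factors correspond exactly to the converged frequencies.
Missing observations are encoded as three equal likelihoods and
resolve, through step 1, to the structure-based imputation
$2\hat\pi_{ij}$.

Two statistics are computed from the converged factors. The
per-component statistic $d_{jk} = v_{jk}\sqrt{M}$ is standard normal
under drift, so $d_{jk}^2 \sim \chi^2_1$; because each column of $V$
has unit norm, $\sum_j d_{jk}^2 = M$ holds exactly and is used as an
internal consistency check. The multivariate statistic regresses each
site's standardized column on $U$ — the coefficients come free from the
factorization, $\beta_j = S V_{j\cdot}$, because $U^\top U = I$ — forms
z-scores by dividing by the site's residual standard error
$\sqrt{(y_j-\hat y_j)^\top(y_j-\hat y_j)/(N-K)}$, and measures each
site's squared robust Mahalanobis distance in z-score space, which is
$\chi^2_K$ under drift. The per-component statistic is reported without
genomic control; the Mahalanobis statistic is always divided by the
genomic inflation factor $\lambda = \mathrm{median}(D^2) /
\mathrm{median}(\chi^2_K)$, so its corrected median equals the null
median by construction.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `K` | user-supplied | number of principal components fitted and tested; no automatic selection is attempted |
| `maf_min` | 0.05 | strict minor-allele-frequency bound: a site with $\hat f_j$ exactly 0.05 is excluded |
| `snp_p` | 1e-6 | likelihood-ratio SNP-test threshold (skipped in genotype mode, where sites are known) |
| `alpha` | 0.05 | family-wise error target; the Bonferroni threshold divides by the number of retained sites |
| `tol` | 1e-5 | convergence threshold on the RMS change of $\hat\pi$ between iterations |
| `max_iter` | 100 | iteration cap; non-convergence warns and returns the last iterate |
| `clip_lo` | 1e-4 | clipping bound keeping $\hat\pi$ inside the open unit interval so Binomial priors never degenerate |

EM allele-frequency estimation initializes at $f = 0.25$ with
tolerance 1e-6 and at most 200 iterations; on certain (hard-genotype)
likelihood triples the EM fixed point is exactly the sample allele
proportion. The likelihood-ratio test compares the fitted frequency
against the better of the two monomorphic models ($f = 0$ and $f = 1$),
because "variable" means non-monomorphic for either allele.

## Numerical and design choices

**Truncated SVD.** For $N \le M$ (the scan regime) the factorization is
computed exactly from the eigendecomposition of the $N \times N$ Gram
matrix — deterministic, no randomized sketching, and it matches a dense
`svd()` to below 1e-8 at test sizes. Signs are fixed by requiring the
largest-magnitude entry of each column of $U$ to be positive (ties by
lowest index); both statistics depend on $V$ only through squares and
quadratic forms, so the convention affects reproducibility of
intermediates, not results. Singular-value ties are left in the order
the decomposition returns them.

**Robust scatter.** The Mahalanobis center and scatter use the
minimum-covariance-determinant estimator with support fraction 0.75
(`MASS::cov.rob`, fixed internal seed), followed by the standard
reweighting step: rows whose raw distance lies below the 97.5%
$\chi^2_K$ quantile are refit with a classical mean/covariance and the
covariance is rescaled by the normal-consistency factor of that
truncation. The reweighting removes most of the raw MCD's small-sample
scale bias (distance medians land within a few percent of the
$\chi^2_K$ median on normal scores). If the robust fit fails or is
singular the classical mean/covariance is used with a warning; a
singular classical covariance is a fatal error.

**Degenerate sites.** A site whose standardized column lies exactly in
the span of $U$ has zero residual and an undefined z-score. Such sites
arise only in contrived or tiny datasets; they are flagged, excluded
from scatter estimation, and assigned the largest finite distance so a
genome-wide scan never crashes on them. P-values are computed as
chi-square survival functions and floored at the smallest positive
double, never reported as zero. Sites where every individual is missing
have no defined frequency and are masked as monomorphic.

**Convergence trace.** The RMS change of $\hat\pi$ decays by orders of
magnitude and then can wiggle at the 1e-5 scale when entries touch the
clipping bound; convergence is therefore judged by the threshold, not
by strict monotonicity of the trace. With certain-genotype input the
dosage does not depend on $\hat\pi$, so the loop converges on the
second iteration identically.

## What the simulator emulates — and what it does not

`sim_config()`/`make_dataset()` generate structured low-coverage data
in the Balding–Nichols sense: ancestral frequencies uniform on (0.05,
0.95) (so the MAF filter retains most sites and power estimates are
stable), population frequencies Beta-distributed with variance
$F\,p(1-p)$, individuals either in discrete equal-sized groups or on a
linear two-population admixture cline, Binomial genotypes, Poisson read
depth per observation (matching the variability of real low-pass
coverage), and a symmetric per-base error rate applied read by read.
Default depth 6 and error 0.01 mirror typical low-pass panels; "selected"
loci are realized as elevated drift ($F_{ST}$ e.g. 0.3 against a 0.01
background), since excess differentiation along the structure axis is
exactly what the statistics test.

Because both populations draw their frequency independently from the
Beta, an elevated-drift locus can still land with a small
between-population difference: at $F = 0.3$ and a mid-range ancestral
frequency the Beta is nearly uniform, and a substantial fraction of
selected draws are no more differentiated than the background's upper
tail. Power measured against the *injected* label therefore saturates
well below 100% no matter how good the method or how deep the
sequencing — a property of the generator, not of the scan. The
simulator also omits linkage, batch/read-length artifacts and related
individuals, so passing tests say nothing about those failure modes on
real data.

## Test and verification scale

The test suite verifies each estimator against an independent oracle
(grid search for the EM frequencies, dense SVD, normal-equations least
squares, hand-computed Bayes and Mahalanobis cases) and runs the full
scan on simulated panels of 60–200 individuals and 800–5000 sites —
null calibration over 20 seeds at depth 4, power and concordance runs
at depths 3, 6 and 30, and frequency-recovery runs at depths 1, 4
and 16. `scripts/acceptance.R` recomputes the same summary quantities
from scratch at slightly reduced replication (5 null seeds) and writes
them as JSON. These sizes were chosen to make the Monte-Carlo bands in
the tests tight enough to be meaningful while keeping a full run in the
minutes range on a single CPU.

## Known limitations

- `K` must be chosen by the user; no eigenvalue-based selection is
  provided.
- Relatedness and admixture LD are not modeled; kinship-aware
  extensions are out of scope.
- The SNP test and MAF filter assume the major/minor labeling is given;
  allele inference from likelihoods is upstream of this package.
- Discrete, strongly diverged populations violate the "continuous
  differentiation" setting the statistics are calibrated for;
  population-branch statistics are more appropriate there.
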