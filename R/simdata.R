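#' Configuration for synthetic low-coverage datasets
#'
#' Describes a Balding-Nichols style simulation: ancestral allele
#' frequencies drawn uniformly from `maf_range`, per-population drifted
#' frequencies Beta-distributed with variance `fst * p * (1 - p)`,
#' individuals either assigned to discrete populations or placed on an
#' admixture cline between two populations, Binomial genotypes, and
#' read-level genotype likelihoods at Poisson-distributed depth with a
#' symmetric per-base miscall rate. Loci under differential selection
#' are emulated by elevated drift (`selected_fst`), which is exactly the
#' excess differentiation the scan statistics test for.
#'
#' @param n_individuals number of individuals N.
#' @param n_sites number of sites M.
#' @param n_populations number of source populations (cline mode needs 2).
#' @param fst background drift parameter in (0, 1); 0 means no structure.
#' @param admixture_mode "cline" (default) or "discrete".
#' @param depth_mean expected reads per individual per site (default 6,
#'   the coverage regime of typical low-pass population panels).
#' @param error_rate per-base miscall probability in \[0, 0.5).
#' @param selected_sites number of loci with elevated drift.
#' @param selected_fst drift parameter of the selected loci.
#' @param maf_range ancestral-frequency bounds (default 0.05-0.95).
#' @param seed RNG seed making the dataset fully reproducible.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals = 100, n_sites = 2000,
                       n_populations = 2, fst = 0.05,
                       admixture_mode = c("cline", "discrete"),
                       depth_mean = 6, error_rate = 0.01,
                       selected_sites = 0, selected_fst = 0.3,
                       maf_range = c(0.05, 0.95), seed = 1L) {
  admixture_mode <- match.arg(admixture_mode)
  stopifnot(n_individuals >= 2, n_sites >= 1, n_populations >= 1,
            fst >= 0, fst < 1, selected_fst >= 0, selected_fst < 1,
            depth_mean >= 0, error_rate >= 0, error_rate < 0.5,
            selected_sites >= 0, selected_sites <= n_sites,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] < 1,
            maf_range[1] < maf_range[2])
  if (admixture_mode == "cline" && n_populations != 2)
    stop("cline admixture requires exactly 2 source populations")
  structure(as.list(environment()), class = "sim_config")
}

#' Draw ancestral and drifted population allele frequencies
#'
#' Ancestral frequencies are Uniform over `maf_range`; each population's
#' frequency is Beta(p (1 - F) / F, (1 - p)(1 - F) / F), giving mean p
#' and variance F p (1 - p) (the Balding-Nichols model). F = 0 is handled
#' analytically: the population frequency equals the ancestral one.
#' Selected loci use `selected_fst` in place of `fst`.
#'
#' @param config a [sim_config()].
#' @return list with `ancestral` (length M), `pop_freqs`
#'   (populations x M), `selected_mask` (length M logical).
#' @export
sim_population_freqs <- function(config) {
  m <- config$n_sites; np <- config$n_populations
  anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  sel <- rep(FALSE, m)
  if (config$selected_sites > 0)
    sel[sample.int(m, config$selected_sites)] <- TRUE
  fst <- ifelse(sel, config$selected_fst, config$fst)
  pf <- matrix(rep(anc, each = np), nrow = np)
  drift <- fst > 0
  if (any(drift)) {
    fd <- fst[drift]
    pd <- anc[drift]
    a <- pd * (1 - fd) / fd
    b <- (1 - pd) * (1 - fd) / fd
    for (p in seq_len(np))
      pf[p, drift] <- stats::rbeta(sum(drift), a, b)
  }
  list(ancestral = anc, pop_freqs = pf, selected_mask = sel)
}

#' Admixture proportions of the simulated individuals
#'
#' Discrete mode assigns individuals to equal-sized one-hot groups;
#' cline mode places individual i at proportion (i - 1) / (N - 1) of the
#' second population, the linear gradient that produces continuous
#' differentiation along one principal component.
#'
#' @param config a [sim_config()].
#' @return N x populations matrix with rows summing to 1.
#' @export
sim_admixture <- function(config) {
  n <- config$n_individuals; np <- config$n_populations
  if (config$admixture_mode == "cline") {
    q <- seq(0, 1, length.out = n)
    cbind(1 - q, q)
  } else {
    grp <- rep(seq_len(np), each = ceiling(n / np))[seq_len(n)]
    diag(np)[grp, , drop = FALSE]
  }
}

#' Sample genotypes from individual allele frequencies
#'
#' Each genotype is Binomial(2, pi_ij) given the individual allele
#' frequency pi_ij = sum_p admixture_ip * pop_freq_pj.
#'
#' @param true_pi N x M matrix of individual allele frequencies.
#' @return N x M integer matrix of minor-allele dosages.
#' @export
sim_genotypes <- function(true_pi) {
  n <- nrow(true_pi); m <- ncol(true_pi)
  matrix(stats::rbinom(n * m, 2L, true_pi), nrow = n)
}

#' Generate read-level genotype likelihoods
#'
#' Per observation, the read count is Poisson(`depth_mean`); each read
#' carries the minor allele with probability g/2 (1 - e) + (1 - g/2) e
#' given genotype g and error rate e. The genotype likelihood is the
#' Binomial probability of the observed minor-read count under each g
#' (the shared combinatorial factor is irrelevant as likelihoods are
#' scale-free). Zero reads give the equal (missing) triple.
#'
#' @param genotypes N x M matrix of dosages 0/1/2.
#' @param config a [sim_config()] supplying `depth_mean` and `error_rate`.
#' @return a [gl_matrix()].
#' @export
sim_gl <- function(genotypes, config) {
  n <- nrow(genotypes); m <- ncol(genotypes)
  e <- config$error_rate
  depth <- matrix(stats::rpois(n * m, config$depth_mean), nrow = n)
  p_read <- genotypes / 2 * (1 - e) + (1 - genotypes / 2) * e
  k_minor <- matrix(stats::rbinom(n * m, depth, p_read), nrow = n)
  lik <- array(0, dim = c(n, m, 3))
  for (g in 0:2) {
    pg <- g / 2 * (1 - e) + (1 - g / 2) * e
    lik[, , g + 1] <- stats::dbinom(k_minor, depth, pg)
  }
  # no reads: equal triple, the missing-data convention
  miss <- which(depth == 0)
  nm <- n * m
  for (g in 0:2) lik[miss + g * nm] <- 1 / 3
  markers <- parse_marker_ids(paste0("chr1_", seq_len(m)),
                              rep("0", m), rep("1", m))
  gl_matrix(lik, markers)
}

#' Simulate a complete low-coverage dataset
#'
#' Composes frequency drawing, admixture, genotype sampling and
#' likelihood generation; fully reproducible from `config$seed`.
#' Optionally writes the Beagle file and plain-text truth sidecars.
#'
#' @param config a [sim_config()].
#' @param beagle_path optional path for a Beagle file of the likelihoods.
#' @param truth_prefix optional path prefix; writes `<prefix>.truth_pi.tsv`
#'   (true individual allele frequencies), `<prefix>.genotypes.tsv` and
#'   `<prefix>.selected.tsv`.
#' @return list with `gl` (a [gl_matrix()]) and `truth` (ancestral and
#'   population frequencies, admixture, true pi, genotypes,
#'   selected_mask).
#' @export
make_dataset <- function(config, beagle_path = NULL, truth_prefix = NULL) {
  with_local_seed(config$seed, {
    fr <- sim_population_freqs(config)
    adm <- sim_admixture(config)
    true_pi <- adm %*% fr$pop_freqs
    geno <- sim_genotypes(true_pi)
    gl <- sim_gl(geno, config)
    truth <- list(ancestral_freqs = fr$ancestral, pop_freqs = fr$pop_freqs,
                  admixture = adm, true_pi = true_pi, genotypes = geno,
                  selected_mask = fr$selected_mask)
    if (!is.null(beagle_path)) write_beagle(gl, beagle_path)
    if (!is.null(truth_prefix)) {
      utils::write.table(true_pi, paste0(truth_prefix, ".truth_pi.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      utils::write.table(geno, paste0(truth_prefix, ".genotypes.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      utils::write.table(data.frame(selected = as.integer(fr$selected_mask)),
                         paste0(truth_prefix, ".selected.tsv"),
                         sep = "\t", row.names = FALSE)
    }
    list(gl = gl, truth = truth)
  })
}
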