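#' Genotype-likelihood matrix container
#'
#' Holds per-site, per-individual likelihoods of the three diallelic
#' genotypes (minor-allele counts 0, 1, 2) together with marker metadata.
#' Likelihoods are scale-free per (individual, site) pair: any positive
#' rescaling of a triple represents the same observation. A missing
#' observation (no reads) is encoded as three equal entries, the Beagle
#' convention, which makes "no data" and "uninformative data" identical
#' downstream.
#'
#' @param likelihoods numeric array of dimension N x M x 3, non-negative,
#'   with at least one positive entry per (i, j) triple.
#' @param markers data.frame with columns `id`, `allele1`, `allele2`,
#'   `chrom`, `pos` (one row per site), as produced by [parse_marker_ids()].
#' @param sample_ids character vector of length N.
#' @return An object of class `"gl_matrix"`.
#' @export
gl_matrix <- function(likelihoods, markers, sample_ids = NULL) {
  stopifnot(is.array(likelihoods), length(dim(likelihoods)) == 3L,
            dim(likelihoods)[3] == 3L)
  n <- dim(likelihoods)[1]
  m <- dim(likelihoods)[2]
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(n))
  stopifnot(length(sample_ids) == n, nrow(markers) == m)
  if (any(likelihoods < 0) || anyNA(likelihoods))
    stop("genotype likelihoods must be non-negative and non-missing")
  tot <- likelihoods[, , 1, drop = FALSE] + likelihoods[, , 2, drop = FALSE] +
    likelihoods[, , 3, drop = FALSE]
  if (any(tot <= 0))
    stop("invalid likelihood triple: all three genotype likelihoods are zero")
  structure(list(likelihoods = likelihoods,
                 markers = markers,
                 sample_ids = as.character(sample_ids)),
            class = "gl_matrix")
}

#' @export
print.gl_matrix <- function(x, ...) {
  cat(sprintf("gl_matrix: %d individuals x %d sites\n",
              n_ind(x), n_sites(x)))
  nm <- sum(gl_is_missing(x))
  cat(sprintf("  missing observations: %d (%.1f%%)\n",
              nm, 100 * nm / (n_ind(x) * n_sites(x))))
  invisible(x)
}

#' @rdname gl_matrix
#' @param gl a `gl_matrix`.
#' @export
n_ind <- function(gl) dim(gl$likelihoods)[1]

#' @rdname gl_matrix
#' @export
n_sites <- function(gl) dim(gl$likelihoods)[2]

# Extract one genotype's likelihood layer as an N x M matrix (array
# slicing would drop singleton dimensions).
gl_slice <- function(gl, k) {
  matrix(gl$likelihoods[, , k], nrow = dim(gl$likelihoods)[1])
}

#' Identify missing observations
#'
#' An observation is missing when its three genotype likelihoods are equal
#' (up to relative tolerance), i.e. the data carry no information about the
#' genotype.
#'
#' @param gl a `gl_matrix`.
#' @return N x M logical matrix.
#' @export
gl_is_missing <- function(gl) {
  l1 <- gl_slice(gl, 1); l2 <- gl_slice(gl, 2); l3 <- gl_slice(gl, 3)
  hi <- pmax(l1, l2, l3)
  lo <- pmin(l1, l2, l3)
  (hi - lo) <= 1e-9 * hi
}

#' Subset sites of a gl_matrix
#'
#' @param gl a `gl_matrix`.
#' @param keep logical or integer index over sites.
#' @return A `gl_matrix` restricted to the selected sites.
#' @export
gl_subset_sites <- function(gl, keep) {
  gl_matrix(gl$likelihoods[, keep, , drop = FALSE],
            gl$markers[keep, , drop = FALSE],
            gl$sample_ids)
}

#' Parse marker names into chromosome and position
#'
#' Marker ids of the form `"chr_pos"` (underscore-separated integer suffix)
#' are split into chromosome and 1-based position; ids without such a
#' suffix keep the whole id as chromosome and get a sequential position,
#' since the scan itself is position-agnostic and coordinates are
#' report-only.
#'
#' @param id character vector of marker names.
#' @param allele1,allele2 major/minor allele codes (0-3 or A/C/G/T).
#' @return data.frame with columns id, allele1, allele2, chrom, pos.
#' @export
parse_marker_ids <- function(id, allele1, allele2) {
  id <- as.character(id)
  m <- regmatches(id, regexec("^(.*)_([0-9]+)$", id))
  has <- lengths(m) == 3L
  chrom <- id
  pos <- seq_along(id)
  chrom[has] <- vapply(m[has], `[`, "", 2L)
  pos[has] <- as.integer(vapply(m[has], `[`, "", 3L))
  if (any(as.character(allele1) == as.character(allele2)))
    stop("major and minor allele codes must differ at every marker")
  data.frame(id = id, allele1 = as.character(allele1),
             allele2 = as.character(allele2),
             chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Convert hard genotypes to certain genotype likelihoods
#'
#' Genotype g (minor-allele dosage 0/1/2) maps to the certain likelihood
#' triple with 1 at position g; missing genotypes map to the equal triple.
#' Running the resulting `gl_matrix` through the likelihood pipeline
#' reproduces a genotype-based analysis exactly.
#'
#' @param geno N x M matrix with entries 0, 1, 2 or NA.
#' @param markers optional marker data.frame; defaults to sequential ids.
#' @param sample_ids optional sample names.
#' @return A `gl_matrix`.
#' @export
genotypes_to_gl <- function(geno, markers = NULL, sample_ids = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  ok <- is.na(geno) | geno %in% c(0, 1, 2)
  if (!all(ok)) stop("genotype dosages must be 0, 1, 2 or missing")
  if (is.null(markers))
    markers <- parse_marker_ids(paste0("site", seq_len(m)),
                                rep("0", m), rep("1", m))
  lik <- array(0, dim = c(n, m, 3))
  nm <- n * m
  for (g in 0:2) lik[which(geno == g) + g * nm] <- 1
  miss <- which(is.na(geno))
  for (k in 0:2) lik[miss + k * nm] <- 1 / 3
  gl_matrix(lik, markers, sample_ids)
}
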