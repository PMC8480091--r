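#' Read a Beagle genotype-likelihood file
#'
#' Beagle files are (optionally gzipped) whitespace-separated text with a
#' header row `marker allele1 allele2` followed by three likelihood columns
#' per individual, one data row per site. Likelihood triples are stored as
#' read; no renormalization is applied on input because the downstream
#' statistics are invariant to per-observation scaling.
#'
#' @param path path to a Beagle file; a ".gz" suffix is decompressed
#'   transparently.
#' @return A [gl_matrix()].
#' @export
read_beagle <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty Beagle file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  header <- toks[[1]]
  if (length(header) < 6L || (length(header) - 3L) %% 3L != 0L)
    stop("malformed Beagle header: expected 'marker allele1 allele2' plus ",
         "3 columns per individual, got ", length(header), " fields")
  n <- (length(header) - 3L) %/% 3L
  sample_ids <- unique(header[seq(4L, length(header), by = 3L)])
  if (length(sample_ids) != n) sample_ids <- paste0("ind", seq_len(n))
  body <- toks[-1L]
  m <- length(body)
  if (m == 0L) stop("empty Beagle file (header only): ", path)
  nf <- lengths(body)
  bad <- which(nf != 3L + 3L * n)
  if (length(bad))
    stop(sprintf("malformed Beagle row at line %d: expected %d fields, got %d",
                 bad[1] + 1L, 3L + 3L * n, nf[bad[1]]))
  dat <- matrix(unlist(body, use.names = FALSE), nrow = 3L + 3L * n)
  vals <- suppressWarnings(
    matrix(as.numeric(dat[-(1:3), , drop = FALSE]), nrow = 3L * n))
  if (anyNA(vals)) stop("non-numeric likelihood value in Beagle file")
  lik <- array(0, dim = c(n, m, 3))
  for (k in 1:3) lik[, , k] <- vals[seq(k, 3L * n, by = 3L), , drop = FALSE]
  markers <- parse_marker_ids(dat[1, ], dat[2, ], dat[3, ])
  gl_matrix(lik, markers, sample_ids)
}

#' Write a Beagle genotype-likelihood file
#'
#' Likelihood triples are normalized to sum to one and written with six
#' significant digits; output is gzip-compressed when the path ends in
#' ".gz". The dialect written is exactly what [read_beagle()] accepts, so
#' write/read round-trips are the identity up to print precision.
#'
#' @param gl a [gl_matrix()].
#' @param path output path.
#' @export
write_beagle <- function(gl, path) {
  m <- n_sites(gl); n <- n_ind(gl)
  if (m == 0L) stop("cannot write a Beagle file with zero markers")
  tot <- gl_slice(gl, 1) + gl_slice(gl, 2) + gl_slice(gl, 3)
  rows <- matrix("", nrow = 3L * n, ncol = m)
  for (k in 1:3)
    rows[seq(k, 3L * n, by = 3L), ] <-
      signif(gl_slice(gl, k) / tot, 6)
  hdr <- c("marker", "allele1", "allele2",
           rep(gl$sample_ids, each = 3L))
  body <- rbind(gl$markers$id, gl$markers$allele1, gl$markers$allele2, rows)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(paste(hdr, collapse = "\t"),
               apply(body, 2, paste, collapse = "\t")), con)
  invisible(path)
}

#' Read a hard-genotype dosage matrix
#'
#' Tab-separated integers with rows = sites and columns = individuals;
#' entries are minor-allele dosages 0/1/2, with -9 or NA marking missing
#' genotypes. Used for the high-quality-genotype comparison mode.
#'
#' @param path path to a TSV file (optionally gzipped).
#' @param sentinel value encoding missingness (default -9).
#' @return N x M integer matrix (individuals x sites) with NA for missing.
#' @export
read_genotype_matrix <- function(path, sentinel = -9) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty genotype matrix file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  if (length(unique(nf)) != 1L)
    stop("ragged genotype matrix: rows have differing column counts")
  vals <- suppressWarnings(as.numeric(unlist(toks, use.names = FALSE)))
  vals[!is.na(vals) & vals == sentinel] <- NA
  bad <- !is.na(vals) & !vals %in% c(0, 1, 2)
  if (any(bad))
    stop("genotype value outside {0, 1, 2, ", sentinel, "}: ",
         vals[which(bad)[1]])
  # file rows are sites, so filling by line gives individuals x sites
  matrix(vals, nrow = nf[1], ncol = length(lines))
}

#' Write a selection-scan result table
#'
#' Tab-separated, one row per retained site: chromosome, position, marker
#' id, minor-allele frequency, each per-component statistic, the
#' chi-square statistic(s) and p-value(s) of the requested tests, and a
#' significance flag per test. P-values are printed in scientific notation
#' with at least four significant digits.
#'
#' @param result a `pcsel_scan` object from [run_scan()].
#' @param path output path.
#' @export
write_scan <- function(result, path) {
  df <- as.data.frame(result)
  num <- vapply(df, is.numeric, TRUE) & grepl("pval", names(df))
  for (j in which(num)) df[[j]] <- formatC(df[[j]], format = "e", digits = 5)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
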