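#' Genotype matrix container
#'
#' A sites-by-samples matrix of genotype codes with per-site metadata.
#' Codes are 0 (homozygous major allele), 1 (heterozygous), 2 (homozygous
#' minor allele) and `NA` (missing). Orientation (which allele is "major")
#' is panel-global and recorded per site in `sites`.
#'
#' @param geno integer matrix, sites in rows, samples in columns; values
#'   0/1/2/`NA`.
#' @param sites data frame with one row per site: columns `chrom`,
#'   `pos` (1-based), `major`, `minor` (allele bases). Positions must be
#'   strictly increasing within each chromosome.
#' @param samples character vector of unique sample ids, one per column.
#'
#' @return An object of class `geno_matrix`: a list with elements `geno`,
#'   `sites` (tibble) and `samples`.
#' @export
geno_matrix <- function(geno, sites, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  sites <- tibble::as_tibble(sites)
  stopifnot(
    nrow(geno) == nrow(sites),
    ncol(geno) == length(samples),
    all(c("chrom", "pos") %in% names(sites)),
    !anyDuplicated(samples)
  )
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  ord_ok <- all(tapply(sites$pos, sites$chrom, function(p) all(diff(p) > 0)))
  if (!isTRUE(ord_ok)) {
    stop("positions must be strictly increasing within each chromosome",
         call. = FALSE)
  }
  dimnames(geno) <- list(NULL, samples)
  structure(
    list(geno = geno, sites = sites, samples = as.character(samples)),
    class = "geno_matrix"
  )
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d sites x %d samples, %.1f%% missing\n",
              nrow(x$geno), ncol(x$geno),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Subset a genotype matrix by sites and/or samples
#'
#' @param x a [geno_matrix()].
#' @param i site index (integer or logical).
#' @param j sample index (integer, logical or character).
#' @param ... ignored.
#' @return A `geno_matrix`.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  if (is.character(j)) j <- match(j, x$samples)
  geno_matrix(x$geno[i, j, drop = FALSE], x$sites[i, , drop = FALSE],
              x$samples[j])
}

#' Per-site summary statistics
#'
#' Minor-allele frequency, heterozygosity rate and missing rate per site.
#' MAF is computed from called alleles only (missing genotypes contribute
#' no allele observations) and folded into `[0, 0.5]`.
#'
#' @param x a [geno_matrix()].
#' @return A tibble with columns `chrom`, `pos`, `n_called`, `maf`,
#'   `het_rate`, `missing_rate`.
#' @export
site_stats <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  g <- x$geno
  n <- ncol(g)
  n_called <- rowSums(!is.na(g))
  dose_sum <- rowSums(g, na.rm = TRUE)
  f <- ifelse(n_called > 0, dose_sum / (2 * n_called), NA_real_)
  dplyr::mutate(
    dplyr::select(x$sites, "chrom", "pos"),
    n_called = n_called,
    maf = pmin(f, 1 - f),
    het_rate = ifelse(n_called > 0,
                      rowSums(g == 1L, na.rm = TRUE) / n_called, NA_real_),
    missing_rate = 1 - n_called / n
  )
}

#' Allele read-depth container
#'
#' Per site-by-sample counts of reads supporting the panel-major allele,
#' the panel-minor allele, and any other base. Input to the genotype
#' caller.
#'
#' @param major,minor,other nonnegative integer matrices of identical
#'   dimension (sites x samples).
#' @param sites,samples as in [geno_matrix()].
#' @return An object of class `allele_depths`.
#' @export
allele_depths <- function(major, minor, other, sites, samples) {
  major <- as.matrix(major); minor <- as.matrix(minor)
  other <- as.matrix(other)
  stopifnot(
    all(dim(major) == dim(minor)), all(dim(major) == dim(other)),
    nrow(major) == nrow(sites), ncol(major) == length(samples)
  )
  if (min(major, minor, other) < 0) {
    stop("read counts must be nonnegative", call. = FALSE)
  }
  structure(
    list(major = major, minor = minor, other = other,
         sites = tibble::as_tibble(sites), samples = as.character(samples)),
    class = "allele_depths"
  )
}

#' @export
dim.allele_depths <- function(x) dim(x$major)

#' @export
print.allele_depths <- function(x, ...) {
  cat(sprintf("<allele_depths> %d sites x %d samples, mean depth %.2f\n",
              nrow(x$major), ncol(x$major),
              mean(x$major + x$minor + x$other)))
  invisible(x)
}

#' @rdname allele_depths
#' @param x an `allele_depths` object.
#' @param i site index.
#' @param j sample index.
#' @param ... ignored.
#' @export
`[.allele_depths` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$major))
  if (missing(j)) j <- seq_len(ncol(x$major))
  allele_depths(x$major[i, j, drop = FALSE], x$minor[i, j, drop = FALSE],
                x$other[i, j, drop = FALSE], x$sites[i, , drop = FALSE],
                x$samples[j])
}
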