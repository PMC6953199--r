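#' Call a genotype from allele read counts
#'
#' Threshold rules for depth-based calling of a bi-allelic site in one
#' sample:
#' * homozygous for the allele with more reads when that allele has at
#'   least 2 reads and accounts for at least 90% of total reads at the
#'   cell;
#' * heterozygous when both alleles have at least 1 read, each accounts
#'   for at least 20% of total reads, and together they have at least 5
#'   reads making up at least 90% of the total;
#' * missing otherwise.
#'
#' The homozygous rule is evaluated first; when the two alleles tie in
#' read count only the heterozygous rule applies. "Total reads" includes
#' other-base reads. Codes are 0 (homozygous major), 1 (heterozygous),
#' 2 (homozygous minor), `NA` (missing).
#'
#' @param major_reads,minor_reads,other_reads nonnegative integer
#'   vectors (recycled to common length).
#' @return Integer vector of genotype codes.
#' @export
#' @examples
#' call_genotype(9, 1, 0)   # 0: 9 reads, 90% major
#' call_genotype(3, 2, 0)   # 1: both >= 20%, sum 5 reads, 100%
#' call_genotype(1, 0, 0)   # NA: < 2 reads
call_genotype <- function(major_reads, minor_reads, other_reads = 0L) {
  n <- max(length(major_reads), length(minor_reads), length(other_reads))
  a <- rep_len(major_reads, n); b <- rep_len(minor_reads, n)
  o <- rep_len(other_reads, n)
  if (anyNA(c(a, b, o)) || min(a, b, o) < 0) {
    stop("read counts must be nonnegative and non-missing", call. = FALSE)
  }
  tot <- a + b + o
  hi <- pmax(a, b)
  hom_ok <- hi >= 2L & hi >= 0.9 * tot & a != b
  het_ok <- a >= 1L & b >= 1L & a >= 0.2 * tot & b >= 0.2 * tot &
    (a + b) >= 5L & (a + b) >= 0.9 * tot
  out <- rep(NA_integer_, n)
  out[het_ok] <- 1L
  out[hom_ok] <- ifelse(a[hom_ok] > b[hom_ok], 0L, 2L)
  out
}

#' Call genotypes for a whole depth matrix
#'
#' Applies [call_genotype()] independently to every site-sample cell.
#'
#' @param depths an [allele_depths()] object.
#' @return A [geno_matrix()] with the same sites and samples.
#' @export
call_genotypes <- function(depths) {
  stopifnot(inherits(depths, "allele_depths"))
  g <- call_genotype(as.vector(depths$major), as.vector(depths$minor),
                     as.vector(depths$other))
  geno_matrix(matrix(g, nrow(depths$major), ncol(depths$major)),
              depths$sites, depths$samples)
}

#' Site discovery from pooled read depths
#'
#' Retains sites that look reliably bi-allelic: pooling across samples
#' whose cell has at least `min_reads` total reads, the two segregating
#' alleles must account for at least `min_biallelic_frac` of all reads.
#' Base-quality filtering happens upstream of this representation and is
#' acknowledged via `min_quality_applied_upstream`.
#'
#' @param depths an [allele_depths()] object.
#' @param min_reads minimum per-cell total reads for the cell to count.
#' @param min_biallelic_frac minimum pooled (major+minor)/total fraction.
#' @param min_quality_applied_upstream flag recording that per-base
#'   quality screening was done before depth extraction.
#' @return Logical site mask (TRUE = retained).
#' @export
discover_sites <- function(depths, min_reads = 5L,
                           min_biallelic_frac = 0.80,
                           min_quality_applied_upstream = TRUE) {
  stopifnot(inherits(depths, "allele_depths"))
  tot <- depths$major + depths$minor + depths$other
  use <- tot >= min_reads
  ab <- rowSums((depths$major + depths$minor) * use)
  all_reads <- rowSums(tot * use)
  all_reads > 0 & ab >= min_biallelic_frac * all_reads
}

#' Pre-imputation site filter
#'
#' Keeps sites with minor-allele frequency >= `maf_min` (computed from
#' called alleles only), heterozygosity rate <= `het_max` and missing
#' rate <= `missing_max`. Sites with zero calls are dropped and counted.
#'
#' @param genotypes a [geno_matrix()].
#' @param maf_min,het_max,missing_max thresholds.
#' @return Filtered `geno_matrix`; attribute `n_dropped` records removals
#'   (including `n_zero_call` sites with no calls at all).
#' @export
filter_sites_pre <- function(genotypes, maf_min = 0.01, het_max = 0.20,
                             missing_max = 0.70) {
  st <- site_stats(genotypes)
  keep <- !is.na(st$maf) & st$maf >= maf_min &
    st$het_rate <= het_max & st$missing_rate <= missing_max
  out <- genotypes[keep, ]
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "n_zero_call") <- sum(st$n_called == 0)
  out
}

#' Sample filter on missing-data rate
#'
#' Removes samples whose missing rate is greater than or equal to
#' `threshold`.
#'
#' @param genotypes a [geno_matrix()].
#' @param threshold missing-rate cutoff (default 0.80).
#' @return Filtered `geno_matrix` with attribute `n_removed`.
#' @export
filter_samples <- function(genotypes, threshold = 0.80) {
  miss <- colMeans(is.na(genotypes$geno))
  keep <- miss < threshold
  if (!any(keep)) stop("all samples removed by missing-rate filter",
                       call. = FALSE)
  out <- genotypes[, keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Post-imputation site filter
#'
#' Re-applies the MAF and heterozygosity thresholds and additionally
#' requires the minor allele to appear in homozygous state in at least
#' `min_homozygous_minor` samples.
#'
#' @param genotypes an imputed [geno_matrix()].
#' @param min_homozygous_minor minimum count of code-2 samples
#'   (default 20).
#' @param maf_min,het_max as in [filter_sites_pre()].
#' @return Filtered `geno_matrix` with attribute `n_dropped`.
#' @export
filter_sites_post <- function(genotypes, min_homozygous_minor = 20L,
                              maf_min = 0.01, het_max = 0.20) {
  st <- site_stats(genotypes)
  n_hom_minor <- rowSums(genotypes$geno == 2L, na.rm = TRUE)
  keep <- !is.na(st$maf) & st$maf >= maf_min & st$het_rate <= het_max &
    n_hom_minor >= min_homozygous_minor
  out <- genotypes[keep, ]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
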