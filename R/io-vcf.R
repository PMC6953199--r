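#' Read genotypes (and allele depths) from a VCF file
#'
#' Parses bi-allelic SNP records via \pkg{vcfR}. GT is converted to the
#' dosage of the non-reference allele and then re-oriented panel-wide so
#' code 0 is homozygous for the major allele; the AD field, when
#' present, is re-oriented the same way into (major, minor, other)
#' counts. Multi-allelic records are skipped and counted.
#'
#' @param path VCF file (plain text or gzipped).
#' @return A [geno_matrix()]; when AD is present, an [allele_depths()]
#'   object is attached as attribute `depths`. Attribute
#'   `n_multiallelic_skipped` records skipped records.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- get_fix_matrix(v)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1 & nchar(alt) == 1
  n_skip <- sum(!biallelic)
  if (!any(biallelic)) stop("no bi-allelic SNP records in ", path,
                            call. = FALSE)
  v <- v[biallelic, ]
  fix <- get_fix_matrix(v)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- t(as.matrix(gt))
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  bad <- !is.na(gt) & !clean %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (any(bad)) {
    stop("malformed GT at record ", which(rowSums(bad) > 0)[1],
         call. = FALSE)
  }

  # orient: minor allele = panel-wide less frequent ALT or REF
  alt_freq <- rowSums(dose, na.rm = TRUE) /
    (2 * rowSums(!is.na(dose)))
  flip <- !is.na(alt_freq) & alt_freq > 0.5
  dose[flip, ] <- 2L - dose[flip, ]
  major <- ifelse(flip, fix[, "ALT"], fix[, "REF"])
  minor <- ifelse(flip, fix[, "REF"], fix[, "ALT"])

  sites <- tibble::tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    major = major, minor = minor
  )
  samples <- colnames(gt)
  gm <- geno_matrix(dose, sites, samples)
  attr(gm, "n_multiallelic_skipped") <- n_skip

  if (any(grepl("\\bAD\\b", v@gt[, 1]))) {
    ad <- vcfR::extract.gt(v, element = "AD")
    if (is.null(dim(ad))) ad <- t(as.matrix(ad))
    if (!all(is.na(ad))) {
      split_ad <- function(k) {
        out <- matrix(0L, nrow(ad), ncol(ad))
        parts <- strsplit(ifelse(is.na(ad), "0,0", ad), ",", fixed = TRUE)
        vals <- vapply(parts, function(p) {
          as.integer(p[min(k, length(p))])
        }, integer(1))
        matrix(vals, nrow(ad), ncol(ad))
      }
      ref_d <- split_ad(1); alt_d <- split_ad(2)
      maj_d <- ref_d; min_d <- alt_d
      maj_d[flip, ] <- alt_d[flip, ]; min_d[flip, ] <- ref_d[flip, ]
      attr(gm, "depths") <- allele_depths(
        maj_d, min_d, matrix(0L, nrow(ad), ncol(ad)), sites, samples)
    }
  }
  gm
}

# vcfR drops the matrix shape for single-record files
get_fix_matrix <- function(v) {
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  fix
}

#' Write a genotype matrix (and optional depths) to VCF
#'
#' Writes plain-text VCF 4.2 with 1-based positions, the major allele as
#' REF and minor as ALT, FORMAT fields GT (and AD when depths are
#' supplied). Round-trips through [read_vcf()].
#'
#' @param genotypes a [geno_matrix()].
#' @param path output file.
#' @param depths optional [allele_depths()] aligned with `genotypes`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path, depths = NULL) {
  sites <- genotypes$sites
  g <- genotypes$geno
  gt <- matrix("./.", nrow(g), ncol(g))
  gt[!is.na(g) & g == 0L] <- "0/0"
  gt[!is.na(g) & g == 1L] <- "0/1"
  gt[!is.na(g) & g == 2L] <- "1/1"
  fmt <- "GT"
  if (!is.null(depths)) {
    gt <- matrix(paste0(gt, ":", depths$major, ",", depths$minor),
                 nrow(g), ncol(g))
    fmt <- "GT:AD"
  }
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(sites$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(depths)) {
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">"
    },
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", genotypes$samples), collapse = "\t")
  )
  body <- paste(
    sites$chrom, sites$pos, ".",
    sites$major %||% "A", sites$minor %||% "C",
    ".", "PASS", ".", fmt,
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
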