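#' Phenotypic variance explained by a set of trait-associated SNPs
#'
#' Fits the full linear model `Y = mu + sum_i beta_i x_i` over all TAS
#' dosages by least squares, giving `R2_full`; for each TAS `j` a reduced
#' model omitting `x_j` gives `R2_j`, and `PVE_j = R2_full - R2_j`.
#' Collinear TAS dosage columns are dropped with a warning before
#' fitting.
#'
#' @param tas_geno numeric matrix of TAS dosages (samples x TASs, named
#'   columns) or a [geno_matrix()] restricted to the TAS set (sites
#'   become columns).
#' @param trait numeric response.
#' @return A list of class `pve_result`: `r2_full` (joint PVE), `per_tas`
#'   tibble (`tas`, `r2_reduced`, `pve`), `dropped` (collinear columns).
#' @export
pve <- function(tas_geno, trait) {
  x <- if (inherits(tas_geno, "geno_matrix")) {
    m <- t(tas_geno$geno)
    colnames(m) <- paste0(tas_geno$sites$chrom, ":", tas_geno$sites$pos)
    m
  } else as.matrix(tas_geno)
  if (is.null(colnames(x))) colnames(x) <- paste0("tas", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(trait))
  if (ncol(x) >= nrow(x)) stop("more TASs than samples", call. = FALSE)
  qx <- qr(cbind(1, x))
  dropped <- character(0)
  if (qx$rank < ncol(x) + 1) {
    keep <- sort(setdiff(qx$pivot[seq_len(qx$rank)], 1L)) - 1L
    dropped <- colnames(x)[-keep]
    warning("dropping collinear TAS column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  r2 <- function(design) {
    f <- stats::lm.fit(cbind(1, design), trait)
    1 - sum(f$residuals^2) / sum((trait - mean(trait))^2)
  }
  r2_full <- r2(x)
  r2_red <- vapply(seq_len(ncol(x)),
                   function(j) r2(x[, -j, drop = FALSE]), numeric(1))
  structure(
    list(r2_full = r2_full,
         per_tas = tibble::tibble(tas = colnames(x),
                                  r2_reduced = r2_red,
                                  pve = r2_full - r2_red),
         dropped = dropped),
    class = "pve_result"
  )
}

#' @export
print.pve_result <- function(x, ...) {
  cat(sprintf("<pve_result> joint R2 = %.3f over %d TASs\n",
              x$r2_full, nrow(x$per_tas)))
  invisible(x)
}

#' Homozygote-contrast allele effect at a trait-associated SNP
#'
#' Compares mean trait values between the two homozygote classes (codes
#' 0 and 2) with a Welch t-test; heterozygotes are excluded. Classes with
#' fewer than two members are flagged not-estimable (means and counts are
#' still reported).
#'
#' @param genotypes a [geno_matrix()].
#' @param trait numeric trait values (one per sample).
#' @param chrom,pos coordinates of the TAS.
#' @param sample_mask optional logical/integer subset (e.g. one
#'   subpopulation).
#' @param group,location labels copied into the output row.
#' @return A one-row tibble: class means and counts, `diff` (mean of
#'   code-2 minus code-0 class, trait units), `t`, `p`, `direction`
#'   (sign of `diff`), `estimable`.
#' @export
allele_contrast <- function(genotypes, trait, chrom, pos,
                            sample_mask = NULL, group = NA_character_,
                            location = NA_character_) {
  s <- which(genotypes$sites$chrom == chrom & genotypes$sites$pos == pos)
  if (length(s) != 1) stop("TAS ", chrom, ":", pos, " not found",
                           call. = FALSE)
  g <- genotypes$geno[s, ]
  if (!is.null(sample_mask)) {
    g <- g[sample_mask]; trait <- trait[sample_mask]
  }
  ok <- !is.na(g) & !is.na(trait)
  y0 <- trait[ok & g == 0L]; y2 <- trait[ok & g == 2L]
  estimable <- length(y0) >= 2 && length(y2) >= 2
  tt <- if (estimable && (stats::sd(y0) > 0 || stats::sd(y2) > 0)) {
    stats::t.test(y2, y0)
  } else NULL
  d <- mean(y2) - mean(y0)
  tibble::tibble(
    chrom = chrom, pos = pos, group = group, location = location,
    mean_hom_major = mean(y0), n_hom_major = length(y0),
    mean_hom_minor = mean(y2), n_hom_minor = length(y2),
    diff = d,
    t = if (!is.null(tt)) unname(tt$statistic) else NA_real_,
    p = if (!is.null(tt)) tt$p.value else NA_real_,
    direction = sign(d),
    estimable = estimable
  )
}

#' Early-allele stacking score
#'
#' Number of trait-associated SNPs at which a sample is homozygous for
#' the designated early allele (heterozygotes contribute `het_weight`,
#' default 0.5). When a trait is supplied, the Pearson correlation
#' between score and trait is attached.
#'
#' @param genotypes a [geno_matrix()].
#' @param tas tibble with columns `chrom`, `pos`, `early_code` (0 or 2:
#'   the homozygote code of the early allele at that TAS).
#' @param trait optional numeric trait.
#' @param het_weight contribution of a heterozygous call.
#' @return A tibble (`sample_id`, `score`); attributes `cor` and `cor_p`
#'   when a trait is given (NA with an `undefined` flag for an empty TAS
#'   set or zero-variance score).
#' @export
early_allele_score <- function(genotypes, tas, trait = NULL,
                               het_weight = 0.5) {
  score <- rep(0, ncol(genotypes$geno))
  for (r in seq_len(nrow(tas))) {
    s <- which(genotypes$sites$chrom == tas$chrom[r] &
                 genotypes$sites$pos == tas$pos[r])
    if (length(s) != 1) stop("TAS ", tas$chrom[r], ":", tas$pos[r],
                             " not found", call. = FALSE)
    g <- genotypes$geno[s, ]
    score <- score + (g == tas$early_code[r]) * 1 +
      (g == 1L) * het_weight
  }
  out <- tibble::tibble(sample_id = genotypes$samples, score = score)
  if (!is.null(trait)) {
    if (nrow(tas) == 0 || stats::sd(score) == 0) {
      attr(out, "cor") <- NA_real_
      attr(out, "cor_p") <- NA_real_
      attr(out, "undefined") <- TRUE
    } else {
      ct <- stats::cor.test(score, trait)
      attr(out, "cor") <- unname(ct$estimate)
      attr(out, "cor_p") <- ct$p.value
      attr(out, "undefined") <- FALSE
    }
  }
  out
}

#' Designate the early allele at each TAS
#'
#' The early allele is the one whose homozygote class has the smaller
#' mean trait value (earlier flowering) in the discovery data.
#'
#' @param genotypes a [geno_matrix()].
#' @param trait numeric trait values.
#' @param tas tibble with `chrom`, `pos`.
#' @return `tas` with an `early_code` column (0 or 2).
#' @export
designate_early_allele <- function(genotypes, trait, tas) {
  ec <- vapply(seq_len(nrow(tas)), function(r) {
    s <- which(genotypes$sites$chrom == tas$chrom[r] &
                 genotypes$sites$pos == tas$pos[r])
    g <- genotypes$geno[s, ]
    m0 <- mean(trait[g == 0L], na.rm = TRUE)
    m2 <- mean(trait[g == 2L], na.rm = TRUE)
    if (isTRUE(m2 < m0)) 2L else 0L
  }, integer(1))
  dplyr::mutate(tas, early_code = ec)
}

#' Overlap of LD blocks with candidate intervals
#'
#' Closed-interval overlap on 1-based coordinates between TAS LD blocks
#' and a table of candidate gene/QTL intervals; for non-overlapping
#' pairs on the same chromosome the gap distance is reported
#' (adjacent intervals, e.g. block ending at 200 and interval starting
#' at 201, have distance 1).
#'
#' @param blocks tibble from [ld_block()] (`chrom`, `focal_pos`, `start`,
#'   `end`).
#' @param intervals tibble (`chrom`, `start`, `end`, `name`).
#' @return A tibble with one row per block-interval pair on a shared
#'   chromosome: `overlaps` (logical) and `distance_bp` (0 when
#'   overlapping).
#' @export
interval_overlap <- function(blocks, intervals) {
  dplyr::inner_join(
    dplyr::rename(blocks, block_start = "start", block_end = "end"),
    dplyr::rename(intervals, iv_start = "start", iv_end = "end"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      overlaps = .data$block_start <= .data$iv_end &
        .data$iv_start <= .data$block_end,
      distance_bp = ifelse(.data$overlaps, 0L,
                           pmax(.data$iv_start - .data$block_end,
                                .data$block_start - .data$iv_end))
    )
}
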