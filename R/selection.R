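#' Domestication selection scan at trait-associated SNPs
#'
#' A TAS is flagged as carrying a domestication signal when (i) its
#' wild-vs-landrace per-SNP Weir-Cockerham Fst exceeds the genome-wide
#' empirical quantile `fst_quantile` (default 0.95) and (ii) the
#' landrace frequency of the focal (minor-coded) allele differs from the
#' wild frequency by at least `min_delta` (default 0.1). Both criteria
#' are recorded in the output.
#'
#' @param genotypes a [geno_matrix()] over the full panel.
#' @param wild_mask,landrace_mask logical/integer sample selectors;
#'   both must be non-empty.
#' @param tas tibble with columns `chrom`, `pos` (all must exist in the
#'   genotype matrix).
#' @param fst_quantile genome-wide Fst quantile for criterion (i).
#' @param min_delta minimum absolute allele-frequency change.
#' @return A tibble per TAS: `fst_wl`, `fst_cutoff`, `freq_wild`,
#'   `freq_landrace`, `delta`, `domestication_selected`.
#' @export
domestication_scan <- function(genotypes, wild_mask, landrace_mask, tas,
                               fst_quantile = 0.95, min_delta = 0.1) {
  wl <- selector_to_logical(wild_mask, ncol(genotypes$geno))
  lm_ <- selector_to_logical(landrace_mask, ncol(genotypes$geno))
  if (!any(wl) || !any(lm_)) stop("both masks must be non-empty",
                                  call. = FALSE)
  grp <- ifelse(wl, "WILD", ifelse(lm_, "LANDRACE", NA))
  fst <- wc_fst(genotypes[, wl | lm_], grp[wl | lm_],
                labels = c("WILD", "LANDRACE"))
  cutoff <- stats::quantile(fst$per_snp$fst[is.finite(fst$per_snp$fst)],
                            fst_quantile, names = FALSE)
  idx <- match_tas(genotypes, tas)
  freq <- function(mask) {
    g <- genotypes$geno[idx, mask, drop = FALSE]
    rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
  }
  fw <- freq(wl); fl <- freq(lm_)
  tibble::tibble(
    chrom = tas$chrom, pos = tas$pos,
    fst_wl = fst$per_snp$fst[idx], fst_cutoff = cutoff,
    freq_wild = fw, freq_landrace = fl, delta = fl - fw,
    domestication_selected = is.finite(fst$per_snp$fst[idx]) &
      fst$per_snp$fst[idx] > cutoff & abs(fl - fw) >= min_delta
  )
}

#' Diversification selection scan among landrace subpopulations
#'
#' A TAS is flagged when any pairwise subpopulation Fst exceeds that
#' pair's genome-wide empirical quantile. For each TAS the
#' subpopulations where the minor allele is rare (within-group MAF below
#' `maf_threshold`, default 0.05) are listed as `subpop_specific`
#' (geographically constrained alleles).
#'
#' @param genotypes a [geno_matrix()].
#' @param groups per-sample subpopulation labels (samples with other
#'   labels, e.g. MIXED or WILD, are ignored).
#' @param tas tibble with `chrom`, `pos`.
#' @param subpops labels to compare (default the landrace trio).
#' @param fst_quantile per-pair genome-wide quantile.
#' @param maf_threshold within-group MAF cutoff for subpopulation
#'   specificity.
#' @return A tibble per TAS: per-pair Fst columns, per-group MAF
#'   columns, `diversification_selected`, `subpop_specific`
#'   (list-column of group labels).
#' @export
diversification_scan <- function(genotypes, groups, tas,
                                 subpops = c("NR", "HR", "SR"),
                                 fst_quantile = 0.95,
                                 maf_threshold = 0.05) {
  idx <- match_tas(genotypes, tas)
  out <- tibble::tibble(chrom = tas$chrom, pos = tas$pos)
  exceed <- matrix(FALSE, nrow(tas), 0)
  pairs <- utils::combn(subpops, 2, simplify = FALSE)
  for (pr in pairs) {
    fst <- wc_fst(genotypes[, groups %in% pr], groups[groups %in% pr],
                  labels = pr)
    vals <- fst$per_snp$fst
    cutoff <- stats::quantile(vals[is.finite(vals)], fst_quantile,
                              names = FALSE)
    nm <- paste0("fst_", pr[1], "_", pr[2])
    out[[nm]] <- vals[idx]
    exceed <- cbind(exceed, is.finite(vals[idx]) & vals[idx] > cutoff)
  }
  maf_by_group <- vapply(subpops, function(g2) {
    gg <- genotypes$geno[idx, groups == g2, drop = FALSE]
    f <- rowSums(gg, na.rm = TRUE) / (2 * rowSums(!is.na(gg)))
    pmin(f, 1 - f)
  }, numeric(nrow(tas)))
  maf_by_group <- matrix(maf_by_group, nrow = nrow(tas),
                         dimnames = list(NULL, subpops))
  for (g2 in subpops) out[[paste0("maf_", g2)]] <- maf_by_group[, g2]
  out$diversification_selected <- rowSums(exceed) > 0
  out$subpop_specific <- lapply(seq_len(nrow(tas)), function(r) {
    subpops[maf_by_group[r, ] < maf_threshold]
  })
  out
}

#' Classify selection history of trait-associated SNPs
#'
#' Combines the domestication and diversification flags into the
#' four-way category `both` / `domestication_only` /
#' `diversification_only` / `none`, with a count table.
#'
#' @param domestication logical vector (or [domestication_scan()]
#'   output).
#' @param diversification logical vector (or [diversification_scan()]
#'   output) of the same length.
#' @return A list of class `selection_report`: `per_tas` tibble
#'   (`domestication_selected`, `diversification_selected`, `category`)
#'   and `counts` (named integer table over the four categories).
#' @export
classify_selection <- function(domestication, diversification) {
  dom <- if (is.data.frame(domestication)) {
    domestication$domestication_selected
  } else domestication
  div <- if (is.data.frame(diversification)) {
    diversification$diversification_selected
  } else diversification
  stopifnot(length(dom) == length(div))
  category <- dplyr::case_when(
    dom & div ~ "both",
    dom & !div ~ "domestication_only",
    !dom & div ~ "diversification_only",
    .default = "none"
  )
  lev <- c("both", "domestication_only", "diversification_only", "none")
  per_tas <- tibble::tibble(
    domestication_selected = dom, diversification_selected = div,
    category = factor(category, levels = lev)
  )
  if (is.data.frame(domestication) &&
      all(c("chrom", "pos") %in% names(domestication))) {
    per_tas <- dplyr::bind_cols(
      dplyr::select(domestication, "chrom", "pos"), per_tas)
  }
  structure(list(per_tas = per_tas, counts = table(per_tas$category)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  print(x$counts)
  invisible(x)
}

match_tas <- function(genotypes, tas) {
  key_g <- paste(genotypes$sites$chrom, genotypes$sites$pos)
  idx <- match(paste(tas$chrom, tas$pos), key_g)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))
    stop("TAS not in genotype matrix: ",
         paste(tas$chrom[miss], tas$pos[miss], sep = ":",
               collapse = ", "), call. = FALSE)
  }
  idx
}

selector_to_logical <- function(mask, n) {
  if (is.logical(mask)) {
    stopifnot(length(mask) == n)
    mask
  } else {
    out <- rep(FALSE, n); out[mask] <- TRUE; out
  }
}
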