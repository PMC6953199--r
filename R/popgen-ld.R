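#' Pairwise genotype r-squared within a distance limit
#'
#' Composite (genotype-level) LD: squared Pearson correlation of dosage
#' vectors for every intra-chromosome pair of SNPs separated by at most
#' `max_distance_bp`. Sites are pre-filtered to MAF >= `maf_min`.
#'
#' @param genotypes a [geno_matrix()] (complete genotypes).
#' @param max_distance_bp maximum pair separation (default 1e6).
#' @param maf_min MAF threshold (default 0.01).
#' @return A tibble (`chrom`, `pos1`, `pos2`, `dist_bp`, `r2`).
#' @export
ld_r2 <- function(genotypes, max_distance_bp = 1e6, maf_min = 0.01) {
  st <- site_stats(genotypes)
  keep <- !is.na(st$maf) & st$maf >= maf_min
  gm <- genotypes[keep, ]
  out <- lapply(unique(gm$sites$chrom), function(ch) {
    idx <- which(gm$sites$chrom == ch)
    if (length(idx) < 2) return(NULL)
    pos <- gm$sites$pos[idx]
    cc <- suppressWarnings(stats::cor(t(gm$geno[idx, , drop = FALSE])))
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    d <- pos[pr[, 2]] - pos[pr[, 1]]
    ok <- d <= max_distance_bp
    tibble::tibble(chrom = ch, pos1 = pos[pr[ok, 1]],
                   pos2 = pos[pr[ok, 2]], dist_bp = d[ok],
                   r2 = cc[pr[ok, , drop = FALSE]]^2)
  })
  dplyr::bind_rows(out)
}

#' LD decay profile and half-maximum distance
#'
#' Bins SNP pairs into 1-kb distance windows (0-1 kb up to 999-1000 kb by
#' default), averages r-squared per bin, optionally applies decreasing
#' isotonic smoothing, and reports the half-maximum decay distance: the
#' smallest bin midpoint at which the (smoothed) mean r-squared has
#' declined to one half of its maximum observed value. A profile that
#' never reaches half its maximum reports `NA` with
#' `half_max_reached = FALSE`.
#'
#' @param pairs tibble from [ld_r2()] (needs `dist_bp`, `r2`).
#' @param bin_width_bp bin width (default 1000).
#' @param max_distance_bp profile extent (default 1e6).
#' @param smooth apply isotonic (monotone nonincreasing) smoothing before
#'   locating the half-maximum (default TRUE; recorded in the result).
#' @return A list of class `ld_profile`: `bins` tibble (`bin_start`,
#'   `bin_end`, `mid_bp`, `mean_r2`, `smoothed_r2`, `n_pairs`),
#'   `half_max_bp`, `half_max_reached`, `smoothed` flag.
#' @export
ld_decay_profile <- function(pairs, bin_width_bp = 1000,
                             max_distance_bp = 1e6, smooth = TRUE) {
  stopifnot(all(c("dist_bp", "r2") %in% names(pairs)))
  pairs <- pairs[pairs$dist_bp >= 0 & pairs$dist_bp <= max_distance_bp &
                   is.finite(pairs$r2), ]
  if (nrow(pairs) == 0) stop("no usable pairs", call. = FALSE)
  bin <- pmin(pairs$dist_bp %/% bin_width_bp,
              max_distance_bp / bin_width_bp - 1)
  bins <- tibble::tibble(bin = bin, r2 = pairs$r2) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$bin) |>
    dplyr::mutate(bin_start = .data$bin * bin_width_bp,
                  bin_end = (.data$bin + 1) * bin_width_bp,
                  mid_bp = .data$bin_start + bin_width_bp / 2)
  sm <- if (smooth && nrow(bins) > 1) {
    -stats::isoreg(bins$mid_bp, -bins$mean_r2)$yf
  } else bins$mean_r2
  bins$smoothed_r2 <- sm
  half <- max(sm) / 2
  at <- which(sm <= half)
  reached <- length(at) > 0
  structure(
    list(bins = dplyr::select(bins, "bin_start", "bin_end", "mid_bp",
                              "mean_r2", "smoothed_r2", "n_pairs"),
         half_max_bp = if (reached) bins$mid_bp[min(at)] else NA_real_,
         half_max_reached = reached, smoothed = smooth,
         bin_width_bp = bin_width_bp),
    class = "ld_profile"
  )
}

#' @export
print.ld_profile <- function(x, ...) {
  cat(sprintf("<ld_profile> %d bins; half-max distance: %s\n",
              nrow(x$bins),
              if (x$half_max_reached) {
                sprintf("%.1f kb", x$half_max_bp / 1000)
              } else "not reached"))
  invisible(x)
}

#' LD block around a focal SNP
#'
#' The block is bounded on each side by the farthest SNP within
#' `context_bp` (default 1 Mb) whose genotype r-squared with the focal
#' SNP is at least `r2_min` (default 0.8); a side with no such SNP
#' collapses to the focal position.
#'
#' @param genotypes a [geno_matrix()].
#' @param chrom,pos focal SNP coordinates (must exist in the matrix).
#' @param r2_min r-squared threshold (default 0.8).
#' @param context_bp context half-width (default 1e6).
#' @return A one-row tibble (`chrom`, `focal_pos`, `start`, `end`,
#'   `n_members`).
#' @export
ld_block <- function(genotypes, chrom, pos, r2_min = 0.8,
                     context_bp = 1e6) {
  sites <- genotypes$sites
  focal <- which(sites$chrom == chrom & sites$pos == pos)
  if (length(focal) != 1) {
    stop("focal SNP ", chrom, ":", pos, " not found", call. = FALSE)
  }
  ctx <- which(sites$chrom == chrom &
                 abs(sites$pos - pos) <= context_bp)
  ctx <- setdiff(ctx, focal)
  if (length(ctx)) {
    r2 <- suppressWarnings(
      stats::cor(genotypes$geno[focal, ],
                 t(genotypes$geno[ctx, , drop = FALSE]))[1, ])^2
    linked <- ctx[!is.na(r2) & r2 >= r2_min]
  } else linked <- integer(0)
  left <- linked[sites$pos[linked] < pos]
  right <- linked[sites$pos[linked] > pos]
  tibble::tibble(
    chrom = chrom, focal_pos = pos,
    start = if (length(left)) min(sites$pos[left]) else pos,
    end = if (length(right)) max(sites$pos[right]) else pos,
    n_members = length(linked) + 1L
  )
}
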