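#' Weir-Cockerham Fst
#'
#' Per-SNP variance-components estimator of differentiation (Weir &
#' Cockerham 1984) including the heterozygosity terms, for two or more
#' groups. Per site, with `r` groups of `n_i` called individuals, allele
#' frequencies `p_i` and observed heterozygosity `h_i`, the components
#' `a` (among groups), `b` (among individuals within groups) and `c`
#' (within individuals) give per-SNP Fst `a / (a + b + c)`; the
#' genome-wide estimate is the ratio of summed numerators over summed
#' denominators; windowed values are means of per-SNP estimates in
#' tiling windows.
#'
#' Sites contribute only when every group has at least two called
#' individuals and the site is polymorphic overall.
#'
#' @param genotypes a [geno_matrix()].
#' @param groups character/factor of group membership per sample; use
#'   `labels` to restrict to two (or more) groups.
#' @param labels which group labels to compare (default: all present).
#' @param window_bp window length for windowed means (default 30000).
#' @return A list of class `fst_result`: `per_snp` tibble (`chrom`,
#'   `pos`, `fst`), `windows` tibble (`chrom`, `start`, `end`, `n_snps`,
#'   `mean_fst`), `overall` (ratio-of-sums estimate).
#' @export
wc_fst <- function(genotypes, groups, labels = NULL, window_bp = 30000) {
  stopifnot(inherits(genotypes, "geno_matrix"),
            length(groups) == ncol(genotypes$geno))
  if (is.null(labels)) labels <- unique(as.character(groups))
  keep <- groups %in% labels
  empty <- labels[!labels %in% groups]
  if (length(empty)) stop("empty group(s): ",
                          paste(empty, collapse = ", "), call. = FALSE)
  g <- genotypes$geno[, keep, drop = FALSE]
  grp <- factor(as.character(groups[keep]), levels = labels)
  comp <- wc_components(g, grp)
  fst <- comp$a / (comp$a + comp$b + comp$c)
  per_snp <- dplyr::mutate(
    dplyr::select(genotypes$sites, "chrom", "pos"), fst = fst)

  denom <- comp$a + comp$b + comp$c
  usable <- is.finite(comp$a) & is.finite(denom)
  overall <- sum(comp$a[usable]) / sum(denom[usable])

  windows <- per_snp |>
    dplyr::filter(is.finite(.data$fst)) |>
    dplyr::mutate(start = (.data$pos - 1) %/% window_bp * window_bp + 1) |>
    dplyr::group_by(.data$chrom, .data$start) |>
    dplyr::summarise(n_snps = dplyr::n(), mean_fst = mean(.data$fst),
                     .groups = "drop") |>
    dplyr::mutate(end = .data$start + window_bp - 1, .after = "start")

  structure(list(per_snp = per_snp, windows = windows, overall = overall,
                 labels = labels, window_bp = window_bp),
            class = "fst_result")
}

# Per-site WC84 variance components a, b, c across groups (matrix form).
wc_components <- function(g, grp) {
  r <- nlevels(grp)
  lv <- levels(grp)
  m <- nrow(g)
  n_i <- p_i <- h_i <- matrix(NA_real_, m, r)
  for (j in seq_len(r)) {
    gj <- g[, grp == lv[j], drop = FALSE]
    called <- !is.na(gj)
    n_i[, j] <- rowSums(called)
    p_i[, j] <- rowSums(gj, na.rm = TRUE) / (2 * n_i[, j])
    h_i[, j] <- rowSums(gj == 1L, na.rm = TRUE) / n_i[, j]
  }
  ok <- rowSums(n_i >= 2) == r
  nbar <- rowMeans(n_i)
  nsum <- rowSums(n_i)
  nc <- (nsum - rowSums(n_i^2) / nsum) / (r - 1)
  pbar <- rowSums(n_i * p_i) / nsum
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  bad <- !ok | !poly
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf(
    "<fst_result> %s: genome-wide Fst = %.4f (%d SNPs, %d windows)\n",
    paste(x$labels, collapse = " vs "), x$overall,
    sum(is.finite(x$per_snp$fst)), nrow(x$windows)))
  invisible(x)
}

#' Watterson's theta in sliding windows
#'
#' Per window, `theta_w = S / (a_{n-1} L)` where `S` is the number of
#' segregating sites in the window, `a_{n-1} = sum_{i=1}^{n-1} 1/i` with
#' `n` the allele count (2 x samples), and `L` the window length in bp,
#' giving a per-bp diversity comparable across windows. Sites are
#' pre-filtered to within-group MAF >= `maf_min`. Windows without SNPs
#' report 0.
#'
#' @param genotypes a [geno_matrix()] (complete; allele count is
#'   2 x sample count).
#' @param samples optional sample index/mask restricting to one group.
#' @param window_bp window length (default 1e6).
#' @param maf_min within-group MAF threshold for a site to be usable.
#' @return A tibble (`chrom`, `start`, `end`, `s`, `theta_w`) with
#'   attributes `mean_theta` and `central95` (the central 95% range of
#'   window values).
#' @export
watterson_theta <- function(genotypes, samples = NULL, window_bp = 1e6,
                            maf_min = 0.01) {
  gm <- if (is.null(samples)) genotypes else genotypes[, samples]
  st <- site_stats(gm)
  seg <- !is.na(st$maf) & st$maf >= maf_min & st$maf > 0
  n_alleles <- 2L * ncol(gm$geno)
  a_n <- sum(1 / seq_len(n_alleles - 1))
  grid <- gm$sites |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(max_pos = max(.data$pos), .groups = "drop")
  windows <- grid |>
    dplyr::rowwise() |>
    dplyr::reframe(chrom = .data$chrom,
                   start = seq(1, .data$max_pos, by = window_bp)) |>
    dplyr::mutate(end = .data$start + window_bp - 1)
  counts <- gm$sites[seg, ] |>
    dplyr::mutate(start = (.data$pos - 1) %/% window_bp * window_bp + 1) |>
    dplyr::count(.data$chrom, .data$start, name = "s")
  out <- windows |>
    dplyr::left_join(counts, by = c("chrom", "start")) |>
    dplyr::mutate(s = dplyr::coalesce(.data$s, 0L),
                  theta_w = .data$s / (a_n * window_bp))
  attr(out, "mean_theta") <- mean(out$theta_w)
  attr(out, "central95") <- stats::quantile(out$theta_w, c(0.025, 0.975),
                                            names = FALSE)
  out
}

#' Pst: phenotypic differentiation with bootstrap interval
#'
#' A Qst proxy from one-way ANOVA variance components:
#' \deqn{P_{st} = \frac{(c/h^2)\,\sigma^2_B}
#'   {(c/h^2)\,\sigma^2_B + 2\sigma^2_W}}
#' where the between-group component is `(MSB - MSW)/n0` (floored at 0,
#' `n0` the effective group size) and the within component is `MSW`.
#' `c` scales the proportion of between-group trait variance that is
#' additive, `h2` the within-group heritability; both default to 1 so
#' `c/h2 = 1`. The bootstrap resamples individuals within groups.
#'
#' @param trait numeric trait values.
#' @param groups group membership (2+ groups, each with >= 2 members).
#' @param c_scale,h2 scaling parameters.
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for resampling.
#' @param fst_mean optional mean pairwise Fst carried along for
#'   comparison with Pst.
#' @return A list of class `pst_result`: `estimate`, `ci` (length 2),
#'   `c_scale`, `h2`, `n_boot`, `fst_mean`, `boot` (replicate values).
#' @export
pst <- function(trait, groups, c_scale = 1, h2 = 1, n_boot = 1000L,
                conf = 0.95, seed = 1L, fst_mean = NULL) {
  ok <- !is.na(trait) & !is.na(groups)
  trait <- trait[ok]; groups <- factor(as.character(groups[ok]))
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 individuals; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  est <- pst_point(trait, groups, c_scale, h2)
  idx_by_group <- split(seq_along(trait), groups)
  boot <- with_op_seed(seed, "pst", {
    vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(idx_by_group, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      pst_point(trait[idx], groups[idx], c_scale, h2)
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  structure(
    list(estimate = est,
         ci = stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE),
         c_scale = c_scale, h2 = h2, n_boot = n_boot,
         fst_mean = fst_mean, boot = boot),
    class = "pst_result"
  )
}

pst_point <- function(trait, groups, c_scale, h2) {
  fit <- stats::aov(trait ~ groups)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  n_i <- table(groups); n <- sum(n_i); k <- length(n_i)
  n0 <- (n - sum(n_i^2) / n) / (k - 1)
  s2b <- max(0, (msb - msw) / n0)
  ratio <- c_scale / h2
  (ratio * s2b) / (ratio * s2b + 2 * msw)
}

#' @export
print.pst_result <- function(x, ...) {
  cat(sprintf("<pst_result> Pst = %.3f [%.3f, %.3f] (c/h2 = %.2f, %d boot)",
              x$estimate, x$ci[1], x$ci[2], x$c_scale / x$h2, x$n_boot))
  if (!is.null(x$fst_mean)) cat(sprintf("; mean Fst = %.3f", x$fst_mean))
  cat("\n")
  invisible(x)
}
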