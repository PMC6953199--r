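#' Impute missing genotypes
#'
#' Fills every missing cell so downstream matrix statistics see complete
#' data; non-missing calls are never altered. Two fillers are provided:
#'
#' * `"mode"` - each missing cell takes the site's most frequent called
#'   genotype (ties broken toward the smaller code);
#' * `"knn-haplotype"` - each missing cell is filled from the `k` samples
#'   nearest by allele-sharing distance over a local window of
#'   `window` sites centred on the focal site, taking the most frequent
#'   genotype among neighbours called at the site (falling back to the
#'   site mode when no neighbour is called). In high-LD data the local
#'   window makes neighbours share haplotype background, so this fill is
#'   more accurate than the marginal mode.
#'
#' @param genotypes a [geno_matrix()].
#' @param method `"mode"` or `"knn-haplotype"`.
#' @param k neighbour count for `"knn-haplotype"`.
#' @param window number of flanking sites on each side of the focal site
#'   used for the local distance.
#' @return A complete `geno_matrix`.
#' @export
impute_genotypes <- function(genotypes, method = c("mode", "knn-haplotype"),
                             k = 10L, window = 10L) {
  method <- match.arg(method)
  g <- genotypes$geno
  zero_call <- rowSums(!is.na(g)) == 0
  if (any(zero_call)) {
    stop("cannot impute site(s) with zero calls: ",
         paste(utils::head(which(zero_call), 10), collapse = ", "),
         call. = FALSE)
  }
  if (!anyNA(g)) return(genotypes)

  site_mode <- apply(g, 1, function(row) {
    tab <- tabulate(row + 1L, nbins = 3L)
    which.max(tab) - 1L   # ties -> smaller code
  })

  if (method == "mode") {
    miss <- which(is.na(g), arr.ind = TRUE)
    g[miss] <- site_mode[miss[, 1]]
  } else {
    miss_sites <- which(rowSums(is.na(g)) > 0)
    m <- nrow(g)
    for (s in miss_sites) {
      win <- max(1L, s - window):min(m, s + window)
      miss_cols <- which(is.na(g[s, ]))
      gw <- g[win, , drop = FALSE]
      for (j in miss_cols) {
        # allele-sharing distance to every other sample over the window
        diffs <- abs(gw - gw[, j])
        shared <- colMeans(2L - diffs, na.rm = TRUE)
        shared[j] <- -Inf
        callers <- which(!is.na(g[s, ]))
        nb <- callers[order(shared[callers], decreasing = TRUE)]
        nb <- utils::head(nb, k)
        if (length(nb) == 0) {
          g[s, j] <- site_mode[s]
        } else {
          tab <- tabulate(g[s, nb] + 1L, nbins = 3L)
          g[s, j] <- which.max(tab) - 1L
        }
      }
    }
  }
  geno_matrix(g, genotypes$sites, genotypes$samples)
}
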