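#' Single-marker least-squares association scan
#'
#' Per SNP, fits `trait ~ intercept + covariates + dosage` by least
#' squares and reports the dosage coefficient, its standard error and the
#' two-sided p-value from its t statistic. Implemented by projecting the
#' trait and every dosage column off the covariate space once
#' (Frisch-Waugh), so the scan is a single pass of vectorized algebra
#' with the correct residual degrees of freedom.
#'
#' SNPs collinear with the covariates (no residual dosage variance) are
#' flagged `not_estimable`.
#'
#' @param genotypes a complete [geno_matrix()].
#' @param trait numeric response (no missing values).
#' @param covariates optional numeric matrix/data frame; collinear
#'   covariate columns raise an error naming them.
#' @param trait_name label stored in the result.
#' @return A tibble of class `assoc_result` (`chrom`, `pos`, `maf`,
#'   `beta`, `se`, `p`, `not_estimable`) with attributes `trait`,
#'   `n_covariates`, `n`.
#' @export
scan_glm <- function(genotypes, trait, covariates = NULL,
                     trait_name = "trait") {
  g <- genotypes$geno
  stopifnot(!anyNA(g), length(trait) == ncol(g))
  if (anyNA(trait)) stop("trait must be complete", call. = FALSE)
  if (stats::sd(trait) == 0) stop("trait is constant", call. = FALSE)
  x <- cbind(`(Intercept)` = rep(1, length(trait)),
             if (!is.null(covariates)) as.matrix(covariates))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("collinear covariate column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- length(trait)
  df <- n - ncol(x) - 1
  y_r <- qr.resid(qx, trait)
  g_r <- t(qr.resid(qx, t(g)))   # residualize each SNP row
  sxx <- rowSums(g_r^2)
  sxy <- drop(g_r %*% y_r)
  est <- sxx > 1e-10 * n
  beta <- ifelse(est, sxy / sxx, NA_real_)
  rss <- sum(y_r^2) - ifelse(est, beta * sxy, 0)
  se <- ifelse(est, sqrt(pmax(rss, 0) / df / sxx), NA_real_)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  st <- site_stats(genotypes)
  out <- tibble::tibble(
    chrom = genotypes$sites$chrom, pos = genotypes$sites$pos,
    maf = st$maf, beta = beta, se = se,
    p = pmax(p, .Machine$double.xmin),
    not_estimable = !est
  )
  structure(out, class = c("assoc_result", class(out)),
            trait = trait_name,
            n_covariates = ncol(x) - 1L, n = n)
}

#' Bonferroni significance threshold
#'
#' `alpha / n_tests`, together with the one-significant-figure rounded
#' convention often quoted for genome scans (e.g. 0.01 / 99085 is quoted
#' as 1e-7).
#'
#' @param alpha family-wise error rate (default 0.01).
#' @param n_tests number of tests.
#' @return A list with `threshold` (exact) and `rounded` (one
#'   significant figure).
#' @export
#' @examples
#' bonferroni_threshold(0.01, 99085)
bonferroni_threshold <- function(alpha = 0.01, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  thr <- alpha / n_tests
  list(threshold = thr, rounded = signif(thr, 1))
}

#' QQ coordinates and genomic inflation factor
#'
#' Sorted expected-vs-observed -log10 p pairs for a QQ plot, plus the
#' genomic control inflation factor
#' `lambda_GC = median(qchisq(1 - p, 1)) / 0.4549364`.
#'
#' @param result an `assoc_result` (or anything with a `p` column).
#' @return A list of class `qq_result`: `points` tibble (`expected`,
#'   `observed` on the -log10 scale), `lambda_gc`, `low_confidence`
#'   (TRUE when fewer than 30 p-values contribute).
#' @export
qq_and_inflation <- function(result) {
  p <- result$p
  p <- p[is.finite(p) & p > 0 & p <= 1]
  if (!length(p)) stop("no usable p-values", call. = FALSE)
  m <- length(p)
  obs <- sort(p)
  expd <- (seq_len(m) - 0.5) / m
  lambda <- stats::median(stats::qchisq(obs, df = 1,
                                        lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  structure(
    list(points = tibble::tibble(expected = -log10(expd),
                                 observed = -log10(obs)),
         lambda_gc = lambda, low_confidence = m < 30),
    class = "qq_result"
  )
}
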