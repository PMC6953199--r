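# Independent, deliberately naive oracle implementations used to
# cross-check the package's vectorized code, plus small fixture builders.

toy_geno <- function(m = 30, n = 20, seed = 1, missing_rate = 0,
                     n_chrom = 2) {
  set.seed(seed)
  g <- matrix(sample(0:2, m * n, replace = TRUE,
                     prob = c(0.55, 0.2, 0.25)), m, n)
  if (missing_rate > 0) g[runif(m * n) < missing_rate] <- NA
  chrom <- sort(rep_len(sprintf("Chr%02d", seq_len(n_chrom)), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix) {
    sort(sample.int(1e6, length(ix)))
  }), use.names = FALSE)
  geno_matrix(g, tibble::tibble(chrom = chrom, pos = pos,
                                major = "A", minor = "C"),
              sprintf("T%03d", seq_len(n)))
}

# caller rules restated as one boolean predicate per clause
oracle_call <- function(a, b, o) {
  tot <- a + b + o
  # homozygous clause, allele with strictly more reads
  if (a != b) {
    hi <- max(a, b)
    if (hi >= 2 && hi >= 0.9 * tot) return(if (a > b) 0L else 2L)
  }
  # heterozygous clause
  if (a >= 1 && b >= 1 && a >= 0.2 * tot && b >= 0.2 * tot &&
      (a + b) >= 5 && (a + b) >= 0.9 * tot) return(1L)
  NA_integer_
}

# per-SNP Weir-Cockerham components, scalar loops (two or more groups)
oracle_wc_fst_site <- function(g_site, grp) {
  lv <- unique(grp)
  r <- length(lv)
  n_i <- p_i <- h_i <- numeric(r)
  for (j in seq_len(r)) {
    gj <- g_site[grp == lv[j]]
    gj <- gj[!is.na(gj)]
    n_i[j] <- length(gj)
    p_i[j] <- sum(gj) / (2 * length(gj))
    h_i[j] <- mean(gj == 1)
  }
  if (any(n_i < 2)) return(NA_real_)
  nbar <- mean(n_i); nsum <- sum(n_i)
  pbar <- sum(n_i * p_i) / nsum
  if (pbar <= 0 || pbar >= 1) return(NA_real_)
  nc <- (nsum - sum(n_i^2) / nsum) / (r - 1)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / nsum
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

oracle_relmat <- function(g) {
  p <- rowMeans(g) / 2
  keep <- p > 0 & p < 1
  g <- g[keep, , drop = FALSE]; p <- p[keep]
  n <- ncol(g); m <- nrow(g)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    k[i, j] <- sum((g[, i] - 2 * p) * (g[, j] - 2 * p) /
                     (2 * p * (1 - p))) / m
  }
  k
}

# per-SNP least squares via lm(), the slow reference for scan_glm
oracle_scan_glm <- function(gm, y, covar = NULL) {
  vapply(seq_len(nrow(gm$geno)), function(s) {
    df <- data.frame(y = y, x = gm$geno[s, ])
    if (!is.null(covar)) df <- cbind(df, as.data.frame(covar))
    fit <- stats::lm(y ~ ., data = df)
    co <- summary(fit)$coefficients
    if (!"x" %in% rownames(co)) return(c(NA, NA))
    co["x", c(1, 4)]
  }, numeric(2))
}

sim_two_group <- function(seed, fst, n = 150, m = 1000, ...) {
  args <- list(
    seed = seed, n_per_group = c(NR = as.integer(n), HR = as.integer(n)),
    n_snps = as.integer(m), n_chromosomes = 5L,
    fst_targets = tibble::tibble(group1 = "NR", group2 = "HR", fst = fst),
    n_causal = 2L)
  args <- utils::modifyList(args, list(...))
  simulate_genotypes(do.call(sim_config, args))
}
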