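#' Iterative fixed/random-model association scan
#'
#' A simplified fixed-and-random-model circulating scan in the FarmCPU
#' mould. Each iteration:
#'
#' 1. runs the fixed-effect single-marker scan ([scan_glm()]) with the
#'    current pseudo-QTNs included as covariates (pseudo-QTNs are not
#'    tested against themselves; they report the p-value from the
#'    iteration in which they were selected);
#' 2. nominates candidate pseudo-QTNs as the best SNP per physical bin,
#'    sweeping the bin sizes in `bin_sizes` and ranking the union by
#'    p-value (ties broken by genome order);
#' 3. prunes candidates whose dosage r-squared with an already-kept
#'    candidate reaches `r2_prune`, capping at `max_qtn`;
#' 4. accepts the candidate prefix that maximizes the restricted
#'    likelihood of the random-effect model whose kinship is built from
#'    the pseudo-QTN dosages (the empty prefix - no QTNs - competes too).
#'
#' Iteration stops when the accepted set repeats or `max_iter` is
#' reached (the latter flags non-convergence with a warning). With
#' `max_qtn = 0` the scan is identical to [scan_glm()]. The procedure is
#' deterministic given its inputs.
#'
#' @inheritParams scan_glm
#' @param bin_sizes physical bin widths (bp) swept when nominating
#'   candidates.
#' @param max_qtn maximum number of pseudo-QTNs (default 20).
#' @param max_iter maximum iterations (default 10).
#' @param r2_prune mutual r-squared above which candidates are pruned.
#' @param qtn_p_threshold nomination gate: only SNPs with a step-1
#'   p-value at or below this enter the candidate pool (default
#'   `0.01 / n_snps`). Because the random-model likelihood can only
#'   improve when markers are added, an unconditional candidate pool
#'   would accrete pseudo-QTNs even for a heritability-zero trait; the
#'   gate keeps the null case empty.
#' @return An `assoc_result` tibble as in [scan_glm()], with attributes
#'   `pseudo_qtns` (tibble of selected markers and their reported
#'   p-values), `converged`, `iterations`.
#' @export
scan_farmcpu <- function(genotypes, trait, covariates = NULL,
                         bin_sizes = c(1e5, 5e5, 1e6), max_qtn = 20L,
                         max_iter = 10L, r2_prune = 0.7,
                         qtn_p_threshold = NULL,
                         trait_name = "trait") {
  base_cov <- if (!is.null(covariates)) as.matrix(covariates)
  if (is.null(qtn_p_threshold)) {
    qtn_p_threshold <- 0.01 / nrow(genotypes$geno)
  }
  if (max_qtn == 0L) {
    out <- scan_glm(genotypes, trait, base_cov, trait_name)
    attr(out, "pseudo_qtns") <- tibble::tibble(
      chrom = character(), pos = integer(), p = numeric())
    attr(out, "converged") <- TRUE
    attr(out, "iterations") <- 1L
    return(out)
  }
  sites <- genotypes$sites
  g <- genotypes$geno
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  qtn_set <- integer(0)
  # selection-time statistics, named by site index
  qtn_p <- qtn_beta <- qtn_se <- numeric(0)
  converged <- FALSE
  x0 <- cbind(`(Intercept)` = rep(1, length(trait)), base_cov)
  scan <- NULL

  for (iter in seq_len(max_iter)) {
    cov_iter <- cbind(base_cov, qtn_covariates(g, qtn_set))
    scan <- scan_glm(genotypes, trait, cov_iter, trait_name)
    if (length(qtn_set)) {
      scan$p[qtn_set] <- qtn_p[as.character(qtn_set)]
      scan$not_estimable[qtn_set] <- FALSE
    }

    # candidate nomination: best SNP per bin, swept over bin sizes
    cand <- integer(0)
    for (bs in bin_sizes) {
      bin_id <- paste0(sites$chrom, "_", sites$pos %/% bs)
      ranked <- ord[order(scan$p[ord])]      # p, then genome order
      ranked <- ranked[!scan$not_estimable[ranked] &
                         is.finite(scan$p[ranked]) &
                         scan$p[ranked] <= qtn_p_threshold]
      best <- ranked[!duplicated(bin_id[ranked])]
      cand <- union(cand, best)
    }
    cand <- cand[order(scan$p[cand], match(cand, ord))]

    # prune by mutual LD, cap
    kept <- integer(0)
    for (s in cand) {
      if (length(kept) >= max_qtn) break
      if (length(kept)) {
        r2 <- suppressWarnings(
          stats::cor(g[s, ], t(g[kept, , drop = FALSE]))[1, ])^2
        if (any(r2 >= r2_prune, na.rm = TRUE)) next
      }
      kept <- c(kept, s)
    }

    # accepted set: likelihood-optimal prefix (0..length(kept))
    ll <- vapply(0:length(kept), function(s) {
      z <- if (s == 0) NULL else t(g[kept[seq_len(s)], , drop = FALSE])
      reml_loglik_lowrank(trait, x0, z)
    }, numeric(1))
    new_set <- kept[seq_len(which.max(ll) - 1L)]

    newly <- setdiff(new_set, qtn_set)
    if (length(newly)) {
      key <- as.character(newly)
      qtn_p[key] <- scan$p[newly]
      qtn_beta[key] <- scan$beta[newly]
      qtn_se[key] <- scan$se[newly]
    }
    keep_key <- as.character(new_set)
    qtn_p <- qtn_p[keep_key]
    qtn_beta <- qtn_beta[keep_key]
    qtn_se <- qtn_se[keep_key]
    if (setequal(new_set, qtn_set)) {
      qtn_set <- new_set
      converged <- TRUE
      break
    }
    qtn_set <- new_set
  }
  if (!converged) {
    warning("pseudo-QTN set did not stabilize within ", max_iter,
            " iterations")
  }
  if (length(qtn_set)) {
    key <- as.character(qtn_set)
    scan$p[qtn_set] <- qtn_p[key]
    scan$beta[qtn_set] <- qtn_beta[key]
    scan$se[qtn_set] <- qtn_se[key]
    scan$not_estimable[qtn_set] <- FALSE
  }
  attr(scan, "pseudo_qtns") <- tibble::tibble(
    chrom = sites$chrom[qtn_set], pos = sites$pos[qtn_set],
    p = unname(qtn_p[as.character(qtn_set)]))
  attr(scan, "converged") <- converged
  attr(scan, "iterations") <- iter
  scan
}

# Pseudo-QTN dosage columns, dropping any collinear with already-included
# columns so the fixed-effect scan never sees a rank-deficient design.
qtn_covariates <- function(g, qtn_set) {
  if (!length(qtn_set)) return(NULL)
  z <- t(g[qtn_set, , drop = FALSE])
  colnames(z) <- paste0("qtn_", qtn_set)
  qz <- qr(cbind(1, z))
  if (qz$rank < ncol(z) + 1) {
    keep <- sort(setdiff(qz$pivot[seq_len(qz$rank)], 1L)) - 1L
    z <- z[, keep, drop = FALSE]
  }
  z
}
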