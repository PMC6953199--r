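#' Simulate structured genotypes with distance-decaying LD
#'
#' Generates a complete (no-missing) genotype panel for the configured
#' groups. Per site, an ancestral allele frequency is drawn uniform on
#' (0.05, 0.95) and each group's frequency from the Balding-Nichols beta
#' distribution `Beta(p(1-F)/F, (1-p)(1-F)/F)`, with the group-level F
#' calibrated from the pairwise Fst targets (expected pairwise
#' Weir-Cockerham Fst between groups i and j is `(F_i + F_j)/2`).
#'
#' Haplotypes are built by a marginal-preserving first-order dependence
#' process along each chromosome: a latent Gaussian AR(1) with correlation
#' `exp(-d / ld_copy_decay_bp)` between adjacent sites at distance `d` is
#' thresholded at each site's group frequency. Marginals are therefore
#' exactly Balding-Nichols (so differentiation calibration is exact) while
#' genotype r-squared decays with physical distance. The wild group uses a
#' shorter dependence scale (`wild_ld_frac`), reproducing the faster LD
#' decay of wild panels.
#'
#' Genotypes are returned oriented so that code 2 counts the panel-wide
#' minor allele. Causal loci and their additive effects (days per minor
#' allele) are drawn here and carried in the truth set.
#'
#' @param config a [sim_config()].
#' @return A list with elements `genotypes` (a [geno_matrix()]) and
#'   `truth` (class `truth_set`: `causal_indices`, `causal_effects`,
#'   `true_genotypes`, `true_group`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  groups <- names(config$n_per_group)[config$n_per_group > 0]
  n_per <- config$n_per_group[groups]
  f_group <- group_f_from_targets(groups, config$fst_targets)
  m <- config$n_snps
  nc <- config$n_chromosomes

  with_op_seed(config$seed, "simulate_genotypes", {
    # site map: positions unique, sorted within chromosome
    m_per_chrom <- rep(m %/% nc, nc) + c(rep(1L, m %% nc), rep(0L, nc - m %% nc))
    chrom <- rep(sprintf("Chr%02d", seq_len(nc)), m_per_chrom)
    pos <- unlist(lapply(m_per_chrom, function(k) {
      sort(sample.int(config$chrom_length_bp, k))
    }), use.names = FALSE)

    p_anc <- stats::runif(m, 0.05, 0.95)
    bases <- c("A", "C", "G", "T")
    maj <- sample(bases, m, replace = TRUE)
    mnr <- vapply(maj, function(b) sample(setdiff(bases, b), 1), character(1))

    dose <- matrix(0L, m, sum(n_per))
    grp_of <- rep(groups, n_per)
    col0 <- 0L
    for (g in groups) {
      fg <- f_group[[g]]
      p_g <- if (fg > 0) {
        stats::rbeta(m, p_anc * (1 - fg) / fg, (1 - p_anc) * (1 - fg) / fg)
      } else p_anc
      p_g <- pmin(pmax(p_g, 1e-4), 1 - 1e-4)
      delta <- config$ld_copy_decay_bp *
        if (g == "WILD") config$wild_ld_frac else 1
      n_hap <- 2L * n_per[[g]]
      hap <- matrix(0L, m, n_hap)
      for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        mc <- length(idx)
        z <- matrix(0, n_hap, mc)
        z[, 1] <- stats::rnorm(n_hap)
        if (mc > 1) {
          gaps <- diff(pos[idx])
          rho <- if (delta > 0) exp(-gaps / delta) else rep(0, mc - 1)
          for (s in 2:mc) {
            z[, s] <- rho[s - 1] * z[, s - 1] +
              sqrt(1 - rho[s - 1]^2) * stats::rnorm(n_hap)
          }
        }
        thr <- matrix(p_g[idx], n_hap, mc, byrow = TRUE)
        hap[idx, ] <- t(stats::pnorm(z) < thr) * 1L
      }
      cols <- col0 + seq_len(n_per[[g]])
      h1 <- hap[, seq(1, n_hap, by = 2), drop = FALSE]
      h2 <- hap[, seq(2, n_hap, by = 2), drop = FALSE]
      # selfing: an `inbreeding` fraction of accessions is autozygous
      auto <- stats::runif(n_per[[g]]) < config$inbreeding
      h2[, auto] <- h1[, auto]
      dose[, cols] <- h1 + h2
      col0 <- col0 + n_per[[g]]
    }

    # orient so code 2 is the panel-wide minor allele
    f1 <- rowMeans(dose) / 2
    flip <- f1 > 0.5
    dose[flip, ] <- 2L - dose[flip, ]
    swap <- maj[flip]
    maj[flip] <- mnr[flip]
    mnr[flip] <- swap

    sites <- tibble::tibble(chrom = chrom, pos = pos,
                            major = maj, minor = mnr)
    samples <- sprintf("S%04d", seq_len(ncol(dose)))
    gm <- geno_matrix(dose, sites, samples)

    causal <- sort(sample.int(m, config$n_causal))
    effects <- stats::rnorm(config$n_causal, 0, config$effect_sd)
    truth <- structure(
      list(causal_indices = causal, causal_effects = effects,
           true_genotypes = gm, true_group = grp_of),
      class = "truth_set"
    )
    list(genotypes = gm, truth = truth)
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d causal loci, %d samples (%s)\n",
              length(x$causal_indices), length(x$true_group),
              paste(names(table(x$true_group)), table(x$true_group),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
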