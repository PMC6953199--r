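#' Simulate flowering-time phenotypes at two locations
#'
#' Phenotype at each location is
#' `intercept + location offset + genetic value + residual`, where the
#' genetic value is the additive sum of causal effects times minor-allele
#' dosage and is shared between locations (no genotype-by-environment
#' interaction). Residual variance is set so the additive heritability at
#' each location equals `h2_target`; residuals at the two locations are
#' correlated `resid_cor` (shared non-genetic plasticity), so the expected
#' between-location phenotype correlation is
#' `h2 + (1 - h2) * resid_cor`.
#'
#' @param truth a `truth_set` from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @return A tibble (`sample_id`, `FT_loc1`, `FT_loc2`), days.
#' @export
simulate_phenotypes <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  if (config$h2_target <= 0 || config$h2_target >= 1) {
    stop("h2_target must lie in (0, 1)", call. = FALSE)
  }
  g_mat <- truth$true_genotypes$geno[truth$causal_indices, , drop = FALSE]
  gv <- drop(crossprod(g_mat, truth$causal_effects))
  var_g <- stats::var(gv)
  var_e <- if (var_g > 0) var_g * (1 - config$h2_target) / config$h2_target
           else 1
  n <- length(gv)
  with_op_seed(config$seed, "simulate_phenotypes", {
    e_shared <- stats::rnorm(n)
    e1 <- stats::rnorm(n)
    e2 <- stats::rnorm(n)
    rc <- config$resid_cor
    r1 <- sqrt(var_e) * (sqrt(rc) * e_shared + sqrt(1 - rc) * e1)
    r2 <- sqrt(var_e) * (sqrt(rc) * e_shared + sqrt(1 - rc) * e2)
    tibble::tibble(
      sample_id = truth$true_genotypes$samples,
      FT_loc1 = config$ft_intercept + config$location_offsets[1] + gv + r1,
      FT_loc2 = config$ft_intercept + config$location_offsets[2] + gv + r2
    )
  })
}

#' Simulate sequencing read depths from true genotypes
#'
#' Per site-sample cell, total depth is Poisson with mean
#' `config$depth_mean`; reads are allocated to the minor allele binomially
#' with probability `g/2` perturbed by the per-read error `seq_error`
#' toward the other allele; a `missing_rate` fraction of cells is zeroed
#' (no coverage). Other-base reads are not generated (errors flip between
#' the two segregating alleles).
#'
#' @param truth a `truth_set` from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @return An [allele_depths()] object aligned with the truth genotypes.
#' @export
simulate_read_depths <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  gm <- truth$true_genotypes
  m <- nrow(gm$geno); n <- ncol(gm$geno)
  with_op_seed(config$seed, "simulate_read_depths", {
    depth <- matrix(stats::rpois(m * n, config$depth_mean), m, n)
    if (config$missing_rate > 0) {
      zero <- stats::runif(m * n) < config$missing_rate
      depth[zero] <- 0L
    }
    e <- config$seq_error
    p_minor <- (gm$geno / 2) * (1 - e) + (1 - gm$geno / 2) * e
    minor <- matrix(
      stats::rbinom(m * n, as.vector(depth), as.vector(p_minor)), m, n)
    allele_depths(depth - minor, minor, matrix(0L, m, n),
                  gm$sites, gm$samples)
  })
}

#' Simulate a full structured panel
#'
#' Convenience wrapper running geography, climate, genotypes, phenotypes
#' and read depths under one configuration.
#'
#' @param config a [sim_config()].
#' @return A list with `samples` (passport + climate tibble), `genotypes`,
#'   `truth`, `phenotypes`, `depths`.
#' @export
simulate_panel <- function(config) {
  samples <- simulate_climate(simulate_geography(config), config)
  sim <- simulate_genotypes(config)
  # align sample ids between geography and genotypes (both S%04d in order,
  # grouped identically by construction)
  phen <- simulate_phenotypes(sim$truth, config)
  depths <- simulate_read_depths(sim$truth, config)
  list(samples = samples, genotypes = sim$genotypes, truth = sim$truth,
       phenotypes = phen, depths = depths)
}
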