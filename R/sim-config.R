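#' Simulation configuration for a structured landrace panel
#'
#' Assembles and validates the parameters of the synthetic-panel generator.
#' Defaults emulate a genotyping-by-sequencing panel of Chinese soya bean
#' landraces plus a wild outgroup: three landrace subpopulations (NR
#' northern, HR central/Huanghuai, SR southern) and one wild group, with
#' pairwise differentiation, distance-decaying LD, latitude-driven climate,
#' additive flowering-time genetics and Poisson read depths.
#'
#' @param seed integer master seed; every operation derives its own
#'   sub-stream from it.
#' @param n_per_group named integer vector of sample counts for groups
#'   `WILD`, `NR`, `HR`, `SR` (any subset).
#' @param n_snps total number of SNPs across the genome.
#' @param n_chromosomes number of chromosomes (contigs `Chr01`...).
#' @param chrom_length_bp chromosome length in bp.
#' @param fst_targets data frame with columns `group1`, `group2`, `fst`
#'   giving target pairwise Weir-Cockerham Fst in (0, 1). Defaults to the
#'   landrace trio 0.077/0.136/0.164 plus 0.15 against the wild group.
#' @param ld_copy_decay_bp distance scale (bp) of the haplotype dependence
#'   process; larger values give slower r-squared decay.
#' @param inbreeding fraction of accessions that are fully autozygous
#'   (their two haplotypes identical genome-wide). Landrace panels of
#'   selfing crops are nearly homozygous, which is what makes the
#'   heterozygosity-based site filters meaningful; default 0.95.
#' @param wild_ld_frac multiplier on `ld_copy_decay_bp` for the wild group
#'   (wild panels decay faster).
#' @param n_causal number of causal flowering-time loci.
#' @param effect_sd standard deviation (days per minor-allele copy) of
#'   causal effects.
#' @param h2_target narrow-sense heritability of flowering time at each
#'   location, in (0, 1).
#' @param resid_cor correlation of non-genetic residuals between the two
#'   growing locations (plasticity shared across sites).
#' @param ft_intercept baseline flowering time, days.
#' @param location_offsets length-2 numeric, additive day offsets of the
#'   two phenotyping locations.
#' @param depth_mean mean sequencing depth per site and sample (Poisson).
#' @param seq_error per-read probability of reading the other allele.
#' @param missing_rate fraction of site-sample cells with zero coverage.
#' @param climate_params list with elements `tar_slope`, `tar_intercept`,
#'   `tar_sd` (deg C vs latitude) and `ap_slope`, `ap_intercept`, `ap_sd`
#'   (mm vs latitude).
#' @param sowing_harvest_by_group named list mapping group to
#'   `c(sow_doy, harvest_doy)`.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    n_per_group = c(WILD = 97L, NR = 385L, HR = 346L, SR = 1007L),
    n_snps = 5000L,
    n_chromosomes = 20L,
    chrom_length_bp = 5e6,
    fst_targets = default_fst_targets(),
    ld_copy_decay_bp = 1.7e5,
    wild_ld_frac = 0.21,
    inbreeding = 0.95,
    n_causal = 20L,
    effect_sd = 2,
    h2_target = 0.704,
    resid_cor = 0.7,
    ft_intercept = 60,
    location_offsets = c(0, -15),
    depth_mean = 13,
    seq_error = 0.005,
    missing_rate = 0.05,
    climate_params = list(
      tar_slope = 1.33, tar_intercept = -9.9, tar_sd = 3,
      ap_slope = -57.4, ap_intercept = 3031, ap_sd = 150
    ),
    sowing_harvest_by_group = list(
      WILD = c(130L, 300L), NR = c(121L, 274L),
      HR = c(166L, 288L), SR = c(180L, 320L)
    )) {
  cfg <- list(
    seed = as.integer(seed), n_per_group = n_per_group,
    n_snps = as.integer(n_snps), n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp, fst_targets = fst_targets,
    ld_copy_decay_bp = ld_copy_decay_bp, wild_ld_frac = wild_ld_frac,
    inbreeding = inbreeding,
    n_causal = as.integer(n_causal), effect_sd = effect_sd,
    h2_target = h2_target, resid_cor = resid_cor,
    ft_intercept = ft_intercept, location_offsets = location_offsets,
    depth_mean = depth_mean, seq_error = seq_error,
    missing_rate = missing_rate, climate_params = climate_params,
    sowing_harvest_by_group = sowing_harvest_by_group
  )
  validate_sim_config(cfg)
}

default_fst_targets <- function() {
  tibble::tribble(
    ~group1, ~group2, ~fst,
    "NR", "HR", 0.077,
    "NR", "SR", 0.136,
    "HR", "SR", 0.164,
    "WILD", "NR", 0.15,
    "WILD", "HR", 0.15,
    "WILD", "SR", 0.15
  )
}

validate_sim_config <- function(cfg) {
  known <- c("WILD", "NR", "HR", "SR")
  groups <- names(cfg$n_per_group)
  if (is.null(groups) || !all(groups %in% known)) {
    stop("n_per_group must be named with groups among ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  stopifnot(
    all(cfg$n_per_group >= 0), cfg$n_snps > 0, cfg$n_chromosomes > 0,
    cfg$chrom_length_bp > 0, cfg$n_causal <= cfg$n_snps,
    cfg$h2_target > 0, cfg$h2_target < 1,
    cfg$depth_mean > 0, cfg$seq_error >= 0, cfg$seq_error < 0.5,
    cfg$missing_rate >= 0, cfg$missing_rate < 1,
    cfg$inbreeding >= 0, cfg$inbreeding <= 1,
    cfg$resid_cor >= 0, cfg$resid_cor <= 1,
    length(cfg$location_offsets) == 2
  )
  ft <- cfg$fst_targets
  stopifnot(all(c("group1", "group2", "fst") %in% names(ft)))
  if (any(ft$fst <= 0 | ft$fst >= 1)) {
    stop("fst targets must lie in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Solve per-group Balding-Nichols F from pairwise Fst targets.
# Under the model, the expected pairwise Weir-Cockerham Fst between groups
# i and j is (F_i + F_j) / 2, so targets define a linear system solved by
# least squares. Groups absent from the target table get F = 0.
group_f_from_targets <- function(groups, fst_targets) {
  ft <- fst_targets[fst_targets$group1 %in% groups &
                      fst_targets$group2 %in% groups, , drop = FALSE]
  f <- stats::setNames(rep(0, length(groups)), groups)
  if (nrow(ft) == 0 || length(groups) < 2) return(f)
  if (length(groups) == 2) {
    # one equation, symmetric split
    f[] <- ft$fst[1]
    return(f)
  }
  a <- matrix(0, nrow(ft), length(groups), dimnames = list(NULL, groups))
  for (r in seq_len(nrow(ft))) {
    a[r, ft$group1[r]] <- 0.5
    a[r, ft$group2[r]] <- 0.5
  }
  sol <- stats::lsfit(a, ft$fst, intercept = FALSE)$coefficients
  names(sol) <- groups
  bad <- names(sol)[sol < 0 | sol >= 1]
  if (length(bad)) {
    pairs <- ft[ft$group1 %in% bad | ft$group2 %in% bad, ]
    stop("infeasible Fst target(s) involving pair(s): ",
         paste(paste(pairs$group1, pairs$group2, sep = "-"), collapse = ", "),
         call. = FALSE)
  }
  f[names(sol)] <- sol
  f
}
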