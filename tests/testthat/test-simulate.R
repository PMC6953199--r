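small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed,
             n_per_group = c(WILD = 20L, NR = 30L, HR = 30L, SR = 40L),
             n_snps = 400L, n_chromosomes = 4L, chrom_length_bp = 1e6,
             n_causal = 10L, ...)
}

test_that("identical configs give bit-identical outputs", {
  c1 <- small_cfg(seed = 5); c2 <- small_cfg(seed = 5)
  expect_identical(simulate_geography(c1), simulate_geography(c2))
  s1 <- simulate_genotypes(c1); s2 <- simulate_genotypes(c2)
  expect_identical(s1$genotypes$geno, s2$genotypes$geno)
  expect_identical(simulate_phenotypes(s1$truth, c1),
                   simulate_phenotypes(s2$truth, c2))
  d1 <- simulate_read_depths(s1$truth, c1)
  d2 <- simulate_read_depths(s2$truth, c2)
  expect_identical(d1$minor, d2$minor)
})

test_that("geography respects group latitude bands and counts", {
  geo <- simulate_geography(small_cfg(seed = 2))
  expect_identical(nrow(geo), 120L)
  rng <- dplyr::summarise(dplyr::group_by(geo, group),
                          lo = min(latitude), hi = max(latitude))
  bands <- list(WILD = c(24, 53), NR = c(40, 51.4),
                HR = c(34, 40), SR = c(18.2, 34))
  for (r in seq_len(nrow(rng))) {
    b <- bands[[rng$group[r]]]
    expect_gte(rng$lo[r], b[1]); expect_lte(rng$hi[r], b[2])
  }
  expect_true(all(geo$altitude >= 0))
  expect_true(all(geo$longitude >= 80.5 & geo$longitude <= 134))
  # single group, exact count
  one <- sim_config(seed = 1, n_per_group = c(SR = 5L), n_snps = 10L,
                    n_causal = 2L)
  expect_identical(nrow(simulate_geography(one)), 5L)
  expect_error(sim_config(n_per_group = c(XX = 5L)), "named with groups")
})

test_that("climate trends follow latitude and MDL is the deterministic daylength max", {
  cfg <- small_cfg(seed = 3)
  cfg$climate_params$tar_sd <- 0
  cfg$climate_params$ap_sd <- 0
  geo <- simulate_geography(cfg)
  cl <- simulate_climate(geo, cfg)
  o <- order(cl$latitude)
  expect_true(all(diff(cl$TAR[o]) >= 0))
  expect_true(all(diff(cl$AP[o]) <= 0))
  expect_equal(cl$MDL,
               mdl(cl$latitude, cl$sowing_doy, cl$harvest_doy),
               tolerance = 1e-12)
  expect_gt(cor(cl$MDL, cl$TAR), 0.8)
  geo$latitude[1] <- NA
  expect_error(simulate_climate(geo, cfg), "latitude")
})

test_that("Balding-Nichols Fst targets are recovered genome-wide", {
  est <- vapply(c(0.05, 0.10, 0.15), function(f) {
    sim <- sim_two_group(17, f, n = 150, m = 2000)
    wc_fst(sim$genotypes, sim$truth$true_group)$overall
  }, numeric(1))
  expect_true(all(abs(est - c(0.05, 0.10, 0.15)) < 0.02))
})

test_that("near-zero differentiation targets give near-zero mean Fst", {
  sim <- sim_two_group(19, 1e-4, n = 150, m = 2000)
  expect_lt(abs(wc_fst(sim$genotypes, sim$truth$true_group)$overall), 0.01)
})

test_that("infeasible Fst target triples name the offending pair", {
  bad <- tibble::tibble(group1 = c("NR", "NR", "HR"),
                        group2 = c("HR", "SR", "SR"),
                        fst = c(0.01, 0.9, 0.05))
  cfg <- sim_config(n_per_group = c(NR = 10L, HR = 10L, SR = 10L),
                    n_snps = 50L, n_causal = 2L, fst_targets = bad)
  expect_error(simulate_genotypes(cfg), "NR-HR")
})

test_that("LD decays with distance and vanishes as the dependence scale shrinks", {
  sim <- sim_two_group(23, 0.08, n = 200, m = 800, n_chromosomes = 2L,
                       chrom_length_bp = 1e6, ld_copy_decay_bp = 2e5)
  prof <- ld_decay_profile(ld_r2(sim$genotypes), bin_width_bp = 2e4)
  expect_true(all(diff(prof$bins$smoothed_r2) <= 1e-12))
  expect_gt(prof$bins$mean_r2[1], 0.1)

  sim0 <- sim_two_group(23, 0.08, n = 200, m = 300, n_chromosomes = 1L,
                        chrom_length_bp = 1e6, ld_copy_decay_bp = 1e-9)
  g <- sim0$genotypes$geno
  adj <- vapply(seq_len(nrow(g) - 1), function(s) {
    suppressWarnings(cor(g[s, ], g[s + 1, ]))^2
  }, numeric(1))
  set.seed(1)
  perm <- sample(nrow(g))
  adj_perm <- vapply(seq_len(nrow(g) - 1), function(s) {
    suppressWarnings(cor(g[perm[s], ], g[perm[s + 1], ]))^2
  }, numeric(1))
  expect_lt(abs(mean(adj, na.rm = TRUE) - mean(adj_perm, na.rm = TRUE)),
            0.005)
})

test_that("phenotypes share genetic values across locations", {
  cfg <- small_cfg(seed = 31, resid_cor = 1)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$truth, cfg)
  # fully shared residuals: the location difference is a constant offset
  expect_lt(sd(ph$FT_loc1 - ph$FT_loc2), 1e-10)
  expect_equal(mean(ph$FT_loc1 - ph$FT_loc2),
               cfg$location_offsets[1] - cfg$location_offsets[2])

  cfg2 <- small_cfg(seed = 32)
  sim2 <- simulate_genotypes(cfg2)
  ph2 <- simulate_phenotypes(sim2$truth, cfg2)
  expect_gt(cor(ph2$FT_loc1, ph2$FT_loc2), 0.9 * cfg2$h2_target)
  expect_error(simulate_phenotypes(
    sim2$truth, small_cfg(h2_target = NA)), "h2_target")
})

test_that("a null genetic architecture yields near-zero heritability estimates", {
  cfg <- sim_config(seed = 41, n_per_group = c(NR = 250L), n_snps = 1500L,
                    n_chromosomes = 5L, n_causal = 5L, effect_sd = 0)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$truth, cfg)
  h <- heritability(relationship_matrix(sim$genotypes), ph$FT_loc1)
  expect_lt(h$h2, 0.1)
})

test_that("read depths have the configured mean and error behaviour", {
  cfg <- sim_config(seed = 51, n_per_group = c(NR = 100L), n_snps = 1000L,
                    n_causal = 5L, missing_rate = 0, depth_mean = 13)
  sim <- simulate_genotypes(cfg)
  dep <- simulate_read_depths(sim$truth, cfg)
  expect_lt(abs(mean(dep$major + dep$minor + dep$other) - 13), 0.1)

  cfg0 <- sim_config(seed = 52, n_per_group = c(NR = 50L), n_snps = 300L,
                     n_causal = 5L, seq_error = 0, missing_rate = 0)
  sim0 <- simulate_genotypes(cfg0)
  dep0 <- simulate_read_depths(sim0$truth, cfg0)
  hom_major <- sim0$truth$true_genotypes$geno == 0L
  expect_identical(sum(dep0$minor[hom_major]), 0L)
})

test_that("the caller recovers simulated truth at high depth", {
  cfg <- sim_config(seed = 61, n_per_group = c(NR = 100L, SR = 100L),
                    n_snps = 1000L, n_causal = 5L, depth_mean = 30,
                    seq_error = 0.01, missing_rate = 0)
  sim <- simulate_genotypes(cfg)
  called <- call_genotypes(simulate_read_depths(sim$truth, cfg))
  agree <- called$geno == sim$truth$true_genotypes$geno
  expect_gt(mean(agree, na.rm = TRUE), 0.99)
  # at shallow depth the caller abstains rather than miscalling
  cfg5 <- sim_config(seed = 62, n_per_group = c(NR = 60L), n_snps = 400L,
                     n_causal = 5L, depth_mean = 5, seq_error = 0.01,
                     missing_rate = 0)
  sim5 <- simulate_genotypes(cfg5)
  called5 <- call_genotypes(simulate_read_depths(sim5$truth, cfg5))
  expect_gt(mean(is.na(called5$geno)), mean(is.na(called$geno)))
  expect_gt(mean(called5$geno == sim5$truth$true_genotypes$geno,
                 na.rm = TRUE), 0.9)
  expect_lt(mean(called5$geno == sim5$truth$true_genotypes$geno,
                 na.rm = TRUE), mean(agree, na.rm = TRUE))
})
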