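test_that("PVE reduces to squared correlation for one TAS and adds up when orthogonal", {
  set.seed(41)
  x1 <- rnorm(200)
  y <- 2 * x1 + rnorm(200)
  pv <- pve(cbind(t1 = x1), y)
  expect_equal(pv$r2_full, cor(x1, y)^2, tolerance = 1e-12)
  expect_equal(pv$per_tas$pve, pv$r2_full, tolerance = 1e-12)
  # orthogonal designs decompose exactly
  x2 <- residuals(lm(rnorm(200) ~ x1))
  y2 <- x1 + 0.5 * x2 + rnorm(200)
  pv2 <- pve(cbind(a = x1, b = x2), y2)
  expect_equal(sum(pv2$per_tas$pve), pv2$r2_full, tolerance = 1e-10)
  expect_true(all(pv2$per_tas$pve >= -1e-12))
  expect_gte(pv2$r2_full, max(cor(x1, y2)^2, cor(x2, y2)^2))
})

test_that("PVE matches independent refits on a random fixture", {
  set.seed(43)
  x <- matrix(rnorm(150 * 4), 150, 4,
              dimnames = list(NULL, paste0("t", 1:4)))
  y <- drop(x %*% c(1, -0.5, 0.2, 0)) + rnorm(150)
  pv <- pve(x, y)
  r2 <- function(fit) summary(fit)$r.squared
  full <- r2(lm(y ~ x))
  expect_equal(pv$r2_full, full, tolerance = 1e-10)
  for (j in 1:4) {
    expect_equal(pv$per_tas$pve[j],
                 full - r2(lm(y ~ x[, -j])), tolerance = 1e-10)
  }
  expect_error(pve(matrix(rnorm(20), 4, 5), rnorm(4)), "more TASs")
  expect_warning(pve(cbind(a = x[, 1], b = x[, 1]), y), "collinear")
})

test_that("REML heritability recovers simulated truth on average", {
  ests <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = 200 + s, n_per_group = c(NR = 400L),
                      n_snps = 1500L, n_chromosomes = 5L, n_causal = 20L,
                      h2_target = 0.5)
    sim <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(sim$truth, cfg)
    heritability(relationship_matrix(sim$genotypes), ph$FT_loc1)$h2
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.5), 0.08)
  expect_true(all(ests >= 0 & ests <= 1))
})

test_that("pure-noise traits estimate near-zero heritability", {
  sim <- sim_two_group(211, 0.05, n = 250, m = 1000)
  set.seed(3)
  h <- heritability(relationship_matrix(sim$genotypes), rnorm(500))
  expect_lt(h$h2, 0.1)
  gl <- glance(h)
  expect_identical(gl$h2, h$h2)
  expect_identical(nrow(tidy(h)), 2L)
})

test_that("duplicated samples trigger the degenerate-kinship warning", {
  sim <- sim_two_group(221, 0.05, n = 40, m = 300)
  g <- sim$genotypes
  dup <- geno_matrix(cbind(g$geno, g$geno), g$sites,
                     c(g$samples, paste0(g$samples, "_d")))
  set.seed(4)
  y <- rnorm(80); y2 <- c(y, y)
  expect_warning(heritability(relationship_matrix(dup), y2),
                 "degenerate kinship")
})

test_that("allele contrasts measure homozygote differences and flag reversals", {
  set.seed(51)
  n <- 200
  g <- matrix(sample(0:2, n, replace = TRUE, prob = c(0.4, 0.2, 0.4)),
              1, n)
  gm <- geno_matrix(g, tibble::tibble(chrom = "Chr06", pos = 19873100,
                                      major = "A", minor = "C"),
                    sprintf("s%03d", 1:n))
  y_eq <- rnorm(n)
  row_eq <- allele_contrast(gm, y_eq, "Chr06", 19873100)
  expect_lt(abs(row_eq$diff), 1)
  expect_true(row_eq$estimable)
  # constructed 10-day shift
  y_shift <- rnorm(n, sd = 1) - 10 * (g[1, ] == 2)
  row <- allele_contrast(gm, y_shift, "Chr06", 19873100)
  expect_lt(row$p, 1e-10)
  expect_identical(row$direction, -1)
  expect_identical(row$n_hom_major + row$n_hom_minor,
                   sum(g[1, ] != 1))
  # group-specific reversal shows opposite signs across masks
  grp <- rep(c("NR", "SR"), each = n / 2)
  y_rev <- rnorm(n, sd = 1) +
    ifelse(grp == "SR", 8, -8) * (g[1, ] == 2)
  rows <- dplyr::bind_rows(
    allele_contrast(gm, y_rev, "Chr06", 19873100, grp == "NR", "NR"),
    allele_contrast(gm, y_rev, "Chr06", 19873100, grp == "SR", "SR"))
  expect_identical(rows$direction, c(-1, 1))
  # a class with < 2 members is not estimable
  g2 <- gm
  g2$geno[1, ] <- c(2L, rep(0L, n - 1))
  row2 <- allele_contrast(g2, y_eq, "Chr06", 19873100)
  expect_false(row2$estimable)
  expect_error(allele_contrast(gm, y_eq, "Chr01", 5), "not found")
})

test_that("early-allele scores count designated alleles and track the trait", {
  cfg <- sim_config(seed = 231, n_per_group = c(NR = 300L),
                    n_snps = 500L, n_causal = 8L, effect_sd = 3)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$truth, cfg)
  tas <- sim$genotypes$sites[sim$truth$causal_indices, c("chrom", "pos")]
  tas <- designate_early_allele(sim$genotypes, ph$FT_loc1, tas)
  sc <- early_allele_score(sim$genotypes, tas, ph$FT_loc1)
  expect_lt(attr(sc, "cor"), 0)
  expect_lt(attr(sc, "cor_p"), 1e-6)
  # all-early sample scores the full set size
  gm1 <- geno_matrix(matrix(2L, 3, 2),
                     tibble::tibble(chrom = "Chr01", pos = c(1, 5, 9),
                                    major = "A", minor = "C"),
                     c("a", "b"))
  tas1 <- tibble::tibble(chrom = "Chr01", pos = c(1, 5, 9),
                         early_code = 2L)
  sc1 <- early_allele_score(gm1, tas1)
  expect_equal(unname(sc1$score), c(3, 3))
  sc0 <- early_allele_score(gm1, tas1[0, ], trait = c(1, 2))
  expect_true(attr(sc0, "undefined"))
  expect_equal(unname(sc0$score), c(0, 0))
})

test_that("interval overlap uses closed 1-based coordinates", {
  blocks <- tibble::tibble(chrom = "Chr01", focal_pos = 150,
                           start = 100, end = 200)
  iv <- tibble::tibble(chrom = "Chr01",
                       start = c(150, 201, 500), end = c(300, 300, 600),
                       name = c("g1", "g2", "g3"))
  ov <- interval_overlap(blocks, iv)
  expect_identical(ov$overlaps, c(TRUE, FALSE, FALSE))
  expect_equal(ov$distance_bp, c(0, 1, 300))
  # brute-force random oracle
  set.seed(61)
  b2 <- tibble::tibble(chrom = sample(c("Chr01", "Chr02"), 15, TRUE),
                       focal_pos = 0,
                       start = sample(1000, 15))
  b2$end <- b2$start + sample(200, 15)
  i2 <- tibble::tibble(chrom = sample(c("Chr01", "Chr02"), 10, TRUE),
                       start = sample(1000, 10))
  i2$end <- i2$start + sample(200, 10)
  i2$name <- paste0("iv", 1:10)
  ov2 <- interval_overlap(b2, i2)
  for (r in seq_len(nrow(ov2))) {
    expect_identical(ov2$overlaps[r],
                     ov2$block_start[r] <= ov2$iv_end[r] &&
                       ov2$iv_start[r] <= ov2$block_end[r])
  }
})
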