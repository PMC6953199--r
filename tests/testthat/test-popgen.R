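test_that("per-SNP Weir-Cockerham Fst matches the scalar oracle", {
  gm <- toy_geno(50, 40, seed = 3, missing_rate = 0.1)
  grp <- rep(c("A", "B"), each = 20)
  res <- wc_fst(gm, grp)
  want <- vapply(seq_len(50),
                 function(s) oracle_wc_fst_site(gm$geno[s, ], grp),
                 numeric(1))
  expect_equal(res$per_snp$fst, want, tolerance = 1e-10)
  # three groups too
  grp3 <- rep(c("A", "B", "C"), length.out = 40)
  res3 <- wc_fst(gm, grp3)
  want3 <- vapply(seq_len(50),
                  function(s) oracle_wc_fst_site(gm$geno[s, ], grp3),
                  numeric(1))
  expect_equal(res3$per_snp$fst, want3, tolerance = 1e-10)
})

test_that("Fst limiting cases: no differentiation and complete fixation", {
  g_eq <- matrix(rep(c(0L, 1L, 2L, 1L), 10), 1)  # same profile per group
  gm <- geno_matrix(rbind(g_eq, g_eq),
                    tibble::tibble(chrom = "Chr01", pos = c(5, 10),
                                   major = "A", minor = "C"),
                    sprintf("s%02d", 1:40))
  grp <- rep(c("A", "B"), 20)   # interleaved -> identical freq and het
  res <- wc_fst(gm, grp)
  expect_true(all(res$per_snp$fst <= 1e-10))
  gfix <- matrix(c(rep(0L, 20), rep(2L, 20)), 1)
  gmf <- geno_matrix(gfix, tibble::tibble(chrom = "Chr01", pos = 1,
                                          major = "A", minor = "C"),
                     sprintf("s%02d", 1:40))
  resf <- wc_fst(gmf, rep(c("A", "B"), each = 20))
  expect_equal(resf$per_snp$fst, 1)
  expect_error(wc_fst(gmf, rep("A", 40), labels = c("A", "B")), "empty")
})

test_that("genome-wide ratio-of-sums lies within the windowed means", {
  sim <- sim_two_group(55, 0.1, n = 80, m = 600)
  res <- wc_fst(sim$genotypes, sim$truth$true_group)
  expect_gte(res$overall, min(res$windows$mean_fst) - 1e-12)
  expect_lte(res$overall, max(res$windows$mean_fst) + 1e-12)
  expect_true(all(res$windows$end - res$windows$start == 30000 - 1))
})

test_that("Watterson's theta closed forms and density monotonicity", {
  # one diploid sample (n = 2 alleles, a_1 = 1), 10 het sites in 1 Mb
  g <- matrix(1L, 10, 1)
  gm <- geno_matrix(g, tibble::tibble(chrom = "Chr01",
                                      pos = seq(1e4, 1e5, length.out = 10),
                                      major = "A", minor = "C"), "s1")
  th <- watterson_theta(gm, window_bp = 1e6, maf_min = 0)
  expect_equal(th$theta_w, 1e-5)
  expect_equal(th$s, 10L)
  # an empty window reports zero
  g2 <- rbind(g, 1L)
  gm2 <- geno_matrix(g2, tibble::tibble(
    chrom = "Chr01", pos = c(gm$sites$pos, 2.5e6),
    major = "A", minor = "C"), "s1")
  th2 <- watterson_theta(gm2, window_bp = 1e6, maf_min = 0)
  expect_equal(th2$theta_w[2], 0)
  # denser polymorphism raises the genome mean
  dense <- toy_geno(200, 20, seed = 8, n_chrom = 1)
  sparse <- dense[1:40, ]
  expect_gt(attr(watterson_theta(dense), "mean_theta"),
            attr(watterson_theta(sparse), "mean_theta"))
})

test_that("pairwise r2 agrees with naive correlation and null scale", {
  gm <- toy_geno(40, 30, seed = 15, n_chrom = 2)
  pr <- ld_r2(gm, max_distance_bp = 1e6, maf_min = 0)
  for (r in sample(nrow(pr), 10)) {
    i <- which(gm$sites$chrom == pr$chrom[r] & gm$sites$pos == pr$pos1[r])
    j <- which(gm$sites$chrom == pr$chrom[r] & gm$sites$pos == pr$pos2[r])
    expect_equal(pr$r2[r], cor(gm$geno[i, ], gm$geno[j, ])^2,
                 tolerance = 1e-10)
  }
  expect_true(all(pr$dist_bp > 0 & pr$dist_bp <= 1e6))
  # duplicated column at a different position -> r2 = 1
  gm$geno[2, ] <- gm$geno[1, ]
  pr2 <- ld_r2(gm, maf_min = 0)
  key <- pr2$chrom == gm$sites$chrom[1] & pr2$pos1 == gm$sites$pos[1] &
    pr2$pos2 == gm$sites$pos[2]
  expect_equal(pr2$r2[key], 1)
  # independent sites: mean r2 near 1/(n-1)
  sim0 <- sim_two_group(71, 1e-4, n = 250, m = 400, n_chromosomes = 1L,
                        ld_copy_decay_bp = 1e-9)
  pr0 <- ld_r2(sim0$genotypes)
  expect_lt(mean(pr0$r2), 0.01)
})

test_that("LD decay profile recovers a known exponential half-max", {
  set.seed(101)
  d <- runif(150000, 0, 1e6)
  delta <- 8e4                       # true half-max at delta*ln2 ~ 55.45 kb
  r2 <- pmin(pmax(0.45 * exp(-d / delta) + rnorm(length(d), 0, 0.04), 0), 1)
  prof <- ld_decay_profile(tibble::tibble(dist_bp = d, r2 = r2))
  expect_true(prof$half_max_reached)
  expect_lt(abs(prof$half_max_bp - delta * log(2)), 2600)
  # scaling all r2 by a constant leaves the half-max unchanged
  prof2 <- ld_decay_profile(tibble::tibble(dist_bp = d, r2 = r2 / 3))
  expect_equal(prof2$half_max_bp, prof$half_max_bp)
  # a flat profile never reaches half its maximum
  flat <- ld_decay_profile(tibble::tibble(dist_bp = runif(5000, 0, 1e6),
                                          r2 = 0.3))
  expect_false(flat$half_max_reached)
  expect_true(is.na(flat$half_max_bp))
  expect_error(ld_decay_profile(tibble::tibble(dist_bp = -1, r2 = 0.1)),
               "no usable pairs")
})

test_that("landrace-like panels decay more slowly than wild-like panels", {
  land <- sim_two_group(81, 0.05, n = 150, m = 600, n_chromosomes = 2L,
                        chrom_length_bp = 1e6, ld_copy_decay_bp = 1.7e5)
  wild <- sim_two_group(81, 0.05, n = 150, m = 600, n_chromosomes = 2L,
                        chrom_length_bp = 1e6, ld_copy_decay_bp = 0.3e5)
  p_land <- ld_decay_profile(ld_r2(land$genotypes), bin_width_bp = 5e3)
  p_wild <- ld_decay_profile(ld_r2(wild$genotypes), bin_width_bp = 5e3)
  expect_gt(p_land$half_max_bp, p_wild$half_max_bp)
})

test_that("LD block bounds come from the farthest r2 >= 0.8 context SNPs", {
  set.seed(19)
  base <- sample(0:2, 80, replace = TRUE)
  g <- rbind(base,
             base,                          # perfect copy at -50 kb
             sample(0:2, 80, replace = TRUE),
             base,                          # perfect copy at +50 kb
             sample(0:2, 80, replace = TRUE))
  pos <- c(950000, 1000000 - 50000 + 1, 990000, 1050000, 1900000)
  o <- order(pos)
  gm <- geno_matrix(g[o, ], tibble::tibble(chrom = "Chr01", pos = pos[o],
                                           major = "A", minor = "C"),
                    sprintf("s%03d", 1:80))
  blk <- ld_block(gm, "Chr01", 1000000 - 50000 + 1)
  expect_identical(blk$start, 950000)
  expect_identical(blk$end, 1050000)
  # an unlinked focal SNP collapses to a zero-length block
  blk0 <- ld_block(gm, "Chr01", 1900000)
  expect_identical(c(blk0$start, blk0$end), c(1900000, 1900000))
  expect_error(ld_block(gm, "Chr01", 123), "not found")
  # brute-force oracle on a random fixture
  gm2 <- toy_geno(60, 50, seed = 27, n_chrom = 1)
  focal <- 30
  fp <- gm2$sites$pos[focal]
  r2 <- vapply(seq_len(60), function(s) {
    suppressWarnings(cor(gm2$geno[focal, ], gm2$geno[s, ]))^2
  }, numeric(1))
  linked <- which(r2 >= 0.8 & abs(gm2$sites$pos - fp) <= 1e6)
  linked <- setdiff(linked, focal)
  want_start <- if (any(gm2$sites$pos[linked] < fp)) {
    min(gm2$sites$pos[linked][gm2$sites$pos[linked] < fp])
  } else fp
  want_end <- if (any(gm2$sites$pos[linked] > fp)) {
    max(gm2$sites$pos[linked][gm2$sites$pos[linked] > fp])
  } else fp
  blk2 <- ld_block(gm2, "Chr01", fp)
  expect_identical(c(blk2$start, blk2$end), c(want_start, want_end))
})

test_that("Pst behaves at its limits and exceeds Fst under trait divergence", {
  set.seed(5)
  y_same <- rnorm(60)
  g3 <- rep(c("A", "B", "C"), each = 20)
  p0 <- pst(y_same, g3, n_boot = 200)
  expect_lt(p0$estimate, 0.15)
  expect_true(p0$ci[1] <= p0$estimate && p0$estimate <= p0$ci[2])
  y_div <- rnorm(60, mean = rep(c(0, 30, 60), each = 20), sd = 1)
  p1 <- pst(y_div, g3, n_boot = 200)
  expect_gt(p1$estimate, 0.99)
  expect_error(pst(rnorm(3), c("A", "A", "B")), "at least 2")
  # strong trait divergence with modest genetic differentiation
  sim <- sim_two_group(91, 0.08, n = 60, m = 400)
  fst <- wc_fst(sim$genotypes, sim$truth$true_group)$overall
  y <- rnorm(120, mean = ifelse(sim$truth$true_group == "NR", 0, 8), sd = 2)
  p2 <- pst(y, sim$truth$true_group, n_boot = 200, fst_mean = fst)
  expect_gt(p2$estimate, p2$fst_mean)
  td <- tidy(p2)
  expect_equal(td$estimate, p2$estimate)
})
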