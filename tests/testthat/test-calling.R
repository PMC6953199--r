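test_that("caller matches the brute-force rule oracle on all triples <= 20", {
  grid <- expand.grid(a = 0:20, b = 0:20, o = 0:20)
  got <- call_genotype(grid$a, grid$b, grid$o)
  want <- mapply(oracle_call, grid$a, grid$b, grid$o)
  expect_identical(got, as.integer(want))
  # the two rules never both match once totals reach 2
  hom <- !is.na(got) & got != 1L
  het_also <- mapply(function(a, b, o) {
    tot <- a + b + o
    a >= 1 && b >= 1 && a >= 0.2 * tot && b >= 0.2 * tot &&
      (a + b) >= 5 && (a + b) >= 0.9 * tot
  }, grid$a, grid$b, grid$o)
  expect_false(any(hom & het_also))
})

test_that("caller worked examples and input validation", {
  expect_identical(call_genotype(9, 1, 0), 0L)
  expect_identical(call_genotype(3, 2, 0), 1L)
  expect_true(is.na(call_genotype(1, 0, 0)))
  expect_identical(call_genotype(0, 7, 0), 2L)  # minor-allele homozygote
  expect_error(call_genotype(-1, 2, 0), "nonnegative")
})

test_that("calling is per-cell: permuting samples permutes calls", {
  set.seed(7)
  m <- 40; n <- 15
  dep <- allele_depths(matrix(rpois(m * n, 8), m, n),
                       matrix(rpois(m * n, 3), m, n),
                       matrix(rpois(m * n, 0.2), m, n),
                       toy_geno(m, n)$sites, sprintf("T%03d", 1:n))
  perm <- sample(n)
  expect_identical(call_genotypes(dep[, perm])$geno,
                   call_genotypes(dep)$geno[, perm])
})

test_that("site discovery applies the pooled bi-allelic and depth rules", {
  sites <- tibble::tibble(chrom = "Chr01", pos = 1:3 * 100,
                          major = "A", minor = "C")
  maj <- rbind(c(10, 10), c(3, 3), c(10, 0))
  mnr <- rbind(c(2, 2), c(1, 1), c(0, 0))
  oth <- rbind(c(0, 0), c(0, 0), c(8, 0))
  dep <- allele_depths(maj, mnr, oth, sites, c("s1", "s2"))
  mask <- discover_sites(dep)
  expect_true(mask[1])          # clean bi-allelic site
  expect_false(mask[2])         # no cell reaches 5 reads
  expect_false(mask[3])         # pooled 10/18 = 56% < 80%
  # random fixture equals direct recomputation
  set.seed(11)
  m <- 50; n <- 12
  dep2 <- allele_depths(matrix(rpois(m * n, 6), m, n),
                        matrix(rpois(m * n, 2), m, n),
                        matrix(rpois(m * n, 1.5), m, n),
                        toy_geno(m, n)$sites, sprintf("T%03d", 1:n))
  want <- vapply(seq_len(m), function(s) {
    tot <- dep2$major[s, ] + dep2$minor[s, ] + dep2$other[s, ]
    use <- tot >= 5
    sum(tot[use]) > 0 &&
      sum((dep2$major + dep2$minor)[s, use]) >= 0.8 * sum(tot[use])
  }, logical(1))
  expect_identical(discover_sites(dep2), want)
})

test_that("pre-imputation site filter applies the three thresholds exactly", {
  gm <- toy_geno(120, 40, seed = 3, missing_rate = 0.3)
  # plant a monomorphic and an over-heterozygous site
  gm$geno[1, ] <- 0L
  gm$geno[2, ] <- 1L
  out <- filter_sites_pre(gm)
  st <- site_stats(gm)
  want <- !is.na(st$maf) & st$maf >= 0.01 & st$het_rate <= 0.20 &
    st$missing_rate <= 0.70
  expect_identical(nrow(out$geno), sum(want))
  expect_identical(out$sites$pos, gm$sites$pos[want])
  expect_false(1 %in% match(out$sites$pos, gm$sites$pos))
})

test_that("filters are idempotent", {
  gm <- toy_geno(100, 30, seed = 5, missing_rate = 0.25)
  f1 <- filter_sites_pre(gm)
  expect_identical(filter_sites_pre(f1)$geno, f1$geno)
  s1 <- filter_samples(gm, 0.5)
  expect_identical(filter_samples(s1, 0.5)$geno, s1$geno)
  imp <- impute_genotypes(filter_sites_pre(gm))
  p1 <- filter_sites_post(imp, min_homozygous_minor = 2L)
  expect_identical(filter_sites_post(p1, min_homozygous_minor = 2L)$geno,
                   p1$geno)
})

test_that("sample filter removes by missing rate and errors when empty", {
  gm <- toy_geno(50, 10, seed = 9)
  gm$geno[1:43, 3] <- NA   # 86% missing
  out <- filter_samples(gm, 0.80)
  expect_identical(ncol(out$geno), 9L)
  expect_identical(attr(out, "n_removed"), 1L)
  expect_false("T003" %in% out$samples)
  full <- toy_geno(20, 5, seed = 2)
  expect_identical(filter_samples(full)$geno, full$geno)
  gm$geno[] <- NA_integer_
  expect_error(filter_samples(gm), "all samples")
})

test_that("mode imputation fills with the site mode and leaves calls alone", {
  gm <- toy_geno(10, 20, seed = 4)
  gm$geno[1, ] <- c(rep(0L, 18), 2L, NA)
  gm$geno[2, 5] <- NA
  out <- impute_genotypes(gm, "mode")
  expect_identical(unname(out$geno[1, 20]), 0L)
  expect_false(anyNA(out$geno))
  called <- !is.na(gm$geno)
  expect_identical(out$geno[called], gm$geno[called])
  # no missing -> identity
  expect_identical(impute_genotypes(out)$geno, out$geno)
  gm$geno[3, ] <- NA
  expect_error(impute_genotypes(gm), "zero calls")
})

test_that("knn-haplotype imputation beats mode filling under high LD", {
  sim <- sim_two_group(21, 0.1, n = 60, m = 400,
                       chrom_length_bp = 4e5, ld_copy_decay_bp = 3e5)
  gm <- sim$genotypes
  set.seed(77)
  idx <- which(runif(length(gm$geno)) < 0.05)
  hidden <- gm$geno[idx]
  gm$geno[idx] <- NA
  conc_mode <- mean(impute_genotypes(gm, "mode")$geno[idx] == hidden)
  conc_knn <- mean(
    impute_genotypes(gm, "knn-haplotype", k = 8, window = 15)$geno[idx] ==
      hidden)
  expect_gt(conc_knn, conc_mode)
})

test_that("post-imputation filter enforces the homozygous-minor count", {
  n <- 60
  g <- matrix(0L, 3, n)
  g[1, 1:19] <- 2L                       # 19 homozygous minor
  g[2, 1:20] <- 2L                       # 20: boundary kept
  g[3, 1:25] <- 2L
  gm <- geno_matrix(g, tibble::tibble(chrom = "Chr01", pos = c(10, 20, 30),
                                      major = "A", minor = "C"),
                    sprintf("s%02d", 1:n))
  out <- filter_sites_post(gm, min_homozygous_minor = 20L)
  expect_identical(out$sites$pos, c(20, 30))
})
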