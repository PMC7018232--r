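test_that("MAF is the folded alternate-allele frequency", {
  expect_equal(compute_maf(c(0, 1, 2, 2)), 0.375)
  expect_equal(compute_maf(rep(0, 5)), 0)
  expect_equal(compute_maf(rep(2, 5)), 0)
  expect_error(compute_maf(numeric(0)), "empty")
})

test_that("HWE chi-square matches hand computations", {
  h <- hwe_test(25, 50, 25)
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)
  h2 <- hwe_test(30, 40, 30)
  expect_equal(h2$chi2, 4)
  expect_equal(h2$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(h2$p, 4), 0.0455)
  h3 <- hwe_test(100, 0, 100)
  expect_equal(h3$chi2, 200)
  expect_lt(h3$p, 1e-15)
  expect_equal(hwe_test(10, 0, 0)$p, 1)   # monomorphic convention
})

test_that("SNP filtering applies the MAF, HWE and INFO thresholds", {
  set.seed(1)
  dos <- matrix(rbinom(50 * 10, 2, 0.3), 50, 10)
  g <- fake_genotypes(dos,
                      maf = c(0.04, rep(0.2, 9)),
                      hwe_p = c(1, 5e-4, rep(1, 8)),
                      info = c(1, 1, 0.1, rep(1, 7)))
  kept <- filter_snps(g, 0.05, 0.001, 0.3)
  expect_equal(ncol(kept$dosages), 7)
  expect_equal(kept$snps$snp_id, g$snps$snp_id[4:10])
  # imputation-stage parameterization keeps the marginal SNPs
  kept2 <- filter_snps(g, 0.01, 1e-6, 0.3)
  expect_equal(ncol(kept2$dosages), 9)
})

test_that("the OLS grid agrees with lm to numerical precision", {
  set.seed(2)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    g <- ols_grid(matrix(x, ncol = 1), matrix(y, ncol = 1))
    ref <- summary(lm(y ~ x))$coefficients
    expect_equal(g$beta[1, 1], ref[2, 1], tolerance = 1e-10)
    expect_equal(g$se[1, 1], ref[2, 2], tolerance = 1e-10)
    expect_equal(g$p[1, 1], ref[2, 4], tolerance = 1e-10)
  }
})

test_that("BH q-values equal the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(3)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("trans-eQTL mapping recovers a planted dosage effect", {
  set.seed(4)
  n <- 100
  dos <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  g <- fake_genotypes(dos)
  A <- cbind(2 * dos[, 1] + rnorm(n, sd = 0.1), rnorm(n))
  res <- map_component_trans_eqtl(A, g)
  hit <- res[res$snp_id == "s001" & res$component == "1", ]
  expect_lt(abs(hit$beta - 2), 0.1)
  expect_lt(hit$p, 1e-20)
  expect_true(hit$significant)
  # single test: q equals p
  one <- map_component_trans_eqtl(matrix(rnorm(n), ncol = 1),
                                  fake_genotypes(dos[, 1, drop = FALSE]))
  expect_equal(one$q, one$p)
  # zero-variance dosage is skipped with a warning
  g0 <- fake_genotypes(cbind(dos[, 1], 1))
  expect_warning(r0 <- map_component_trans_eqtl(A, g0), "zero-variance")
  expect_equal(nrow(r0), 2)
})

test_that("type-I error is nominal under the global null", {
  set.seed(5)
  n <- 300
  g <- simulate_genotypes(n, 500, 0.1, 0.4, seed = 5)
  A <- matrix(rnorm(n * 4), n, 4)
  res <- map_component_trans_eqtl(A, g)
  expect_equal(nrow(res), 2000)
  rate <- mean(res$p < 0.05)
  expect_lt(abs(rate - 0.05), 2.576 * sqrt(0.05 * 0.95 / 2000))
})

test_that("permutation p-values are valid and reach their floor", {
  set.seed(6)
  n <- 200
  g <- simulate_genotypes(n, 40, 0.2, 0.4, seed = 6)
  A <- cbind(1.5 * g$dosages[, 1] + rnorm(n), rnorm(n))
  obs <- map_component_trans_eqtl(A, g)
  perm <- permutation_pvalues(A, g, obs, n_perm = 200, seed = 6)
  expect_true(all(perm$perm_p >= 0 & perm$perm_p <= 1))
  planted <- perm[perm$snp_id == "rs00001" & perm$component == "1", ]
  expect_lte(planted$perm_p, 1 / 201)
  # an observed p of ~1 maps to a permutation p of ~1
  worst <- perm[which.max(perm$p), ]
  expect_gt(worst$perm_p, 0.95)
  # determinism
  perm2 <- permutation_pvalues(A, g, obs, n_perm = 200, seed = 6)
  expect_identical(perm$perm_p, perm2$perm_p)
  # per-SNP pooling mode
  ps <- permutation_pvalues(A, g, obs, n_perm = 100, seed = 6, pool = "snp")
  expect_true(all(ps$perm_p >= 1 / 101))
})

test_that("LD r-squared behaves as squared correlation", {
  set.seed(7)
  d <- rbinom(200, 2, 0.3)
  expect_equal(ld_r2(d, d), 1)
  expect_equal(ld_r2(d, 2 - d), 1)          # affine invariance
  e <- rbinom(2000, 2, 0.3); f <- rbinom(2000, 2, 0.3)
  expect_lt(ld_r2(e, f), 0.01)
  expect_error(ld_r2(d, rep(1, 200)), "polymorphic")
  expect_error(ld_r2(d, d[1:10]), "length")
})

test_that("greedy LD pruning keeps a mutually unlinked set", {
  set.seed(8)
  one <- fake_genotypes(matrix(rbinom(100, 2, 0.4), ncol = 1))
  expect_equal(ld_prune(one), "s001")
  d <- rbinom(100, 2, 0.4)
  dup <- fake_genotypes(cbind(d, d, rbinom(100, 2, 0.4)))
  expect_length(ld_prune(dup, 0.4), 2)
  # post-condition sweep on correlated blocks
  base <- matrix(rbinom(150 * 6, 2, 0.3), 150, 6)
  blocks <- cbind(base, pmin(pmax(base + rbinom(150 * 6, 1, 0.1), 0), 2))
  g <- fake_genotypes(blocks)
  for (r2max in c(0.2, 0.5, 0.9)) {
    kept <- ld_prune(g, r2max)
    idx <- match(kept, g$snps$snp_id)
    if (length(idx) > 1) {
      combs <- combn(idx, 2)
      r2 <- apply(combs, 2, function(jk) {
        ld_r2(g$dosages[, jk[1]], g$dosages[, jk[2]])
      })
      expect_true(all(r2 < r2max))
    }
  }
  # priority by p-value keeps the best-associated SNP of a linked pair
  pvals <- c(0.5, 1e-6, 0.2)
  kept <- ld_prune(dup, 0.4, priority = pvals)
  expect_true("s002" %in% kept)
  expect_false("s001" %in% kept)
})

test_that("cis windows are inclusive around TSS and TES", {
  set.seed(9)
  n <- 60
  pos <- c(4000000L, 4000001L, 5500000L, 6010000L, 6010001L)
  dos <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  g <- fake_genotypes(dos, pos = pos)
  ann <- tibble::tibble(gene_id = "gX", chrom = "1", tss = 5000000L,
                        tes = 5010000L, strand = "+")
  expr <- matrix(rnorm(n), 1, dimnames = list("gX", NULL))
  res <- map_cis_eqtl(expr, g, ann, window = 1e6, n_factors = 0)
  # boundaries inclusive: 4,000,000 is exactly 1 Mb from the TSS (kept);
  # 6,010,001 lies 1,000,001 from the TES (excluded)
  expect_setequal(res$snp_id, c("s001", "s002", "s003", "s004"))

  # genes without annotation are skipped with a warning
  expr2 <- rbind(expr, gY = rnorm(n))
  expect_warning(map_cis_eqtl(expr2, g, ann, n_factors = 0), "gY")
})

test_that("a planted cis effect is recovered after factor correction", {
  set.seed(10)
  n <- 200
  g <- simulate_genotypes(n, 8, 0.2, 0.4, seed = 10)
  L <- 30
  expr <- matrix(rnorm(L * n), L, n,
                 dimnames = list(sprintf("g%02d", 1:L), NULL))
  expr[1, ] <- expr[1, ] + 1 * g$dosages[, 1]
  ann <- tibble::tibble(gene_id = sprintf("g%02d", 1:L), chrom = "1",
                        tss = 50000L * (1:L), tes = 50000L * (1:L) + 1000L,
                        strand = "+")
  res <- map_cis_eqtl(expr, g, ann, window = 1e6, n_factors = 3)
  hit <- res[res$snp_id == "rs00001" & res$gene_id == "g01", ]
  expect_lt(abs(hit$beta - 1), 0.2)
  expect_lt(hit$q, 0.05)
})

test_that("GWAS-catalog overlap joins by SNP at the liberal FDR", {
  trans <- tibble::tibble(
    snp_id = sprintf("s%02d", 1:5), component = "1",
    beta = 1, se = 1, t = 1, p = c(1e-8, 1e-6, 0.01, 0.2, 0.5),
    q = c(0.001, 0.10, 0.14, 0.5, 0.9))
  catalog <- tibble::tibble(snp_id = c("s01", "s03", "s99"),
                            trait = c("T1", "T2", "T3"), p = 1e-9)
  expect_equal(nrow(overlap_gwas(trans, tibble::tibble(
    snp_id = character(), trait = character(), p = numeric()))), 0)
  got <- overlap_gwas(trans, catalog, fdr_max = 0.15)
  expect_equal(nrow(got), 2)
  expect_setequal(got$snp_id, c("s01", "s03"))
  # at q < 0.10 threshold only the strong hit remains
  expect_equal(overlap_gwas(trans, catalog, fdr_max = 0.10)$snp_id, "s01")
})
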