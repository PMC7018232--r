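test_that("simulated genotypes are binomial dosages with faithful metadata", {
  g <- simulate_genotypes(400, 1, maf_low = 0.5, maf_high = 0.5, seed = 42)
  expect_true(all(g$dosages %in% 0:2))
  # symmetric Binomial(2, 0.5): mean dosage 1
  expect_lt(abs(mean(g$dosages) - 1), 0.1)

  g2 <- simulate_genotypes(2000, 50, 0.1, 0.4, seed = 7)
  # realized MAF within binomial-standard-error bound of sampled p for
  # every SNP; recover sampled p from the dosage-generating stream
  expect_true(all(g2$snps$maf > 0.07 & g2$snps$maf < 0.43))
  emp <- unname(apply(g2$dosages, 2, mean) / 2)
  emp <- pmin(emp, 1 - emp)
  expect_equal(g2$snps$maf, emp, tolerance = 1e-12)

  g3 <- simulate_genotypes(2000, 200, 0.1, 0.4, seed = 12)
  # HWE holds by construction, so its p-values are uniform
  expect_lt(abs(mean(g3$snps$hwe_p < 0.05) - 0.05), 0.02)

  expect_error(simulate_genotypes(0, 5), "whole number")
  expect_error(simulate_genotypes(10, 5, maf_low = 0, maf_high = 0.2))
})

test_that("HWE p-values of simulated SNPs pass a uniformity KS test", {
  g <- simulate_genotypes(1500, 500, 0.1, 0.4, seed = 5)
  ks <- suppressWarnings(ks.test(g$snps$hwe_p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("generator output is bit-identical under a fixed seed", {
  cfg <- sim_config(n_individuals = 40, n_genes = 80, seed = 9)
  g1 <- simulate_genotypes(40, 12, seed = 9)
  g2 <- simulate_genotypes(40, 12, seed = 9)
  expect_identical(g1$dosages, g2$dosages)
  t1 <- simulate_truth(cfg); t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)
  y1 <- assemble_tensor(t1, missing_fraction = 0.1, seed = 9)
  y2 <- assemble_tensor(t2, missing_fraction = 0.1, seed = 9)
  expect_identical(y1$values, y2$values)
  expect_identical(y1$mask, y2$mask)
})

test_that("planted truth honours supports, B patterns and SNP effects", {
  geno <- simulate_genotypes(300, 5, 0.28, 0.32, seed = 2)
  cfg <- sim_config(n_individuals = 300, n_genes = 1000, n_tissues = 3,
                    n_sparse_components = 1, n_dense_components = 1,
                    genes_per_sparse_component = 20,
                    snp_effects = tibble::tibble(snp = 1, component = 1,
                                                 beta = 1.5),
                    seed = 2)
  tr <- simulate_truth(cfg, geno)
  expect_equal(sum(tr$support_true[1, ]), 20)
  expect_true(all(tr$X_true[1, tr$support_true[1, ] == 0] == 0))
  expect_true(all(tr$support_true[2, ] == 1))     # dense row: all ones
  expect_gt(cor(tr$A_true[, 1], geno$dosages[, 1]), 0.5)

  expect_error(simulate_truth(sim_config(n_genes = 10,
                                         genes_per_sparse_component = 20)),
               "cannot exceed")
  bad <- sim_config(snp_effects = tibble::tibble(snp = 99, component = 1,
                                                 beta = 1))
  expect_error(simulate_truth(bad, simulate_genotypes(150, 5, seed = 1)),
               "outside")
})

test_that("assembled tensor matches the triple sum and the noise model", {
  cfg <- sim_config(n_individuals = 20, n_genes = 30, n_tissues = 2,
                    n_sparse_components = 2, n_dense_components = 0,
                    genes_per_sparse_component = 5, seed = 4)
  tr <- simulate_truth(cfg)
  y0 <- assemble_tensor(tr, seed = 4, noiseless = TRUE)
  manual <- array(0, dim(y0$values))
  for (t in 1:2) {
    manual[, , t] <- tr$A_true %*% (tr$B_true[t, ] * tr$X_true)
  }
  expect_equal(y0$values, manual, tolerance = 1e-12)

  # all loadings zero: per-(gene, condition) variance is 1/lambda
  cfg2 <- sim_config(n_individuals = 500, n_genes = 40, n_tissues = 2,
                     n_sparse_components = 1, n_dense_components = 0,
                     genes_per_sparse_component = 1,
                     noise_precision_range = c(2, 6), seed = 6)
  tr2 <- simulate_truth(cfg2)
  tr2$X_true[] <- 0
  y2 <- assemble_tensor(tr2, seed = 6)
  v <- apply(y2$values, c(2, 3), var)
  rel <- abs(v - 1 / tr2$lambda_true) * tr2$lambda_true
  expect_true(all(rel < 0.15))

  # missingness is planted at the individual x condition level
  cfg3 <- sim_config(n_individuals = 1000, n_genes = 5, n_tissues = 5,
                     n_sparse_components = 1, n_dense_components = 0,
                     genes_per_sparse_component = 2, seed = 8)
  y3 <- assemble_tensor(simulate_truth(cfg3), missing_fraction = 0.1,
                        seed = 8)
  expect_lt(abs(mean(y3$mask) - 0.9), 0.02)
  expect_true(all(rowSums(y3$mask) >= 1) && all(colSums(y3$mask) >= 1))
})

test_that("mediation triples encode the planted causal chain", {
  tr <- simulate_mediation_triple(500, 0.3, alpha = 1, gamma = 0.8,
                                  delta = 0, seed = 21)
  ratio <- cov(tr$outcome, tr$dosage) / cov(tr$cis, tr$dosage)
  expect_lt(abs(ratio - 0.8), 0.15)

  # pleiotropy masquerades as mediation for the ratio estimator
  trp <- simulate_mediation_triple(2000, 0.3, alpha = 1, gamma = 0,
                                   delta = 0.5, seed = 22)
  ratio_p <- cov(trp$outcome, trp$dosage) / cov(trp$cis, trp$dosage)
  expect_lt(abs(ratio_p - 0.5), 0.15)

  tr0 <- simulate_mediation_triple(2000, 0.3, alpha = 0, gamma = 0,
                                   delta = 0, seed = 23)
  expect_lt(abs(cor(tr0$dosage, tr0$cis)), 0.08)
  expect_lt(abs(cor(tr0$dosage, tr0$outcome)), 0.08)
  expect_lt(abs(cor(tr0$cis, tr0$outcome)), 0.08)

  expect_error(simulate_mediation_triple(5, 0.3), ">= 10")
})

test_that("expression normalization divides by gene means and log2-transforms", {
  expect_equal(normalize_expression(matrix(c(2, 2, 2), nrow = 1)),
               matrix(0, 1, 3))
  out <- normalize_expression(matrix(c(1, 4), nrow = 1))
  expect_equal(as.vector(out), c(log2(0.4), log2(1.6)))
  m <- matrix(c(1, 2, 0, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), NULL))
  expect_error(normalize_expression(m), "gB")
})
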