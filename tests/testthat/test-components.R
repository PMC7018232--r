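test_that("gene selection intersects the PIP and tail-quantile rules", {
  set.seed(1)
  L <- 1000
  x <- rnorm(L, sd = 0.01)
  pip <- rep(0.01, L)
  planted <- 1:20
  x[planted] <- c(rep(3, 10), rep(-3, 10))
  pip[planted] <- 0.99
  dec <- list(X_mean = matrix(x, 1), pip = matrix(pip, 1),
              gene_ids = sprintf("g%04d", seq_len(L)))
  got <- select_component_genes(dec, 1)
  expect_setequal(got, sprintf("g%04d", planted))

  # all PIPs zero: empty set
  dec0 <- dec; dec0$pip[] <- 0
  expect_length(select_component_genes(dec0, 1), 0)

  # lowering the PIP threshold can only add genes
  lo <- select_component_genes(dec, 1, sparsity_config(pip_threshold = 0.2))
  expect_true(all(got %in% lo))
})

test_that("gene selection is monotone in both thresholds", {
  for (s in 1:5) {
    set.seed(s)
    dec <- list(X_mean = matrix(rnorm(400), 2),
                pip = matrix(runif(400), 2), gene_ids = as.character(1:200))
    base <- select_component_genes(dec, 1)
    # loosening either rule (lower PIP threshold, wider tail fraction)
    # can only add genes
    for (cfg in list(sparsity_config(pip_threshold = 0.3),
                     sparsity_config(tail_fraction = 0.05))) {
      expect_true(all(base %in% select_component_genes(dec, 1, cfg)))
    }
  }
})

test_that("the sparsity statistic follows its f/g algebra", {
  # two components with identical selected-gene weight, 10 vs 40 genes
  set.seed(2)
  L <- 2000
  mk_row <- function(k) {
    x <- rnorm(L, sd = 1e-4)
    x[seq_len(k)] <- rep(c(3, -3), length.out = k)
    x
  }
  dec <- list(X_mean = rbind(mk_row(10), mk_row(40)),
              pip = rbind(c(rep(0.99, 10), rep(0.01, L - 10)),
                          c(rep(0.99, 40), rep(0.01, L - 40))),
              gene_ids = as.character(seq_len(L)))
  calls <- sparsity_statistic(dec)
  calls <- calls[order(calls$component), ]
  expect_equal(calls$n_genes, c(10, 40))
  expect_equal(calls$weight[1], calls$weight[2])
  expect_equal(calls$statistic[1] / calls$statistic[2], 4)

  # an empty component scores zero and is not sparse
  dec0 <- list(X_mean = matrix(rnorm(100, sd = 0.01), 1),
               pip = matrix(0, 1, 100), gene_ids = as.character(1:100))
  c0 <- sparsity_statistic(dec0)
  expect_equal(c0$statistic, 0)
  expect_false(c0$sparse)
})

test_that("planted sparse and dense components are classified correctly", {
  for (s in 1:3) {
    truth <- simulate_truth(sim_config(seed = s))
    calls <- sparsity_statistic(truth_decomposition(truth))
    calls <- calls[order(calls$component), ]
    expect_equal(calls$sparse, c(rep(TRUE, 4), rep(FALSE, 2)))
  }
})

test_that("the statistic is invariant to sign flips and orient_and_scale", {
  truth <- simulate_truth(sim_config(seed = 13))
  dec <- truth_decomposition(truth)
  flipped <- dec; flipped$X_mean <- -flipped$X_mean
  a <- sparsity_statistic(dec); b <- sparsity_statistic(flipped)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$sparse, b$sparse)

  rk <- make_rank1(12, 40, 2, seed = 3)
  f <- fit_sda(rk$tensor, 2, max_iter = 40, seed = 3)
  s1 <- sparsity_statistic(f)
  s2 <- sparsity_statistic(orient_and_scale(f))
  expect_equal(s1$sparse, s2$sparse)
})

test_that("covariate screening flags confounded components only", {
  set.seed(4)
  n <- 200
  A <- matrix(rnorm(n * 5), n, 5)
  batch <- rep(c("b1", "b2"), each = n / 2)
  A[, 3] <- A[, 3] + 2 * (batch == "b2")      # batch-driven component
  cov <- data.frame(age = rnorm(n), batch = batch,
                    self = A[, 1])
  # the self covariate gives an exact fit; lm warns about it, correctly
  sc <- suppressWarnings(screen_covariates(A, cov))
  expect_true(all(c(1, 3) %in% sc$flagged))
  expect_lt(sc$p_values[1, "self"], 1e-10)
  expect_false(2 %in% sc$flagged)

  # independent covariates on many components: no flags under Bonferroni
  A0 <- matrix(rnorm(150 * 100), 150, 100)
  cov0 <- data.frame(x1 = rnorm(150), x2 = rnorm(150))
  expect_length(screen_covariates(A0, cov0)$flagged, 0)

  expect_warning(sc2 <- screen_covariates(A, data.frame(k = rep(1, n))),
                 "constant")
  expect_true(all(sc2$p_values == 1))
  expect_error(screen_covariates(A, data.frame(x = 1:3)), "align")
})

test_that("two-way reverse correlation matches components across fits", {
  truth <- simulate_truth(sim_config(seed = 17))
  dec <- truth_decomposition(truth)
  self <- match_components(dec, dec, dec$gene_ids)
  expect_equal(self$component_b, self$component_a)
  expect_equal(self$r_forward, rep(1, 6))
  expect_true(all(self$reciprocal))

  # two decompositions sharing 3 loading rows
  set.seed(18)
  L <- 300
  shared <- matrix(rnorm(3 * L, sd = 1), 3, L)
  mk <- function(extra_seed) {
    set.seed(extra_seed)
    X <- rbind(shared + matrix(rnorm(3 * L, sd = 0.05), 3, L),
               matrix(rnorm(2 * L), 2, L))
    list(X_mean = X, pip = matrix(0.9, 5, L),
         gene_ids = as.character(seq_len(L)))
  }
  m <- match_components(mk(1), mk(2), as.character(seq_len(L)))
  expect_true(all(m$reciprocal[1:3]))
  expect_equal(m$component_b[1:3], 1:3)
  expect_true(all(abs(m$r_forward[1:3]) > 0.9))

  # disjoint components: no reciprocal pair above threshold
  d1 <- list(X_mean = matrix(rnorm(2 * L), 2, L), pip = matrix(0.9, 2, L),
             gene_ids = as.character(seq_len(L)))
  d2 <- list(X_mean = matrix(rnorm(2 * L), 2, L), pip = matrix(0.9, 2, L),
             gene_ids = as.character(seq_len(L)))
  expect_false(any(match_components(d1, d2,
                                    as.character(seq_len(L)))$reciprocal))

  expect_error(match_components(d1, d2, as.character(1:5)), "10 shared")
})

test_that("greedy matching assigns each component at most once", {
  set.seed(20)
  X <- matrix(rnorm(4 * 50), 4, 50)
  fitX <- X[c(3, 1, 4, 2), ] + matrix(rnorm(200, sd = 0.01), 4, 50)
  m <- greedy_match_loadings(fitX, X)
  expect_equal(m$fit, c(2, 4, 1, 3))
  expect_true(all(m$r > 0.99))
  expect_equal(anyDuplicated(m$fit), 0)
})
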