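# Synthetic-data generator: genotypes, planted decompositions, expression
# tensors and mediation triples with the statistical structure the pipeline
# assumes, so every downstream stage is testable without cohort downloads.

#' Simulation configuration for the synthetic benchmark
#'
#' Collects the generative quantities of the tensor model: the dimensions of
#' the individuals x genes x conditions array, the number and size of planted
#' sparse components, dense confounder components, SNP effects on component
#' individual scores, per-(gene, condition) noise precisions and the fraction
#' of missing individual x condition slices.
#'
#' The defaults define the package's standard synthetic benchmark: 150
#' individuals, 600 genes, 3 conditions, 4 sparse components of 20 genes each
#' with on-support loadings drawn from N(0, 1), 2 dense confounder components
#' with loadings N(0, 0.1^2) on every gene, noise precision 4 (noise sd 0.5),
#' and no missing slices.
#'
#' @param n_individuals,n_genes,n_tissues Tensor dimensions (N, L, T).
#' @param n_sparse_components Number of planted sparse components.
#' @param n_dense_components Number of planted dense confounder components
#'   (may be zero).
#' @param genes_per_sparse_component Support size k of each sparse component.
#' @param snp_effects A data frame (or tibble) with columns `snp`, `component`
#'   and `beta` giving linear effects of a SNP dosage on a component's
#'   individual scores, or `NULL` for none.
#' @param maf_range Length-2 numeric, the range in (0, 0.5] from which each
#'   simulated SNP's allele frequency is drawn.
#' @param noise_precision_range Length-2 positive numeric; each gene x
#'   condition noise precision lambda_lt is drawn uniformly from this range.
#' @param missing_fraction Fraction in [0, 1) of individual x condition slices
#'   masked as unobserved.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 50, n_genes = 100, seed = 1)
#' cfg$n_sparse_components
sim_config <- function(n_individuals = 150L,
                       n_genes = 600L,
                       n_tissues = 3L,
                       n_sparse_components = 4L,
                       n_dense_components = 2L,
                       genes_per_sparse_component = 20L,
                       snp_effects = NULL,
                       maf_range = c(0.1, 0.4),
                       noise_precision_range = c(4, 4),
                       missing_fraction = 0,
                       seed = 1L) {
  cfg <- list(
    n_individuals = assert_count(n_individuals, "n_individuals"),
    n_genes = assert_count(n_genes, "n_genes"),
    n_tissues = assert_count(n_tissues, "n_tissues"),
    n_sparse_components = assert_count(n_sparse_components,
                                       "n_sparse_components"),
    n_dense_components = assert_count(n_dense_components,
                                      "n_dense_components", min = 0L),
    genes_per_sparse_component = assert_count(genes_per_sparse_component,
                                              "genes_per_sparse_component"),
    snp_effects = snp_effects,
    maf_range = maf_range,
    noise_precision_range = as.numeric(noise_precision_range),
    missing_fraction = assert_fraction(missing_fraction, "missing_fraction",
                                       0, 1, open_hi = TRUE),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$genes_per_sparse_component > cfg$n_genes) {
    stop("`genes_per_sparse_component` cannot exceed `n_genes`", call. = FALSE)
  }
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("`maf_range` must be an increasing pair within (0, 0.5]",
         call. = FALSE)
  }
  if (any(cfg$noise_precision_range <= 0) ||
      cfg$noise_precision_range[1] > cfg$noise_precision_range[2]) {
    stop("`noise_precision_range` must be a non-decreasing positive pair",
         call. = FALSE)
  }
  if (!is.null(snp_effects)) {
    snp_effects <- tibble::as_tibble(snp_effects)
    if (!all(c("snp", "component", "beta") %in% names(snp_effects))) {
      stop("`snp_effects` needs columns snp, component, beta", call. = FALSE)
    }
    if (any(!is.finite(snp_effects$beta))) {
      stop("`snp_effects$beta` must be finite", call. = FALSE)
    }
    cfg$snp_effects <- snp_effects
  }
  structure(cfg, class = "sim_config")
}

#' Simulate biallelic genotype dosages
#'
#' Each SNP's per-individual dosage is drawn as Binomial(2, p) with its allele
#' frequency p drawn uniformly from `[maf_low, maf_high]`. Per-SNP metadata
#' (realized minor allele frequency, Hardy-Weinberg chi-square p-value, and an
#' INFO imputation-quality placeholder of 1) is computed from the realized
#' dosages, mirroring the post-imputation dosage files eQTL pipelines consume.
#'
#' @param n_individuals,n_snps Counts.
#' @param maf_low,maf_high Allele-frequency range, 0 < maf_low <= maf_high
#'   <= 0.5.
#' @param seed Integer seed.
#' @param chrom Chromosome label(s) recycled across SNPs.
#' @return A `genotype_data` object: list with `dosages` (individuals x SNPs
#'   matrix), `snps` (tibble of SNP metadata) and `individual_ids`.
#' @export
#' @examples
#' g <- simulate_genotypes(20, 5, seed = 1)
#' dim(g$dosages)
simulate_genotypes <- function(n_individuals, n_snps, maf_low = 0.1,
                               maf_high = 0.4, seed = 1L, chrom = "1") {
  n <- assert_count(n_individuals, "n_individuals")
  m <- assert_count(n_snps, "n_snps")
  assert_fraction(maf_low, "maf_low", 0, 0.5, open_lo = TRUE)
  assert_fraction(maf_high, "maf_high", maf_low, 0.5)
  dos <- with_seed(derive_seed(seed, 1L), {
    p <- stats::runif(m, maf_low, maf_high)
    matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  })
  ids <- sprintf("ind%03d", seq_len(n))
  snp_ids <- sprintf("rs%05d", seq_len(m))
  rownames(dos) <- ids
  colnames(dos) <- snp_ids
  snps <- tibble::tibble(
    snp_id = snp_ids,
    chrom = rep_len(as.character(chrom), m),
    pos = seq_len(m) * 50000L,
    ref = "A",
    alt = "G",
    maf = unname(apply(dos, 2, compute_maf)),
    hwe_p = unname(apply(dos, 2, function(d) {
      h <- table(factor(round(d), levels = 0:2))
      hwe_test(h[[1]], h[[2]], h[[3]])$p
    })),
    info = 1
  )
  new_genotype_data(dos, snps, ids)
}

new_genotype_data <- function(dosages, snps, individual_ids) {
  stopifnot(ncol(dosages) == nrow(snps), nrow(dosages) ==
              length(individual_ids))
  structure(list(dosages = dosages, snps = tibble::as_tibble(snps),
                 individual_ids = individual_ids),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("<genotype_data> %d individuals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  print(utils::head(x$snps, 5))
  invisible(x)
}

# Condition-activity pattern library for B columns: components are active in
# a single condition, in all conditions, or in a contiguous subset, mirroring
# stimulus-specific vs shared transcriptional programs.
b_pattern <- function(idx, n_tissues) {
  kind <- idx %% 3L
  b <- numeric(n_tissues)
  if (kind == 0L || n_tissues == 1L) {
    b[] <- 1
  } else if (kind == 1L) {
    b[(idx %% n_tissues) + 1L] <- 1
  } else {
    k <- max(2L, ceiling(n_tissues / 2))
    start <- (idx %% n_tissues) + 1L
    b[((start + seq_len(k) - 2L) %% n_tissues) + 1L] <- 1
  }
  b
}

#' Plant a ground-truth decomposition
#'
#' Draws the true individual scores A (N x C), condition scores B (T x C) and
#' gene loadings X (C x L) of the generative tensor model. Sparse components
#' receive k-gene supports with on-support loadings N(0, 1); dense confounder
#' components load weakly (N(0, 0.1^2)) on every gene. Individual scores are
#' standard normal except for genetically driven components, where
#' `A[, c] = beta * dosage + N(0, 1)`.
#'
#' @param config A [sim_config()].
#' @param genotypes A `genotype_data`, required when `config$snp_effects` is
#'   non-empty.
#' @return A `ground_truth` object with elements `A_true`, `B_true`, `X_true`,
#'   `support_true`, `lambda_true`, `snp_effects`, `seed`.
#' @export
simulate_truth <- function(config, genotypes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$n_individuals
  L <- config$n_genes
  Tt <- config$n_tissues
  Cs <- config$n_sparse_components
  Cd <- config$n_dense_components
  C <- Cs + Cd
  k <- config$genes_per_sparse_component
  eff <- config$snp_effects
  if (!is.null(eff) && nrow(eff) > 0) {
    if (is.null(genotypes)) {
      stop("`genotypes` required when snp_effects are planted", call. = FALSE)
    }
    if (any(eff$snp < 1 | eff$snp > ncol(genotypes$dosages))) {
      stop("snp_effects reference SNP indices outside the genotype data",
           call. = FALSE)
    }
    if (any(eff$component < 1 | eff$component > C)) {
      stop("snp_effects reference component indices outside 1..C",
           call. = FALSE)
    }
  }
  with_seed(derive_seed(config$seed, 2L), {
    X <- matrix(0, C, L)
    support <- matrix(0L, C, L)
    for (c in seq_len(Cs)) {
      on <- sample.int(L, k)
      support[c, on] <- 1L
      X[c, on] <- stats::rnorm(k)
    }
    if (Cd > 0) {
      for (c in Cs + seq_len(Cd)) {
        support[c, ] <- 1L
        X[c, ] <- stats::rnorm(L, sd = 0.1)
      }
    }
    B <- vapply(seq_len(C), function(c) b_pattern(c - 1L, Tt), numeric(Tt))
    B <- matrix(B, nrow = Tt, ncol = C)
    A <- matrix(stats::rnorm(N * C), N, C)
    if (!is.null(eff) && nrow(eff) > 0) {
      for (i in seq_len(nrow(eff))) {
        d <- genotypes$dosages[, eff$snp[i]]
        A[, eff$component[i]] <- A[, eff$component[i]] + eff$beta[i] * d
      }
    }
    lambda <- matrix(stats::runif(L * Tt, config$noise_precision_range[1],
                                  config$noise_precision_range[2]), L, Tt)
    structure(list(A_true = A, B_true = B, X_true = X, support_true = support,
                   lambda_true = lambda, snp_effects = eff,
                   seed = config$seed),
              class = "ground_truth")
  })
}

#' Assemble an expression tensor from a planted truth
#'
#' Forms `Y[n, l, t] = sum_c A[n, c] B[t, c] X[c, l] + eps`, with noise drawn
#' independently per entry at precision `lambda_true[l, t]` (so noise sd is
#' `1/sqrt(lambda)`), and masks a random fraction of whole individual x
#' condition slices as unobserved. The mask is repaired so every individual
#' and every condition retains at least one observation.
#'
#' @param truth A `ground_truth` from [simulate_truth()].
#' @param missing_fraction Fraction in [0, 1) of (individual, condition)
#'   slices set to unobserved.
#' @param seed Integer seed for noise and mask.
#' @param noiseless If `TRUE`, omit the noise term entirely.
#' @return An [expression_tensor()] object.
#' @export
assemble_tensor <- function(truth, missing_fraction = 0, seed = 1L,
                            noiseless = FALSE) {
  stopifnot(inherits(truth, "ground_truth"))
  assert_fraction(missing_fraction, "missing_fraction", 0, 1, open_hi = TRUE)
  A <- truth$A_true
  B <- truth$B_true
  X <- truth$X_true
  N <- nrow(A); C <- ncol(A); Tt <- nrow(B); L <- ncol(X)
  stopifnot(ncol(B) == C, nrow(X) == C, nrow(truth$lambda_true) == L,
            ncol(truth$lambda_true) == Tt)
  Y <- array(0, dim = c(N, L, Tt))
  for (t in seq_len(Tt)) {
    Y[, , t] <- A %*% (B[t, ] * X)
  }
  with_seed(derive_seed(seed, 3L), {
    if (!noiseless) {
      for (t in seq_len(Tt)) {
        sds <- 1 / sqrt(truth$lambda_true[, t])
        Y[, , t] <- Y[, , t] +
          matrix(stats::rnorm(N * L, sd = rep(sds, each = N)), N, L)
      }
    }
    mask <- matrix(1L, N, Tt)
    if (missing_fraction > 0) {
      drop <- matrix(stats::runif(N * Tt) < missing_fraction, N, Tt)
      mask[drop] <- 0L
      # every individual and condition must keep at least one observation
      for (n in which(rowSums(mask) == 0)) mask[n, sample.int(Tt, 1L)] <- 1L
      for (t in which(colSums(mask) == 0)) mask[sample.int(N, 1L), t] <- 1L
    }
    expression_tensor(
      values = Y, mask = mask,
      individual_ids = sprintf("ind%03d", seq_len(N)),
      gene_ids = sprintf("gene%04d", seq_len(L)),
      tissue_labels = sprintf("cond%d", seq_len(Tt))
    )
  })
}

#' Simulate a SNP -> cis gene -> trans outcome mediation triple
#'
#' Generates the causal chain used to validate Mendelian-randomization
#' mediation: `cis = alpha * g + e1`, `outcome = gamma * cis + delta * g + e2`
#' with `e1, e2 ~ N(0, 1)`. `delta` is a direct (pleiotropic) SNP effect on
#' the outcome that bypasses the cis gene; the single-instrument ratio
#' estimator attributes `delta / alpha` of it to mediation, which is the
#' documented exclusion-restriction failure mode.
#'
#' @param n Sample size (>= 10).
#' @param maf Allele frequency of the instrument SNP.
#' @param alpha SNP -> cis-gene effect.
#' @param gamma cis-gene -> outcome effect.
#' @param delta Direct SNP -> outcome (pleiotropic) effect.
#' @param seed Integer seed.
#' @return A tibble with columns `dosage`, `cis`, `outcome`.
#' @export
#' @examples
#' tr <- simulate_mediation_triple(200, 0.3, alpha = 1, gamma = 0.8, seed = 1)
#' cov(tr$outcome, tr$dosage) / cov(tr$cis, tr$dosage)
simulate_mediation_triple <- function(n, maf = 0.3, alpha = 1, gamma = 0.5,
                                      delta = 0, seed = 1L) {
  n <- assert_count(n, "n", min = 10L)
  assert_fraction(maf, "maf", 0, 0.5, open_lo = TRUE)
  with_seed(derive_seed(seed, 4L), {
    g <- stats::rbinom(n, 2L, maf)
    cis <- alpha * g + stats::rnorm(n)
    outcome <- gamma * cis + delta * g + stats::rnorm(n)
    tibble::tibble(dosage = g, cis = cis, outcome = outcome)
  })
}

#' Normalize an expression matrix by gene means and log2-transform
#'
#' Divides each gene's expression values by that gene's mean across
#' individuals and applies log2, so a gene at its mean maps to 0. All values
#' must be strictly positive.
#'
#' @param mat Numeric matrix, genes x individuals; row names are gene ids.
#' @return Matrix of the same shape, log2 of mean-scaled expression.
#' @export
#' @examples
#' normalize_expression(matrix(c(1, 4, 2, 2), nrow = 2, byrow = TRUE))
normalize_expression <- function(mat) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("`mat` must be numeric", call. = FALSE)
  bad <- which(apply(mat, 1, function(r) any(!is.finite(r) | r <= 0)))
  if (length(bad)) {
    nm <- rownames(mat)[bad[1]] %||% as.character(bad[1])
    stop(sprintf(
      "normalize_expression: gene '%s' has non-positive or non-finite values",
      nm), call. = FALSE)
  }
  log2(mat / rowMeans(mat))
}
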