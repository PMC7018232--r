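# Genotype QC, component trans-eQTL regression with BH FDR and a permutation
# empirical null, SNP-by-gene cis mapping with latent-factor correction,
# LD pruning and GWAS-catalog overlap.

#' Minor allele frequency of a dosage vector
#'
#' The alternate-allele frequency folded into [0, 0.5].
#'
#' @param dosages Numeric vector of allele dosages in [0, 2].
#' @return A frequency in [0, 0.5].
#' @export
#' @examples
#' compute_maf(c(0, 1, 2, 2))  # 0.375
compute_maf <- function(dosages) {
  if (length(dosages) == 0) stop("empty dosage vector", call. = FALSE)
  f <- mean(dosages) / 2
  min(f, 1 - f)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit of observed genotype counts against
#' Hardy-Weinberg expectations computed from the sample allele frequency.
#' Monomorphic sites return p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (dosages hard-called by rounding
#'   when fractional).
#' @return A list with `chi2` and `p`.
#' @export
#' @examples
#' hwe_test(30, 40, 30)  # chi2 = 4, p ~ 0.0455
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required", call. = FALSE)
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(chi2 = 0, p = 1))
  }
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expd)^2 / expd)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Filter SNPs on MAF, HWE and imputation quality
#'
#' Keeps SNPs with `maf > maf_min`, `hwe_p > hwe_p_min` and
#' `info >= info_min`, preserving order. The defaults are the association
#' -stage filter (MAF > 0.05, HWE p > 0.001); setting `maf_min = 0.01,
#' info_min = 0.3, hwe_p_min = 1e-6` reproduces an imputation-stage filter.
#'
#' @param genotypes A `genotype_data`.
#' @param maf_min,hwe_p_min,info_min Thresholds.
#' @return A filtered `genotype_data`.
#' @export
filter_snps <- function(genotypes, maf_min = 0.05, hwe_p_min = 0.001,
                        info_min = 0) {
  stopifnot(inherits(genotypes, "genotype_data"))
  keep <- genotypes$snps$maf > maf_min & genotypes$snps$hwe_p > hwe_p_min &
    genotypes$snps$info >= info_min
  new_genotype_data(genotypes$dosages[, keep, drop = FALSE],
                    genotypes$snps[keep, ], genotypes$individual_ids)
}

# Vectorized OLS of each column of `scores` (N x C) on each column of
# `dosages` (N x M) with intercept: returns list of M x C matrices.
ols_grid <- function(dosages, scores) {
  n <- nrow(dosages)
  stopifnot(nrow(scores) == n, n > 2)
  xc <- sweep(dosages, 2, colMeans(dosages))
  yc <- sweep(scores, 2, colMeans(scores))
  sxx <- colSums(xc^2)
  sxy <- crossprod(xc, yc)                  # M x C
  syy <- colSums(yc^2)
  beta <- sxy / sxx
  # residual SS = syy - beta^2 * sxx
  rss <- sweep(-beta^2 * sxx, 2, syy, `+`)
  sigma2 <- pmax(rss, 0) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(beta = beta, se = se, t = tstat, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Map component individual scores to genotype dosages (trans-eQTLs)
#'
#' For every SNP x component pair, ordinary least squares of the component's
#' individual scores on the allele dosage (with intercept) and a two-sided
#' t-test on the slope. Benjamini-Hochberg correction is applied jointly
#' across all SNP x component tests (genome-wide correction, not
#' per-component).
#'
#' @param A Individual-score matrix (individuals x components), e.g.
#'   `fit$A` of an [fit_sda()] fit, individuals aligned with `genotypes`.
#' @param genotypes A `genotype_data`, already QC-filtered.
#' @param fdr_level FDR at which `significant` is flagged (default 0.05).
#' @return A tibble of class `eqtl_result` with columns `snp_id`,
#'   `component`, `beta`, `se`, `t`, `p`, `q`, `significant`.
#' @export
map_component_trans_eqtl <- function(A, genotypes, fdr_level = 0.05) {
  stopifnot(inherits(genotypes, "genotype_data"))
  A <- as.matrix(A)
  if (nrow(A) != nrow(genotypes$dosages)) {
    stop("individuals of `A` and `genotypes` are not aligned", call. = FALSE)
  }
  dos <- genotypes$dosages
  keep <- apply(dos, 2, stats::var) > 0
  if (any(!keep)) {
    warning(sprintf("%d zero-variance SNP(s) skipped", sum(!keep)))
    dos <- dos[, keep, drop = FALSE]
  }
  snp_ids <- genotypes$snps$snp_id[keep]
  C <- ncol(A)
  comp_ids <- colnames(A) %||% as.character(seq_len(C))
  g <- ols_grid(dos, A)
  out <- tibble::tibble(
    snp_id = rep(snp_ids, times = C),
    component = rep(comp_ids, each = length(snp_ids)),
    beta = as.vector(g$beta), se = as.vector(g$se), t = as.vector(g$t),
    p = as.vector(g$p)
  )
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr_level
  class(out) <- c("eqtl_result", class(out))
  out
}

#' Permutation empirical null for trans-eQTL p-values
#'
#' Permutes the rows of the individual-score matrix relative to the genotypes
#' `n_perm` times and recomputes all association p-values each round. The
#' null p-values are pooled per component across SNPs (`pool = "component"`,
#' the default) or kept per SNP x component pair (`pool = "snp"`), and each
#' observed association receives
#' `perm_p = (1 + #(null p <= observed p)) / (1 + #null)`.
#'
#' @param A Individual-score matrix.
#' @param genotypes A `genotype_data`.
#' @param observed Result of [map_component_trans_eqtl()] on the same data.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param pool `"component"` or `"snp"`.
#' @return `observed` with a `perm_p` column appended.
#' @export
permutation_pvalues <- function(A, genotypes, observed, n_perm = 1000L,
                                seed = 1L, pool = c("component", "snp")) {
  n_perm <- assert_count(n_perm, "n_perm", min = 100L)
  pool <- match.arg(pool)
  A <- as.matrix(A)
  dos <- genotypes$dosages
  keep <- apply(dos, 2, stats::var) > 0
  dos <- dos[, keep, drop = FALSE]
  M <- ncol(dos)
  C <- ncol(A)
  comp_ids <- colnames(A) %||% as.character(seq_len(C))
  null_p <- with_seed(derive_seed(seed, 6L), {
    lapply(seq_len(n_perm), function(i) {
      ols_grid(dos, A[sample.int(nrow(A)), , drop = FALSE])$p
    })
  })
  perm_p <- numeric(nrow(observed))
  for (ci in seq_len(C)) {
    pool_vals <- if (pool == "component") {
      sort(unlist(lapply(null_p, function(m) m[, ci])))
    } else {
      NULL
    }
    idx <- which(observed$component == comp_ids[ci])
    if (pool == "component") {
      cnt <- findInterval(observed$p[idx], pool_vals)
      perm_p[idx] <- (1 + cnt) / (1 + length(pool_vals))
    } else {
      snp_pos <- match(observed$snp_id[idx], genotypes$snps$snp_id[keep])
      nulls <- vapply(null_p, function(m) m[snp_pos, ci],
                      numeric(length(idx)))
      nulls <- matrix(nulls, nrow = length(idx))
      cnt <- rowSums(nulls <= observed$p[idx])
      perm_p[idx] <- (1 + cnt) / (1 + n_perm)
    }
  }
  observed$perm_p <- perm_p
  observed
}

#' Pairwise linkage-disequilibrium r-squared
#'
#' Squared Pearson correlation of two dosage vectors.
#'
#' @param dosages_i,dosages_j Equal-length polymorphic dosage vectors.
#' @return r-squared in [0, 1].
#' @export
ld_r2 <- function(dosages_i, dosages_j) {
  if (length(dosages_i) != length(dosages_j)) {
    stop("dosage vectors differ in length", call. = FALSE)
  }
  if (stats::var(dosages_i) == 0 || stats::var(dosages_j) == 0) {
    stop("ld_r2 requires polymorphic SNPs", call. = FALSE)
  }
  stats::cor(dosages_i, dosages_j)^2
}

#' Greedy LD pruning
#'
#' Iterates SNPs in priority order and keeps a SNP only if its r-squared with
#' every already-kept SNP on the same chromosome stays below `r2_max`. With
#' `priority = "by_position"` SNPs are visited in map order; passing a
#' numeric vector of p-values visits them in ascending p (best associations
#' retained first).
#'
#' @param genotypes A `genotype_data`.
#' @param r2_max Pruning threshold in (0, 1].
#' @param priority `"by_position"` or a numeric vector of per-SNP p-values.
#' @return Character vector of kept SNP ids.
#' @export
ld_prune <- function(genotypes, r2_max = 0.4, priority = "by_position") {
  stopifnot(inherits(genotypes, "genotype_data"))
  assert_fraction(r2_max, "r2_max", 0, 1, open_lo = TRUE)
  M <- ncol(genotypes$dosages)
  ord <- if (is.numeric(priority)) {
    if (length(priority) != M) {
      stop("`priority` p-values must match the number of SNPs",
           call. = FALSE)
    }
    order(priority)
  } else {
    order(genotypes$snps$chrom, genotypes$snps$pos)
  }
  kept <- integer(0)
  for (j in ord) {
    dj <- genotypes$dosages[, j]
    if (stats::var(dj) == 0) next
    same_chr <- kept[genotypes$snps$chrom[kept] == genotypes$snps$chrom[j]]
    ok <- TRUE
    for (k in same_chr) {
      if (ld_r2(dj, genotypes$dosages[, k]) >= r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, j)
  }
  genotypes$snps$snp_id[sort(kept)]
}

#' Cis-eQTL mapping with latent-factor correction
#'
#' Residualizes the expression matrix against its leading latent factors
#' (truncated SVD of the gene-centered matrix, a stand-alone analogue of
#' factor-model confounder correction), then regresses each gene on every SNP
#' whose position lies within `window` of the gene's transcription start or
#' end site (inclusive, 1-based coordinates). BH correction is applied across
#' all cis tests.
#'
#' @param expression Genes x individuals matrix with gene ids as row names.
#' @param genotypes A `genotype_data` aligned to the columns.
#' @param annotations A data frame with columns `gene_id`, `chrom`, `tss`,
#'   `tes`, `strand`.
#' @param window Cis window in bases either side of TSS/TES (default 1e6).
#' @param n_factors Latent factors removed before association (default 15;
#'   0 disables correction).
#' @param fdr_level FDR flagging level.
#' @return An `eqtl_result` tibble with columns `snp_id`, `gene_id`, `beta`,
#'   `se`, `t`, `p`, `q`, `significant`.
#' @export
map_cis_eqtl <- function(expression, genotypes, annotations, window = 1e6,
                         n_factors = 15L, fdr_level = 0.05) {
  stopifnot(inherits(genotypes, "genotype_data"))
  expression <- as.matrix(expression)
  if (ncol(expression) != nrow(genotypes$dosages)) {
    stop("expression columns and genotype individuals are not aligned",
         call. = FALSE)
  }
  annotations <- tibble::as_tibble(annotations)
  gene_ids <- rownames(expression) %||%
    stop("`expression` needs gene row names", call. = FALSE)
  resid <- residualize_factors(expression, n_factors)
  snps <- genotypes$snps
  rec <- vector("list", length(gene_ids))
  for (i in seq_along(gene_ids)) {
    ann <- annotations[annotations$gene_id == gene_ids[i], ]
    if (nrow(ann) == 0) {
      warning(sprintf("gene '%s' has no annotation; skipped", gene_ids[i]))
      next
    }
    lo <- min(ann$tss[1], ann$tes[1]) - window
    hi <- max(ann$tss[1], ann$tes[1]) + window
    sel <- which(snps$chrom == ann$chrom[1] & snps$pos >= lo &
                   snps$pos <= hi)
    if (!length(sel)) next
    dos <- genotypes$dosages[, sel, drop = FALSE]
    poly <- apply(dos, 2, stats::var) > 0
    sel <- sel[poly]
    if (!length(sel)) next
    g <- ols_grid(dos[, poly, drop = FALSE],
                  matrix(resid[i, ], ncol = 1))
    rec[[i]] <- tibble::tibble(
      snp_id = snps$snp_id[sel], gene_id = gene_ids[i],
      beta = as.vector(g$beta), se = as.vector(g$se), t = as.vector(g$t),
      p = as.vector(g$p))
  }
  out <- dplyr::bind_rows(rec)
  if (nrow(out)) {
    out$q <- bh_fdr(out$p)
    out$significant <- out$q < fdr_level
  }
  class(out) <- c("eqtl_result", class(out))
  out
}

# Remove the top-k latent factors (right singular vectors over individuals)
# from a gene-centered expression matrix.
residualize_factors <- function(expression, n_factors) {
  n_factors <- assert_count(n_factors, "n_factors", min = 0L)
  centered <- expression - rowMeans(expression)
  if (n_factors == 0) return(centered)
  k <- min(n_factors, nrow(centered) - 1L, ncol(centered) - 1L)
  sv <- svd(centered, nu = 0, nv = k)
  centered - (centered %*% sv$v) %*% t(sv$v)
}

#' Overlap trans-eQTLs with a GWAS catalog
#'
#' Joins trans-eQTL records below `fdr_max` to catalog entries by SNP id.
#' The catalog is expected to be pre-filtered to genome-wide significance
#' (p < 5e-8) and LD-pruned.
#'
#' @param trans_records An `eqtl_result` from [map_component_trans_eqtl()].
#' @param catalog A data frame with columns `snp_id`, `trait`, `p`.
#' @param fdr_max Liberal FDR for trait-overlap reporting (default 0.15).
#' @return A tibble with columns `snp_id`, `trait`, `component`, `q` and,
#'   when present, `perm_p`.
#' @export
overlap_gwas <- function(trans_records, catalog, fdr_max = 0.15) {
  catalog <- tibble::as_tibble(catalog)
  hits <- trans_records[trans_records$q < fdr_max, , drop = FALSE]
  out <- dplyr::inner_join(
    tibble::as_tibble(hits), catalog, by = "snp_id",
    suffix = c("", ".gwas"), relationship = "many-to-many")
  cols <- c("snp_id", "trait", "component", "q",
            intersect("perm_p", names(out)))
  out[, cols, drop = FALSE]
}
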