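# Shared fixture builders. Everything is generated in code at test time.

# A noiseless rank-1 tensor with known factors.
make_rank1 <- function(N = 10, L = 30, Tt = 3, seed = 1) {
  set.seed(seed)
  a <- rnorm(N); b <- rnorm(Tt); x <- rnorm(L)
  Y <- array(0, c(N, L, Tt))
  for (t in seq_len(Tt)) Y[, , t] <- outer(a, x) * b[t]
  list(tensor = expression_tensor(Y), a = a, b = b, x = x)
}

# A decomposition-like object carrying the planted truth, for exercising
# component calling independently of the variational fit.
truth_decomposition <- function(truth) {
  list(X_mean = truth$X_true,
       pip = ifelse(truth$support_true == 1, 0.99, 0.01),
       gene_ids = sprintf("gene%04d", seq_len(ncol(truth$X_true))))
}

# Hand-built genotype container with designed metadata.
fake_genotypes <- function(dosages, maf = NULL, hwe_p = NULL, info = NULL,
                           chrom = "1", pos = NULL) {
  m <- ncol(dosages)
  snps <- tibble::tibble(
    snp_id = sprintf("s%03d", seq_len(m)),
    chrom = rep_len(chrom, m),
    pos = pos %||% (seq_len(m) * 1000L),
    ref = "A", alt = "G",
    maf = maf %||% apply(dosages, 2, compute_maf),
    hwe_p = hwe_p %||% rep(1, m),
    info = info %||% rep(1, m))
  colnames(dosages) <- snps$snp_id
  structure(list(dosages = dosages, snps = snps,
                 individual_ids = sprintf("i%03d", seq_len(nrow(dosages)))),
            class = "genotype_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force BH step-up: q_(i) = min_{j >= i} min(1, m p_(j) / j).
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}
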