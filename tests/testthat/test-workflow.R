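# Orchestration and I/O: round trips, the synthetic end-to-end run, its
# determinism, and run summaries.

small_config <- function(seed = 3) {
  pipeline_config(
    sim = sim_config(n_individuals = 80, n_genes = 150, n_tissues = 2,
                     n_sparse_components = 2, n_dense_components = 1,
                     genes_per_sparse_component = 10, seed = seed),
    n_snps = 30L, n_components = 5L, max_iter = 80L, n_perm = 100L,
    n_mediation_chains = 2L, n_mediation_nulls = 2L, seed = seed)
}

test_that("genotype VCF and TSV writers round-trip through the readers", {
  g <- simulate_genotypes(25, 8, seed = 51)
  vcf <- file.path(withr::local_tempdir(), "g.vcf")
  write_genotypes(g, vcf)
  back <- read_genotypes(vcf)
  expect_equal(unname(back$dosages), unname(g$dosages))
  expect_equal(back$snps$maf, g$snps$maf, tolerance = 1e-6)
  expect_equal(back$individual_ids, g$individual_ids)

  tsv <- file.path(withr::local_tempdir(), "g.tsv")
  write_genotypes(g, tsv)
  back2 <- read_genotypes(tsv)
  expect_equal(unname(back2$dosages), unname(g$dosages))
  expect_equal(back2$snps$hwe_p, g$snps$hwe_p)
})

test_that("GT-only VCF yields allele-count dosages", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "gt.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "i1", "i2", "i3"), collapse = "\t"),
    paste(c("1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1|1"), collapse = "\t")), vcf)
  g <- read_genotypes(vcf)
  expect_equal(as.vector(g$dosages), c(0, 1, 2))
  expect_equal(g$snps$maf, 0.5)
})

test_that("malformed VCF records are reported with their line number", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "bad.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "i1"), collapse = "\t"),
    paste(c("1", "100", "v1", "A", "G", ".", "PASS", ".", "DS", "1"),
          collapse = "\t"),
    "1\t200\tv2\tA"), vcf)
  expect_error(read_genotypes(vcf), "line 4")
  writeLines("just text", file.path(dir, "not.vcf"))
  expect_error(read_genotypes(file.path(dir, "not.vcf")), "#CHROM")
})

test_that("expression tensors round-trip through per-condition TSVs", {
  cfg <- sim_config(n_individuals = 15, n_genes = 12, n_tissues = 2,
                    n_sparse_components = 1, n_dense_components = 0,
                    genes_per_sparse_component = 3, seed = 52)
  y <- assemble_tensor(simulate_truth(cfg), missing_fraction = 0.15,
                       seed = 52)
  dir <- file.path(withr::local_tempdir(), "tensor")
  write_expression_tensor(y, dir)
  back <- read_expression_tensor(dir)
  expect_equal(back$values, y$values, tolerance = 1e-12)
  expect_identical(back$mask, y$mask)
  expect_identical(back$gene_ids, y$gene_ids)
})

test_that("decompositions round-trip with their metadata", {
  rk <- make_rank1(8, 20, 2, seed = 53)
  f <- fit_sda(rk$tensor, 2, max_iter = 30, seed = 53)
  dir <- file.path(withr::local_tempdir(), "dec")
  write_decomposition(f, dir)
  back <- read_decomposition(dir)
  expect_equal(unname(back$A), unname(f$A), tolerance = 1e-12)
  expect_equal(unname(back$pip), unname(f$pip), tolerance = 1e-12)
  expect_equal(back$elbo_trace, f$elbo_trace, tolerance = 1e-12)
  expect_equal(back$converged, f$converged)
  # the reloaded decomposition feeds component calling directly
  expect_s3_class(sparsity_statistic(back), "component_calls")
})

test_that("the synthetic pipeline runs all stages deterministically", {
  cfg <- small_config()
  d1 <- file.path(withr::local_tempdir(), "r1")
  d2 <- file.path(withr::local_tempdir(), "r2")
  run_pipeline(cfg, d1)
  run_pipeline(cfg, d2)
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_named(m1$stages,
               c("simulate", "decompose", "components", "screen",
                 "trans_eqtl", "permutation", "gwas", "mediation"))
  expect_identical(m1$stages, m2$stages)   # per-file checksums equal
  s <- summarize_run(d1)
  expect_true(s$n_trans_eqtl_tests > 0)
  expect_true(is.finite(s$recovery$mean_matched_loading_r))
  expect_true(file.exists(file.path(d1, "summary.json")))
})

test_that("pipeline configuration is validated before any stage runs", {
  expect_error(pipeline_config(mode = "real"), "requires existing")
  expect_error(summarize_run(withr::local_tempdir()), "manifest")
  dir <- withr::local_tempdir()
  jsonlite::write_json(list(stages = list(simulate = list())),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  expect_error(summarize_run(dir), "missing stage")
})

test_that("pipeline configuration reads from YAML", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c(
    "mode: synthetic",
    "seed: 5",
    "n_snps: 25",
    "n_components: 4",
    "sim:",
    "  n_individuals: 50",
    "  n_genes: 100",
    "  seed: 5"), yml)
  cfg <- read_pipeline_config(yml)
  expect_s3_class(cfg, "pipeline_config")
  expect_equal(cfg$n_snps, 25L)
  expect_equal(cfg$sim$n_individuals, 50L)
})
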