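# End-to-end orchestration: simulate (or load) -> decompose -> call sparse
# components -> covariate screen -> trans-eQTL -> permutation null -> GWAS
# overlap -> mediation, with every stage's outputs written as TSV/JSON and a
# manifest of per-stage checksums for reproducibility checks.

PIPELINE_STAGES <- c("simulate", "decompose", "components", "screen",
                     "trans_eqtl", "permutation", "gwas", "mediation")

#' Pipeline configuration
#'
#' Collects every stage parameter of [run_pipeline()]. In synthetic mode the
#' generator settings come from a [sim_config()]; in real mode, paths to an
#' expression-tensor directory and a genotype file are required (covariates,
#' annotations and a GWAS catalog optional).
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param sim A [sim_config()] (synthetic mode).
#' @param expression_dir,genotype_path,covariate_path,gwas_path Input paths
#'   (real mode; `covariate_path` and `gwas_path` optional).
#' @param n_snps Number of simulated SNPs (synthetic mode).
#' @param snp_effects Planted SNP-on-component effects forwarded to
#'   [sim_config()]; default plants `beta = 1.5` of SNP 1 on component 1.
#' @param n_components,max_iter,init Decomposition settings.
#' @param sparsity A [sparsity_config()].
#' @param maf_min,hwe_p_min,info_min Genotype QC thresholds.
#' @param fdr,fdr_gwas FDR levels for trans-eQTL reporting (0.05) and
#'   GWAS-overlap reporting (0.15).
#' @param n_perm Permutations for the empirical null.
#' @param r2_prune LD-pruning threshold for the synthetic GWAS catalog.
#' @param n_mediation_chains,n_mediation_nulls Planted and null mediation
#'   triples exercised by the mediation stage (synthetic mode).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"),
                            sim = sim_config(seed = seed),
                            expression_dir = NULL, genotype_path = NULL,
                            covariate_path = NULL, gwas_path = NULL,
                            n_snps = 60L,
                            snp_effects = tibble::tibble(
                              snp = 1L, component = 1L, beta = 1.5),
                            n_components = 8L, max_iter = 150L,
                            init = "svd",
                            sparsity = sparsity_config(),
                            maf_min = 0.05, hwe_p_min = 0.001, info_min = 0,
                            fdr = 0.05, fdr_gwas = 0.15, n_perm = 200L,
                            r2_prune = 0.4,
                            n_mediation_chains = 3L, n_mediation_nulls = 3L,
                            seed = 1L) {
  mode <- match.arg(mode)
  seed <- assert_count(seed, "seed", min = 0L)
  assert_fraction(fdr, "fdr", 0, 1, TRUE, TRUE)
  assert_fraction(fdr_gwas, "fdr_gwas", 0, 1, TRUE, TRUE)
  if (mode == "real") {
    if (is.null(expression_dir) || !file.exists(expression_dir) ||
        is.null(genotype_path) || !file.exists(genotype_path)) {
      stop("real mode requires existing expression_dir and genotype_path",
           call. = FALSE)
    }
  }
  if (mode == "synthetic" && !is.null(snp_effects) && nrow(snp_effects)) {
    sim$snp_effects <- tibble::as_tibble(snp_effects)
  }
  structure(list(
    mode = mode, sim = sim, expression_dir = expression_dir,
    genotype_path = genotype_path, covariate_path = covariate_path,
    gwas_path = gwas_path, n_snps = assert_count(n_snps, "n_snps"),
    n_components = assert_count(n_components, "n_components"),
    max_iter = assert_count(max_iter, "max_iter"), init = init,
    sparsity = sparsity, maf_min = maf_min, hwe_p_min = hwe_p_min,
    info_min = info_min, fdr = fdr, fdr_gwas = fdr_gwas,
    n_perm = assert_count(n_perm, "n_perm", min = 100L),
    r2_prune = r2_prune,
    n_mediation_chains = assert_count(n_mediation_chains,
                                      "n_mediation_chains", min = 0L),
    n_mediation_nulls = assert_count(n_mediation_nulls,
                                     "n_mediation_nulls", min = 0L),
    seed = seed), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML keys mirror the [pipeline_config()] arguments; `sim:` may hold
#' a nested block of [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$sparsity)) y$sparsity <- do.call(sparsity_config, y$sparsity)
  if (!is.null(y$snp_effects)) {
    y$snp_effects <- tibble::as_tibble(y$snp_effects)
  }
  do.call(pipeline_config, y)
}

stage_file <- function(run_dir, stage, name) {
  file.path(run_dir, stage, name)
}

write_stage <- function(run_dir, stage, writer) {
  dir <- file.path(run_dir, stage)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writer(dir)
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  sums <- tools::md5sum(files)
  names(sums) <- substring(files, nchar(run_dir) + 2L)
  as.list(sums)
}

#' Run the full component trans-eQTL pipeline
#'
#' Executes the stages simulate, decompose, components, screen, trans_eqtl,
#' permutation, gwas and mediation in order, writing each stage's outputs
#' under `run_dir/<stage>/` and a `manifest.json` with the configuration,
#' per-stage seeds and per-file checksums. A failed stage halts the run with
#' a stage-tagged error; completed stage outputs are retained.
#'
#' @param config A [pipeline_config()].
#' @param run_dir Output directory (created).
#' @return `run_dir`, invisibly.
#' @export
run_pipeline <- function(config, run_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(mode = config$mode, seed = config$seed,
                   stage_seeds = list(), stages = list())
  run_stage <- function(stage, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[stage]] <<- res
    manifest$stage_seeds[[stage]] <<-
      derive_seed(config$seed, match(stage, PIPELINE_STAGES))
  }
  sd_of <- function(stage) derive_seed(config$seed,
                                       match(stage, PIPELINE_STAGES))

  ## 1. simulate (or load) ------------------------------------------------
  truth <- NULL
  if (config$mode == "synthetic") {
    genotypes <- simulate_genotypes(config$sim$n_individuals, config$n_snps,
                                    config$sim$maf_range[1],
                                    config$sim$maf_range[2],
                                    seed = sd_of("simulate"))
    truth <- simulate_truth(config$sim, genotypes)
    tensor <- assemble_tensor(truth, config$sim$missing_fraction,
                              seed = sd_of("simulate"))
    covariates <- with_seed(derive_seed(sd_of("simulate"), 99L), {
      tibble::tibble(
        age = stats::rnorm(config$sim$n_individuals, 50, 10),
        sex = sample(c("F", "M"), config$sim$n_individuals, replace = TRUE))
    })
    run_stage("simulate", function() write_stage(run_dir, "simulate",
      function(dir) {
        write_genotypes(genotypes, file.path(dir, "genotypes.vcf"))
        write_expression_tensor(tensor, file.path(dir, "tensor"))
        readr::write_tsv(covariates, file.path(dir, "covariates.tsv"))
        # planted truth, for recovery scoring by summarize_run
        jsonlite::write_json(list(
          snp_effects = truth$snp_effects,
          support_true = truth$support_true,
          X_true = truth$X_true),
          file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
      }))
  } else {
    tensor <- read_expression_tensor(config$expression_dir)
    genotypes <- read_genotypes(config$genotype_path)
    covariates <- if (!is.null(config$covariate_path)) {
      readr::read_tsv(config$covariate_path, show_col_types = FALSE)
    } else NULL
    run_stage("simulate", function() write_stage(run_dir, "simulate",
      function(dir) {
        jsonlite::write_json(list(
          inputs = list(expression = config$expression_dir,
                        genotypes = config$genotype_path)),
          file.path(dir, "inputs.json"), auto_unbox = TRUE)
      }))
  }

  ## 2. decompose ----------------------------------------------------------
  fit <- fit_sda(tensor, config$n_components, max_iter = config$max_iter,
                 seed = sd_of("decompose"), init = config$init)
  fit <- orient_and_scale(fit)
  run_stage("decompose", function() write_stage(run_dir, "decompose",
    function(dir) write_decomposition(fit, file.path(dir, "decomposition"))))

  ## 3. sparse-component calling -------------------------------------------
  calls <- sparsity_statistic(fit, config$sparsity)
  run_stage("components", function() write_stage(run_dir, "components",
    function(dir) {
      out <- calls
      out$genes <- vapply(out$genes, paste, character(1), collapse = ";")
      readr::write_tsv(out, file.path(dir, "component_calls.tsv"))
    }))

  ## 4. covariate screen ----------------------------------------------------
  screened <- if (!is.null(covariates)) {
    screen_covariates(fit$A, covariates)
  } else {
    list(p_values = matrix(numeric(0), ncol(fit$A), 0), flagged = integer(0))
  }
  run_stage("screen", function() write_stage(run_dir, "screen",
    function(dir) {
      jsonlite::write_json(list(flagged = screened$flagged),
                           file.path(dir, "flagged.json"), digits = NA)
      if (ncol(screened$p_values)) {
        pv <- tibble::as_tibble(screened$p_values, .name_repair = "minimal")
        pv <- dplyr::bind_cols(
          tibble::tibble(component = seq_len(nrow(screened$p_values))), pv)
        readr::write_tsv(pv, file.path(dir, "covariate_pvalues.tsv"))
      }
    }))

  ## 5. trans-eQTL ----------------------------------------------------------
  sparse_keep <- setdiff(calls$component[calls$sparse], screened$flagged)
  if (!length(sparse_keep)) {
    sparse_keep <- setdiff(seq_len(ncol(fit$A)), screened$flagged)
  }
  A_use <- fit$A[, sparse_keep, drop = FALSE]
  colnames(A_use) <- as.character(sparse_keep)
  geno_qc <- filter_snps(genotypes, config$maf_min, config$hwe_p_min,
                         config$info_min)
  trans <- map_component_trans_eqtl(A_use, geno_qc, config$fdr)
  run_stage("trans_eqtl", function() write_stage(run_dir, "trans_eqtl",
    function(dir) readr::write_tsv(trans, file.path(dir, "trans_eqtl.tsv"))))

  ## 6. permutation null -----------------------------------------------------
  trans <- permutation_pvalues(A_use, geno_qc, trans, config$n_perm,
                               seed = sd_of("permutation"))
  run_stage("permutation", function() write_stage(run_dir, "permutation",
    function(dir) readr::write_tsv(trans,
                                   file.path(dir, "trans_eqtl_perm.tsv"))))

  ## 7. GWAS-catalog overlap -------------------------------------------------
  catalog <- if (config$mode == "real" && !is.null(config$gwas_path)) {
    readr::read_tsv(config$gwas_path, show_col_types = FALSE)
  } else {
    synthetic_gwas_catalog(geno_qc, truth, config$r2_prune,
                           seed = sd_of("gwas"))
  }
  overlaps <- overlap_gwas(trans, catalog, config$fdr_gwas)
  run_stage("gwas", function() write_stage(run_dir, "gwas",
    function(dir) {
      readr::write_tsv(catalog, file.path(dir, "catalog.tsv"))
      readr::write_tsv(overlaps, file.path(dir, "overlaps.tsv"))
    }))

  ## 8. mediation -------------------------------------------------------------
  med <- pipeline_mediation(config, seed = sd_of("mediation"))
  run_stage("mediation", function() write_stage(run_dir, "mediation",
    function(dir) readr::write_tsv(med, file.path(dir, "mediation.tsv"))))

  jsonlite::write_json(
    c(manifest, list(n_stages = length(manifest$stages))),
    file.path(run_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(run_dir)
}

# A GWAS-catalog-like table for synthetic runs: the planted trans-eSNPs (if
# any) plus a few additional catalog SNPs, all at genome-wide significance,
# LD-pruned by position.
synthetic_gwas_catalog <- function(genotypes, truth, r2_prune = 0.4,
                                   seed = 1L) {
  planted <- if (!is.null(truth) && !is.null(truth$snp_effects)) {
    # planted indices refer to pre-QC SNP order; map by id when still present
    sprintf("rs%05d", truth$snp_effects$snp)
  } else character(0)
  with_seed(derive_seed(seed, 7L), {
    extra <- setdiff(genotypes$snps$snp_id, planted)
    extra <- sample(extra, min(3L, length(extra)))
    cat_ids <- c(planted, extra)
    kept <- ld_prune(genotypes, r2_prune)
    cat_ids <- cat_ids[cat_ids %in% kept | !(cat_ids %in%
                                               genotypes$snps$snp_id)]
    tibble::tibble(
      snp_id = cat_ids,
      trait = paste0("trait", seq_along(cat_ids)),
      p = stats::runif(length(cat_ids), 1e-12, 4e-8))
  })
}

# The mediation stage of a synthetic run works on planted chain triples
# (SNP -> cis gene -> outcome) plus null triples, generated at the stage
# seed so the stage is independently re-executable.
pipeline_mediation <- function(config, seed) {
  n <- config$sim$n_individuals %||% 300L
  n <- max(n, 30L)
  chains <- config$n_mediation_chains
  nulls <- config$n_mediation_nulls
  rows <- list()
  for (i in seq_len(chains)) {
    tr <- simulate_mediation_triple(n, 0.3, alpha = 1, gamma = 0.8,
                                    delta = 0, seed = derive_seed(seed, i))
    rows[[length(rows) + 1L]] <-
      dplyr::mutate(mr_mediation(tr$dosage, tr$cis, tr$outcome,
                                 snp_id = sprintf("chain%02d", i),
                                 mediator_gene = sprintf("cis%02d", i),
                                 outcome_id = sprintf("target%02d", i)),
                    planted = TRUE)
  }
  for (i in seq_len(nulls)) {
    tr <- simulate_mediation_triple(n, 0.3, alpha = 1, gamma = 0,
                                    delta = 0,
                                    seed = derive_seed(seed, 100L + i))
    rows[[length(rows) + 1L]] <-
      dplyr::mutate(mr_mediation(tr$dosage, tr$cis, tr$outcome,
                                 snp_id = sprintf("null%02d", i),
                                 mediator_gene = sprintf("cisnull%02d", i),
                                 outcome_id = sprintf("nulltarget%02d", i)),
                    planted = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out$q <- bh_fdr(out$p)
  out
}

#' Summarize a completed pipeline run
#'
#' Reads the stage outputs of [run_pipeline()] and returns (and writes)
#' headline counts: sparse components, significant trans-eQTLs at the
#' mapping FDR, GWAS overlaps at the liberal FDR, significant mediations,
#' and — for synthetic runs — recovery metrics against the planted truth
#' (component match rate, support balanced accuracy, trans-eQTL power for
#' planted SNP effects, mediation recovery).
#'
#' @param run_dir A completed run directory.
#' @param fdr,fdr_gwas FDR levels used for counting (defaults 0.05, 0.15).
#' @return The summary list, invisibly written to `summary.json`.
#' @export
summarize_run <- function(run_dir, fdr = 0.05, fdr_gwas = 0.15) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path)) {
    stop("not a pipeline run directory (no manifest.json)", call. = FALSE)
  }
  manifest <- jsonlite::read_json(man_path, simplifyVector = FALSE)
  missing <- setdiff(PIPELINE_STAGES, names(manifest$stages))
  if (length(missing)) {
    stop(sprintf("incomplete run; missing stage(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  calls <- readr::read_tsv(stage_file(run_dir, "components",
                                      "component_calls.tsv"),
                           show_col_types = FALSE)
  trans <- readr::read_tsv(stage_file(run_dir, "permutation",
                                      "trans_eqtl_perm.tsv"),
                           show_col_types = FALSE)
  overlaps <- readr::read_tsv(stage_file(run_dir, "gwas", "overlaps.tsv"),
                              show_col_types = FALSE)
  med <- readr::read_tsv(stage_file(run_dir, "mediation", "mediation.tsv"),
                         show_col_types = FALSE)
  summary <- list(
    n_components = nrow(calls),
    n_sparse_components = sum(calls$sparse),
    n_trans_eqtl_tests = nrow(trans),
    n_trans_eqtl_significant = sum(trans$q < fdr),
    n_gwas_overlaps = nrow(overlaps),
    n_mediation_significant = sum(med$p < 0.05, na.rm = TRUE))
  truth_path <- stage_file(run_dir, "simulate", "truth.json")
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    dec <- read_decomposition(stage_file(run_dir, "decompose",
                                         "decomposition"))
    as_mat <- function(x) {
      if (is.matrix(x)) x else do.call(rbind, lapply(x, unlist))
    }
    X_true <- as_mat(truth$X_true)
    support <- as_mat(truth$support_true)
    suppressWarnings(cc <- abs(stats::cor(t(dec$X_mean), t(X_true))))
    cc[is.na(cc)] <- 0
    m <- apply(cc, 2, which.max)
    matched_r <- cc[cbind(m, seq_len(ncol(cc)))]
    sparse_rows <- which(rowSums(support) < ncol(support))
    pip_call <- dec$pip[m, , drop = FALSE] > 0.5
    sens <- mean(pip_call[support == 1])
    spec <- mean(!pip_call[support == 0])
    eff <- truth$snp_effects
    power <- NA_real_
    if (!is.null(eff) && length(eff)) {
      eff <- tibble::as_tibble(eff)
      hit <- vapply(seq_len(nrow(eff)), function(i) {
        snp <- sprintf("rs%05d", eff$snp[i])
        comp_fit <- as.character(m[eff$component[i]])
        any(trans$snp_id == snp & as.character(trans$component) == comp_fit &
              trans$q < fdr)
      }, logical(1))
      power <- mean(hit)
    }
    summary$recovery <- list(
      mean_matched_loading_r = mean(matched_r),
      support_balanced_accuracy = (sens + spec) / 2,
      planted_eqtl_power = power,
      mediation_recovery = mean(med$q[isTRUE_vec(med$planted)] < 0.05,
                                na.rm = TRUE))
  }
  jsonlite::write_json(summary, file.path(run_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

isTRUE_vec <- function(x) !is.na(x) & x
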