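# Readers and writers for the package's on-disk formats: genotypes as
# minimal VCF v4.2 (DS dosage FORMAT) or TSV dosage matrix, decompositions
# as a directory of TSV matrices plus JSON metadata.

#' Write genotypes as a minimal VCF v4.2 or TSV
#'
#' VCF output carries one sample column per individual with a `DS` dosage
#' FORMAT field and per-SNP `MAF`, `HWP` and `INFO` entries in INFO. TSV
#' output is a dosage matrix (SNP rows) preceded by the metadata columns.
#' Format is chosen from the file extension (`.vcf` vs anything else).
#'
#' @param genotypes A `genotype_data`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_data"))
  if (grepl("\\.vcf$", path)) {
    s <- genotypes$snps
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
      "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
      "##INFO=<ID=HWP,Number=1,Type=Float,Description=\"HWE chi-square p\">",
      "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation INFO score\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", genotypes$individual_ids), collapse = "\t"))
    body <- vapply(seq_len(nrow(s)), function(j) {
      paste(c(s$chrom[j], s$pos[j], s$snp_id[j], s$ref[j], s$alt[j], ".",
              "PASS",
              sprintf("MAF=%.6g;HWP=%.6g;INFO=%.6g", s$maf[j], s$hwe_p[j],
                      s$info[j]),
              "DS", format(genotypes$dosages[, j], trim = TRUE)),
            collapse = "\t")
    }, character(1))
    writeLines(c(hdr, body), path)
  } else {
    df <- dplyr::bind_cols(
      genotypes$snps,
      tibble::as_tibble(t(genotypes$dosages), .name_repair = "minimal"))
    names(df) <- c(names(genotypes$snps), genotypes$individual_ids)
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' Read genotypes from VCF or TSV
#'
#' VCF input uses the `DS` FORMAT field when present, otherwise allele
#' counts from `GT`. TSV input round-trips [write_genotypes()] output.
#' Missing MAF/HWE metadata is recomputed from the realized dosages.
#'
#' @param path A `.vcf` file or a TSV written by [write_genotypes()].
#' @return A `genotype_data`.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf$", path)) {
    read_genotypes_vcf(path)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt", "maf", "hwe_p",
                   "info")
    missing <- setdiff(c("snp_id", "chrom", "pos"), names(df))
    if (length(missing)) {
      stop(sprintf("TSV genotype file lacks column(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    ind <- setdiff(names(df), meta_cols)
    dos <- t(as.matrix(df[ind]))
    colnames(dos) <- df$snp_id
    rownames(dos) <- ind
    snps <- tibble::tibble(
      snp_id = df$snp_id, chrom = as.character(df$chrom), pos = df$pos,
      ref = df$ref %||% "A", alt = df$alt %||% "G",
      maf = df$maf %||% apply(dos, 2, compute_maf),
      hwe_p = df$hwe_p %||% apply(dos, 2, function(d) {
        h <- table(factor(round(d), levels = 0:2))
        hwe_test(h[[1]], h[[2]], h[[3]])$p
      }),
      info = df$info %||% 1)
    new_genotype_data(dos, snps, ind)
  }
}

read_genotypes_vcf <- function(path) {
  # structural validation first, so malformed records are reported with
  # their line number (the upstream parser is more forgiving)
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  if (!length(hdr_i)) stop("not a VCF: no #CHROM header line", call. = FALSE)
  nfld <- length(strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]])
  if (nfld < 10) stop("VCF has no sample columns", call. = FALSE)
  for (j in seq_along(lines)) {
    if (j <= hdr_i || !nzchar(lines[j])) next
    if (length(strsplit(lines[j], "\t", fixed = TRUE)[[1]]) != nfld) {
      stop(sprintf("malformed VCF record at line %d", j), call. = FALSE)
    }
  }
  if (hdr_i == length(lines)) {
    stop("VCF contains no variant records", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.matrix(fix)) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  has_ds <- any(grepl("DS", v@gt[, 1]))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(col, function(g) {
        sum(strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)[[1]] == "1")
      }, numeric(1), USE.NAMES = FALSE)
    })
    ds <- matrix(ds, nrow = nrow(gt), dimnames = dimnames(gt))
  }
  if (any(is.na(ds))) {
    bad <- which(rowSums(is.na(ds)) > 0)[1]
    stop(sprintf("unparsable genotype at VCF line %d", hdr_i + bad),
         call. = FALSE)
  }
  dos <- t(ds)                                    # individuals x SNPs
  grab <- function(key) {
    val <- vcfR::extract.info(v, element = key, as.numeric = TRUE)
    if (is.null(val)) rep(NA_real_, nrow(fix)) else val
  }
  maf <- grab("MAF"); hwe <- grab("HWP"); info <- grab("INFO")
  need <- is.na(maf) | is.na(hwe)
  for (j in which(need)) {
    maf[j] <- compute_maf(dos[, j])
    h <- table(factor(round(dos[, j]), levels = 0:2))
    hwe[j] <- hwe_test(h[[1]], h[[2]], h[[3]])$p
  }
  info[is.na(info)] <- 1
  snp_id <- fix[, "ID"]
  colnames(dos) <- snp_id
  new_genotype_data(dos, tibble::tibble(
    snp_id = snp_id, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], maf = maf, hwe_p = hwe,
    info = info), rownames(dos))
}

#' Write / read a decomposition as TSV matrices plus JSON metadata
#'
#' The directory holds `A.tsv`, `B.tsv`, `X_mean.tsv`, `pip.tsv`,
#' `lambda.tsv` and `meta.json` (seed, hyperparameters, ELBO trace,
#' convergence and pruning flags).
#'
#' @param fit An `sda_fit`.
#' @param dir Directory to create/use.
#' @return `write_decomposition()` the directory, invisibly;
#'   `read_decomposition()` a decomposition-like list (sufficient for all
#'   downstream component and eQTL operations, but not refittable).
#' @export
write_decomposition <- function(fit, dir) {
  stopifnot(inherits(fit, "sda_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, fname, rn, cn) {
    df <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
    names(df) <- cn
    readr::write_tsv(dplyr::bind_cols(tibble::tibble(id = rn), df),
                     file.path(dir, fname))
  }
  cids <- sprintf("comp%03d", seq_len(ncol(fit$A)))
  wm(fit$A, "A.tsv", fit$individual_ids, cids)
  wm(fit$B, "B.tsv", fit$tissue_labels, cids)
  wm(fit$X_mean, "X_mean.tsv", cids, fit$gene_ids)
  wm(fit$pip, "pip.tsv", cids, fit$gene_ids)
  wm(fit$lambda_mean, "lambda.tsv", fit$gene_ids, fit$tissue_labels)
  jsonlite::write_json(
    list(seed = fit$seed, hyper = unclass(fit$hyper),
         elbo_trace = fit$elbo_trace, converged = fit$converged,
         monotone = fit$monotone, n_iter = fit$n_iter, pruned = fit$pruned),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(dir) {
  rm_ <- function(fname) {
    df <- readr::read_tsv(file.path(dir, fname), show_col_types = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df[[1]]
    m
  }
  A <- rm_("A.tsv"); B <- rm_("B.tsv"); X <- rm_("X_mean.tsv")
  pip <- rm_("pip.tsv"); lam <- rm_("lambda.tsv")
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  structure(list(
    A = A, B = B, X_mean = X, pip = pip, lambda_mean = lam,
    elbo_trace = meta$elbo_trace, converged = meta$converged,
    monotone = meta$monotone, n_iter = meta$n_iter,
    pruned = meta$pruned, seed = meta$seed,
    hyper = do.call(sda_hyper, as.list(meta$hyper)),
    individual_ids = rownames(A), gene_ids = colnames(X),
    tissue_labels = rownames(B)
  ), class = "sda_fit")
}
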