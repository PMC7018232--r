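# The three-way expression container: individuals x genes x conditions with
# an individuals x conditions observation mask (whole slices are either
# measured or not, as in multi-condition cohorts where some individuals were
# not assayed under every stimulus).

#' Construct an expression tensor
#'
#' @param values Numeric array N x L x T of (normalized) expression values.
#' @param mask Binary N x T matrix; `mask[n, t] = 1` when individual n was
#'   measured in condition t. Defaults to fully observed.
#' @param individual_ids,gene_ids,tissue_labels Identifier vectors matching
#'   the array dimensions.
#' @return An object of class `expression_tensor`.
#' @export
expression_tensor <- function(values, mask = NULL, individual_ids = NULL,
                              gene_ids = NULL, tissue_labels = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-way array (individuals x genes x conditions)",
         call. = FALSE)
  }
  d <- dim(values)
  if (is.null(mask)) mask <- matrix(1L, d[1], d[3])
  mask <- matrix(as.integer(mask != 0), d[1], d[3])
  individual_ids <- individual_ids %||% sprintf("ind%03d", seq_len(d[1]))
  gene_ids <- gene_ids %||% sprintf("gene%04d", seq_len(d[2]))
  tissue_labels <- tissue_labels %||% sprintf("cond%d", seq_len(d[3]))
  if (length(individual_ids) != d[1] || length(gene_ids) != d[2] ||
      length(tissue_labels) != d[3]) {
    stop("identifier lengths must match tensor dimensions", call. = FALSE)
  }
  if (all(mask == 0)) stop("mask excludes every observation", call. = FALSE)
  if (any(rowSums(mask) == 0) || any(colSums(mask) == 0)) {
    stop("every individual and condition needs at least one observation",
         call. = FALSE)
  }
  for (t in seq_len(d[3])) {
    obs <- mask[, t] == 1L
    if (any(!is.finite(values[obs, , t]))) {
      stop("observed tensor entries must be finite", call. = FALSE)
    }
  }
  structure(list(values = values, mask = mask,
                 individual_ids = as.character(individual_ids),
                 gene_ids = as.character(gene_ids),
                 tissue_labels = as.character(tissue_labels)),
            class = "expression_tensor")
}

#' @export
print.expression_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<expression_tensor> %d individuals x %d genes x %d conditions (%.1f%% slices observed)\n",
    d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.expression_tensor <- function(x) dim(x$values)

#' Write / read an expression tensor as per-condition TSV files
#'
#' One `genes x individuals` TSV per condition plus a mask TSV
#' (individuals x conditions), the layout cohort expression releases use.
#'
#' @param tensor An `expression_tensor`.
#' @param dir Directory to create/use.
#' @return `write_expression_tensor()` returns the directory invisibly;
#'   `read_expression_tensor()` returns an `expression_tensor`.
#' @export
write_expression_tensor <- function(tensor, dir) {
  stopifnot(inherits(tensor, "expression_tensor"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(tensor$tissue_labels)) {
    m <- t(tensor$values[, , t])
    df <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
    names(df) <- tensor$individual_ids
    df <- dplyr::bind_cols(tibble::tibble(gene_id = tensor$gene_ids), df)
    readr::write_tsv(df, file.path(dir, paste0(
      "expression_", tensor$tissue_labels[t], ".tsv")))
  }
  mk <- tibble::as_tibble(as.data.frame(tensor$mask), .name_repair = "minimal")
  names(mk) <- tensor$tissue_labels
  mk <- dplyr::bind_cols(tibble::tibble(individual_id = tensor$individual_ids),
                         mk)
  readr::write_tsv(mk, file.path(dir, "mask.tsv"))
  invisible(dir)
}

#' @rdname write_expression_tensor
#' @export
read_expression_tensor <- function(dir) {
  mask_df <- readr::read_tsv(file.path(dir, "mask.tsv"),
                             show_col_types = FALSE)
  individual_ids <- mask_df$individual_id
  tissue_labels <- setdiff(names(mask_df), "individual_id")
  mask <- as.matrix(mask_df[tissue_labels])
  first <- readr::read_tsv(
    file.path(dir, paste0("expression_", tissue_labels[1], ".tsv")),
    show_col_types = FALSE)
  gene_ids <- first$gene_id
  vals <- array(NA_real_, dim = c(length(individual_ids), length(gene_ids),
                                  length(tissue_labels)))
  for (t in seq_along(tissue_labels)) {
    df <- if (t == 1) first else readr::read_tsv(
      file.path(dir, paste0("expression_", tissue_labels[t], ".tsv")),
      show_col_types = FALSE)
    vals[, , t] <- t(as.matrix(df[individual_ids]))
  }
  expression_tensor(vals, mask, individual_ids, gene_ids, tissue_labels)
}
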