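# Calling sparse components: PIP + tail-quantile gene selection, the
# sparsity ranking statistic, covariate screening of individual scores, and
# two-way reverse correlation matching of components across datasets.

#' Configuration for sparse-component calling
#'
#' @param pip_threshold Posterior inclusion probability a gene must exceed
#'   (default 0.5).
#' @param tail_fraction Two-sided distributional cut-off: genes must lie
#'   beyond the `tail_fraction` / `1 - tail_fraction` empirical quantiles of
#'   the component's loading distribution (default 0.025).
#' @param t_max Maximum number of selected genes for a component to qualify
#'   as sparse; `NULL` (default) resolves to 5% of the gene count at call
#'   time, consistent with sparse gene networks of tens of genes out of
#'   thousands.
#' @param min_genes Minimum number of selected genes (default 5).
#' @return A `sparsity_config` list.
#' @export
sparsity_config <- function(pip_threshold = 0.5, tail_fraction = 0.025,
                            t_max = NULL, min_genes = 5L) {
  assert_fraction(pip_threshold, "pip_threshold", 0, 1, TRUE, TRUE)
  assert_fraction(tail_fraction, "tail_fraction", 0, 0.5, TRUE, TRUE)
  min_genes <- assert_count(min_genes, "min_genes")
  if (!is.null(t_max)) {
    t_max <- assert_count(t_max, "t_max")
    if (min_genes > t_max) stop("`min_genes` must be <= `t_max`",
                                call. = FALSE)
  }
  structure(list(pip_threshold = pip_threshold,
                 tail_fraction = tail_fraction,
                 t_max = t_max, min_genes = min_genes),
            class = "sparsity_config")
}

resolve_t_max <- function(cfg, n_genes) {
  cfg$t_max %||% max(cfg$min_genes, floor(0.05 * n_genes))
}

#' Select the genes of one component
#'
#' A gene belongs to a component when its posterior inclusion probability
#' exceeds `pip_threshold` *and* its loading lies beyond the component's
#' two-sided empirical tail quantiles (the distributional cut-off). The two
#' rules are intersected.
#'
#' @param fit An `sda_fit` (or a decomposition-like list with `X_mean`,
#'   `pip`, `gene_ids`).
#' @param component Component index.
#' @param cfg A [sparsity_config()].
#' @return Character vector of selected gene ids.
#' @export
select_component_genes <- function(fit, component, cfg = sparsity_config()) {
  x <- fit$X_mean[component, ]
  pip <- fit$pip[component, ]
  gene_ids <- fit$gene_ids %||% as.character(seq_along(x))
  qs <- stats::quantile(x, c(cfg$tail_fraction, 1 - cfg$tail_fraction),
                        names = FALSE)
  sel <- pip > cfg$pip_threshold & (x < qs[1] | x > qs[2])
  gene_ids[sel]
}

#' Sparsity ranking statistic and sparse-component calls
#'
#' For each component, the selected gene set (see
#' [select_component_genes()]), its size `n_genes`, the mean absolute
#' loading `weight` of the selected genes, and the ranking statistic
#' `statistic = 1\{min_genes <= n_genes <= t_max\} * f(weight) / g(n_genes)`
#' with defaults `f(w) = w`, `g(N) = N`. A component is called sparse when
#' its statistic exceeds a limiting-case lower-bound cutoff: the statistic
#' of a hypothetical component carrying `min_genes` genes at that
#' component's own tail-quantile loading magnitude (the selection threshold
#' itself), which is the smallest configuration that could still qualify.
#'
#' @param fit An `sda_fit`.
#' @param cfg A [sparsity_config()].
#' @param f,g Weight and size functions, injectable; defaults identity and
#'   identity.
#' @return A tibble of class `component_calls`, one row per component,
#'   ranked by descending statistic, with columns `component`, `n_genes`,
#'   `weight`, `statistic`, `cutoff`, `sparse`, `genes` (list-column).
#' @export
sparsity_statistic <- function(fit, cfg = sparsity_config(),
                               f = identity, g = identity) {
  C <- nrow(fit$X_mean)
  L <- ncol(fit$X_mean)
  t_max <- resolve_t_max(cfg, L)
  rows <- purrr::map(seq_len(C), function(ci) {
    genes <- select_component_genes(fit, ci, cfg)
    x <- fit$X_mean[ci, ]
    gene_ids <- fit$gene_ids %||% as.character(seq_along(x))
    n_i <- length(genes)
    w_i <- if (n_i > 0) mean(abs(x[match(genes, gene_ids)])) else 0
    qs <- stats::quantile(x, c(cfg$tail_fraction, 1 - cfg$tail_fraction),
                          names = FALSE)
    w_star <- max(abs(qs))
    in_range <- n_i >= cfg$min_genes && n_i <= t_max
    r_i <- if (in_range) f(w_i) / g(n_i) else 0
    cutoff <- f(w_star) / g(cfg$min_genes)
    tibble::tibble(component = ci, n_genes = n_i, weight = w_i,
                   statistic = r_i, cutoff = cutoff,
                   sparse = in_range && r_i > cutoff,
                   genes = list(genes))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$statistic))
  class(out) <- c("component_calls", class(out))
  out
}

#' Screen component individual scores against known covariates
#'
#' Components whose individual scores associate with biological or technical
#' covariates are confounder candidates and are excluded from trans-eQTL
#' mapping. Continuous covariates are tested by the OLS slope t-test,
#' categorical ones by a one-way ANOVA F-test; a component is flagged when
#' any of its p-values falls below the Bonferroni level
#' `0.05 / (n_components * n_covariates)`.
#'
#' @param A Individual-score matrix (individuals x components).
#' @param covariates Data frame of per-individual covariates, rows aligned
#'   with `A`.
#' @param alpha Family-wise level before Bonferroni division (default 0.05).
#' @return A list with `p_values` (components x covariates matrix) and
#'   `flagged` (integer vector of flagged component indices).
#' @export
screen_covariates <- function(A, covariates, alpha = 0.05) {
  A <- as.matrix(A)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(A)) {
    stop("covariate rows must align with the individuals of `A`",
         call. = FALSE)
  }
  C <- ncol(A)
  K <- ncol(covariates)
  p <- matrix(NA_real_, C, K,
              dimnames = list(colnames(A) %||% as.character(seq_len(C)),
                              names(covariates)))
  for (k in seq_len(K)) {
    v <- covariates[[k]]
    if (is.character(v)) v <- factor(v)
    constant <- if (is.factor(v)) nlevels(droplevels(v)) < 2 else
      stats::var(v) == 0
    if (constant) {
      warning(sprintf("covariate '%s' is constant; p set to 1",
                      names(covariates)[k]))
      p[, k] <- 1
      next
    }
    for (ci in seq_len(C)) {
      fit <- stats::lm(A[, ci] ~ v)
      if (is.factor(v)) {
        an <- stats::anova(fit)
        p[ci, k] <- an$`Pr(>F)`[1]
      } else {
        p[ci, k] <- summary(fit)$coefficients[2, 4]
      }
    }
  }
  thr <- alpha / (C * K)
  list(p_values = p, flagged = which(apply(p, 1, min) < thr),
       threshold = thr)
}

#' Match components across two decompositions
#'
#' Two-way reverse correlation on the common genes: for each component of
#' fit a, the Pearson correlation of absolute gene loadings (restricted to
#' `shared_genes`) against every component of fit b, and vice versa.
#' Reciprocal best-hit pairs with |r| above `min_r` are reported.
#'
#' @param fit_a,fit_b `sda_fit` objects (or decomposition-like lists).
#' @param shared_genes Character vector of gene ids present in both fits
#'   (at least 10).
#' @param min_r Reporting threshold on |r| (default 0.5).
#' @return A tibble with `component_a`, `component_b`, `r_forward`,
#'   `r_reverse`, `reciprocal`; one row per component of fit a (its best
#'   hit), with `reciprocal = TRUE` when the pair is mutual and above
#'   `min_r`.
#' @export
match_components <- function(fit_a, fit_b, shared_genes, min_r = 0.5) {
  ga <- fit_a$gene_ids %||% as.character(seq_len(ncol(fit_a$X_mean)))
  gb <- fit_b$gene_ids %||% as.character(seq_len(ncol(fit_b$X_mean)))
  shared_genes <- intersect(intersect(shared_genes, ga), gb)
  if (length(shared_genes) < 10) {
    stop("need at least 10 shared genes to match components", call. = FALSE)
  }
  Xa <- abs(fit_a$X_mean[, match(shared_genes, ga), drop = FALSE])
  Xb <- abs(fit_b$X_mean[, match(shared_genes, gb), drop = FALSE])
  suppressWarnings(R <- stats::cor(t(Xa), t(Xb)))
  R[is.na(R)] <- 0
  best_ab <- apply(abs(R), 1, which.max)
  best_ba <- apply(abs(R), 2, which.max)
  tibble::tibble(
    component_a = seq_len(nrow(R)),
    component_b = best_ab,
    r_forward = R[cbind(seq_len(nrow(R)), best_ab)],
    r_reverse = R[cbind(best_ba[best_ab], best_ab)],
    reciprocal = best_ba[best_ab] == seq_len(nrow(R)) &
      abs(R[cbind(seq_len(nrow(R)), best_ab)]) > min_r
  )
}

#' Greedily match fitted loading rows to reference (e.g. planted) rows
#'
#' Computes all pairwise |Pearson r| between rows of the two loading
#' matrices and repeatedly assigns the best remaining pair, so each fitted
#' and each reference component is used at most once.
#'
#' @param X_fit,X_ref Loading matrices (components x genes) over the same
#'   genes.
#' @return A tibble with `ref`, `fit`, `r` (absolute correlation), one row
#'   per reference component.
#' @export
greedy_match_loadings <- function(X_fit, X_ref) {
  suppressWarnings(R <- abs(stats::cor(t(X_fit), t(X_ref))))
  R[is.na(R)] <- 0
  out <- vector("list", nrow(X_ref))
  for (i in seq_len(min(nrow(X_ref), nrow(X_fit)))) {
    j <- arrayInd(which.max(R), dim(R))
    out[[i]] <- tibble::tibble(ref = j[2], fit = j[1], r = R[j[1], j[2]])
    R[j[1], ] <- -1
    R[, j[2]] <- -1
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$ref)
}
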