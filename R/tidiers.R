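# broom-style tidiers for the decomposition fit.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decomposition fit
#'
#' One row per component x gene with the posterior-mean loading and PIP
#' (`matrix = "loadings"`, default), per individual x component score
#' (`"scores"`), or per condition x component activity (`"activity"`).
#'
#' @param x An `sda_fit`.
#' @param matrix Which posterior summary to return.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sda_fit
#' @export
tidy.sda_fit <- function(x, matrix = c("loadings", "scores", "activity"),
                         ...) {
  matrix <- match.arg(matrix)
  C <- ncol(x$A)
  switch(matrix,
    loadings = tibble::tibble(
      component = rep(seq_len(C), times = ncol(x$X_mean)),
      gene = rep(x$gene_ids, each = C),
      loading = as.vector(x$X_mean),
      pip = as.vector(x$pip)),
    scores = tibble::tibble(
      individual = rep(x$individual_ids, times = C),
      component = rep(seq_len(C), each = nrow(x$A)),
      score = as.vector(x$A)),
    activity = tibble::tibble(
      condition = rep(x$tissue_labels, times = C),
      component = rep(seq_len(C), each = nrow(x$B)),
      activity = as.vector(x$B)))
}

#' One-row summary of a decomposition fit
#'
#' @param x An `sda_fit`.
#' @param ... Unused.
#' @return A tibble with the number of components, pruned components,
#'   sweeps, convergence flag and final ELBO.
#' @method glance sda_fit
#' @export
glance.sda_fit <- function(x, ...) {
  tibble::tibble(
    n_components = ncol(x$A),
    n_pruned = sum(x$pruned %||% FALSE),
    n_iter = x$n_iter,
    converged = x$converged,
    elbo = x$elbo_trace[length(x$elbo_trace)])
}
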