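# ggplot2 graphics for fits and result tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the ELBO trace of a fit
#'
#' @param fit An `sda_fit`.
#' @return A ggplot.
#' @export
plot_elbo <- function(fit) {
  df <- tibble::tibble(sweep = seq_along(fit$elbo_trace),
                       elbo = fit$elbo_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$elbo)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "coordinate-ascent sweep", y = "ELBO") +
    ggplot2::theme_minimal()
}

#' Gene-loading profile of selected components
#'
#' Loadings along the gene axis, one facet per component, with genes above
#' the PIP threshold highlighted.
#'
#' @param fit An `sda_fit`.
#' @param components Component indices (default: all unpruned).
#' @param pip_threshold Highlight threshold (default 0.5).
#' @return A ggplot.
#' @export
plot_loadings <- function(fit, components = NULL, pip_threshold = 0.5) {
  components <- components %||% which(!(fit$pruned %||%
                                          rep(FALSE, ncol(fit$A))))
  df <- tidy(fit, "loadings")
  df <- df[df$component %in% components, ]
  df$index <- match(df$gene, fit$gene_ids)
  df$included <- df$pip > pip_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$loading,
                                   colour = .data$included)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "gene index", y = "posterior-mean loading",
                  colour = sprintf("PIP > %.2g", pip_threshold)) +
    ggplot2::theme_minimal()
}

#' Condition-activity heat map of a fit
#'
#' @param fit An `sda_fit`.
#' @return A ggplot.
#' @export
plot_activity <- function(fit) {
  df <- tidy(fit, "activity")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$component),
                                   y = .data$condition,
                                   fill = .data$activity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "component", y = NULL, fill = "activity") +
    ggplot2::theme_minimal()
}

#' @method autoplot sda_fit
#' @export
autoplot.sda_fit <- function(object, type = c("elbo", "loadings",
                                              "activity"), ...) {
  type <- match.arg(type)
  switch(type,
    elbo = plot_elbo(object),
    loadings = plot_loadings(object, ...),
    activity = plot_activity(object))
}

#' Volcano-style plot of trans-eQTL results
#'
#' @param records An `eqtl_result` tibble.
#' @param fdr_level Highlighting threshold on q (default 0.05).
#' @return A ggplot.
#' @export
plot_trans_eqtl <- function(records, fdr_level = 0.05) {
  df <- tibble::as_tibble(records)
  df$sig <- df$q < fdr_level
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = -log10(.data$p),
                                   colour = .data$sig)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "dosage effect on individual scores",
                  y = expression(-log[10]~p),
                  colour = sprintf("q < %.2g", fdr_level)) +
    ggplot2::theme_minimal()
}
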