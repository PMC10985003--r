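#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_hline scale_fill_gradient2 labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot the objective trace of a fitted factorization
#'
#' @param model a `meth_plier` model.
#' @param log_scale log10 the objective axis; default `TRUE`.
#' @return a ggplot.
#' @export
plot_objective_trace <- function(model, log_scale = TRUE) {
  stopifnot(inherits(model, "meth_plier"))
  p <- ggplot(model$trace, aes(x = .data$iteration, y = .data$objective)) +
    geom_line() +
    labs(x = "iteration", y = "objective",
         title = "Alternating-minimization objective") +
    theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn plot_objective_trace heatmap of the nonzero gene-set weights
#'   `U` (which pathways load on which latent variable).
#' @param object a `meth_plier` model.
#' @param ... unused.
#' @export
autoplot.meth_plier <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = .data$lv, y = .data$gene_set, fill = .data$weight)) +
    geom_tile() +
    scale_fill_gradient2(low = "white", high = "firebrick") +
    labs(x = "latent variable", y = "gene set", fill = "U weight",
         title = "Gene-set associations of latent variables") +
    theme_minimal()
}

#' @describeIn plot_objective_trace heatmap of sample loadings.
#' @export
autoplot.meth_loadings <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = .data$sample_id, y = .data$lv, fill = .data$loading)) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    labs(x = "sample", y = "latent variable", fill = "loading",
         title = "Transferred sample loadings") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Volcano-style plot of differential latent variables or DMPs
#'
#' @param diff a result tibble from [differential_lv()] or [dmp_test()].
#' @param q_cutoff dashed significance line; default 0.05.
#' @return a ggplot.
#' @export
plot_volcano <- function(diff, q_cutoff = 0.05) {
  stopifnot(all(c("t", "q_value") %in% names(diff)))
  ggplot(diff, aes(x = .data$t, y = -log10(pmax(.data$q_value, 1e-300)))) +
    geom_point(aes(color = .data$q_value < q_cutoff), show.legend = FALSE) +
    geom_hline(yintercept = -log10(q_cutoff), linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey50")) +
    labs(x = "t statistic", y = "-log10 q", title = "Differential features") +
    theme_minimal()
}

#' Scatter plot of a 2-D embedding with optional labels
#'
#' @param embedding tibble from [umap_embed()].
#' @param labels optional per-sample grouping to color by.
#' @return a ggplot.
#' @export
plot_embedding <- function(embedding, labels = NULL) {
  stopifnot(all(c("UMAP1", "UMAP2") %in% names(embedding)))
  df <- embedding
  if (!is.null(labels)) df$label <- as.factor(labels)
  p <- ggplot(df, aes(x = .data$UMAP1, y = .data$UMAP2))
  p <- if (is.null(labels)) p + geom_point() else
    p + geom_point(aes(color = .data$label)) + labs(color = "group")
  p + theme_minimal() + labs(title = "UMAP embedding of samples")
}
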