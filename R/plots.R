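#' Plot an enrichment series
#'
#' Per-depth one-tailed Wilcoxon p-values of the kN-enrichment walk on a
#' -log10 scale, with the significance level as a dashed line and
#' significant depths highlighted — the standard way to read the series,
#' since no correction is applied across depths.
#'
#' @param object An `enrichment_series` tibble (see [iterative_wilcoxon()]
#'   or [enrichment_by_axis()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_series <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  dat <- dplyr::filter(object, !is.na(.data$p_value))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$m,
                                         y = -log10(.data$p_value))) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant), width = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = "top-m SNPs in contribution rank",
                  y = expression(-log[10](p)),
                  title = "kN enrichment along the contribution rank")
  if ("axis" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~axis)
  }
  p
}

#' Plot ordination scores
#'
#' Observations on the first two axes of a PCA or DAPC, coloured by cluster
#' when the fit carries one.
#'
#' @param object An `ordination_contributions` object.
#' @param axes Which two axes to draw (default 1:2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ordination_contributions <- function(object, axes = 1:2, ...) {
  sc <- object$scores
  if (ncol(sc) < 2) axes <- c(1, 1)
  dat <- tibble::tibble(
    id = rownames(sc) %||% as.character(seq_len(nrow(sc))),
    x = sc[, axes[1]], y = sc[, axes[2]]
  )
  lab <- colnames(sc)[axes]
  mapping <- ggplot2::aes(x = .data$x, y = .data$y)
  if (!is.null(object$clusters)) dat$cluster <- object$clusters
  p <- ggplot2::ggplot(dat, mapping) +
    ggplot2::labs(x = lab[1], y = lab[2], title = toupper(object$method))
  if (!is.null(object$clusters)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2) +
      ggplot2::geom_text(ggplot2::aes(label = .data$id), vjust = -0.8,
                         size = 3)
  }
}

#' Bar plot of the top SNP contributions on one axis
#'
#' @param ord An `ordination_contributions` object.
#' @param axis Axis index (default 1).
#' @param top_n How many top-ranked SNPs to show (default 50).
#' @param highlight Optional locus ids to colour (e.g. kN SNPs).
#' @return A ggplot.
#' @export
plot_contributions <- function(ord, axis = 1, top_n = 50, highlight = NULL) {
  rk <- rank_contributions(ord$contrib[, axis])
  rk <- rk[seq_len(min(top_n, nrow(rk))), ]
  rk$highlight <- rk$locus_id %in% (highlight %||% character())
  ggplot2::ggplot(rk, ggplot2::aes(x = .data$rank, y = .data$contribution,
                                   fill = .data$highlight)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey50",
                                          `TRUE` = "goldenrod"),
                               guide = "none") +
    ggplot2::labs(x = "contribution rank", y = "contribution (%)",
                  title = colnames(ord$contrib)[axis])
}

#' Plot a BIC curve from cluster search
#'
#' @param clusters Result of [find_clusters_bic()].
#' @return A ggplot with the chosen k marked.
#' @export
plot_bic <- function(clusters) {
  ggplot2::ggplot(clusters$bic, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = clusters$k, linetype = "dotted") +
    ggplot2::labs(x = "number of clusters k", y = "BIC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
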