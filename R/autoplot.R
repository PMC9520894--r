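#' Plot the loss trace of a masked NMF fit
#'
#' @param object A `bfsig_nmf`.
#' @param ... Unused.
#' @return A ggplot: mean KL loss against iteration (log10 y).
#' @method autoplot bfsig_nmf
#' @export
autoplot.bfsig_nmf <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$loss_trace),
               mean_kl = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$mean_kl)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "mean KL divergence",
                  title = sprintf("Masked NMF, rank %d", object$rank)) +
    ggplot2::theme_minimal()
}

#' Plot cophenetic coefficients across candidate ranks
#'
#' @param object A `bfsig_rank_report`.
#' @param ... Unused.
#' @return A ggplot with the chosen rank highlighted.
#' @method autoplot bfsig_rank_report
#' @export
autoplot.bfsig_rank_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$cophenetic)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "rank k", y = "cophenetic correlation",
                  title = "Consensus stability across ranks") +
    ggplot2::theme_minimal()
}

#' Heatmap of normalized signature gene weights
#'
#' @param object A `bfsig_signatures`.
#' @param top_n Show the `top_n` highest-weight genes per signature
#'   (default 25).
#' @param ... Unused.
#' @return A ggplot tile heatmap.
#' @method autoplot bfsig_signatures
#' @export
autoplot.bfsig_signatures <- function(object, top_n = 25, ...) {
  df <- tidy(object)
  keep <- df |>
    dplyr::group_by(.data$signature) |>
    dplyr::slice_max(.data$weight, n = top_n) |>
    dplyr::ungroup() |>
    dplyr::pull(.data$gene_id) |>
    unique()
  df <- df[df$gene_id %in% keep, ]
  df$gene_id <- factor(df$gene_id, levels = rev(sort(unique(df$gene_id))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signature, y = .data$gene_id,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "weight",
                  title = "Signature gene weights (columns sum to 1)") +
    ggplot2::theme_minimal()
}

#' Plot averaged sensitivity probabilities by response group
#'
#' @param object A `bfsig_classifier_eval`.
#' @param ... Unused.
#' @return A ggplot jitter/box plot of per-sample averaged probabilities.
#' @method autoplot bfsig_classifier_eval
#' @export
autoplot.bfsig_classifier_eval <- function(object, ...) {
  df <- object$probabilities
  df <- df[!is.na(df$probability), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$probability,
                                   colour = .data$label)) +
    ggplot2::geom_boxplot(outlier.shape = NA, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = "averaged sensitivity probability",
                  title = sprintf("Pooled AUROC %.3f (95%% CI %.3f-%.3f)",
                                  object$pooled$auroc, object$pooled$ci_low,
                                  object$pooled$ci_high)) +
    ggplot2::theme_minimal()
}

#' Consensus-matrix heatmap at one rank
#'
#' @param report A `bfsig_rank_report`.
#' @param k Rank to show (default the chosen rank).
#' @return A ggplot tile heatmap with samples ordered by the consensus
#'   dendrogram.
#' @export
plot_consensus <- function(report, k = report$chosen_rank) {
  key <- paste0("k", k)
  if (!key %in% names(report$consensus)) {
    abort(sprintf("rank %d was not evaluated", k))
  }
  C <- report$consensus[[key]]
  ord <- hclust(as.dist(1 - C), method = "average")$order
  C <- C[ord, ord]
  df <- tibble(i = rep(seq_len(nrow(C)), times = ncol(C)),
               j = rep(seq_len(ncol(C)), each = nrow(C)),
               consensus = as.vector(C))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$consensus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Consensus matrix, rank %d", k)) +
    ggplot2::theme_minimal()
}
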