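# ggplot2 diagnostics for the main result types.

#' MA-style plot of differential accessibility or expression
#'
#' @param records Differential tibble with `log2fc` and a `call` column
#'   (from [call_significant()]).
#' @param counts Optional count matrix used to place features on the mean
#'   axis; without it features are ranked by name.
#' @return A ggplot.
#' @export
plot_differential <- function(records, counts = NULL) {
  df <- records
  df$mean_count <- if (!is.null(counts)) {
    log2(rowMeans(counts[df$feature, , drop = FALSE]) + 1)
  } else {
    seq_len(nrow(df))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_count, y = .data$log2fc,
                                   colour = .data$call)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", ns = "grey60")
    ) +
    ggplot2::labs(x = "log2 mean count", y = "log2 fold change",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve of a random-forest fit
#'
#' @param object A `bafdep_rf`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bafdep_rf <- function(object, ...) {
  ggplot2::ggplot(object$metrics$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey70") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUROC = %.3f", object$metrics$auroc)
    ) +
    ggplot2::theme_minimal()
}

#' Ranked ridge coefficients with the extreme features highlighted
#'
#' @param object A `bafdep_ridge`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bafdep_ridge <- function(object, ...) {
  df <- object$coefficients
  df$extreme <- df$feature %in% c(object$top_features, object$bottom_features)
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$beta,
                                   colour = .data$extreme)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey50"),
                                 guide = "none") +
    ggplot2::labs(x = "Feature rank", y = "Averaged ridge coefficient") +
    ggplot2::theme_minimal()
}

#' Distribution of tau by restriction status
#'
#' @param tau_records Tibble from [compute_tau()].
#' @return A ggplot.
#' @export
plot_tau <- function(tau_records) {
  df <- tau_records[!is.na(tau_records$tau), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$tau, fill = .data$restricted)) +
    ggplot2::geom_histogram(bins = 40, colour = NA) +
    ggplot2::labs(x = expression(tau), y = "Genes", fill = "Restricted") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
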