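# ggplot2 views of the main result types.

#' Bar chart of the small-RNA category composition
#'
#' @param cat_tab result of [category_table()].
#' @param log_scale log10 the percentage axis (the miRNA/unknown classes
#'   dwarf the rest otherwise).
#' @return a ggplot object.
#' @export
plot_category_table <- function(cat_tab, log_scale = TRUE) {
  long <- cat_tab |>
    select("category", "pct_delay", "pct_activation") |>
    pivot_longer(-"category", names_to = "library", names_prefix = "pct_",
                 values_to = "percent")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$category,
                                          y = .data$percent,
                                          fill = .data$library)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of library reads", fill = NULL) +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Per-position editing-rate profile plot
#'
#' @param object an [editing_profile()].
#' @param ... unused.
#' @return a ggplot object; significant positions are highlighted.
#' @method autoplot editing_profile
#' @export
autoplot.editing_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$rate)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::scale_x_continuous(breaks = object$position) +
    ggplot2::labs(
      x = "position on mature miRNA (5' to 3')",
      y = "editing rate",
      title = sprintf("%s (%s library)", attr(object, "mirna") %||% "",
                      attr(object, "library") %||% "")
    ) +
    ggplot2::theme_minimal()
}

#' MA-style plot of a two-library differential-expression result
#'
#' @param object a `delayseq_de` tibble from [de_test()].
#' @param min_tpm,min_fold,alpha,p_kind filter drawn as the highlighted
#'   subset (see [de_filter()]).
#' @param ... unused.
#' @return a ggplot object: mean TPM vs signed fold, significant features
#'   highlighted.
#' @method autoplot delayseq_de
#' @export
autoplot.delayseq_de <- function(object, min_tpm = 100, min_fold = 1.2,
                                 alpha = 0.001, p_kind = "bonferroni", ...) {
  sig <- de_filter(object, min_tpm, min_fold, alpha, p_kind)
  d <- object |>
    mutate(mean_tpm = (.data$tpm_delay + .data$tpm_activation) / 2,
           significant = .data$feature %in% sig$feature)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_tpm, y = .data$signed_fold,
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "mean TPM", y = "signed fold (activation / delay)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of miRNA vs host-gene expression
#'
#' @param object a [host_gene_correlation()] result.
#' @param ... unused.
#' @return a ggplot object of the transformed values with the fitted line.
#' @method autoplot host_correlation
#' @export
autoplot.host_correlation <- function(object, ...) {
  lab <- if (object$method == "pearson") "log10(TPM + 1)" else "TPM"
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = paste("miRNA", lab), y = paste("host gene", lab),
                  subtitle = sprintf("r = %.2f, p = %.3g", object$estimate,
                                     object$p)) +
    ggplot2::theme_minimal()
}
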