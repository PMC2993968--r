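# Integration of miRNA and mRNA expression: host-gene co-expression,
# coherent-target classification, and direction enrichment of predicted
# targets of differentially expressed miRNAs.

#' Correlation between intragenic miRNAs and their host genes
#'
#' Pearson correlation (default) of `log10(TPM + 1)`-transformed miRNA
#' expression against host-gene expression within one library, with the
#' p-value from the t-distribution transform of r (via [stats::cor.test()]).
#' Spearman is available for a transform-free check.
#'
#' @param pairs data frame with columns `mirna`, `host_gene`, `mirna_tpm`,
#'   `host_tpm` (one library's values).
#' @param method `"pearson"` (on log10(TPM+1)) or `"spearman"` (rank-based,
#'   applied to raw TPM).
#' @return object of class `host_correlation`: list with `estimate`, `p`,
#'   `n`, `method`, and the transformed data in `data`.
#' @export
host_gene_correlation <- function(pairs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_cols(pairs, c("mirna", "host_gene", "mirna_tpm", "host_tpm"), "pairs")
  if (nrow(pairs) < 3) abort("need at least 3 miRNA/host pairs")
  x <- if (method == "pearson") log10(pairs$mirna_tpm + 1) else pairs$mirna_tpm
  y <- if (method == "pearson") log10(pairs$host_tpm + 1) else pairs$host_tpm
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in one of the series")
  ct <- cor.test(x, y, method = method, exact = FALSE)
  structure(list(estimate = unname(ct$estimate), p = ct$p.value,
                 n = nrow(pairs), method = method,
                 data = tibble(mirna = pairs$mirna, host_gene = pairs$host_gene,
                               x = x, y = y)),
            class = "host_correlation")
}

#' @export
print.host_correlation <- function(x, ...) {
  cat(sprintf("miRNA/host-gene co-expression (%s): r = %.3f, p = %.3g, n = %d\n",
              x$method, x$estimate, x$p, x$n))
  invisible(x)
}

#' Classify predicted targets of DE miRNAs as coherent or non-coherent
#'
#' A coherent target is a predicted target gene whose differential-
#' expression direction is opposite to its miRNA's (up-miRNA with
#' down-gene, or down-miRNA with up-gene). Genes not in the DE set are
#' `unchanged` and non-coherent. Predictions naming unknown miRNAs are
#' skipped with a warning.
#'
#' @param de_mirnas filtered miRNA DE results: columns `feature`,
#'   `direction` (from [de_filter()]).
#' @param de_genes filtered gene DE results: columns `feature`, `direction`.
#' @param predictions data frame with columns `mirna`, `gene` (merged
#'   external prediction tables; an optional `source` column is carried
#'   through).
#' @return list with `calls` — per (DE miRNA, predicted gene) tibble with
#'   `mirna_direction`, `gene_direction`, `coherent` — and `tally` — per
#'   miRNA-direction totals of predicted and coherent targets, with and
#'   without gene repeats.
#' @export
coherent_targets <- function(de_mirnas, de_genes, predictions) {
  assert_cols(de_mirnas, c("feature", "direction"), "de_mirnas")
  assert_cols(de_genes, c("feature", "direction"), "de_genes")
  assert_cols(predictions, c("mirna", "gene"), "predictions")
  unknown <- setdiff(unique(predictions$mirna), de_mirnas$feature)
  preds <- predictions |>
    as_tibble() |>
    filter(.data$mirna %in% de_mirnas$feature)
  if (length(unknown)) {
    warn(sprintf("skipping predictions for %d miRNA(s) not in the DE set",
                 length(unknown)))
  }
  calls <- preds |>
    left_join(de_mirnas |> select(mirna = "feature",
                                  mirna_direction = "direction"),
              by = "mirna") |>
    left_join(de_genes |> select(gene = "feature",
                                 gene_direction = "direction"),
              by = "gene") |>
    mutate(
      gene_direction = replace_na(.data$gene_direction, "unchanged"),
      coherent = (.data$mirna_direction == "up" &
                    .data$gene_direction == "down") |
        (.data$mirna_direction == "down" & .data$gene_direction == "up")
    )
  tally <- calls |>
    group_by(.data$mirna_direction) |>
    summarise(
      n_predicted = dplyr::n(),
      n_predicted_unique = dplyr::n_distinct(.data$gene),
      n_coherent = sum(.data$coherent),
      n_coherent_unique = dplyr::n_distinct(.data$gene[.data$coherent]),
      .groups = "drop"
    )
  list(calls = calls, tally = tally)
}

#' Direction enrichment of predicted targets among DE genes
#'
#' Among the predicted targets that are themselves differentially
#' expressed, the observed fraction in the direction opposite to the miRNA
#' set is compared with the background fraction of that direction among
#' all DE genes, by the chi-square (1 df) two-proportion test
#' ([stats::prop.test()] without continuity correction).
#'
#' @param de_genes filtered gene DE results (columns `feature`,
#'   `direction`).
#' @param predictions data frame of predicted targets (`mirna`, `gene`) of
#'   one miRNA direction set.
#' @param mirna_direction direction of the miRNA set the predictions belong
#'   to (`"up"` or `"down"`); the coherent gene direction is the opposite.
#' @return object of class `target_enrichment`: list with
#'   `observed_fraction`, `background_fraction`, `enrichment_ratio`,
#'   `n_targets_de`, `n_background`, `chisq`, `p`.
#' @export
target_enrichment <- function(de_genes, predictions,
                              mirna_direction = c("up", "down")) {
  mirna_direction <- match.arg(mirna_direction)
  assert_cols(de_genes, c("feature", "direction"), "de_genes")
  assert_cols(predictions, c("mirna", "gene"), "predictions")
  opposite <- if (mirna_direction == "up") "down" else "up"
  targets_de <- de_genes |> filter(.data$feature %in% predictions$gene)
  if (nrow(targets_de) == 0) abort("no predicted target is in the DE gene set")
  k_obs <- sum(targets_de$direction == opposite)
  n_obs <- nrow(targets_de)
  k_bg <- sum(de_genes$direction == opposite)
  n_bg <- nrow(de_genes)
  pt <- suppressWarnings(
    prop.test(c(k_obs, k_bg), c(n_obs, n_bg), correct = FALSE)
  )
  structure(list(
    mirna_direction = mirna_direction,
    observed_fraction = k_obs / n_obs,
    background_fraction = k_bg / n_bg,
    enrichment_ratio = (k_obs / n_obs) / (k_bg / n_bg),
    n_targets_de = n_obs,
    n_background = n_bg,
    chisq = unname(pt$statistic),
    p = pt$p.value
  ), class = "target_enrichment")
}

#' @export
print.target_enrichment <- function(x, ...) {
  cat(sprintf(
    paste0("targets of %s-regulated miRNAs: %.2f%% in the opposite direction",
           " (background %.2f%%), ratio %.2f, chi-square p = %.3g\n"),
    x$mirna_direction, 100 * x$observed_fraction,
    100 * x$background_fraction, x$enrichment_ratio, x$p))
  invisible(x)
}
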