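# Differential expression between two sequencing libraries by the pooled
# two-proportion z-test (Kal et al. 1999), TPM normalisation, signed fold
# change and the threshold filters used for miRNA and DGE comparisons.

#' Tags-per-million normalisation
#'
#' Scales raw read counts to a per-million-library-reads basis:
#' `1e6 * n / N`.
#'
#' @param n non-negative read count(s) for a feature.
#' @param N library total (a single positive number).
#' @return numeric vector of TPM values.
#' @examples
#' tpm(150, 1e6)   # 150
#' tpm(c(0, 500), 2e6)
#' @export
tpm <- function(n, N) {
  if (length(N) != 1L || is.na(N) || N < 1) {
    abort("`N` must be a single library total >= 1")
  }
  if (any(n < 0, na.rm = TRUE)) abort("counts must be non-negative")
  1e6 * n / N
}

#' Pooled two-proportion z-statistic for two-library count comparison
#'
#' The Kal et al. (1999) statistic used for SAGE-style library comparison.
#' With phat1 = n1/N1, phat2 = n2/N2 and the pooled proportion
#' p0 = (n1+n2)/(N1+N2),
#' `z = (phat1 - phat2) / sqrt(p0 (1 - p0) (1/N1 + 1/N2))`.
#'
#' Vectorised over `n1`, `n2`. Features whose pooled proportion is 0 or 1
#' (statistic undefined) return `NA` with a warning.
#'
#' @param n1,n2 feature read counts in library 1 and library 2.
#' @param N1,N2 total reads in library 1 and library 2.
#' @return numeric vector of z-statistics. Library 1 excess gives positive z.
#' @examples
#' kal_z(150, 50, 1e6, 1e6)
#' @export
kal_z <- function(n1, n2, N1, N2) {
  if (any(c(N1, N2) < 1)) abort("library totals must be >= 1")
  if (any(n1 < 0) || any(n2 < 0)) abort("counts must be non-negative")
  if (any(n1 > N1) || any(n2 > N2)) abort("counts cannot exceed library totals")
  p1 <- n1 / N1
  p2 <- n2 / N2
  p0 <- (n1 + n2) / (N1 + N2)
  bad <- p0 <= 0 | p0 >= 1
  if (any(bad)) {
    warn(sprintf("%d feature(s) with pooled proportion 0 or 1; z set to NA",
                 sum(bad)))
  }
  z <- (p1 - p2) / sqrt(p0 * (1 - p0) * (1 / N1 + 1 / N2))
  z[bad] <- NA_real_
  z
}

#' Two-sided normal p-value for a z-statistic
#'
#' @param z numeric vector of z-statistics.
#' @return `2 * (1 - pnorm(abs(z)))`.
#' @export
p_two_sided <- function(z) {
  2 * pnorm(abs(z), lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' `min(1, m * p)` for each p; thin wrapper kept for a complete algebra of
#' the testing pipeline.
#'
#' @param p raw p-values.
#' @param m number of tests (defaults to `length(p)`).
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) abort("`m` must be >= 1")
  pmin(1, m * p)
}

#' Signed fold change with the reciprocal-negative convention
#'
#' Up-regulation in condition 2 relative to condition 1 is reported as the
#' plain ratio `x2/x1`; down-regulation as the negative reciprocal
#' `-x1/x2`, so a halving prints as -2.00 rather than 0.5. Equal values give
#' +1. A zero denominator yields +/-Inf.
#'
#' @param x1 reference value(s) (e.g. delay TPM).
#' @param x2 comparison value(s) (e.g. activation TPM).
#' @return numeric vector with `|fold| >= 1`; sign follows `x2 - x1`.
#' @examples
#' signed_fold(10297, 14877)  # 1.44 at 2 d.p.
#' signed_fold(100, 50)       # -2
#' @export
signed_fold <- function(x1, x2) {
  if (any(x1 < 0 | x2 < 0, na.rm = TRUE)) abort("values must be non-negative")
  both0 <- x1 == 0 & x2 == 0
  if (any(both0, na.rm = TRUE)) abort("signed fold undefined when both values are zero")
  ifelse(x2 >= x1, x2 / x1, -x1 / x2)
}

#' Two-library differential expression test
#'
#' Runs the full per-feature comparison used for both the miRNA and the
#' DGE libraries: TPM for each library, the pooled two-proportion
#' z-statistic on raw counts (never on TPM), a two-sided normal p-value,
#' Bonferroni correction over the tested features, and the signed fold
#' change on TPM.
#'
#' @param counts data frame with columns `feature`, `count_delay`,
#'   `count_activation` (raw read counts).
#' @param totals optional named list/vector with elements `delay` and
#'   `activation` giving library totals; defaults to the column sums of
#'   `counts`, i.e. the feature set itself defines the library.
#' @return a tibble of class `delayseq_de` with columns `feature`,
#'   `count_delay`, `count_activation`, `tpm_delay`, `tpm_activation`,
#'   `signed_fold` (activation over delay), `z`, `p_raw`, `p_bonferroni`.
#' @examples
#' de <- de_test(tibble::tibble(
#'   feature = c("a", "b"),
#'   count_delay = c(100, 400),
#'   count_activation = c(300, 380)
#' ))
#' de_filter(de, min_tpm = 100, min_fold = 1.2, alpha = 0.05)
#' @export
de_test <- function(counts, totals = NULL) {
  assert_cols(counts, c("feature", "count_delay", "count_activation"), "counts")
  if (is.null(totals)) {
    totals <- list(delay = sum(counts$count_delay),
                   activation = sum(counts$count_activation))
  }
  N1 <- as.numeric(totals[["delay"]])
  N2 <- as.numeric(totals[["activation"]])
  res <- counts |>
    as_tibble() |>
    mutate(
      tpm_delay = tpm(.data$count_delay, N1),
      tpm_activation = tpm(.data$count_activation, N2),
      signed_fold = signed_fold(.data$tpm_delay, .data$tpm_activation),
      z = kal_z(.data$count_delay, .data$count_activation, N1, N2),
      p_raw = p_two_sided(.data$z),
      p_bonferroni = bonferroni(.data$p_raw)
    )
  attr(res, "totals") <- c(delay = N1, activation = N2)
  class(res) <- c("delayseq_de", class(res))
  res
}

#' Filter differential-expression results by TPM, fold and significance
#'
#' Keeps features with `max(tpm_delay, tpm_activation) > min_tpm`,
#' `|signed_fold| > min_fold` and p below `alpha` (strict inequalities).
#' Defaults follow the miRNA screen (TPM > 100, fold > 1.2, p < 0.001);
#' the DGE gene screen uses `min_fold = 2`.
#'
#' @param de result of [de_test()].
#' @param min_tpm TPM threshold on either library.
#' @param min_fold threshold on `|signed_fold|`.
#' @param alpha significance level.
#' @param p_kind which p-value the `alpha` cut applies to:
#'   `"bonferroni"` (default, as the Methods apply the correction) or
#'   `"raw"`.
#' @return filtered tibble with an added `direction` column
#'   (`"up"`/`"down"`, activation relative to delay).
#' @export
de_filter <- function(de, min_tpm = 100, min_fold = 1.2, alpha = 0.001,
                      p_kind = c("bonferroni", "raw")) {
  p_kind <- match.arg(p_kind)
  pcol <- if (p_kind == "bonferroni") "p_bonferroni" else "p_raw"
  assert_cols(de, c("tpm_delay", "tpm_activation", "signed_fold", pcol), "de")
  de |>
    filter(
      pmax(.data$tpm_delay, .data$tpm_activation) > min_tpm,
      abs(.data$signed_fold) > min_fold,
      !is.na(.data[[pcol]]), .data[[pcol]] < alpha
    ) |>
    mutate(direction = if_else(.data$signed_fold > 0, "up", "down"))
}
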