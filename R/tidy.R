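# broom-style tidiers for the fitted-object result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a differential-expression result
#'
#' @param x a `delayseq_de` tibble.
#' @param ... unused.
#' @return a plain tibble of the per-feature statistics.
#' @method tidy delayseq_de
#' @export
tidy.delayseq_de <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "delayseq_de")
  out
}

#' One-row summary of a differential-expression result
#'
#' @param x a `delayseq_de` tibble.
#' @param ... unused.
#' @return tibble with the feature count, library totals and the number of
#'   Bonferroni-significant features at 0.001.
#' @method glance delayseq_de
#' @export
glance.delayseq_de <- function(x, ...) {
  totals <- attr(x, "totals")
  tibble(
    n_features = nrow(x),
    total_delay = unname(totals["delay"]),
    total_activation = unname(totals["activation"]),
    n_significant_bonferroni = sum(x$p_bonferroni < 0.001, na.rm = TRUE)
  )
}

#' Tidy a host-gene correlation
#'
#' @param x a `host_correlation` object.
#' @param ... unused.
#' @return one-row tibble with `estimate`, `p.value`, `n`, `method`.
#' @method tidy host_correlation
#' @export
tidy.host_correlation <- function(x, ...) {
  tibble(estimate = x$estimate, p.value = x$p, n = x$n, method = x$method)
}

#' @rdname tidy.host_correlation
#' @method glance host_correlation
#' @export
glance.host_correlation <- function(x, ...) tidy(x, ...)

#' Tidy a target-enrichment test
#'
#' @param x a `target_enrichment` object.
#' @param ... unused.
#' @return one-row tibble with the observed and background opposite-
#'   direction fractions, the enrichment ratio and the chi-square p-value.
#' @method tidy target_enrichment
#' @export
tidy.target_enrichment <- function(x, ...) {
  tibble(
    mirna_direction = x$mirna_direction,
    observed_fraction = x$observed_fraction,
    background_fraction = x$background_fraction,
    enrichment_ratio = x$enrichment_ratio,
    statistic = x$chisq,
    p.value = x$p,
    n_targets_de = x$n_targets_de,
    n_background = x$n_background
  )
}

#' @rdname tidy.target_enrichment
#' @method glance target_enrichment
#' @export
glance.target_enrichment <- function(x, ...) tidy(x, ...)

#' Tidy an editing profile
#'
#' @param x an `editing_profile` tibble.
#' @param ... unused.
#' @return the per-position table as a plain tibble.
#' @method tidy editing_profile
#' @export
tidy.editing_profile <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "editing_profile")
  out
}

#' @rdname tidy.editing_profile
#' @method glance editing_profile
#' @export
glance.editing_profile <- function(x, ...) {
  tibble(
    mirna = attr(x, "mirna"),
    library = attr(x, "library"),
    n_positions = nrow(x),
    total_coverage = max(x$coverage),
    n_significant = sum(x$significant, na.rm = TRUE),
    significant_positions = paste(x$position[which(x$significant)],
                                  collapse = ",")
  )
}
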