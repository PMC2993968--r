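# Small-RNA read preprocessing: 3' adapter trimming by the 8-nt
# perfect-match rule, 18-30 nt length selection, and collapsing to unique
# tags with per-library counts.

#' Trim the 3' adapter by the 8-nt perfect-match rule
#'
#' The 3' end of the small RNA is the position immediately before the
#' 3'-most exact occurrence of the first 8 nt of the 3' adapter; the 5' end
#' of the read is taken verbatim as the 5' nucleotide of the small RNA.
#' Reads with no perfect 8-nt adapter match, reads containing `N`, and
#' reads whose insert would be empty are discarded (returned as `NA`).
#'
#' @param reads character vector of read sequences (DNA).
#' @param adapter3 3' adapter sequence, at least 8 nt; only its first 8 nt
#'   are used for matching. Default is the DNA form of the standard small-RNA
#'   3' adapter.
#' @return character vector the same length as `reads`: the insert, or `NA`
#'   for discarded reads.
#' @examples
#' trim_adapter(paste0("TGAGGTAGTAGGTTGTATAGTT", "TCGTATGCCGTCTT"))
#' @export
trim_adapter <- function(reads, adapter3 = "TCGTATGCCGTCTTCTGCTTG") {
  if (nchar(adapter3) < 8) abort("`adapter3` must be at least 8 nt")
  assert_dna(adapter3, allow_n = FALSE, arg = "adapter3")
  probe <- substr(adapter3, 1, 8)
  out <- rep(NA_character_, length(reads))
  ok <- !is.na(reads) & !grepl("N", reads, fixed = TRUE)
  # 3'-most occurrence: last match start minus one is the insert end
  hit <- str_locate_all(reads[ok], stringr::fixed(probe))
  last_start <- vapply(hit, function(m) {
    if (nrow(m) == 0) NA_integer_ else as.integer(m[nrow(m), "start"])
  }, integer(1))
  ins <- ifelse(is.na(last_start) | last_start == 1L, NA_character_,
                substr(reads[ok], 1L, last_start - 1L))
  out[ok] <- ins
  out
}

#' Size-selection filter
#'
#' Keep inserts of 18-30 nt, mirroring the gel size selection of the
#' library protocol.
#'
#' @param inserts character vector of insert sequences.
#' @param min_len,max_len inclusive length bounds.
#' @return logical vector: `TRUE` for kept inserts (`FALSE` for `NA`).
#' @export
length_filter <- function(inserts, min_len = 18, max_len = 30) {
  len <- nchar(inserts)
  !is.na(inserts) & len >= min_len & len <= max_len
}

#' Collapse inserts to unique tags with per-library counts
#'
#' @param inserts data frame with columns `sequence`, `library`
#'   (values `"delay"` / `"activation"`) and optionally `count`
#'   (pre-collapsed multiplicities; defaults to 1 per row).
#' @return tibble with columns `sequence`, `count_delay`,
#'   `count_activation`, sorted by total count descending, ties broken by
#'   sequence.
#' @export
collapse_tags <- function(inserts) {
  assert_cols(inserts, c("sequence", "library"), "inserts")
  if (!"count" %in% names(inserts)) inserts$count <- 1L
  bad <- setdiff(unique(inserts$library), c("delay", "activation"))
  if (length(bad)) abort(sprintf("unknown library label(s): %s",
                                 paste(bad, collapse = ", ")))
  inserts |>
    as_tibble() |>
    group_by(.data$sequence, .data$library) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    pivot_wider(names_from = "library", values_from = "count",
                names_prefix = "count_", values_fill = 0L) |>
    (\(d) {
      for (col in c("count_delay", "count_activation")) {
        if (!col %in% names(d)) d[[col]] <- 0L
      }
      d
    })() |>
    select("sequence", "count_delay", "count_activation") |>
    arrange(desc(.data$count_delay + .data$count_activation), .data$sequence)
}

#' Full small-RNA preprocessing: trim, filter, collapse
#'
#' Applies [trim_adapter()] and [length_filter()] per read and collapses the
#' survivors with [collapse_tags()]. Accounting is exact:
#' `reads_in = discarded_no_adapter + discarded_length + sum(kept counts)`
#' per library.
#'
#' @param reads data frame with columns `sequence`, `library` and optionally
#'   `count`.
#' @inheritParams trim_adapter
#' @inheritParams length_filter
#' @return list with `tags` (the collapsed tibble), and `stats`, a tibble of
#'   per-library read accounting (`reads_in`, `discarded_no_adapter`,
#'   `discarded_length`, `reads_kept`).
#' @export
preprocess_reads <- function(reads, adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                             min_len = 18, max_len = 30) {
  assert_cols(reads, c("sequence", "library"), "reads")
  if (!"count" %in% names(reads)) reads$count <- 1L
  ins <- trim_adapter(reads$sequence, adapter3)
  keep <- length_filter(ins, min_len, max_len)
  stats <- tibble(
    library = reads$library,
    count = reads$count,
    no_adapter = is.na(ins),
    bad_length = !is.na(ins) & !keep
  ) |>
    group_by(.data$library) |>
    summarise(
      reads_in = sum(.data$count),
      discarded_no_adapter = sum(.data$count[.data$no_adapter]),
      discarded_length = sum(.data$count[.data$bad_length]),
      reads_kept = .data$reads_in - .data$discarded_no_adapter -
        .data$discarded_length,
      .groups = "drop"
    )
  kept <- tibble(sequence = ins[keep],
                 library = reads$library[keep],
                 count = reads$count[keep])
  list(tags = collapse_tags(kept), stats = stats)
}
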