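# Nine-way classification of collapsed small-RNA tags: exact genome
# matching (both strands), interval-based category assignment with a fixed
# priority, and the per-library category summary table.

CATEGORY_LEVELS <- c("miRNA", "piRNA", "tRNA", "rRNA", "snRNA", "snoRNA",
                     "mRNA", "genomic", "unknown")
ANNOTATED_CATEGORIES <- CATEGORY_LEVELS[1:7]

#' Assemble a category annotation
#'
#' @param genome named character vector of chromosome/contig sequences.
#' @param intervals data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `name`, `category` (one of the seven annotated
#'   classes), `strand` (`"+"`/`"-"`).
#' @param mature_mirnas named character vector of mature miRNA sequences
#'   (DNA alphabet).
#' @return list of class `category_annotation`.
#' @export
category_annotation <- function(genome, intervals, mature_mirnas) {
  intervals <- as_tibble(intervals)
  assert_cols(intervals, c("chrom", "start", "end", "name", "category", "strand"),
              "intervals")
  bad <- setdiff(unique(intervals$category), ANNOTATED_CATEGORIES)
  if (length(bad)) {
    abort(sprintf("interval category outside the annotated classes: %s",
                  paste(bad, collapse = ", ")))
  }
  missing_chrom <- setdiff(unique(intervals$chrom), names(genome))
  if (length(missing_chrom)) {
    abort(sprintf("intervals reference unknown chromosome(s): %s",
                  paste(missing_chrom, collapse = ", ")))
  }
  over <- intervals$end > nchar(genome)[match(intervals$chrom, names(genome))]
  if (any(over)) abort("interval(s) extend beyond the chromosome end")
  structure(list(genome = genome, intervals = intervals,
                 mature_mirnas = mature_mirnas),
            class = "category_annotation")
}

#' Exact full-length genome hits of tags
#'
#' Finds every exact, 0-mismatch occurrence of each tag in the genome, on
#' the forward strand and as reverse complement. Hits are ordered by
#' chromosome then position.
#'
#' @param sequences character vector of tag sequences.
#' @param annotation a [category_annotation()].
#' @return tibble with columns `sequence`, `chrom`, `start` (0-based),
#'   `end` (half-open), `strand`.
#' @export
map_to_genome <- function(sequences, annotation) {
  genome <- Biostrings::DNAStringSet(annotation$genome)
  uniq <- unique(sequences)
  one_strand <- function(pat, strand) {
    hits <- Biostrings::vmatchPattern(pat, genome)
    n_per <- lengths(hits)
    if (sum(n_per) == 0) return(NULL)
    starts <- unlist(lapply(hits, Biostrings::start), use.names = FALSE)
    tibble(chrom = rep(names(genome), n_per),
           start = starts - 1L,
           end = starts - 1L + nchar(pat),
           strand = strand)
  }
  res <- lapply(uniq, function(tag) {
    h <- bind_rows(one_strand(tag, "+"), one_strand(revcomp(tag), "-"))
    if (is.null(h) || nrow(h) == 0) return(NULL)
    h$sequence <- tag
    h
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(sequence = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), strand = character(0)))
  }
  out |>
    select("sequence", "chrom", "start", "end", "strand") |>
    arrange(.data$sequence, .data$chrom, .data$start, .data$strand)
}

#' Classify tags into the nine small-RNA categories
#'
#' Assignment rule: a tag overlapping any annotated interval takes the
#' highest-priority overlapped category (miRNA > piRNA > tRNA > rRNA >
#' snRNA > snoRNA > mRNA); a tag with genome hits but no interval overlap
#' is `genomic`; a tag with no hits is `unknown`. Independently of genome
#' placement, a tag that the editing module pairs to a mature miRNA (an
#' isomiR) is classified `miRNA`, so sequence variants of known miRNAs are
#' not lost to `genomic`/`unknown`.
#'
#' @param tags tibble from [collapse_tags()] (columns `sequence`,
#'   `count_delay`, `count_activation`).
#' @param annotation a [category_annotation()].
#' @param mirna_sequences optional character vector of tag sequences already
#'   assigned to mature miRNAs by [assign_reads()]; defaults to running the
#'   pairing internally against `annotation$mature_mirnas`.
#' @return `tags` with an added `category` column (factor with the nine
#'   levels).
#' @export
classify_tags <- function(tags, annotation, mirna_sequences = NULL) {
  assert_cols(tags, "sequence", "tags")
  hits <- map_to_genome(tags$sequence, annotation)
  iv <- annotation$intervals
  overlapped <- hits |>
    inner_join(iv, by = "chrom", relationship = "many-to-many",
               suffix = c("", ".iv")) |>
    filter(.data$start < .data$end.iv, .data$end > .data$start.iv) |>
    mutate(priority = match(.data$category, ANNOTATED_CATEGORIES)) |>
    group_by(.data$sequence) |>
    arrange(.data$priority, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    select("sequence", "category")
  has_hit <- unique(hits$sequence)

  if (is.null(mirna_sequences)) {
    asg <- assign_reads(tags$sequence, annotation$mature_mirnas)
    mirna_sequences <- asg$sequence[!is.na(asg$mirna)]
  }

  tags |>
    as_tibble() |>
    left_join(overlapped, by = "sequence") |>
    mutate(
      category = dplyr::case_when(
        .data$sequence %in% mirna_sequences ~ "miRNA",
        !is.na(.data$category) ~ .data$category,
        .data$sequence %in% has_hit ~ "genomic",
        TRUE ~ "unknown"
      ),
      category = factor(.data$category, levels = CATEGORY_LEVELS)
    )
}

#' Per-library category summary (read-count weighted)
#'
#' Aggregates read counts by category for each library and reports the
#' percentage of the library total, rounded to two decimals — the layout of
#' the published small-RNA category table.
#'
#' @param classified tibble with columns `category`, `count_delay`,
#'   `count_activation` (per tag or already per category).
#' @return tibble with one row per category: `category`, `count_delay`,
#'   `pct_delay`, `count_activation`, `pct_activation`.
#' @export
category_table <- function(classified) {
  assert_cols(classified, c("category", "count_delay", "count_activation"),
              "classified")
  out <- classified |>
    as_tibble() |>
    mutate(category = factor(.data$category, levels = CATEGORY_LEVELS)) |>
    group_by(.data$category) |>
    summarise(count_delay = sum(.data$count_delay),
              count_activation = sum(.data$count_activation),
              .groups = "drop") |>
    mutate(
      pct_delay = round(100 * .data$count_delay / sum(.data$count_delay), 2),
      pct_activation = round(100 * .data$count_activation /
                               sum(.data$count_activation), 2)
    ) |>
    select("category", "count_delay", "pct_delay",
           "count_activation", "pct_activation")
  out
}
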