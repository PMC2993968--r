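# SAGE/DGE analysis: 16-bp DpnII reference-tag extraction, reliability-
# scored tag-to-gene (UniGene-cluster) mapping, singleton filtering,
# match-class summary and differential expression of sequenced tags.

EVIDENCE_CLASSES <- c("mRNA", "HTS_mRNA", "EST_polyA", "no_polyA")

#' Extract the reference 16-bp DpnII tag of a transcript
#'
#' Finds the 3'-most `GATC` (DpnII site) on the sense strand and returns the
#' 16 nt immediately downstream (the anchor itself is excluded). Returns
#' `NA` when the transcript has no GATC or fewer than 16 nt remain 3' of
#' the last site. Sense strand only: DGE libraries are stranded.
#'
#' @param sequences character vector of transcript sequences.
#' @return character vector of 16-mers, `NA` where no tag exists.
#' @examples
#' extract_reference_tag("AAAAGATCCCACTTCCCACAAAATTTTT")
#' @export
extract_reference_tag <- function(sequences) {
  hit <- str_locate_all(sequences, stringr::fixed("GATC"))
  vapply(seq_along(sequences), function(i) {
    m <- hit[[i]]
    if (nrow(m) == 0) return(NA_character_)
    after <- m[nrow(m), "end"]  # last base of the 3'-most GATC
    if (nchar(sequences[i]) - after < 16) return(NA_character_)
    substr(sequences[i], after + 1L, after + 16L)
  }, character(1))
}

#' Build the reliability-scored tag-to-gene map
#'
#' For each reference tag, the supporting transcripts are grouped by their
#' UniGene-like cluster and each cluster is scored by the reliable-source
#' formula: `(#mRNA + #HTS_mRNA) + 0.5 * #EST_polyA` over that cluster's
#' transcripts yielding the tag (`no_polyA` transcripts contribute 0).
#' When more than two clusters claim a tag only the two highest-scoring
#' clusters are retained (ties broken by cluster id); the match class
#' records the pre-truncation multiplicity: `single` (1 cluster), `two`
#' (2) or `multiple` (>2).
#'
#' @param transcripts data frame with columns `id`, `cluster_id`,
#'   `sequence`, `evidence_class` (one of `mRNA`, `HTS_mRNA`, `EST_polyA`,
#'   `no_polyA`).
#' @return list with `map` — tibble (`tag`, `cluster_id`, `score`, `rank`)
#'   with at most two rows per tag — and `tag_class` — tibble (`tag`,
#'   `match_class`, `n_clusters`).
#' @export
build_tag_gene_map <- function(transcripts) {
  assert_cols(transcripts, c("id", "cluster_id", "sequence", "evidence_class"),
              "transcripts")
  bad <- setdiff(unique(transcripts$evidence_class), EVIDENCE_CLASSES)
  if (length(bad)) {
    abort(sprintf("unknown evidence class(es): %s", paste(bad, collapse = ", ")))
  }
  tagged <- transcripts |>
    as_tibble() |>
    mutate(tag = extract_reference_tag(.data$sequence)) |>
    filter(!is.na(.data$tag))
  scored <- tagged |>
    group_by(.data$tag, .data$cluster_id) |>
    summarise(
      score = sum(.data$evidence_class %in% c("mRNA", "HTS_mRNA")) +
        0.5 * sum(.data$evidence_class == "EST_polyA"),
      .groups = "drop_last"
    ) |>
    mutate(n_clusters = dplyr::n()) |>
    arrange(desc(.data$score), .data$cluster_id, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  tag_class <- scored |>
    distinct(.data$tag, .data$n_clusters) |>
    mutate(match_class = dplyr::case_when(
      .data$n_clusters == 1 ~ "single",
      .data$n_clusters == 2 ~ "two",
      TRUE ~ "multiple"
    )) |>
    select("tag", "match_class", "n_clusters")
  list(map = scored |> filter(.data$rank <= 2) |>
         select("tag", "cluster_id", "score", "rank"),
       tag_class = tag_class)
}

#' Remove cross-library singleton tags
#'
#' Drops tags whose count pair over the two libraries is exactly (0,1) or
#' (1,0) — sequencing noise by the published filter.
#'
#' @param counts data frame with columns `tag`, `count_delay`,
#'   `count_activation`.
#' @return filtered tibble.
#' @export
remove_singletons <- function(counts) {
  assert_cols(counts, c("tag", "count_delay", "count_activation"), "counts")
  counts |>
    as_tibble() |>
    filter(!(.data$count_delay + .data$count_activation == 1))
}

#' Match-class summary of sequenced tags
#'
#' Per library: total tags, totals after singleton removal, unique tags,
#' unique tags mapping to the reference tag set, and the percentage of
#' mapped unique tags in each match class (`single` / `two` / `multiple`,
#' two decimals) — the layout of the published unique-reads table.
#'
#' @param counts sequenced tag counts (`tag`, `count_delay`,
#'   `count_activation`), before singleton removal.
#' @param tag_map result of [build_tag_gene_map()].
#' @return tibble with columns `statistic`, `delay`, `activation` (counts or
#'   percentages by row).
#' @export
match_class_summary <- function(counts, tag_map) {
  assert_cols(counts, c("tag", "count_delay", "count_activation"), "counts")
  filtered <- remove_singletons(counts)
  cls <- tag_map$tag_class
  per_lib <- function(cnt_col) {
    present <- filtered[filtered[[cnt_col]] > 0, ]
    mapped <- present |> inner_join(cls, by = "tag")
    n_mapped <- nrow(mapped)
    by_class <- table(factor(mapped$match_class,
                             levels = c("single", "two", "multiple")))
    c(
      total_tags = sum(counts[[cnt_col]]),
      total_tags_no_singleton = sum(filtered[[cnt_col]]),
      unique_tags = sum(counts[[cnt_col]] > 0),
      unique_tags_no_singleton = nrow(present),
      unique_mapped = n_mapped,
      pct_single = round(100 * by_class[["single"]] / max(n_mapped, 1), 2),
      pct_two = round(100 * by_class[["two"]] / max(n_mapped, 1), 2),
      pct_multiple = round(100 * by_class[["multiple"]] / max(n_mapped, 1), 2)
    )
  }
  d <- per_lib("count_delay")
  a <- per_lib("count_activation")
  tibble(statistic = names(d), delay = unname(d), activation = unname(a))
}

#' Differential expression of SAGE tags
#'
#' Removes singletons, runs [de_test()] on the surviving tags (library
#' totals default to post-filter totals) and annotates each tag with its
#' best-scoring cluster where one exists. Filter defaults follow the gene
#' screen (TPM > 100, fold > 2).
#'
#' @param counts sequenced tag counts (`tag`, `count_delay`,
#'   `count_activation`).
#' @param tag_map optional result of [build_tag_gene_map()] for cluster
#'   annotation.
#' @param totals optional library totals passed to [de_test()].
#' @return `delayseq_de` tibble with a `feature` column holding the tag and,
#'   if `tag_map` is given, a `cluster_id` column (best-scoring cluster).
#' @export
sage_de <- function(counts, tag_map = NULL, totals = NULL) {
  filtered <- remove_singletons(counts)
  de <- filtered |>
    rename(feature = "tag") |>
    de_test(totals = totals)
  if (!is.null(tag_map)) {
    best <- tag_map$map |> filter(.data$rank == 1) |>
      select(feature = "tag", "cluster_id")
    de <- left_join(de, best, by = "feature")
    class(de) <- c("delayseq_de", class(de)[!class(de) %in% "delayseq_de"])
  }
  de
}
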