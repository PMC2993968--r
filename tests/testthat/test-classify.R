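test_that("genome mapping finds exactly the planted exact hits", {
  ann <- toy_annotation()
  let7a <- ann$mature_mirnas[["mmu-let-7a"]]
  hits <- map_to_genome(let7a, ann)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 10)
  expect_equal(hits$strand, "+")
  # absent sequence
  expect_equal(nrow(map_to_genome("GACGACGACGACGACGACGA", ann)), 0)
  # reverse-complement hit
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(let7a, "")[[1]]), collapse = ""))
  rhits <- map_to_genome(rc, ann)
  expect_equal(rhits$strand, "-")
  expect_equal(rhits$start, 10)
})

test_that("genome mapping equals a naive full scan on random tags", {
  ann <- toy_annotation()
  set.seed(21)
  tags <- c(random_seq(100, 20),
            substr(ann$genome[["chr1"]], 31, 50))  # one guaranteed hit
  for (tag in unique(tags)) {
    got <- map_to_genome(tag, ann)
    want <- oracle_genome_hits(tag, as.list(ann$genome))
    expect_equal(nrow(got), nrow(want), info = tag)
    if (nrow(want)) {
      expect_equal(got$start, want$start, info = tag)
      expect_equal(got$strand, want$strand, info = tag)
    }
  }
})

test_that("classification follows the category priority and fallbacks", {
  # overlapping rRNA and mRNA intervals -> rRNA by priority
  genome <- c(chrA = paste0(strrep("T", 5), "ACGTACGTACGTACGTACGTACGT",
                            strrep("T", 5)))
  iv <- tibble::tibble(chrom = "chrA", start = c(5L, 5L), end = c(29L, 29L),
                       name = c("r1", "m1"), category = c("mRNA", "rRNA"),
                       strand = "+")
  ann <- category_annotation(genome, iv, c(mir = "TTTTTTTTTTGGGGGGGGGGCC"))
  tags <- tibble::tibble(sequence = "ACGTACGTACGTACGTACGT",
                         count_delay = 1L, count_activation = 0L)
  out <- classify_tags(tags, ann, mirna_sequences = character(0))
  expect_equal(as.character(out$category), "rRNA")

  ann2 <- toy_annotation()
  # genome hit outside any interval -> genomic (the planted unannotated
  # feature)
  t2 <- tibble::tibble(sequence = "CCTTAAGGCCTTATAGGCCT",
                       count_delay = 1L, count_activation = 0L)
  expect_equal(as.character(
    classify_tags(t2, ann2, mirna_sequences = character(0))$category),
    "genomic")
  # no hit at all -> unknown
  t3 <- tibble::tibble(sequence = "GACGACGACGACGACGACGA",
                       count_delay = 1L, count_activation = 0L)
  expect_equal(as.character(
    classify_tags(t3, ann2, mirna_sequences = character(0))$category),
    "unknown")
})

test_that("isomiRs absent from the genome are still classified as miRNA", {
  ann <- toy_annotation()
  edited <- ann$mature_mirnas[["mmu-let-7a"]]
  substr(edited, 5, 5) <- "C"
  tags <- tibble::tibble(sequence = edited, count_delay = 3L,
                         count_activation = 1L)
  out <- classify_tags(tags, ann)  # internal isomiR pairing
  expect_equal(as.character(out$category), "miRNA")
})

test_that("every tag receives exactly one category and counts are conserved", {
  set.seed(31)
  cfg <- smallrna_sim_config(n_reads_per_library = 5000)
  sim <- simulate_smallrna_libraries(cfg)
  pre <- preprocess_reads(sim$reads)
  out <- classify_tags(pre$tags, sim$annotation)
  expect_false(any(is.na(out$category)))
  expect_equal(nrow(out), nrow(pre$tags))
  tab <- category_table(out)
  expect_equal(sum(tab$count_delay), sum(pre$tags$count_delay))
  expect_equal(sum(tab$count_activation), sum(pre$tags$count_activation))
  expect_lt(abs(sum(tab$pct_delay) - 100), 0.05)
  expect_lt(abs(sum(tab$pct_activation) - 100), 0.05)
})

test_that("a no-noise simulated library is recovered category-exactly", {
  set.seed(32)
  cfg <- smallrna_sim_config(
    n_reads_per_library = 4000,
    editing_spec = tibble::tibble(),
    three_prime_addition_prob = 0, three_prime_trim_prob = 0
  )
  sim <- simulate_smallrna_libraries(cfg)
  pre <- preprocess_reads(sim$reads)
  out <- classify_tags(pre$tags, sim$annotation)
  got <- category_table(out)
  want <- sim$truth |>
    dplyr::group_by(category, library) |>
    dplyr::summarise(count = sum(count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = library, values_from = count,
                       values_fill = 0L)
  cmp <- merge(got, want, by = "category")
  expect_equal(cmp$count_delay, cmp$delay)
  expect_equal(cmp$count_activation, cmp$activation)
})

test_that("category percentages reproduce the published activation column", {
  printed <- readr::read_tsv(
    system.file("extdata", "smallrna_categories_printed.tsv",
                package = "delayseq"),
    show_col_types = FALSE
  )
  tab <- category_table(printed)
  expect_equal(tab$pct_activation[tab$category == "miRNA"], 76.57)
  expect_equal(tab$pct_activation[tab$category == "unknown"], 21.34)
  # degenerate single-category library
  one <- category_table(tibble::tibble(category = "miRNA",
                                       count_delay = 10L,
                                       count_activation = 7L))
  expect_equal(one$pct_delay[one$category == "miRNA"], 100)
})
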