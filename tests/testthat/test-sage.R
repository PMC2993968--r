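test_that("DpnII tag extraction takes 16 nt after the 3'-most GATC", {
  expect_equal(extract_reference_tag("AAAAGATCCCACTTCCCACAAAATTTTT"),
               "CCACTTCCCACAAAAT")
  expect_true(is.na(extract_reference_tag("AAAACCCCTTTTGGGGAAAACCCC")))
  # fewer than 16 nt downstream of the last site -> no tag
  expect_true(is.na(extract_reference_tag("AAAAGATCCCACTTCC")))
  # multiple sites: verified against a naive occurrence scan
  set.seed(71)
  seqs <- vapply(1:200, function(i) {
    paste(sample(c("A", "C", "G", "T", "GATC"), 40, replace = TRUE),
          collapse = "")
  }, character(1))
  expect_equal(extract_reference_tag(seqs),
               vapply(seqs, oracle_dpnii_tag, character(1), USE.NAMES = FALSE))
})

test_that("tag extraction is sense-strand only", {
  s <- "AAAAGATCCCACTTCCCACAAAATTTTT"
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_false(identical(extract_reference_tag(s), extract_reference_tag(rc)))
})

test_that("cluster reliability scores follow the evidence-weighted formula", {
  tag_ctx <- function(tag) paste0(strrep("A", 30), "GATC", tag, strrep("C", 18))
  tag1 <- "TTTTCCCCGGGGTTTT"
  tx <- tibble::tibble(
    id = sprintf("t%d", 1:6),
    cluster_id = c(rep("Mm.1", 5), "Mm.2"),
    sequence = tag_ctx(tag1),
    evidence_class = c("mRNA", "mRNA", "HTS_mRNA", "EST_polyA", "EST_polyA",
                       "no_polyA")
  )
  m <- build_tag_gene_map(tx)
  expect_equal(m$map$score[m$map$cluster_id == "Mm.1"], 2 + 1 + 0.5 * 2)
  expect_equal(m$map$score[m$map$cluster_id == "Mm.2"], 0)
  expect_equal(m$tag_class$match_class, "two")

  # adding an mRNA transcript never decreases the score
  tx2 <- rbind(tx, tibble::tibble(id = "t7", cluster_id = "Mm.1",
                                  sequence = tag_ctx(tag1),
                                  evidence_class = "mRNA"))
  m2 <- build_tag_gene_map(tx2)
  expect_gte(m2$map$score[m2$map$cluster_id == "Mm.1"],
             m$map$score[m$map$cluster_id == "Mm.1"])
})

test_that("at most two clusters survive per tag, ties broken by id", {
  tag_ctx <- function(tag) paste0(strrep("A", 30), "GATC", tag, strrep("C", 18))
  tag1 <- "TTTTCCCCGGGGTTTT"
  tx <- tibble::tibble(
    id = sprintf("t%d", 1:4),
    cluster_id = c("Mm.9", "Mm.2", "Mm.5", "Mm.7"),
    sequence = tag_ctx(tag1),
    evidence_class = "mRNA"
  )
  m <- build_tag_gene_map(tx)
  expect_equal(nrow(m$map), 2)
  expect_equal(sort(m$map$cluster_id), c("Mm.2", "Mm.5"))
  expect_equal(m$tag_class$match_class, "multiple")
  expect_equal(m$tag_class$n_clusters, 4)
  # a single-cluster tag
  solo <- build_tag_gene_map(tx[1, ])
  expect_equal(solo$tag_class$match_class, "single")
})

test_that("singleton removal drops exactly the (0,1)/(1,0) pairs", {
  counts <- tibble::tibble(tag = c("a", "b", "c", "d"),
                           count_delay = c(0L, 1L, 1L, 5L),
                           count_activation = c(1L, 0L, 1L, 0L))
  out <- remove_singletons(counts)
  expect_equal(out$tag, c("c", "d"))
  expect_equal(nrow(remove_singletons(counts[0, ])), 0)
  set.seed(72)
  m <- 500
  k <- 60
  cnt <- tibble::tibble(
    tag = sprintf("t%04d", 1:m),
    count_delay = c(rep(1L, k / 2), rep(0L, k / 2), sample(2:50, m - k, TRUE)),
    count_activation = c(rep(0L, k / 2), rep(1L, k / 2),
                         sample(2:50, m - k, TRUE))
  )
  expect_equal(nrow(remove_singletons(cnt)), m - k)
})

test_that("match-class summary percentages reproduce a constructed census", {
  # integer-coded 16-mers guarantee uniqueness at scale
  int_tag <- function(i) {
    chartr("0123", "ACGT",
           vapply(i, function(x) {
             paste(rev((x %/% 4^(0:15)) %% 4), collapse = "")
           }, character(1)))
  }
  n_single <- 870; n_two <- 100; n_multi <- 30
  tags <- int_tag(seq_len(n_single + n_two + n_multi))
  counts <- tibble::tibble(tag = tags, count_delay = 2L, count_activation = 2L)
  tag_map <- list(tag_class = tibble::tibble(
    tag = tags,
    match_class = rep(c("single", "two", "multiple"),
                      c(n_single, n_two, n_multi)),
    n_clusters = rep(c(1L, 2L, 3L), c(n_single, n_two, n_multi))
  ))
  s <- match_class_summary(counts, tag_map)
  expect_equal(s$delay[s$statistic == "pct_single"], 87)
  expect_equal(s$delay[s$statistic == "pct_two"], 10)
  expect_equal(s$delay[s$statistic == "pct_multiple"], 3)
  expect_equal(s$delay[s$statistic == "unique_mapped"], 1000)
})

test_that("tag DE recovers a planted fold and respects the singleton filter", {
  set.seed(73)
  cfg <- smallrna_sim_config(n_transcripts = 120, fraction_tagless = 0,
                             n_sage_reads_per_library = 1e5)
  tx <- simulate_transcriptome(cfg)
  cfg$gene_de_spec <- setNames(c(4, 4, 4),
                               tx$truth$cluster_id[1:3])
  sage <- simulate_sage_reads(cfg, tx)
  map <- build_tag_gene_map(tx$transcripts)
  de <- sage_de(sage$counts, map)
  sig <- de_filter(de, min_tpm = 100, min_fold = 2, alpha = 0.001)
  planted_tags <- sage$truth$tag[!is.na(sage$truth$true_fold) &
                                   sage$truth$true_fold == 4]
  expect_true(all(planted_tags %in% sig$feature))
  expect_true(all(sig$feature %in% planted_tags))
  expect_false(any(sage$truth$tag[sage$truth$is_singleton] %in% de$feature))
})
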