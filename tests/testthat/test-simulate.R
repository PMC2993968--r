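test_that("configuration validation rejects inconsistent inputs", {
  expect_error(smallrna_sim_config(category_mix = c(miRNA = 0.5)),
               "nine categories")
  mix <- delayseq:::default_category_mix()
  mix["miRNA"] <- mix["miRNA"] + 0.1
  expect_error(smallrna_sim_config(category_mix = mix), "sum to 1")
  expect_error(smallrna_sim_config(de_spec = c(nosuch = 2)), "unknown miRNA")
  expect_error(smallrna_sim_config(three_prime_trim_prob = 1.5),
               "\\[0, 1\\]")
  expect_error(smallrna_sim_config(editing_spec = tibble::tibble(
    mirna = "mmu-let-7a", position = 1L, from = "A", to = "G",
    prob_delay = 0.1, prob_activation = 0.1)), "does not match")
})

test_that("a fixed seed reproduces the simulation exactly", {
  cfg <- smallrna_sim_config(n_reads_per_library = 3000)
  set.seed(99); a <- simulate_smallrna_libraries(cfg)
  set.seed(99); b <- simulate_smallrna_libraries(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
})

test_that("per-library totals are exact and the no-noise limit is clean", {
  set.seed(61)
  cfg <- smallrna_sim_config(n_reads_per_library = 8000,
                             editing_spec = tibble::tibble(),
                             three_prime_addition_prob = 0,
                             three_prime_trim_prob = 0)
  sim <- simulate_smallrna_libraries(cfg)
  totals <- tapply(sim$truth$count, sim$truth$library, sum)
  expect_equal(as.vector(totals), c(8000, 8000))
  mir <- sim$truth[sim$truth$category == "miRNA", ]
  expect_true(all(mir$sequence %in% cfg$mirna_set$sequence))
})

test_that("a degenerate all-miRNA mix yields only adapter-bearing miRNA reads", {
  set.seed(62)
  mix <- setNames(rep(0, 9), names(delayseq:::default_category_mix()))
  mix["miRNA"] <- 1
  cfg <- smallrna_sim_config(n_reads_per_library = 1000, category_mix = mix,
                             editing_spec = tibble::tibble(),
                             three_prime_addition_prob = 0,
                             three_prime_trim_prob = 0)
  sim <- simulate_smallrna_libraries(cfg)
  expect_true(all(sim$truth$category == "miRNA"))
  pre <- preprocess_reads(sim$reads)
  expect_true(all(pre$stats$discarded_no_adapter == 0))
  cls <- classify_tags(pre$tags, sim$annotation)
  expect_true(all(cls$category == "miRNA"))
})

test_that("planted fold changes are realised within sampling error", {
  set.seed(63)
  cfg <- smallrna_sim_config(
    n_reads_per_library = 1e6,
    de_spec = c("mmu-miR-146b" = 2),
    editing_spec = tibble::tibble(),
    three_prime_addition_prob = 0, three_prime_trim_prob = 0
  )
  sim <- simulate_smallrna_libraries(cfg)
  mir <- sim$truth[!is.na(sim$truth$mirna) &
                     sim$truth$mirna == "mmu-miR-146b", ]
  cd <- sum(mir$count[mir$library == "delay"])
  ca <- sum(mir$count[mir$library == "activation"])
  # expected ratio: the planted fold times the activation renormalisation
  ab <- cfg$mirna_set$abundance
  fold <- ifelse(cfg$mirna_set$name == "mmu-miR-146b", 2, 1)
  expected <- 2 * sum(ab) / sum(ab * fold)
  se <- expected * sqrt(1 / ca + 1 / cd)
  expect_lt(abs(ca / cd - expected), 3 * se)
})

test_that("transcriptome tags match an independent re-scan of the sequences", {
  set.seed(64)
  cfg <- smallrna_sim_config(n_transcripts = 150)
  tx <- simulate_transcriptome(cfg)
  rescanned <- vapply(tx$transcripts$sequence, oracle_dpnii_tag, character(1))
  expect_equal(unname(rescanned), tx$truth$tag)
  expect_equal(sum(is.na(tx$truth$tag)), round(0.05 * 150))
  # planted shared tags are shared across clusters
  shared <- tx$truth |>
    dplyr::filter(!is.na(tag)) |>
    dplyr::count(tag) |>
    dplyr::filter(n > 1)
  expect_gt(nrow(shared), 0)
})

test_that("a fully tagless transcriptome yields no reference tags", {
  set.seed(65)
  cfg <- smallrna_sim_config(n_transcripts = 40, fraction_tagless = 1)
  tx <- simulate_transcriptome(cfg)
  expect_true(all(is.na(extract_reference_tag(tx$transcripts$sequence))))
})

test_that("SAGE counts carry planted folds and singletons", {
  set.seed(66)
  cfg <- smallrna_sim_config(n_transcripts = 100, fraction_tagless = 0,
                             n_sage_reads_per_library = 1e5,
                             n_singletons = 10)
  tx <- simulate_transcriptome(cfg)
  cfg$gene_de_spec <- setNames(4, tx$truth$cluster_id[1])
  sage <- simulate_sage_reads(cfg, tx)
  expect_equal(sum(sage$truth$is_singleton), 10)
  filtered <- remove_singletons(sage$counts)
  expect_equal(nrow(filtered), nrow(sage$counts) - 10)
  planted <- sage$counts[sage$counts$tag == tx$truth$tag[1], ]
  n_tags <- sum(!sage$truth$is_singleton)
  expected <- 4 * n_tags / (n_tags + 3)
  se <- expected * sqrt(1 / planted$count_activation + 1 / planted$count_delay)
  expect_lt(abs(planted$count_activation / planted$count_delay - expected),
            3 * se)
})

test_that("host-pair generator hits the target correlation on average", {
  set.seed(67)
  r <- replicate(100, {
    pairs <- simulate_host_pairs(75, r_target = 0.35)
    host_gene_correlation(pairs)$estimate
  })
  expect_lt(abs(mean(r) - 0.35), 0.1)
})

test_that("prediction generator plants the requested coherent bias", {
  set.seed(68)
  de_mirnas <- tibble::tibble(feature = sprintf("m%02d", 1:10),
                              direction = rep(c("up", "down"), 5))
  de_genes <- tibble::tibble(feature = sprintf("g%03d", 1:100),
                             direction = rep(c("up", "down"), 50))
  preds <- simulate_target_predictions(de_mirnas, de_genes,
                                       sprintf("g%03d", 1:200),
                                       targets_per_mirna = 40,
                                       coherent_bias = 0.8)
  calls <- coherent_targets(de_mirnas, de_genes, preds)
  frac <- sum(calls$calls$coherent) / nrow(calls$calls)
  expect_gt(frac, 0.6)
})
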