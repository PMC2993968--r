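matures2 <- c("mmu-let-7a" = "TGAGGTAGTAGGTTGTATAGTT",
              "mmu-miR-21" = "TAGCTTATCAGACTGATGTTGA",
              "mmu-miR-143" = "TGAGATGAAGCACTGTAGCTC")

test_that("k-mer pairing proposes the true source and nothing for noise", {
  cand <- pair_candidates(matures2[["mmu-let-7a"]], matures2)
  expect_true("mmu-let-7a" %in% cand[[1]])
  # an edit in the middle of the read still leaves a shared default k-mer
  mid <- matures2[["mmu-let-7a"]]
  substr(mid, 11, 11) <- "C"
  expect_true("mmu-let-7a" %in% pair_candidates(mid, matures2)[[1]])
  set.seed(51)
  # random 22-mers sharing no 12-mer with any mature find no candidate at
  # k = 12
  rnd <- random_seq(20, 22)
  share <- vapply(rnd, function(s) {
    any(vapply(matures2, function(m) {
      any(substring(s, 1:11, 12:22) %in% substring(m, 1:(nchar(m) - 11),
                                                   12:nchar(m)))
    }, logical(1)))
  }, logical(1))
  cands <- pair_candidates(rnd[!share], matures2, k = 12)
  expect_true(all(lengths(cands) == 0))
})

test_that("tags with up to two edits are assigned to the true source", {
  set.seed(52)
  for (i in 1:50) {
    nm <- sample(names(matures2), 1)
    s <- matures2[[nm]]
    n_edit <- sample(0:2, 1)
    pos <- sample(nchar(s), n_edit)
    for (p in pos) {
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    }
    asg <- assign_reads(s, matures2)
    expect_equal(asg$mirna, nm, info = s)
  }
  # identical sequences under two names tie on score and events:
  # alphabetical name wins
  twins <- c(zzz = matures2[["mmu-let-7a"]], aaa = matures2[["mmu-let-7a"]])
  expect_equal(assign_reads(matures2[["mmu-let-7a"]], twins)$mirna, "aaa")
  # heavily divergent sequence stays unassigned (score floor)
  junk <- paste0(substr(matures2[["mmu-let-7a"]], 1, 12), "CCCCCCCCCC")
  expect_true(is.na(assign_reads(junk, matures2)$mirna))
})

test_that("isomiR tables rank by TPM and conserve assigned counts", {
  # counts chosen so TPM equals the count (totals 1e6)
  iso <- c("TAGCTTATCAGACTGATGTTGA", "TAGCTTATCAGACTGATGTTGAC",
           "TAGCTTATCAGACTGATGTTG")
  tags <- tibble::tibble(sequence = iso,
                         count_delay = c(7054L, 2313L, 4214L),
                         count_activation = c(6756L, 8427L, 3781L))
  asg <- assign_reads(tags$sequence, matures2)
  tab <- isomir_table(asg, tags, "mmu-miR-21",
                      totals = list(delay = 1e6, activation = 1e6))
  expect_equal(sum(tab$tpm_activation), 18964)
  expect_equal(sum(tab$tpm_delay), 13581)
  expect_equal(sum(tab$count_delay) + sum(tab$count_activation),
               sum(tags$count_delay) + sum(tags$count_activation))
  # reference row renders clean; the 3' addition is lower-cased
  expect_match(attr(tab, "reference_display"), "TAGCTTATCAGACTGATGTTGA")
  expect_match(tab$display[tab$sequence == iso[2]], "c")
  ranked <- order(tab$tpm_delay + tab$tpm_activation, decreasing = TRUE)
  expect_equal(tab$rank, seq_len(nrow(tab)))
  expect_equal(ranked, seq_len(nrow(tab)))
})

test_that("editing rates are count-weighted substitution fractions", {
  ref <- matures2[["mmu-let-7a"]]
  edited <- ref
  substr(edited, 5, 5) <- "C"
  tags <- tibble::tibble(sequence = c(ref, edited, substr(ref, 1, 21)),
                         count_delay = c(10L, 10L, 10L),
                         count_activation = c(0L, 0L, 0L))
  asg <- assign_reads(tags$sequence, matures2)
  prof <- editing_profile(asg, tags, "mmu-let-7a", library = "delay")
  expect_equal(prof$rate[prof$position == 5], 1 / 3)
  expect_true(all(prof$rate[prof$position != 5] == 0))
  expect_true(all(prof$coverage >= prof$edited))
  # all-reference library: rate 0 everywhere
  t0 <- tibble::tibble(sequence = ref, count_delay = 5L,
                       count_activation = 0L)
  p0 <- editing_profile(assign_reads(ref, matures2), t0, "mmu-let-7a",
                        library = "delay")
  expect_true(all(p0$rate == 0))
})

test_that("position Z-scores are median-centred with an upper-tail p", {
  zs <- position_zscores(rep(0.01, 22))
  expect_true(all(zs$z == 0))
  expect_true(all(zs$p == 0.5))
  expect_false(any(zs$significant))
  set.seed(53)
  r <- runif(22, 0, 0.05)
  expect_equal(median(position_zscores(r)$z), 0)
  # a single hot position against a quiet background is the only flag
  rates <- c(rep(0.01, 3), 0.3, rep(0.01, 18))
  zs2 <- position_zscores(rates)
  expect_equal(which(zs2$significant), 4L)
  # direct normal-tail cross-check of the hot position's p
  zraw <- (rates - mean(rates)) / sd(rates)
  zc <- zraw - median(zraw)
  expect_equal(zs2$p[4], pnorm(zc[4], lower.tail = FALSE))
  expect_error(position_zscores(c(0.1, NA, NA)), "at least 3")
})

test_that("substitution spectrum is count-weighted and excludes end variants", {
  ref <- matures2[["mmu-let-7a"]]
  ta <- ref
  substr(ta, 18, 18) <- "A"  # T -> A
  added <- paste0(ref, "A")  # 3' addition must not count as a substitution
  tags <- tibble::tibble(sequence = c(ref, ta, added),
                         count_delay = c(93L, 2L, 5L),
                         count_activation = c(100L, 0L, 0L))
  asg <- assign_reads(tags$sequence, matures2)
  spec <- substitution_spectrum(asg, tags)
  expect_equal(nrow(spec), 12)
  expect_equal(spec$pct_delay[spec$from == "T" & spec$to == "A"], 2)
  expect_equal(sum(spec$pct_delay), 2)
  expect_equal(sum(spec$pct_activation), 0)
})

test_that("region comparison reduces to the pooled two-proportion test", {
  pa <- tibble::tibble(position = 1:5, coverage = rep(200, 5),
                       edited = c(0, 0, 0, 15, 15))
  pb <- tibble::tibble(position = 1:5, coverage = rep(200, 5),
                       edited = c(0, 0, 0, 5, 5))
  cmp <- compare_region_editing(pa, pb, 4:5)
  expect_equal(cmp$z, kal_z(30, 10, 400, 400))
  same <- compare_region_editing(pa, pa, 4:5)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_error(compare_region_editing(pa, pb, 10:12), "coverage")
})

test_that("planted editing is recovered at the planted positions only", {
  set.seed(54)
  cfg <- smallrna_sim_config(n_reads_per_library = 2e4)
  sim <- simulate_smallrna_libraries(cfg)
  pre <- preprocess_reads(sim$reads)
  asg <- assign_reads(pre$tags$sequence, with(cfg$mirna_set,
                                              setNames(sequence, name)))
  prof <- editing_profile(asg, pre$tags, "mmu-let-7a", library = "delay")
  expect_equal(prof$position[prof$significant], c(4L, 5L))
  # conservation: isoform counts equal assigned counts
  tab <- isomir_table(asg, pre$tags, "mmu-let-7a", n_top = Inf)
  assigned <- pre$tags[pre$tags$sequence %in%
                         asg$sequence[!is.na(asg$mirna) &
                                        asg$mirna == "mmu-let-7a"], ]
  expect_equal(sum(tab$count_delay), sum(assigned$count_delay))
  expect_equal(sum(tab$count_activation), sum(assigned$count_activation))
})
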