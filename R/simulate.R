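# Synthetic-data generator: every input the pipeline consumes, with planted
# ground truth. Two libraries ("delay", "activation") mirror the study
# design of a delayed-implantation uterus versus its estrogen-activated
# counterpart. Reads are represented collapsed as (sequence, count); the
# per-read Bernoulli editing and end-variant model is realised exactly as a
# multinomial over the enumerated variant space, so simulations are cheap
# at any depth without changing the distribution.

LIBRARIES <- c("delay", "activation")

# Category fractions of the study's delay library (exact count ratios, so
# they sum to 1 by construction).
default_category_mix <- function() {
  counts <- c(miRNA = 3972448, piRNA = 11912, tRNA = 9900, rRNA = 9377,
              snRNA = 434, snoRNA = 12875, mRNA = 18321, genomic = 30611,
              unknown = 1268643)
  counts / sum(counts)
}

default_mirna_set <- function() {
  tibble(
    name = c("mmu-let-7a", "mmu-let-7b", "mmu-let-7c", "mmu-let-7f",
             "mmu-miR-21", "mmu-miR-143", "mmu-miR-146b", "mmu-miR-145",
             "mmu-miR-29a", "mmu-miR-16"),
    sequence = c("TGAGGTAGTAGGTTGTATAGTT", "TGAGGTAGTAGGTTGTGTGGTT",
                 "TGAGGTAGTAGGTTGTATGGTT", "TGAGGTAGTAGATTGTATAGTT",
                 "TAGCTTATCAGACTGATGTTGA", "TGAGATGAAGCACTGTAGCTC",
                 "TGAGAACTGAATTCCATAGGCT", "GTCCAGTTTTCCCAGGAATCCCT",
                 "TAGCACCATCTGAAATCGGTTA", "TAGCAGCACGTAAATATTGGCG"),
    host_gene = NA_character_,
    abundance = c(20, 18, 30, 12, 3, 2, 1, 0.5, 4, 1)
  )
}

#' Simulation configuration for the small-RNA libraries
#'
#' Defaults describe the study conditions at desk scale: two libraries
#' whose category composition follows the published delay-library
#' fractions, a ten-miRNA catalog with let-7-dominated abundances,
#' activation/delay fold changes planted on a few miRNAs, and editing
#' planted in the seed region (positions 4-5) of let-7a at a higher rate
#' under delay — the study's headline editing contrast.
#'
#' @param n_reads_per_library reads per library.
#' @param category_mix named fractions over the nine categories, summing
#'   to 1.
#' @param mirna_set tibble with columns `name`, `sequence`, optional
#'   `host_gene` and `abundance` (relative within the miRNA category).
#' @param de_spec named numeric vector of true activation/delay fold
#'   changes per miRNA (1 = null; 2 = doubled under activation).
#' @param editing_spec tibble with columns `mirna`, `position` (1-based),
#'   `from`, `to`, `prob_delay`, `prob_activation` (per-read substitution
#'   probabilities; a single `prob` column is accepted for both).
#' @param three_prime_addition_prob,three_prime_trim_prob per-read
#'   probabilities of a one-base non-templated 3' addition (an `A`) or a
#'   one-base 3' trim.
#' @param adapter3 3' adapter appended to each insert.
#' @param read_length fixed emitted read length (insert + adapter prefix,
#'   truncated).
#' @param no_adapter_prob per-read probability that the adapter is replaced
#'   by random sequence (exercises the adapter-discard path).
#' @param decoy_pool_size unique sequences per non-miRNA annotated
#'   category.
#' @param unknown_pool_size unique unmappable sequences.
#' @param n_transcripts,evidence_class_mix,fraction_tagless,gene_de_spec,
#'   n_sage_reads_per_library,n_singletons transcriptome/DGE parameters
#'   (see [simulate_transcriptome()] and [simulate_sage_reads()]).
#' @return validated list of class `smallrna_sim_config`.
#' @export
smallrna_sim_config <- function(
    n_reads_per_library = 1e5,
    category_mix = default_category_mix(),
    mirna_set = default_mirna_set(),
    de_spec = c("mmu-let-7f" = 1.27, "mmu-miR-21" = 1.44,
                "mmu-miR-146b" = 3.52, "mmu-miR-145" = 1 / 2.56,
                "mmu-let-7b" = 1 / 1.20, "mmu-miR-29a" = 1 / 1.47,
                "mmu-miR-16" = 1 / 1.69),
    editing_spec = tibble(
      mirna = c("mmu-let-7a", "mmu-let-7a"),
      position = c(4L, 5L), from = c("G", "G"), to = c("A", "C"),
      prob_delay = c(0.08, 0.08), prob_activation = c(0.02, 0.02)
    ),
    three_prime_addition_prob = 0.05,
    three_prime_trim_prob = 0.10,
    adapter3 = "TCGTATGCCGTCTTCTGCTTG",
    read_length = 36,
    no_adapter_prob = 0,
    decoy_pool_size = 25,
    unknown_pool_size = 100,
    n_transcripts = 300,
    evidence_class_mix = c(mRNA = 0.5, HTS_mRNA = 0.2, EST_polyA = 0.2,
                           no_polyA = 0.1),
    fraction_tagless = 0.05,
    gene_de_spec = NULL,
    n_sage_reads_per_library = 1e5,
    n_singletons = 20) {
  if (!setequal(names(category_mix), CATEGORY_LEVELS)) {
    abort("`category_mix` must name exactly the nine categories")
  }
  if (abs(sum(category_mix) - 1) > 1e-9) {
    abort("`category_mix` fractions must sum to 1")
  }
  mirna_set <- as_tibble(mirna_set)
  assert_cols(mirna_set, c("name", "sequence"), "mirna_set")
  if (!"abundance" %in% names(mirna_set)) mirna_set$abundance <- 1
  if (!"host_gene" %in% names(mirna_set)) mirna_set$host_gene <- NA_character_
  assert_dna(mirna_set$sequence, allow_n = FALSE, arg = "mirna_set$sequence")
  editing_spec <- as_tibble(editing_spec)
  if (nrow(editing_spec) > 0) {
    if ("prob" %in% names(editing_spec) &&
        !"prob_delay" %in% names(editing_spec)) {
      editing_spec$prob_delay <- editing_spec$prob
      editing_spec$prob_activation <- editing_spec$prob
    }
    assert_cols(editing_spec,
                c("mirna", "position", "from", "to", "prob_delay",
                  "prob_activation"), "editing_spec")
    unknown <- setdiff(editing_spec$mirna, mirna_set$name)
    if (length(unknown)) {
      abort(sprintf("editing_spec names unknown miRNA(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    ref_base <- substr(mirna_set$sequence[match(editing_spec$mirna,
                                                mirna_set$name)],
                       editing_spec$position, editing_spec$position)
    if (any(ref_base != editing_spec$from)) {
      abort("editing_spec `from` base does not match the mature sequence")
    }
  }
  unknown_de <- setdiff(names(de_spec), mirna_set$name)
  if (length(unknown_de)) {
    abort(sprintf("de_spec names unknown miRNA(s): %s",
                  paste(unknown_de, collapse = ", ")))
  }
  probs <- c(three_prime_addition_prob, three_prime_trim_prob,
             no_adapter_prob,
             if (nrow(editing_spec)) editing_spec$prob_delay,
             if (nrow(editing_spec)) editing_spec$prob_activation)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (three_prime_addition_prob + three_prime_trim_prob > 1) {
    abort("3' addition and trim probabilities must sum to <= 1")
  }
  if (abs(sum(evidence_class_mix) - 1) > 1e-9 ||
      !setequal(names(evidence_class_mix), EVIDENCE_CLASSES)) {
    abort("`evidence_class_mix` must cover exactly the four classes and sum to 1")
  }
  if (nchar(adapter3) < 8) abort("`adapter3` must be at least 8 nt")
  structure(
    list(n_reads_per_library = n_reads_per_library,
         category_mix = category_mix, mirna_set = mirna_set,
         de_spec = de_spec, editing_spec = editing_spec,
         three_prime_addition_prob = three_prime_addition_prob,
         three_prime_trim_prob = three_prime_trim_prob,
         adapter3 = adapter3, read_length = read_length,
         no_adapter_prob = no_adapter_prob,
         decoy_pool_size = decoy_pool_size,
         unknown_pool_size = unknown_pool_size,
         n_transcripts = n_transcripts,
         evidence_class_mix = evidence_class_mix,
         fraction_tagless = fraction_tagless,
         gene_de_spec = gene_de_spec,
         n_sage_reads_per_library = n_sage_reads_per_library,
         n_singletons = n_singletons),
    class = "smallrna_sim_config")
}

# Sample unique random sequences avoiding a set of forbidden substrings and
# the adapter probe. Internal.
sample_pool <- function(n, len_range, forbid_probe, avoid = character(0)) {
  out <- character(0)
  guard <- 0
  while (length(out) < n && guard < 50) {
    cand <- random_dna(2L * n, sample(len_range[1]:len_range[2], 2L * n,
                                      replace = TRUE))
    cand <- cand[!str_detect(cand, stringr::fixed(forbid_probe))]
    cand <- setdiff(unique(cand), c(avoid, out))
    out <- c(out, cand)
    guard <- guard + 1
  }
  head(out, n)
}

# Enumerate the variant space of one miRNA under the editing and
# end-variant model; returns sequences with per-library probabilities.
# Internal.
mirna_variants <- function(name, mature, spec, p_add, p_trim) {
  if (nrow(spec) == 0 || !"mirna" %in% names(spec)) {
    spec <- tibble(mirna = character(0), position = integer(0),
                   from = character(0), to = character(0),
                   prob_delay = numeric(0), prob_activation = numeric(0))
  }
  sites <- spec[spec$mirna == name, , drop = FALSE]
  n_sites <- nrow(sites)
  site_sets <- expand.grid(rep(list(c(FALSE, TRUE)), n_sites))
  if (n_sites == 0) site_sets <- data.frame(row.names = 1)
  ends <- tibble(end = c("none", "trim3", "add3"),
                 p_end = c(1 - p_add - p_trim, p_trim, p_add))
  ends <- ends[ends$p_end > 0, ]
  rows <- list()
  for (si in seq_len(nrow(site_sets))) {
    on <- if (n_sites) unlist(site_sets[si, , drop = TRUE]) else logical(0)
    seq0 <- mature
    for (j in which(on)) {
      substr(seq0, sites$position[j], sites$position[j]) <- sites$to[j]
    }
    p_del <- prod(ifelse(on, sites$prob_delay, 1 - sites$prob_delay))
    p_act <- prod(ifelse(on, sites$prob_activation, 1 - sites$prob_activation))
    for (ei in seq_len(nrow(ends))) {
      s <- switch(ends$end[ei],
                  none = seq0,
                  trim3 = substr(seq0, 1, nchar(seq0) - 1L),
                  add3 = paste0(seq0, "A"))
      rows[[length(rows) + 1L]] <- tibble(
        mirna = name, sequence = s,
        edited_positions = paste(sites$position[on], collapse = ","),
        end_variant = ends$end[ei],
        p_delay = p_del * ends$p_end[ei],
        p_activation = p_act * ends$p_end[ei])
    }
  }
  list_rbind(rows)
}

#' Simulate the two small-RNA libraries with planted ground truth
#'
#' Builds a toy genome carrying every annotated feature, enumerates the
#' isomiR variant space of each miRNA under the editing/end-variant model,
#' and draws one multinomial per library over the full sequence universe,
#' so per-library totals are exact and planted fold changes are realised
#' as binomial sampling around the specified ratios. Each emitted read is
#' the insert followed by the 3' adapter, truncated to the fixed read
#' length.
#'
#' @param config a [smallrna_sim_config()].
#' @return list with `reads` (tibble `sequence`, `library`, `count` —
#'   adapter-bearing reads, collapsed), `truth` (tibble per insert and
#'   library: `sequence`, `library`, `count`, `category`, `mirna`,
#'   `edited_positions`, `end_variant`), and `annotation` (a
#'   [category_annotation()] for the toy genome).
#' @export
simulate_smallrna_libraries <- function(config) {
  stopifnot(inherits(config, "smallrna_sim_config"))
  probe <- substr(config$adapter3, 1, 8)
  mirnas <- config$mirna_set

  # decoy pools for the non-miRNA annotated categories
  decoy_cats <- setdiff(ANNOTATED_CATEGORIES, "miRNA")
  pools <- list(miRNA = mirnas$sequence)
  avoid <- mirnas$sequence
  for (cat in decoy_cats) {
    pools[[cat]] <- sample_pool(config$decoy_pool_size, c(20, 26), probe, avoid)
    avoid <- c(avoid, pools[[cat]])
  }
  pools[["genomic"]] <- sample_pool(config$decoy_pool_size, c(20, 26), probe,
                                    avoid)
  avoid <- c(avoid, pools[["genomic"]])

  # toy genome: planted features with random spacers; intervals annotate
  # every category except "genomic" (those sequences sit in the genome
  # without a feature interval)
  planted_cats <- c("miRNA", decoy_cats, "genomic")
  feats <- tibble(
    category = rep(planted_cats, lengths(pools[planted_cats])),
    name = unlist(lapply(planted_cats, function(cat) {
      if (cat == "miRNA") mirnas$name
      else sprintf("%s_%03d", cat, seq_along(pools[[cat]]))
    }), use.names = FALSE),
    sequence = unlist(pools[planted_cats], use.names = FALSE)
  )
  spacers <- random_dna(nrow(feats) + 1L, 12)
  pieces <- character(2L * nrow(feats) + 1L)
  pieces[seq(1, length(pieces), by = 2)] <- spacers
  pieces[seq(2, length(pieces), by = 2)] <- feats$sequence
  genome <- c(chr1 = paste(pieces, collapse = ""))
  starts <- cumsum(c(0L, nchar(pieces)))[seq(2, length(pieces), by = 2)]
  intervals <- tibble(chrom = "chr1", start = starts,
                      end = starts + nchar(feats$sequence),
                      name = feats$name, category = feats$category,
                      strand = "+") |>
    filter(.data$category != "genomic")
  mature_named <- setNames(mirnas$sequence, mirnas$name)
  annotation <- category_annotation(genome, intervals, mature_named)

  # unknown pool: screened off the genome and off any 12-mer of a mature
  mature_12mers <- unique(unlist(lapply(mirnas$sequence, kmers, k = 12)))
  unknown_pool <- character(0)
  while (length(unknown_pool) < config$unknown_pool_size) {
    cand <- sample_pool(config$unknown_pool_size, c(20, 26), probe,
                        c(avoid, unknown_pool))
    ok <- !str_detect(genome, stringr::fixed(cand)) &
      !str_detect(genome, stringr::fixed(revcomp(cand))) &
      !vapply(cand, function(s) any(kmers(s, 12) %in% mature_12mers),
              logical(1))
    unknown_pool <- c(unknown_pool, cand[ok])
  }
  unknown_pool <- head(unknown_pool, config$unknown_pool_size)

  # sequence universe with per-library weights
  fold <- setNames(rep(1, nrow(mirnas)), mirnas$name)
  fold[names(config$de_spec)] <- config$de_spec
  variants <- list_rbind(lapply(seq_len(nrow(mirnas)), function(i) {
    v <- mirna_variants(mirnas$name[i], mirnas$sequence[i],
                        config$editing_spec,
                        config$three_prime_addition_prob,
                        config$three_prime_trim_prob)
    v$p_delay <- v$p_delay * mirnas$abundance[i]
    v$p_activation <- v$p_activation * mirnas$abundance[i] *
      fold[[mirnas$name[i]]]
    v
  }))
  mir_universe <- variants |>
    mutate(category = "miRNA",
           w_delay = .data$p_delay / sum(.data$p_delay) *
             config$category_mix[["miRNA"]],
           w_activation = .data$p_activation / sum(.data$p_activation) *
             config$category_mix[["miRNA"]]) |>
    select("sequence", "category", "mirna", "edited_positions",
           "end_variant", "w_delay", "w_activation")
  other_universe <- list_rbind(lapply(c(decoy_cats, "genomic", "unknown"),
                                      function(cat) {
    pool <- if (cat == "unknown") unknown_pool else pools[[cat]]
    tibble(sequence = pool, category = cat, mirna = NA_character_,
           edited_positions = NA_character_, end_variant = NA_character_,
           w_delay = config$category_mix[[cat]] / length(pool),
           w_activation = config$category_mix[[cat]] / length(pool))
  }))
  universe <- bind_rows(mir_universe, other_universe)

  n <- config$n_reads_per_library
  cnt_delay <- rmultinom(1, n, universe$w_delay)[, 1]
  cnt_act <- rmultinom(1, n, universe$w_activation)[, 1]
  truth <- bind_rows(
    universe |> mutate(library = "delay", count = cnt_delay),
    universe |> mutate(library = "activation", count = cnt_act)
  ) |>
    filter(.data$count > 0) |>
    select("sequence", "library", "count", "category", "mirna",
           "edited_positions", "end_variant")

  reads <- truth |>
    mutate(sequence = substr(paste0(.data$sequence, config$adapter3),
                             1L, config$read_length)) |>
    group_by(.data$sequence, .data$library) |>
    summarise(count = sum(.data$count), .groups = "drop")
  if (config$no_adapter_prob > 0) {
    moved <- reads |>
      mutate(junk = rbinom(dplyr::n(), .data$count, config$no_adapter_prob))
    junk <- moved |>
      filter(.data$junk > 0) |>
      mutate(sequence = vapply(substr(.data$sequence, 1, 18), function(s) {
        paste0(s, paste(sample(DNA_BASES, config$read_length - 18,
                               replace = TRUE), collapse = ""))
      }, character(1)), count = .data$junk)
    reads <- bind_rows(moved |> mutate(count = .data$count - .data$junk),
                       junk |> select(-"junk")) |>
      select(-dplyr::any_of("junk")) |>
      filter(.data$count > 0)
  }
  list(reads = reads, truth = truth, annotation = annotation,
       config = config)
}

#' Simulate a transcript database with planted DpnII tags
#'
#' Every transcript (except a configurable tagless fraction) carries a
#' GATC site followed by a known GATC-free 16-mer tag and tail, so the
#' planted tag is provably the one downstream of the 3'-most site. A
#' configurable number of tag collisions (the same 16-mer planted in
#' transcripts of different clusters) exercises the two/multiple match
#' classes.
#'
#' @param config a [smallrna_sim_config()].
#' @param n_shared_two,n_shared_multi numbers of tags planted in exactly 2
#'   and in 3 clusters.
#' @return list with `transcripts` (tibble `id`, `cluster_id`, `sequence`,
#'   `evidence_class`) and `truth` (tibble `id`, `cluster_id`, `tag`;
#'   `tag` is NA for tagless transcripts).
#' @export
simulate_transcriptome <- function(config, n_shared_two = 10,
                                   n_shared_multi = 5) {
  stopifnot(inherits(config, "smallrna_sim_config"))
  n <- config$n_transcripts
  if (n < 1) abort("need at least one transcript")
  n_tagless <- round(config$fraction_tagless * n)
  n_tagged <- n - n_tagless

  gatc_free <- function(k, len) {
    out <- character(0)
    while (length(out) < k) {
      cand <- random_dna(2L * k, len)
      cand <- cand[!str_detect(cand, stringr::fixed("GATC"))]
      out <- unique(c(out, cand))
    }
    head(out, k)
  }
  # cluster layout: shared tags span clusters; the rest are singletons
  n_two <- min(n_shared_two, n_tagged %/% 4)
  n_multi <- min(n_shared_multi, n_tagged %/% 6)
  n_shared_tx <- 2L * n_two + 3L * n_multi
  n_single <- n_tagged - n_shared_tx
  tags_single <- gatc_free(n_single, 16)
  tags_two <- gatc_free(n_two + n_multi, 16)
  tags_multi <- tags_two[seq_len(n_multi)]
  tags_two <- tags_two[n_multi + seq_len(n_two)]

  tag_of <- c(tags_single, rep(tags_two, each = 2), rep(tags_multi, each = 3))
  cluster <- sprintf("Mm.%05d", seq_len(n_tagged))
  tx <- tibble(
    id = sprintf("TX%05d", seq_len(n)),
    cluster_id = c(cluster, sprintf("Mm.%05d", n_tagged + seq_len(n_tagless))),
    tag = c(tag_of, rep(NA_character_, n_tagless))
  )
  tails <- gatc_free(n, 20)
  # no GATC may form across the tag/tail junction, or the planted tag would
  # not be the one downstream of the 3'-most site
  for (i in seq_len(n)) {
    if (is.na(tx$tag[i])) next
    while (grepl("GATC", paste0(tx$tag[i], tails[i]), fixed = TRUE)) {
      tails[i] <- gatc_free(1, 20)
    }
  }
  prefixes <- random_dna(n, 60)
  tx$sequence <- ifelse(
    is.na(tx$tag),
    gatc_free(1, 80)[rep(1, n)],  # placeholder, replaced below
    paste0(prefixes, "GATC", tx$tag, tails)
  )
  if (n_tagless > 0) {
    tx$sequence[is.na(tx$tag)] <- gatc_free(n_tagless, 80)
  }
  classes <- names(config$evidence_class_mix)
  tx$evidence_class <- sample(classes, n, replace = TRUE,
                              prob = config$evidence_class_mix)
  list(transcripts = tx |> select("id", "cluster_id", "sequence",
                                  "evidence_class"),
       truth = tx |> select("id", "cluster_id", "tag"))
}

#' Simulate sequenced SAGE tag counts for the two libraries
#'
#' Tag counts are drawn multinomially per library from per-cluster weights,
#' with `gene_de_spec` folds (activation/delay) applied to the named
#' clusters; planted singleton tags with count pairs (1,0) and (0,1)
#' exercise the singleton filter.
#'
#' @param config a [smallrna_sim_config()].
#' @param transcriptome result of [simulate_transcriptome()].
#' @return list with `counts` (tibble `tag`, `count_delay`,
#'   `count_activation`) and `truth` (tibble `tag`, `cluster_id`,
#'   `true_fold`, `is_singleton`).
#' @export
simulate_sage_reads <- function(config, transcriptome) {
  stopifnot(inherits(config, "smallrna_sim_config"))
  tags <- transcriptome$truth |>
    filter(!is.na(.data$tag)) |>
    distinct(.data$tag, .keep_all = TRUE)
  fold <- setNames(rep(1, nrow(tags)), tags$cluster_id)
  if (!is.null(config$gene_de_spec)) {
    known <- intersect(names(config$gene_de_spec), tags$cluster_id)
    fold[known] <- config$gene_de_spec[known]
  }
  w_delay <- rep(1, nrow(tags))
  w_act <- unname(fold[tags$cluster_id])
  n <- config$n_sage_reads_per_library
  counts <- tibble(
    tag = tags$tag,
    count_delay = rmultinom(1, n, w_delay / sum(w_delay))[, 1],
    count_activation = rmultinom(1, n, w_act / sum(w_act))[, 1]
  )
  k <- config$n_singletons
  if (k > 0) {
    probe <- "GATC"
    sing <- character(0)
    while (length(sing) < k) {
      cand <- random_dna(2L * k, 16)
      cand <- setdiff(cand[!str_detect(cand, stringr::fixed(probe))],
                      c(tags$tag, sing))
      sing <- c(sing, cand)
    }
    sing <- head(sing, k)
    half <- k %/% 2
    singles <- tibble(
      tag = sing,
      count_delay = c(rep(1L, half), rep(0L, k - half)),
      count_activation = c(rep(0L, half), rep(1L, k - half))
    )
    counts <- bind_rows(counts, singles)
  } else {
    sing <- character(0)
  }
  truth <- tibble(tag = counts$tag,
                  cluster_id = c(tags$cluster_id, rep(NA_character_,
                                                      length(sing))),
                  true_fold = c(unname(fold[tags$cluster_id]),
                                rep(NA_real_, length(sing))),
                  is_singleton = counts$tag %in% sing)
  list(counts = counts, truth = truth)
}

#' Simulate co-expressed miRNA/host-gene TPM pairs
#'
#' Draws a latent shared log-normal factor per pair so that the Pearson
#' correlation of the log10(TPM+1) values is `r_target` in expectation.
#'
#' @param n_pairs number of intragenic miRNA / host-gene pairs.
#' @param r_target target correlation on the log scale.
#' @param log_mean,log_sd location and scale of the log10 expression.
#' @return tibble with columns `mirna`, `host_gene`, `mirna_tpm`,
#'   `host_tpm`.
#' @export
simulate_host_pairs <- function(n_pairs = 75, r_target = 0.35,
                                log_mean = 2, log_sd = 0.8) {
  if (r_target <= 0 || r_target >= 1) abort("`r_target` must be in (0, 1)")
  f <- stats::rnorm(n_pairs)
  a <- sqrt(r_target)
  e_scale <- sqrt(1 - r_target)
  x <- a * f + e_scale * stats::rnorm(n_pairs)
  y <- a * f + e_scale * stats::rnorm(n_pairs)
  tibble(
    mirna = sprintf("sim-miR-%03d", seq_len(n_pairs)),
    host_gene = sprintf("Host%03d", seq_len(n_pairs)),
    mirna_tpm = pmax(10^(log_mean + log_sd * x) - 1, 0),
    host_tpm = pmax(10^(log_mean + log_sd * y) - 1, 0)
  )
}

#' Simulate a miRNA-to-target prediction table with planted coherence
#'
#' For each DE miRNA a set of predicted target genes is drawn; with
#' probability `coherent_bias` a target is taken from the genes moving
#' opposite to the miRNA (a repressed target), otherwise uniformly from
#' the remaining genes.
#'
#' @param de_mirnas tibble with columns `feature`, `direction` (miRNA DE
#'   calls).
#' @param de_genes tibble with columns `feature`, `direction` (gene DE
#'   calls).
#' @param all_genes character vector of the full gene universe.
#' @param targets_per_mirna predictions drawn per miRNA.
#' @param coherent_bias probability a prediction is planted coherent.
#' @return tibble with columns `mirna`, `gene`, `source`.
#' @export
simulate_target_predictions <- function(de_mirnas, de_genes, all_genes,
                                        targets_per_mirna = 10,
                                        coherent_bias = 0.65) {
  assert_cols(de_mirnas, c("feature", "direction"), "de_mirnas")
  assert_cols(de_genes, c("feature", "direction"), "de_genes")
  rows <- lapply(seq_len(nrow(de_mirnas)), function(i) {
    opp <- if (de_mirnas$direction[i] == "up") "down" else "up"
    opp_genes <- de_genes$feature[de_genes$direction == opp]
    other <- setdiff(all_genes, opp_genes)
    pick_coherent <- runif(targets_per_mirna) < coherent_bias &
      length(opp_genes) > 0
    gene <- character(targets_per_mirna)
    gene[pick_coherent] <- sample(opp_genes, sum(pick_coherent),
                                  replace = TRUE)
    gene[!pick_coherent] <- sample(other, sum(!pick_coherent),
                                   replace = TRUE)
    tibble(mirna = de_mirnas$feature[i], gene = gene,
           source = sample(c("targetscan", "pita"), targets_per_mirna,
                           replace = TRUE))
  })
  list_rbind(rows) |> distinct(.data$mirna, .data$gene, .keep_all = TRUE)
}
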