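# End-to-end orchestration: simulate (or load) inputs, preprocess,
# classify, test differential expression, profile editing, run the DGE
# branch and the integrative analysis, and optionally write every table.

#' Per-miRNA read counts from isomiR assignments
#'
#' Two counting modes are provided because published miRNA count tables do
#' not always state which was used: `"all_isomirs"` sums every tag assigned
#' to the miRNA (reference plus variants); `"reference_only"` counts only
#' tags identical to the mature reference.
#'
#' @param assignments output of [assign_reads()].
#' @param tags collapsed tag counts (`sequence`, `count_delay`,
#'   `count_activation`).
#' @param mature_mirnas named character vector of mature sequences (needed
#'   for `"reference_only"`).
#' @param mode counting mode.
#' @return tibble with columns `feature` (miRNA name), `count_delay`,
#'   `count_activation`.
#' @export
mirna_counts <- function(assignments, tags, mature_mirnas = NULL,
                         mode = c("all_isomirs", "reference_only")) {
  mode <- match.arg(mode)
  asg <- assignments |>
    filter(!is.na(.data$mirna)) |>
    inner_join(tags, by = "sequence")
  if (mode == "reference_only") {
    if (is.null(mature_mirnas)) {
      abort("`mature_mirnas` is required for reference_only counting")
    }
    asg <- asg |>
      filter(.data$sequence == unname(mature_mirnas[.data$mirna]))
  }
  asg |>
    group_by(feature = .data$mirna) |>
    summarise(count_delay = sum(.data$count_delay),
              count_activation = sum(.data$count_activation),
              .groups = "drop")
}

#' Pipeline configuration
#'
#' Bundles the simulation configuration, every analysis threshold and the
#' seed into one object; [read_pipeline_config()] builds it from YAML.
#'
#' @param seed integer seed controlling all randomness.
#' @param sim a [smallrna_sim_config()].
#' @param mirna_min_tpm,mirna_min_fold,mirna_alpha miRNA DE filter.
#' @param gene_min_tpm,gene_min_fold,gene_alpha gene (DGE) DE filter.
#' @param p_kind which p-value the filters cut on (`"bonferroni"`/`"raw"`).
#' @param editing_alpha per-position editing significance level.
#' @param counting_mode miRNA counting mode (see [mirna_counts()]).
#' @param n_host_pairs,host_r host-gene co-expression simulation.
#' @param targets_per_mirna,coherent_bias target-prediction simulation.
#' @param outdir optional output directory for the TSV bundle.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = smallrna_sim_config(),
                            mirna_min_tpm = 100, mirna_min_fold = 1.2,
                            mirna_alpha = 0.001,
                            gene_min_tpm = 100, gene_min_fold = 2,
                            gene_alpha = 0.001,
                            p_kind = "bonferroni",
                            editing_alpha = 0.01,
                            counting_mode = "all_isomirs",
                            n_host_pairs = 75, host_r = 0.35,
                            targets_per_mirna = 10, coherent_bias = 0.65,
                            outdir = NULL) {
  if (any(c(mirna_min_tpm, mirna_min_fold, mirna_alpha, gene_min_tpm,
            gene_min_fold, gene_alpha, editing_alpha) <= 0)) {
    abort("thresholds must be positive")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; a `sim` block maps
#' to [smallrna_sim_config()] arguments (`de_spec` and `gene_de_spec` as
#' named maps, `editing_spec` as a list of records).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  for (nm in c("de_spec", "gene_de_spec")) {
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  }
  if (!is.null(sim_args$editing_spec)) {
    sim_args$editing_spec <- list_rbind(lapply(sim_args$editing_spec,
                                               as_tibble))
  }
  if (!is.null(sim_args$mirna_set)) {
    sim_args$mirna_set <- list_rbind(lapply(sim_args$mirna_set, as_tibble))
  }
  if (!is.null(sim_args$category_mix)) {
    sim_args$category_mix <- unlist(sim_args$category_mix)
  }
  sim <- do.call(smallrna_sim_config, sim_args)
  args <- y[setdiff(names(y), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

#' Run the full pipeline on simulated inputs
#'
#' Executes simulate -> trim/collapse -> classify -> miRNA DE -> editing ->
#' DGE -> integration under one seed. Every stage consumes only the
#' previous stage's outputs; when `config$outdir` is set each table is
#' written as TSV with a provenance header.
#'
#' @param config a [pipeline_config()].
#' @return named list: `reads`, `preprocess_stats`, `tags`,
#'   `category_table`, `mirna_counts`, `mirna_de`, `mirna_de_significant`,
#'   `editing_profiles` (per configured miRNA and library),
#'   `substitution_spectrum`, `seed_region_comparison`, `tag_map`,
#'   `sage_summary`, `gene_de`, `gene_de_significant`, `host_correlation`,
#'   `coherent_targets`, `target_enrichment`, plus `truth` and `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  sim <- stage("simulate", simulate_smallrna_libraries(config$sim))
  matures <- setNames(config$sim$mirna_set$sequence,
                      config$sim$mirna_set$name)

  pre <- stage("trim", preprocess_reads(sim$reads,
                                        adapter3 = config$sim$adapter3))
  tags <- pre$tags
  totals <- list(delay = sum(tags$count_delay),
                 activation = sum(tags$count_activation))

  asg <- stage("assign", assign_reads(tags$sequence, matures))
  classified <- stage("classify",
                      classify_tags(tags, sim$annotation,
                                    mirna_sequences =
                                      asg$sequence[!is.na(asg$mirna)]))
  cat_tab <- category_table(classified)

  mir_counts <- stage("mirna_counts",
                      mirna_counts(asg, tags, matures,
                                   mode = config$counting_mode))
  mir_de <- stage("de", de_test(mir_counts, totals = totals))
  mir_sig <- de_filter(mir_de, config$mirna_min_tpm, config$mirna_min_fold,
                       config$mirna_alpha, config$p_kind)

  profiled <- unique(config$sim$editing_spec$mirna)
  if (!length(profiled)) profiled <- config$sim$mirna_set$name[1]
  profiles <- stage("editing", {
    out <- list()
    for (m in profiled) {
      for (lib in LIBRARIES) {
        out[[paste(m, lib, sep = ".")]] <-
          editing_profile(asg, tags, m, library = lib,
                          alpha = config$editing_alpha)
      }
    }
    out
  })
  spectrum <- substitution_spectrum(asg, tags)
  seed_cmp <- stage("seed_comparison", {
    m <- profiled[1]
    compare_region_editing(profiles[[paste(m, "delay", sep = ".")]],
                           profiles[[paste(m, "activation", sep = ".")]],
                           positions = 4:5)
  })

  txome <- stage("dge_simulate", simulate_transcriptome(config$sim))
  tag_map <- stage("dge_map", build_tag_gene_map(txome$transcripts))
  sage <- stage("dge_counts", simulate_sage_reads(config$sim, txome))
  sage_sum <- match_class_summary(sage$counts, tag_map)
  gene_de_tags <- stage("dge_de", sage_de(sage$counts, tag_map))
  gene_de <- gene_de_tags |>
    filter(!is.na(.data$cluster_id)) |>
    mutate(feature = .data$cluster_id)
  gene_sig <- de_filter(gene_de, config$gene_min_tpm, config$gene_min_fold,
                        config$gene_alpha, config$p_kind)

  host_pairs <- stage("integrate",
                      simulate_host_pairs(config$n_host_pairs,
                                          config$host_r))
  host_cor <- host_gene_correlation(host_pairs)
  integ <- NULL
  enrich <- NULL
  if (nrow(mir_sig) > 0 && nrow(gene_sig) > 0) {
    preds <- simulate_target_predictions(
      mir_sig, gene_sig, unique(gene_de$feature),
      targets_per_mirna = config$targets_per_mirna,
      coherent_bias = config$coherent_bias)
    integ <- coherent_targets(mir_sig, gene_sig, preds)
    up_preds <- preds |> filter(.data$mirna %in%
                                  mir_sig$feature[mir_sig$direction == "up"])
    if (nrow(up_preds) > 0 &&
        any(gene_sig$feature %in% up_preds$gene)) {
      enrich <- target_enrichment(gene_sig, up_preds, "up")
    }
  }

  bundle <- list(
    reads = sim$reads, preprocess_stats = pre$stats, tags = tags,
    category_table = cat_tab, mirna_counts = mir_counts, mirna_de = mir_de,
    mirna_de_significant = mir_sig, editing_profiles = profiles,
    substitution_spectrum = spectrum, seed_region_comparison = seed_cmp,
    tag_map = tag_map, sage_counts = sage$counts, sage_summary = sage_sum,
    gene_de = gene_de, gene_de_significant = gene_sig,
    host_pairs = host_pairs, host_correlation = host_cor,
    coherent_targets = integ, target_enrichment = enrich,
    truth = list(smallrna = sim$truth, transcripts = txome$truth,
                 sage = sage$truth),
    config = config
  )

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    params <- list(seed = config$seed,
                   mirna_filter = c(config$mirna_min_tpm,
                                    config$mirna_min_fold,
                                    config$mirna_alpha),
                   gene_filter = c(config$gene_min_tpm, config$gene_min_fold,
                                   config$gene_alpha),
                   p_kind = config$p_kind,
                   editing_alpha = config$editing_alpha,
                   counting_mode = config$counting_mode)
    w <- function(df, name) {
      write_result_tsv(df, file.path(config$outdir, paste0(name, ".tsv")),
                       params)
    }
    w(pre$stats, "preprocess_stats")
    w(cat_tab, "category_table")
    w(mir_de, "mirna_de")
    w(mir_sig, "mirna_de_significant")
    w(spectrum, "substitution_spectrum")
    for (nm in names(profiles)) w(profiles[[nm]], paste0("editing_", nm))
    w(sage_sum, "sage_summary")
    w(gene_de, "gene_de")
    w(gene_sig, "gene_de_significant")
    if (!is.null(integ)) w(integ$calls, "coherent_targets")
  }
  bundle
}
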