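# IsomiR and editing analysis: read-to-miRNA assignment via k-mer
# pre-filtering plus global alignment, isoform tables, per-position editing
# rates with the median-centred Z-score test, substitution spectra, and
# between-condition comparison of editing in a position set.

#' Candidate mature miRNAs sharing an exact k-mer with each tag
#'
#' A fast pre-filter standing in for a rough alignment step: a mature miRNA
#' is a candidate source of a tag if the two share at least one exact k-mer.
#' Tags with no candidate are not miRNA-derived. The default k = 7 is the
#' largest k guaranteeing (by pigeonhole) that a read carrying up to two
#' substitutions of a >= 21-nt mature still shares an exact k-mer with it:
#' two edits leave an unbroken run of at least ceiling((21 - 2) / 3) = 7
#' matching bases.
#'
#' @param sequences character vector of tag sequences.
#' @param mature_mirnas named character vector of mature sequences.
#' @param k k-mer size of the pre-filter.
#' @return named list (one element per input sequence) of candidate miRNA
#'   names, possibly empty.
#' @export
pair_candidates <- function(sequences, mature_mirnas, k = 7) {
  if (is.null(names(mature_mirnas))) abort("`mature_mirnas` must be named")
  idx <- new.env(parent = emptyenv())
  for (nm in names(mature_mirnas)) {
    for (km in unique(kmers(mature_mirnas[[nm]], k))) {
      assign(km, c(idx[[km]], nm), envir = idx)
    }
  }
  out <- lapply(sequences, function(s) {
    hits <- unlist(lapply(unique(kmers(s, k)), function(km) idx[[km]]),
                   use.names = FALSE)
    sort(unique(hits))
  })
  names(out) <- sequences
  out
}

#' Assign tags to their best-matching mature miRNA
#'
#' Aligns every tag against its k-mer candidates with [nw_align()] and keeps
#' only the highest-scoring alignment. Ties are broken by fewer isomiR
#' events, then alphabetical miRNA name. Alignments scoring below
#' `length(tag) - max_score_drop` are left unassigned — a perfect match
#' scores exactly the tag length, so the drop bounds the tolerated
#' divergence.
#'
#' @param sequences character vector of tag sequences.
#' @param mature_mirnas named character vector of mature sequences; names
#'   listed in `exclude` (e.g. miRNAs with known SNPs in the mature
#'   sequence) are skipped.
#' @param params [nw_params()] alignment scores.
#' @param k k-mer size of the candidate pre-filter.
#' @param max_score_drop assignment floor: minimum accepted score is
#'   `nchar(sequence) - max_score_drop`.
#' @param exclude character vector of miRNA names to skip.
#' @return tibble with one row per input sequence: `sequence`, `mirna`
#'   (`NA` if unassigned), `score`, `aligned_read`, `aligned_ref`,
#'   `n_events`.
#' @export
assign_reads <- function(sequences, mature_mirnas, params = nw_params(),
                         k = 7, max_score_drop = 8, exclude = NULL) {
  mature_mirnas <- mature_mirnas[setdiff(names(mature_mirnas), exclude)]
  uniq <- unique(sequences)
  cand <- pair_candidates(uniq, mature_mirnas, k = k)
  rows <- lapply(uniq, function(s) {
    nms <- cand[[s]]
    best <- NULL
    for (nm in nms) {
      al <- nw_align(s, mature_mirnas[[nm]], params)
      ev <- alignment_events(al$aligned_read, al$aligned_ref)
      rec <- list(mirna = nm, score = al$score,
                  aligned_read = al$aligned_read,
                  aligned_ref = al$aligned_ref, n_events = nrow(ev))
      if (is.null(best) ||
          rec$score > best$score ||
          (rec$score == best$score && rec$n_events < best$n_events) ||
          (rec$score == best$score && rec$n_events == best$n_events &&
           rec$mirna < best$mirna)) {
        best <- rec
      }
    }
    if (is.null(best) || best$score < nchar(s) - max_score_drop) {
      return(tibble(sequence = s, mirna = NA_character_, score = NA_integer_,
                    aligned_read = NA_character_, aligned_ref = NA_character_,
                    n_events = NA_integer_))
    }
    tibble(sequence = s, mirna = best$mirna, score = best$score,
           aligned_read = best$aligned_read, aligned_ref = best$aligned_ref,
           n_events = best$n_events)
  })
  res <- list_rbind(rows)
  res[match(sequences, res$sequence), ]
}

# Events for each assigned sequence, unnested. Internal.
assignment_event_table <- function(assignments) {
  asg <- filter(assignments, !is.na(.data$mirna))
  if (nrow(asg) == 0) {
    return(tibble(sequence = character(0), mirna = character(0),
                  type = character(0), position = integer(0),
                  from = character(0), to = character(0), length = integer(0)))
  }
  asg |>
    mutate(events = map2(.data$aligned_read, .data$aligned_ref,
                         alignment_events)) |>
    select("sequence", "mirna", "events") |>
    unnest("events")
}

# Span of reference positions covered by the aligned read (first..last
# reference position opposite a read base). Internal.
aligned_span <- function(aligned_read, aligned_ref) {
  ra <- strsplit(aligned_read, "")[[1]]
  rb <- strsplit(aligned_ref, "")[[1]]
  refpos <- cumsum(rb != "-")
  covered <- refpos[ra != "-" & rb != "-"]
  if (!length(covered)) return(c(NA_integer_, NA_integer_))
  range(covered)
}

#' Ranked isomiR table for one miRNA
#'
#' Lists the distinct tag sequences assigned to one miRNA, ranked by summed
#' TPM over the two libraries, each rendered against the mature reference:
#' end gaps as `-`, substitutions and non-reference (inserted/added/
#' extended) bases in lower case — the layout of the published isoform
#' tables.
#'
#' @param assignments output of [assign_reads()].
#' @param tags collapsed tag counts (columns `sequence`, `count_delay`,
#'   `count_activation`).
#' @param mirna miRNA name to tabulate.
#' @param totals named list/vector with library totals `delay` and
#'   `activation` used for TPM; defaults to the column sums of `tags`.
#' @param n_top number of isoforms to keep (by total TPM).
#' @return tibble with `rank`, `display`, `sequence`, `tpm_delay`,
#'   `tpm_activation`, `count_delay`, `count_activation`; the rendered
#'   reference row is in attribute `reference_display`.
#' @export
isomir_table <- function(assignments, tags, mirna, totals = NULL, n_top = 30) {
  assert_cols(tags, c("sequence", "count_delay", "count_activation"), "tags")
  if (is.null(totals)) {
    totals <- list(delay = sum(tags$count_delay),
                   activation = sum(tags$count_activation))
  }
  asg <- assignments |>
    filter(!is.na(.data$mirna), .data$mirna == .env$mirna) |>
    inner_join(tags, by = "sequence")
  if (nrow(asg) == 0) abort(sprintf("no tags assigned to '%s'", mirna))

  parts <- map2(asg$aligned_read, asg$aligned_ref, function(ar, ab) {
    ra <- strsplit(ar, "")[[1]]
    rb <- strsplit(ab, "")[[1]]
    k <- length(ra)
    lead <- 0L
    while (lead < k && (ra[lead + 1L] == "-" || rb[lead + 1L] == "-")) {
      lead <- lead + 1L
    }
    trail <- 0L
    while (trail < k - lead && (ra[k - trail] == "-" || rb[k - trail] == "-")) {
      trail <- trail + 1L
    }
    internal <- if (lead + trail < k) (lead + 1L):(k - trail) else integer(0)
    chars <- ra
    nonref <- rb == "-"            # insertion/extension/addition bases
    subst <- ra != rb & ra != "-" & rb != "-"
    chars[nonref | subst] <- str_to_lower(chars[nonref | subst])
    list(body = paste(chars, collapse = ""),
         over5 = sum(rb[seq_len(lead)] == "-"),
         over3 = if (trail > 0) sum(rb[(k - trail + 1L):k] == "-") else 0L,
         lead_gap = sum(ra[seq_len(lead)] == "-"),
         trail_gap = if (trail > 0) sum(ra[(k - trail + 1L):k] == "-") else 0L)
  })
  over5 <- map_int(parts, ~ .x$over5)
  over3 <- map_int(parts, ~ .x$over3)
  pad5 <- max(over5)
  pad3 <- max(over3)
  display <- map_chr(parts, function(p) {
    paste0(strrep("-", pad5 - p$over5), p$body, strrep("-", pad3 - p$over3))
  })
  ref_seq <- gsub("-", "", asg$aligned_ref[1])
  ref_display <- paste0(strrep("-", pad5), ref_seq, strrep("-", pad3))

  out <- asg |>
    mutate(
      display = display,
      tpm_delay = tpm(.data$count_delay, totals[["delay"]]),
      tpm_activation = tpm(.data$count_activation, totals[["activation"]])
    ) |>
    arrange(desc(.data$tpm_delay + .data$tpm_activation), .data$sequence) |>
    mutate(rank = row_number()) |>
    slice_head(n = n_top) |>
    select("rank", "display", "sequence", "tpm_delay", "tpm_activation",
           "count_delay", "count_activation")
  attr(out, "reference_display") <- ref_display
  attr(out, "mirna") <- mirna
  out
}

#' Median-centred Z-scores for per-position editing rates
#'
#' Standardises the rates to `z_raw = (rate - mean) / sd` over positions
#' with defined rates, recentres so the median Z across positions is 0,
#' and assigns an upper-tail normal p-value — the null being that all
#' positions share the same background mismatch (sequencing-error) rate.
#' If the rates have zero spread all Z are 0 and nothing is significant.
#'
#' @param rate numeric vector of per-position editing rates (NA allowed for
#'   uncovered positions, which are excluded and returned as NA).
#' @param alpha significance level on the upper-tail p (default 0.01).
#' @return tibble with columns `z`, `p`, `significant` aligned to `rate`.
#' @export
position_zscores <- function(rate, alpha = 0.01) {
  ok <- !is.na(rate)
  if (sum(ok) < 3) abort("need at least 3 positions with defined rates")
  z <- rep(NA_real_, length(rate))
  s <- sd(rate[ok])
  if (is.na(s) || s == 0) {
    z[ok] <- 0
  } else {
    zr <- (rate[ok] - mean(rate[ok])) / s
    z[ok] <- zr - median(zr)
  }
  p <- pnorm(z, lower.tail = FALSE)
  sig <- !is.na(p) & p <= alpha & (!is.na(s) && s > 0)
  tibble(z = z, p = p, significant = sig)
}

#' Per-position editing profile of one miRNA
#'
#' For every position of the mature reference: read-count-weighted coverage
#' (reads whose alignment spans the position), the count of reads carrying
#' a substitution there, the editing rate `edited / coverage`, and the
#' median-centred Z-score test of [position_zscores()]. Indels and end
#' variants are deliberately not counted as editing; only internal
#' substitutions contribute.
#'
#' @inheritParams isomir_table
#' @param library which library's counts weight the profile: `"delay"`,
#'   `"activation"` or `"both"` (sum).
#' @param alpha significance level for [position_zscores()].
#' @return tibble of class `editing_profile` with columns `position`,
#'   `ref_base`, `coverage`, `edited`, `rate`, `z`, `p`, `significant`.
#' @export
editing_profile <- function(assignments, tags, mirna,
                            library = c("both", "delay", "activation"),
                            alpha = 0.01) {
  library <- match.arg(library)
  assert_cols(tags, c("sequence", "count_delay", "count_activation"), "tags")
  asg <- assignments |>
    filter(!is.na(.data$mirna), .data$mirna == .env$mirna) |>
    inner_join(tags, by = "sequence") |>
    mutate(weight = switch(library,
                           both = .data$count_delay + .data$count_activation,
                           delay = .data$count_delay,
                           activation = .data$count_activation))
  if (nrow(asg) == 0) abort(sprintf("no tags assigned to '%s'", mirna))
  ref_seq <- gsub("-", "", asg$aligned_ref[1])
  L <- nchar(ref_seq)
  coverage <- numeric(L)
  edited <- numeric(L)
  for (i in seq_len(nrow(asg))) {
    w <- asg$weight[i]
    if (w == 0) next
    sp <- aligned_span(asg$aligned_read[i], asg$aligned_ref[i])
    if (is.na(sp[1])) next
    coverage[sp[1]:sp[2]] <- coverage[sp[1]:sp[2]] + w
    ev <- alignment_events(asg$aligned_read[i], asg$aligned_ref[i])
    sub_pos <- ev$position[ev$type == "substitution"]
    edited[sub_pos] <- edited[sub_pos] + w
  }
  rate <- ifelse(coverage > 0, edited / coverage, NA_real_)
  zs <- position_zscores(rate, alpha = alpha)
  out <- tibble(position = seq_len(L),
                ref_base = strsplit(ref_seq, "")[[1]],
                coverage = coverage, edited = edited, rate = rate) |>
    dplyr::bind_cols(zs)
  attr(out, "mirna") <- mirna
  attr(out, "library") <- library
  class(out) <- c("editing_profile", class(out))
  out
}

#' Substitution spectrum across all assigned reads
#'
#' Count-weighted percentage of miRNA-assigned reads carrying each of the
#' 12 from-to substitution types, per library. A read with substitutions of
#' two different types contributes to both.
#'
#' @inheritParams isomir_table
#' @return tibble with one row per ordered base pair: `from`, `to`,
#'   `pct_delay`, `pct_activation`.
#' @export
substitution_spectrum <- function(assignments, tags) {
  assert_cols(tags, c("sequence", "count_delay", "count_activation"), "tags")
  asg <- assignments |>
    filter(!is.na(.data$mirna)) |>
    inner_join(tags, by = "sequence")
  tot_delay <- sum(asg$count_delay)
  tot_act <- sum(asg$count_activation)
  ev <- assignment_event_table(assignments) |>
    filter(.data$type == "substitution") |>
    distinct(.data$sequence, .data$from, .data$to) |>
    inner_join(tags, by = "sequence") |>
    group_by(.data$from, .data$to) |>
    summarise(count_delay = sum(.data$count_delay),
              count_activation = sum(.data$count_activation),
              .groups = "drop")
  grid <- tidyr::expand_grid(from = DNA_BASES, to = DNA_BASES) |>
    filter(.data$from != .data$to)
  grid |>
    left_join(ev, by = c("from", "to")) |>
    mutate(
      pct_delay = 100 * replace_na(.data$count_delay, 0) / max(tot_delay, 1),
      pct_activation = 100 * replace_na(.data$count_activation, 0) /
        max(tot_act, 1)
    ) |>
    select("from", "to", "pct_delay", "pct_activation")
}

#' Compare editing in a position set between two conditions
#'
#' Aggregates edited counts and coverage over the stated positions in each
#' profile and applies the pooled two-proportion z-test ([kal_z()]) with a
#' two-sided p-value — e.g. to ask whether seed-region (positions 4-5)
#' editing differs between delay and activation.
#'
#' @param profile_a,profile_b [editing_profile()] results over the same
#'   miRNA (e.g. delay vs activation weighting).
#' @param positions integer vector of 1-based reference positions.
#' @return one-row tibble: `edited_a`, `coverage_a`, `edited_b`,
#'   `coverage_b`, `z`, `p`.
#' @export
compare_region_editing <- function(profile_a, profile_b, positions) {
  pick <- function(p) filter(p, .data$position %in% positions)
  a <- pick(profile_a)
  b <- pick(profile_b)
  ca <- sum(a$coverage)
  cb <- sum(b$coverage)
  if (ca + cb == 0) abort("zero pooled coverage over the requested positions")
  ea <- sum(a$edited)
  eb <- sum(b$edited)
  z <- kal_z(ea, eb, ca, cb)
  tibble(edited_a = ea, coverage_a = ca, edited_b = eb, coverage_b = cb,
         z = z, p = p_two_sided(z))
}
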