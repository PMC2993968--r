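# Global alignment of small-RNA reads against mature miRNA reference
# sequences. Scores: match +1, mismatch -1; gaps are affine with -2 charged
# on the first gap symbol and -1 on each subsequent symbol of the same gap.

#' Alignment scoring parameters
#'
#' @param match,mismatch,gap_open,gap_extend scores; the defaults
#'   (+1, -1, -2, -1) are the scheme used throughout the package. `gap_open`
#'   is the cost of the first symbol of a gap, `gap_extend` of each
#'   subsequent symbol.
#' @return a named list of class `nw_params`.
#' @export
nw_params <- function(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "nw_params")
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' Gotoh three-state dynamic programming with a deterministic traceback.
#' On exact score ties gap states are preferred over the diagonal (tie
#' order: left = reference base against a read gap, then up = read base
#' against a reference gap, then diagonal), which pushes equal-scoring
#' variants to the 3' end of the alignment. End gaps are charged like any
#' other gap, so trimmed or extended read ends are visible as leading or
#' trailing gap runs in the returned aligned strings.
#'
#' @param read,ref DNA strings (non-empty, intended for sequences <= ~40 nt).
#' @param params an [nw_params()] list.
#' @return list with `score` (integer), `aligned_read` and `aligned_ref`
#'   (equal-length strings with `-` gap symbols).
#' @examples
#' nw_align("TGAGGTAGTAGGTTGTATAGTT", "TGAGGTAGTAGGTTGTATAGTT")$score  # 22
#' @export
nw_align <- function(read, ref, params = nw_params()) {
  if (!nzchar(read) || !nzchar(ref)) abort("both sequences must be non-empty")
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  n <- length(a)
  m <- length(b)
  go <- params$gap_open
  ge <- params$gap_extend
  NEG <- -1e9

  # state 1 = M (diagonal), 2 = X (up: read base, gap in ref),
  # 3 = Y (left: ref base, gap in read)
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  if (n > 0) X[2:(n + 1), 1] <- go + ge * (seq_len(n) - 1L)
  if (m > 0) Y[1, 2:(m + 1)] <- go + ge * (seq_len(m) - 1L)

  for (i in seq_len(n)) {
    s_row <- ifelse(a[i] == b, params$match, params$mismatch)
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- s_row[j] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] + go, X[i, j + 1] + ge, Y[i, j + 1] + go)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + go, Y[i + 1, j] + ge, X[i + 1, j] + go)
    }
  }

  # Traceback. On exact score ties gap states are preferred over the
  # diagonal (priority Y > X > M), which places equal-scoring sequence
  # variants at the alignment ends: a 3'-trimmed read ending in the same
  # base as the reference is rendered with a trailing gap (a trim), not an
  # internal deletion, matching isomiR table conventions.
  prio <- c(3L, 2L, 1L)
  pick <- function(scores, target) {
    prio[which(abs(scores[prio] - target) < 1e-9)[1]]
  }
  scores_end <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  score <- max(scores_end)
  state <- pick(scores_end, score)
  ra <- character(0)
  rb <- character(0)
  i <- n
  j <- m
  while (i > 0 || j > 0) {
    if (state == 1L) {
      s <- if (a[i] == b[j]) params$match else params$mismatch
      prev <- c(M[i, j], X[i, j], Y[i, j])
      ra <- c(a[i], ra); rb <- c(b[j], rb)
      state <- pick(prev, M[i + 1, j + 1] - s)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      prev <- c(M[i, j + 1] + go, X[i, j + 1] + ge, Y[i, j + 1] + go)
      ra <- c(a[i], ra); rb <- c("-", rb)
      state <- pick(prev, X[i + 1, j + 1])
      i <- i - 1L
    } else {
      prev <- c(M[i + 1, j] + go, X[i + 1, j] + go, Y[i + 1, j] + ge)
      ra <- c("-", ra); rb <- c(b[j], rb)
      state <- pick(prev, Y[i + 1, j + 1])
      j <- j - 1L
    }
    if (i == 0 && j > 0) state <- 3L
    if (j == 0 && i > 0) state <- 2L
  }
  list(score = score,
       aligned_read = paste(ra, collapse = ""),
       aligned_ref = paste(rb, collapse = ""))
}

#' Event decomposition of a read/reference alignment
#'
#' Splits an alignment into isomiR events. Leading and trailing gap runs are
#' end variants: a gap run in the read is a 5'/3' trim, a gap run in the
#' reference is a 5' extension / 3' addition. Internal events are
#' substitutions (reference base replaced in the read), insertions (read
#' base with no reference base) and deletions. Positions are 1-based on the
#' mature reference; 3' additions are reported at position `L` (the last
#' reference position) with the number of added bases in `length`.
#'
#' @param aligned_read,aligned_ref equal-length gapped strings from
#'   [nw_align()].
#' @return tibble with columns `type` (one of `substitution`, `insertion`,
#'   `deletion`, `trim5`, `trim3`, `ext5`, `add3`), `position` (1-based on
#'   the reference; NA for 5' overhangs), `from`, `to`, `length`.
#' @export
alignment_events <- function(aligned_read, aligned_ref) {
  ra <- strsplit(aligned_read, "")[[1]]
  rb <- strsplit(aligned_ref, "")[[1]]
  if (length(ra) != length(rb)) abort("aligned strings must have equal length")
  k <- length(ra)
  L <- sum(rb != "-")
  refpos <- cumsum(rb != "-")  # 0 before the first reference base

  lead <- 0L
  while (lead < k && (ra[lead + 1L] == "-" || rb[lead + 1L] == "-")) lead <- lead + 1L
  trail <- 0L
  while (trail < k - lead && (ra[k - trail] == "-" || rb[k - trail] == "-")) trail <- trail + 1L

  ev <- list()
  add <- function(type, position, from = NA_character_, to = NA_character_,
                  len = 1L) {
    ev[[length(ev) + 1L]] <<- tibble(type = type, position = as.integer(position),
                                     from = from, to = to, length = as.integer(len))
  }

  if (lead > 0L) {
    lr <- ra[seq_len(lead)]
    lb <- rb[seq_len(lead)]
    if (any(lr == "-")) add("trim5", sum(lr == "-"), len = sum(lr == "-"))
    if (any(lb == "-")) add("ext5", NA_integer_, to = paste(lr[lb == "-"], collapse = ""),
                            len = sum(lb == "-"))
  }
  if (trail > 0L) {
    idx <- (k - trail + 1L):k
    tr <- ra[idx]
    tb <- rb[idx]
    if (any(tr == "-")) add("trim3", L, len = sum(tr == "-"))
    if (any(tb == "-")) add("add3", L, to = paste(tr[tb == "-"], collapse = ""),
                            len = sum(tb == "-"))
  }
  if (lead + trail < k) {
    for (t in (lead + 1L):(k - trail)) {
      if (rb[t] == "-") {
        add("insertion", max(refpos[t], 1L), to = ra[t])
      } else if (ra[t] == "-") {
        add("deletion", refpos[t], from = rb[t])
      } else if (ra[t] != rb[t]) {
        add("substitution", refpos[t], from = rb[t], to = ra[t])
      }
    }
  }
  if (!length(ev)) {
    return(tibble(type = character(0), position = integer(0),
                  from = character(0), to = character(0), length = integer(0)))
  }
  list_rbind(ev)
}
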