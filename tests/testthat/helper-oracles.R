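# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Exhaustive global-alignment score by enumerating every alignment of two
# short strings under match/mismatch and affine gaps (first gap symbol
# `go`, each further symbol of the same gap `ge`). Exponential; only for
# sequences up to ~8 nt.
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, go = -2, ge = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(av)) {
      cost <- if (identical(prev, "X")) ge else go
      best <- max(best, cost + rec(i + 1, j, "X"))
    }
    if (j <= length(bv)) {
      cost <- if (identical(prev, "Y")) ge else go
      best <- max(best, cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "start")
}

# Naive 3'-most DpnII tag: scan every GATC occurrence with regexpr tools.
oracle_dpnii_tag <- function(seq) {
  pos <- gregexpr("GATC", seq, fixed = TRUE)[[1]]
  if (pos[1] == -1) return(NA_character_)
  last <- max(pos)
  start <- last + 4
  if (nchar(seq) - start + 1 < 16) return(NA_character_)
  substr(seq, start, start + 15)
}

# Naive exact genome scan (both strands) for a tag.
oracle_genome_hits <- function(tag, genome) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(tag, "")[[1]]), collapse = ""))
  hits <- list()
  for (chrom in names(genome)) {
    fwd <- gregexpr(tag, genome[[chrom]], fixed = TRUE)[[1]]
    rev_ <- gregexpr(rc, genome[[chrom]], fixed = TRUE)[[1]]
    if (fwd[1] != -1) {
      hits[[length(hits) + 1]] <- data.frame(chrom = chrom, start = fwd - 1,
                                             strand = "+")
    }
    if (rev_[1] != -1) {
      hits[[length(hits) + 1]] <- data.frame(chrom = chrom, start = rev_ - 1,
                                             strand = "-")
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

random_seq <- function(n, len) {
  vapply(rep(len, n), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# Small annotation shared by classification tests: a genome with one
# feature per category plus known miRNAs.
toy_annotation <- function() {
  matures <- c("mmu-let-7a" = "TGAGGTAGTAGGTTGTATAGTT",
               "mmu-miR-21" = "TAGCTTATCAGACTGATGTTGA")
  feats <- c(miRNA = matures[["mmu-let-7a"]],
             miRNA2 = matures[["mmu-miR-21"]],
             piRNA = "ACGTACGTAGCTTGACCTGAAGGTCAAGCT",
             tRNA = "GGGCCCGGGTTTAAACCCGGGAAATTTGGG",
             rRNA = "TTTTCCCCAAAAGGGGTTTTCCCCAAAAGG",
             snRNA = "ATGCATGCATTTGCATGCATGCGGCATGCA",
             snoRNA = "CAGTCAGTCAGGGACTGACTGACCCAGTCA",
             mRNA = "TGGATCCATGGTACGTAGCAATCGATCGGA",
             genomic = "CCTTAAGGCCTTATAGGCCTTAAGGCCTTG")
  spacer <- "TTTTTTTTTT"
  genome <- c(chr1 = paste0(spacer, paste(feats, collapse = spacer), spacer))
  starts <- integer(length(feats))
  off <- nchar(spacer)
  for (i in seq_along(feats)) {
    starts[i] <- off
    off <- off + nchar(feats[i]) + nchar(spacer)
  }
  cats <- c("miRNA", "miRNA", "piRNA", "tRNA", "rRNA", "snRNA", "snoRNA",
            "mRNA")
  intervals <- tibble::tibble(
    chrom = "chr1",
    start = starts[1:8],
    end = starts[1:8] + nchar(feats[1:8]),
    name = names(feats)[1:8],
    category = cats,
    strand = "+"
  )
  category_annotation(genome, intervals, matures)
}
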