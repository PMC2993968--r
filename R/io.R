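# Plain-text I/O: FASTQ/FASTA via Biostrings, count tables as TSV with a
# provenance header.

#' Write collapsed reads as FASTQ
#'
#' Expands (sequence, count) records to one FASTQ entry per read with a
#' constant dummy quality (`I`). Intended for small simulated sets.
#'
#' @param reads tibble with columns `sequence`, `count` (and optionally
#'   `library`, used in read names).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  assert_cols(reads, "sequence", "reads")
  if (!"count" %in% names(reads)) reads$count <- 1L
  lib <- if ("library" %in% names(reads)) reads$library else "lib"
  seqs <- rep(reads$sequence, reads$count)
  libs <- rep(lib, reads$count)
  ids <- sprintf("@%s_read_%06d", libs, seq_along(seqs))
  writeLines(as.vector(rbind(ids, seqs, "+", strrep("I", nchar(seqs)))), path)
  invisible(path)
}

#' Read small-RNA reads from FASTQ or a sequence/count TSV
#'
#' @param path a FASTQ file (`.fastq`/`.fq`) or a TSV with columns
#'   `sequence` and `count` (header required).
#' @param library library label to attach.
#' @return tibble with columns `sequence`, `library`, `count`.
#' @export
read_smallrna_reads <- function(path, library = "delay") {
  if (grepl("\\.(fastq|fq)$", path)) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    tibble(sequence = as.character(x), library = library, count = 1L) |>
      group_by(.data$sequence, .data$library) |>
      summarise(count = sum(.data$count), .groups = "drop")
  } else {
    readr::read_tsv(path, show_col_types = FALSE) |>
      assert_cols(c("sequence", "count"), "reads TSV") |>
      mutate(library = library) |>
      select("sequence", "library", "count")
  }
}

#' Write a FASTA file from a named character vector
#' @param sequences named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Write a result table as TSV with a provenance header
#'
#' Prepends `#`-prefixed lines naming the package version and any
#' parameters, then the tab-separated table with a header row.
#'
#' @param df data frame to write.
#' @param path output file.
#' @param params optional named list of parameters to record.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, params = list()) {
  version <- as.character(utils::packageVersion("delayseq"))
  hdr <- c(sprintf("# delayseq %s", version),
           if (length(params)) {
             sprintf("# %s = %s", names(params),
                     vapply(params, function(x) paste(format(x), collapse = ","),
                            character(1)))
           })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
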