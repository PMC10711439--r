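## File I/O. Sequence formats go through Biostrings; tables are plain TSV
## written with fixed options so that identical inputs yield byte-identical
## files (the determinism contract of the pipeline).

#' Read a FASTA file as a named character vector
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file as a character vector of read sequences
#' @param path file path.
#' @return character vector (qualities are not used by this pipeline).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(x)
}

#' Write reads to FASTQ with constant quality
#'
#' Qualities are written as a constant `I` (Phred 40) since no stage of the
#' pipeline consumes base quality.
#'
#' @param reads character vector of read sequences.
#' @param path file path.
#' @param ids optional read identifiers.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(reads))
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write a data.frame as TSV (deterministic byte layout)
#' @param df data.frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Write curated locus features as GFF3
#'
#' Converts the package's 1-based inclusive intervals to GFF3 records for
#' the element and, when present, TSD copies and TIRs.
#'
#' @param locus_id sequence identifier.
#' @param element_interval 1-based inclusive element interval.
#' @param tsd TSD string or `NULL`.
#' @param tirs result of [detect_tir()] (intervals in element coordinates)
#'   or `NULL`.
#' @param path file path.
#' @export
write_locus_gff3 <- function(locus_id, element_interval, tsd = NULL,
                             tirs = NULL, path) {
  rows <- list(data.frame(seqid = locus_id, source = "fanzortrace",
                          type = "mobile_genetic_element",
                          start = element_interval[1],
                          end = element_interval[2],
                          score = ".", strand = "+", phase = ".",
                          attributes = "ID=element"))
  if (!is.null(tsd) && nchar(tsd) > 0) {
    k <- nchar(tsd)
    rows <- c(rows, list(
      data.frame(seqid = locus_id, source = "fanzortrace",
                 type = "target_site_duplication",
                 start = element_interval[1] - k,
                 end = element_interval[1] - 1L,
                 score = ".", strand = "+", phase = ".",
                 attributes = "ID=tsd_left"),
      data.frame(seqid = locus_id, source = "fanzortrace",
                 type = "target_site_duplication",
                 start = element_interval[2] + 1L,
                 end = element_interval[2] + k,
                 score = ".", strand = "+", phase = ".",
                 attributes = "ID=tsd_right")))
  }
  if (!is.null(tirs)) {
    off <- element_interval[1] - 1L
    rows <- c(rows, list(
      data.frame(seqid = locus_id, source = "fanzortrace",
                 type = "terminal_inverted_repeat",
                 start = tirs$left[1] + off, end = tirs$left[2] + off,
                 score = ".", strand = "+", phase = ".",
                 attributes = "ID=tir_left"),
      data.frame(seqid = locus_id, source = "fanzortrace",
                 type = "terminal_inverted_repeat",
                 start = tirs$right[1] + off, end = tirs$right[2] + off,
                 score = ".", strand = "-", phase = ".",
                 attributes = "ID=tir_right")))
  }
  gff <- do.call(rbind, rows)
  con <- file(path, "w")
  writeLines("##gff-version 3", con)
  write.table(gff, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  invisible(path)
}
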