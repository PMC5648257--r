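#' Read a FASTQ file
#'
#' @param path FASTQ path (plain or gzip).
#' @return data frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL)
}

#' Write sequences to FASTQ
#'
#' @param sequences character vector of sequences.
#' @param path output path.
#' @param ids read identifiers (defaults to `read1..readN`).
#' @param qualities Phred+33 quality strings (defaults to uniform `I`).
#' @return the path, invisibly.
#' @export
write_fastq <- function(sequences, path, ids = NULL, qualities = NULL) {
  n <- length(sequences)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))
  if (is.null(qualities)) qualities <- strrep("I", nchar(sequences))
  s <- Biostrings::DNAStringSet(sequences)
  names(s) <- ids
  Biostrings::writeXStringSet(s, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qualities))
  invisible(path)
}

#' Write a data frame as TSV
#'
#' @param x data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
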