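#' Reference amplicon annotation
#'
#' Describes the PCR amplicon spanning the drive target site: the reference
#' sequence (1-based coordinates), the predicted double-strand-break
#' position (`cut_after`: the break falls between `cut_after` and
#' `cut_after + 1`), the protospacer + PAM interval, and any known flanking
#' SNPs used for haplotype assignment. Because the drive cassette is far
#' longer than the amplicon, the assay only amplifies non-drive alleles;
#' all downstream frequencies are therefore within the non-drive class.
#'
#' @param sequence reference sequence (character, A/C/G/T).
#' @param cut_after 1-based position immediately left of the cut.
#' @param id amplicon identifier.
#' @param target_start,target_end protospacer + PAM interval; defaults to
#'   the 23-nt SpCas9 layout around the cut (cut between protospacer
#'   positions 17 and 18, PAM 3' of the protospacer).
#' @param snps optional data frame with columns `position`, `ref`, `alt`
#'   (known SNPs, anywhere on the amplicon).
#' @return an object of class `gd_amplicon`.
#' @examples
#' amplicon(paste(rep("ACGT", 80), collapse = ""), cut_after = 208)
#' @export
amplicon <- function(sequence, cut_after = 208, id = "amplicon",
                     target_start = cut_after - 16,
                     target_end = cut_after + 6,
                     snps = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("amplicon sequence must contain only A/C/G/T", call. = FALSE)
  }
  len <- nchar(sequence)
  if (cut_after < 1 || cut_after >= len) {
    stop("cut_after must satisfy 1 <= cut_after < length", call. = FALSE)
  }
  if (target_start > cut_after || target_end <= cut_after) {
    stop("target interval must contain the cut site", call. = FALSE)
  }
  target_start <- max(1L, as.integer(target_start))
  target_end <- min(len, as.integer(target_end))
  if (!is.null(snps)) {
    stopifnot(all(c("position", "ref", "alt") %in% names(snps)),
              all(snps$position >= 1), all(snps$position <= len))
    ref_bases <- substring(sequence, snps$position, snps$position)
    if (!all(ref_bases == toupper(snps$ref))) {
      stop("SNP ref bases disagree with the amplicon sequence", call. = FALSE)
    }
  }
  structure(list(id = id, sequence = sequence, length = len,
                 cut_after = as.integer(cut_after),
                 target_start = target_start, target_end = target_end,
                 snps = snps),
            class = "gd_amplicon")
}

#' @export
print.gd_amplicon <- function(x, ...) {
  cat(sprintf("Amplicon '%s': %d bp, cut after position %d, target %d-%d, %d known SNP(s)\n",
              x$id, x$length, x$cut_after, x$target_start, x$target_end,
              if (is.null(x$snps)) 0L else nrow(x$snps)))
  invisible(x)
}

#' Read an amplicon reference from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @param ... passed to [amplicon()] (`cut_after`, `snps`, ...).
#' @return a `gd_amplicon`.
#' @export
read_amplicon_fasta <- function(path, ...) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("empty FASTA: ", path, call. = FALSE)
  amplicon(as.character(seqs[[1]]), id = names(seqs)[1], ...)
}

#' Write an amplicon reference to FASTA
#'
#' @param x a `gd_amplicon`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_amplicon_fasta <- function(x, path) {
  stopifnot(inherits(x, "gd_amplicon"))
  s <- Biostrings::DNAStringSet(x$sequence)
  names(s) <- x$id
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Read a SNP panel (TSV: position, ref, alt)
#'
#' @param path TSV path.
#' @return data frame with columns `position`, `ref`, `alt`.
#' @export
read_snp_panel <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("position", "ref", "alt") %in% names(x)))
  x$position <- as.integer(x$position)
  x
}

#' Read a colony haplotype pool (TSV: haplotype, frequency)
#'
#' The haplotype string is the ordered concatenation of bases at the SNP
#' panel positions.
#'
#' @param path TSV path.
#' @return data frame with columns `haplotype`, `frequency`.
#' @export
read_haplotype_pool <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(haplotype = "character"))
  stopifnot(all(c("haplotype", "frequency") %in% names(x)))
  x
}
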