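#' Global alignment of a merged read against the reference amplicon
#'
#' Needleman-Wunsch global alignment (via [Biostrings::pairwiseAlignment()])
#' with match +2, mismatch -4 and affine gap cost 10 + L (open 10, extend 1
#' per base). This scheme strongly favours one contiguous indel over
#' scattered gaps, matching the single-junction structure of nuclease
#' end-joining products. Equivalent-score indel placements are subsequently
#' left-normalised within repeat runs before labelling (see
#' [call_indels()]), so the traceback convention of the aligner does not
#' affect allele labels. Sequences whose length differs from the reference
#' by more than 50% are rejected as off-target amplification.
#'
#' @param sequence a merged read (character).
#' @param amp a [amplicon()] object.
#' @return an object of class `gd_alignment`: list with gapped strings
#'   `read` and `ref` (equal length) and the alignment `score`.
#' @export
align_to_reference <- function(sequence, amp) {
  stopifnot(inherits(amp, "gd_amplicon"), is.character(sequence),
            length(sequence) == 1L)
  n <- nchar(sequence)
  if (n < 0.5 * amp$length || n > 1.5 * amp$length) {
    stop("sequence length ", n, " outside [0.5, 1.5] x reference length (",
         amp$length, "): likely off-target amplification", call. = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sequence), Biostrings::DNAString(amp$sequence),
    type = "global",
    substitutionMatrix = .nuc_submat(),
    gapOpening = 10, gapExtension = 1)
  structure(list(read = as.character(Biostrings::alignedPattern(aln)),
                 ref = as.character(Biostrings::alignedSubject(aln)),
                 score = Biostrings::score(aln)),
            class = "gd_alignment")
}

.nuc_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                     baseOnly = TRUE)
    }
    m
  }
})

#' @export
print.gd_alignment <- function(x, ...) {
  cat("read: ", x$read, "\nref:  ", x$ref, "\nscore:", x$score, "\n")
  invisible(x)
}

# Decompose an alignment into ops against the ungapped reference.
# Returns list(del = data.frame(start, length, seq),
#              ins = data.frame(after, seq),
#              sub = data.frame(position, base),
#              ref_len)
.alignment_ops <- function(aln) {
  r <- strsplit(aln$read, "", fixed = TRUE)[[1]]
  s <- strsplit(aln$ref, "", fixed = TRUE)[[1]]
  ref_gap <- s == "-"
  read_gap <- r == "-"
  refpos <- cumsum(!ref_gap)           # reference coordinate of each column
  # deletions: runs of read gaps over reference bases
  del <- data.frame(start = integer(0), length = integer(0),
                    seq = character(0))
  dcols <- which(read_gap & !ref_gap)
  if (length(dcols)) {
    runs <- split(dcols, cumsum(c(1L, diff(dcols) != 1L)))
    del <- do.call(rbind, lapply(runs, function(cc) {
      data.frame(start = refpos[cc[1]], length = length(cc),
                 seq = paste(s[cc], collapse = ""))
    }))
  }
  # insertions: runs of reference gaps, anchored after the preceding ref base
  ins <- data.frame(after = integer(0), seq = character(0))
  icols <- which(ref_gap & !read_gap)
  if (length(icols)) {
    runs <- split(icols, cumsum(c(1L, diff(icols) != 1L)))
    ins <- do.call(rbind, lapply(runs, function(cc) {
      data.frame(after = refpos[cc[1]],  # 0 if inserted before position 1
                 seq = paste(r[cc], collapse = ""))
    }))
  }
  m <- !ref_gap & !read_gap & r != s
  sub <- data.frame(position = refpos[m], base = r[m])
  rownames(del) <- rownames(ins) <- rownames(sub) <- NULL
  list(del = del, ins = ins, sub = sub, ref_len = sum(!ref_gap))
}

#' Left-normalise a deletion within repeat runs
#'
#' A deletion of reference positions `start .. start+length-1` is shifted
#' left one base at a time while the base preceding the deletion equals its
#' last deleted base (the edited sequence is unchanged by such shifts); the
#' leftmost placement is the canonical one used in allele labels.
#'
#' @param ref ungapped reference sequence.
#' @param start 1-based start of the deleted reference interval.
#' @param length number of deleted bases.
#' @return list with canonical `start` and deleted `seq`.
#' @export
normalize_deletion <- function(ref, start, length) {
  stopifnot(start >= 1, length >= 1, start + length - 1 <= nchar(ref))
  b <- strsplit(ref, "", fixed = TRUE)[[1]]
  while (start > 1 && b[start - 1] == b[start + length - 1]) {
    start <- start - 1
  }
  list(start = start, seq = paste(b[start:(start + length - 1)],
                                  collapse = ""))
}

#' Left-normalise an insertion within repeat runs
#'
#' An insertion after reference position `after` whose last inserted base
#' equals the reference base at `after` can be shifted one base left by
#' rotating the inserted string; the leftmost placement is canonical.
#'
#' @param ref ungapped reference sequence.
#' @param after 1-based reference position the insertion follows (0 =
#'   before the first base).
#' @param seq inserted bases.
#' @return list with canonical `after` and rotated `seq`.
#' @export
normalize_insertion <- function(ref, after, seq) {
  stopifnot(after >= 0, after <= nchar(ref), nchar(seq) >= 1)
  b <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- nchar(seq)
  while (after >= 1 && b[after] == substring(seq, n, n)) {
    seq <- paste0(substring(seq, n, n), substring(seq, 1, n - 1))
    after <- after - 1
  }
  list(after = after, seq = seq)
}
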