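#' Enumerate microhomology-mediated end-joining deletion candidates
#'
#' MMEJ repairs a double-strand break by annealing two identical sequences
#' of at least 2 bp, one ending at or left of the cut and one beginning at
#' or right of it, deleting the intervening sequence together with one arm
#' copy. For every such arm pair with deletion size at most `max_del` this
#' enumerates the resulting deletion allele; candidates collapsing to the
#' same left-normalised allele are deduplicated, keeping the longest
#' microhomology.
#'
#' @param amp a [amplicon()] object.
#' @param min_mh minimum microhomology length (>= 2).
#' @param max_del maximum deletion size in bp.
#' @return data frame with columns `mh` (microhomology sequence),
#'   `mh_length`, `arm1_start`, `arm2_start`, `del_start`, `del_seq`,
#'   `del_length`, `label` (canonical allele label) and `frame_class`.
#' @examples
#' amp <- amplicon("AAGAGTTTGAGCC", cut_after = 7, target_start = 7, target_end = 8)
#' enumerate_mmej(amp, min_mh = 3)
#' @export
enumerate_mmej <- function(amp, min_mh = 2, max_del = 50) {
  stopifnot(inherits(amp, "gd_amplicon"))
  if (min_mh < 2) stop("min_mh must be >= 2", call. = FALSE)
  ref <- amp$sequence
  len <- amp$length
  cut <- amp$cut_after
  hits <- list()
  kmax <- min(cut, len - cut)
  k <- min_mh
  while (k <= kmax) {
    # left arm [i, i+k-1] with i+k-1 <= cut; right arm [j, j+k-1] with
    # j >= cut+1; deletion size j - i <= max_del; right arm inside sequence
    for (i in seq(max(1L, cut + 1L - max_del + 0L), cut - k + 1L)) {
      arm <- substring(ref, i, i + k - 1)
      j_hi <- min(i + max_del, len - k + 1L)
      j_lo <- cut + 1L
      if (j_lo > j_hi) next
      for (j in j_lo:j_hi) {
        if (substring(ref, j, j + k - 1) == arm) {
          # annealing keeps one arm copy: positions [i+k, j+k-1] are lost
          norm <- normalize_deletion(ref, i + k, j - i)
          hits[[length(hits) + 1L]] <- data.frame(
            mh = arm, mh_length = k, arm1_start = i, arm2_start = j,
            del_start = norm$start, del_seq = norm$seq,
            del_length = j - i,
            label = paste0(norm$start, "-", norm$seq),
            frame_class = if ((j - i) %% 3 == 0) "in-frame" else "frameshift")
        }
      }
    }
    k <- k + 1L
  }
  if (!length(hits)) {
    return(data.frame(mh = character(0), mh_length = integer(0),
                      arm1_start = integer(0), arm2_start = integer(0),
                      del_start = integer(0), del_seq = character(0),
                      del_length = integer(0), label = character(0),
                      frame_class = character(0)))
  }
  out <- do.call(rbind, hits)
  # dedupe by resulting allele, longest microhomology wins
  out <- out[order(out$label, -out$mh_length), , drop = FALSE]
  out <- out[!duplicated(out$label), , drop = FALSE]
  out <- out[order(out$del_start, out$del_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}
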