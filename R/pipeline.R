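#' Merge one read pair into a full amplicon sequence
#'
#' Reverse-complements mate 2 and scans all ungapped overlaps of at least
#' `min_overlap` bases, scoring each candidate overlap as
#' `matches - 4 * mismatches` and requiring a mismatch fraction of at most
#' `max_mismatch_frac`. The best-scoring overlap wins; base disagreements
#' inside the overlap are resolved toward the mate with the higher base
#' quality (ties toward mate 1), and the consensus quality is the higher of
#' the two. Pairs with no acceptable overlap are returned as failures and
#' are excluded (but counted) downstream.
#'
#' @param read1,read2 mate sequences (characters, forward / reverse
#'   orientation as sequenced).
#' @param qual1,qual2 per-base qualities as Phred+33 strings; uniform high
#'   quality is assumed when omitted.
#' @param min_overlap minimum acceptable overlap length.
#' @param max_mismatch_frac maximum fraction of mismatching bases in the
#'   overlap.
#' @return a list with `success`, `sequence`, `quality`, `overlap` and
#'   `mismatches`.
#' @export
merge_read_pair <- function(read1, read2, qual1 = NULL, qual2 = NULL,
                            min_overlap = 20, max_mismatch_frac = 0.1) {
  out <- merge_read_pairs(read1, read2,
                          if (is.null(qual1)) NULL else qual1,
                          if (is.null(qual2)) NULL else qual2,
                          min_overlap = min_overlap,
                          max_mismatch_frac = max_mismatch_frac)
  list(success = out$success[1], sequence = out$sequence[1],
       quality = out$quality[1], overlap = out$overlap[1],
       mismatches = out$mismatches[1])
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "",
                       fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Merge many read pairs (vectorised)
#'
#' Batch version of [merge_read_pair()]. Pairs are grouped by read lengths
#' and all overlap offsets are evaluated with matrix arithmetic, scanning
#' overlaps from longest to shortest and retiring a pair once no remaining
#' overlap can beat its current score.
#'
#' @param reads1,reads2 character vectors of mate sequences.
#' @param quals1,quals2 optional Phred+33 quality strings.
#' @param min_overlap,max_mismatch_frac as in [merge_read_pair()].
#' @return data frame with columns `sequence`, `quality`, `success`,
#'   `overlap`, `mismatches` (one row per input pair; failed merges have
#'   `NA` sequence).
#' @export
merge_read_pairs <- function(reads1, reads2, quals1 = NULL, quals2 = NULL,
                             min_overlap = 20, max_mismatch_frac = 0.1) {
  n <- length(reads1)
  stopifnot(length(reads2) == n, n >= 1, all(nchar(reads1) > 0),
            all(nchar(reads2) > 0))
  if (is.null(quals1)) quals1 <- strrep("I", nchar(reads1))
  if (is.null(quals2)) quals2 <- strrep("I", nchar(reads2))
  stopifnot(length(quals1) == n, length(quals2) == n,
            all(nchar(quals1) == nchar(reads1)),
            all(nchar(quals2) == nchar(reads2)))

  key <- paste(reads1, reads2, quals1, quals2, sep = "\r")
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])
  r1 <- reads1[uniq]; r2 <- reads2[uniq]
  q1 <- quals1[uniq]; q2 <- quals2[uniq]
  m <- length(r1)

  res <- data.frame(sequence = rep(NA_character_, m),
                    quality = NA_character_,
                    success = FALSE, overlap = NA_integer_,
                    mismatches = NA_integer_)
  grp <- paste(nchar(r1), nchar(r2))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    res[idx, ] <- .merge_group(r1[idx], r2[idx], q1[idx], q2[idx],
                               min_overlap, max_mismatch_frac)
  }
  res[map, , drop = FALSE]
}

# all pairs share (n1, n2); raw-matrix overlap scan
.merge_group <- function(r1, r2, q1, q2, min_overlap, max_mismatch_frac) {
  m <- length(r1)
  n1 <- nchar(r1[1])
  n2 <- nchar(r2[1])
  to_mat <- function(x, n) matrix(charToRaw(paste(x, collapse = "")), nrow = n)
  B1 <- to_mat(r1, n1)
  Q1 <- to_mat(q1, n1)
  B2 <- to_mat(.revcomp(r2), n2)
  Q2 <- to_mat(vapply(strsplit(q2, "", fixed = TRUE),
                      function(v) paste(rev(v), collapse = ""),
                      character(1)), n2)
  best_score <- rep(-Inf, m)
  best_L <- rep(NA_integer_, m)
  best_mm <- rep(NA_integer_, m)
  for (L in seq(min(n1, n2), min_overlap)) {
    active <- which(best_score < L)   # L is the max attainable score
    if (!length(active)) break
    i1 <- (n1 - L + 1):n1
    mm <- colSums(B1[i1, active, drop = FALSE] !=
                    B2[seq_len(L), active, drop = FALSE])
    sc <- (L - mm) - 4 * mm
    upd <- (mm / L <= max_mismatch_frac) & sc > best_score[active]
    ii <- active[upd]
    best_score[ii] <- sc[upd]
    best_L[ii] <- L
    best_mm[ii] <- mm[upd]
  }
  out <- data.frame(sequence = rep(NA_character_, m),
                    quality = NA_character_,
                    success = !is.na(best_L), overlap = best_L,
                    mismatches = best_mm)
  for (L in unique(best_L[!is.na(best_L)])) {
    cols <- which(!is.na(best_L) & best_L == L)
    i1 <- (n1 - L + 1):n1
    i2 <- seq_len(L)
    ov <- B2[i2, cols, drop = FALSE]
    qo <- Q2[i2, cols, drop = FALSE]
    take1 <- Q1[i1, cols, drop = FALSE] >= qo
    ov[take1] <- B1[i1, cols, drop = FALSE][take1]
    qhi <- Q1[i1, cols, drop = FALSE] < qo
    qmax <- Q1[i1, cols, drop = FALSE]
    qmax[qhi] <- qo[qhi]
    tail_idx <- if (L < n2) (L + 1):n2 else integer(0)
    M <- rbind(B1[seq_len(n1 - L), cols, drop = FALSE], ov,
               B2[tail_idx, cols, drop = FALSE])
    QM <- rbind(Q1[seq_len(n1 - L), cols, drop = FALSE], qmax,
                Q2[tail_idx, cols, drop = FALSE])
    out$sequence[cols] <- apply(M, 2, rawToChar)
    out$quality[cols] <- apply(QM, 2, rawToChar)
  }
  out
}

#' Collapse identical reads and apply the read-support filter
#'
#' Exact-match collapsing of merged sequences with counts, restricting the
#' analysis set to sequences represented by at least `min_reads` reads
#' (inclusive); both kept and discarded totals are recorded.
#'
#' @param sequences character vector of merged reads, or a data frame with
#'   columns `sequence` and `count` (pre-counted input).
#' @param min_reads minimum read support per unique sequence.
#' @return an object of class `gd_collapsed`: list with `table` (data frame
#'   `sequence`, `count`, most abundant first), `min_reads`,
#'   `n_total_reads`, `n_kept_reads`, `n_discarded_reads`,
#'   `n_kept_sequences`, `n_discarded_sequences`.
#' @export
collapse_reads <- function(sequences, min_reads = 100) {
  if (is.data.frame(sequences)) {
    stopifnot(all(c("sequence", "count") %in% names(sequences)),
              all(sequences$count >= 1))
    agg <- stats::aggregate(count ~ sequence, data = sequences, FUN = sum)
  } else {
    stopifnot(is.character(sequences), length(sequences) >= 1)
    tab <- table(sequences)
    agg <- data.frame(sequence = names(tab), count = as.integer(tab))
  }
  agg <- agg[order(-agg$count, agg$sequence), , drop = FALSE]
  keep <- agg$count >= min_reads
  out <- structure(list(table = `rownames<-`(agg[keep, , drop = FALSE], NULL),
                        min_reads = min_reads,
                        n_total_reads = sum(agg$count),
                        n_kept_reads = sum(agg$count[keep]),
                        n_discarded_reads = sum(agg$count[!keep]),
                        n_kept_sequences = sum(keep),
                        n_discarded_sequences = sum(!keep)),
                   class = "gd_collapsed")
  if (!out$n_kept_sequences) {
    warning("no sequence reaches min_reads = ", min_reads,
            "; analysis set is empty", call. = FALSE)
  }
  out
}

#' @export
print.gd_collapsed <- function(x, ...) {
  cat(sprintf(
    "Collapsed read set: %d unique sequence(s) kept (>= %d reads, %d reads), %d discarded (%d reads)\n",
    x$n_kept_sequences, x$min_reads, x$n_kept_reads,
    x$n_discarded_sequences, x$n_discarded_reads))
  invisible(x)
}

#' Align a collapsed read set to the reference amplicon
#'
#' Runs [align_to_reference()] on every retained unique sequence and
#' projects each alignment onto reference coordinates (per-position base or
#' deletion, insertion anchors). Sequences failing the off-target length
#' guard are set aside with their read counts.
#'
#' @param collapsed a [collapse_reads()] result.
#' @param amp a [amplicon()] object.
#' @return an object of class `gd_aligned_set`: list with `amplicon`,
#'   `table` (`sequence`, `count`), `alignments` (list of `gd_alignment`),
#'   `bases` (reference-length x sequence character matrix; `-` marks a
#'   deleted position), `ins_after` (logical matrix, insertion immediately
#'   after each position) and `rejected` (data frame of off-target
#'   sequences).
#' @export
align_collapsed <- function(collapsed, amp) {
  stopifnot(inherits(collapsed, "gd_collapsed"), inherits(amp, "gd_amplicon"))
  tab <- collapsed$table
  ok <- logical(nrow(tab))
  alns <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    a <- tryCatch(align_to_reference(tab$sequence[i], amp),
                  error = function(e) NULL)
    if (!is.null(a)) {
      ok[i] <- TRUE
      alns[[i]] <- a
    }
  }
  rejected <- tab[!ok, , drop = FALSE]
  tab <- tab[ok, , drop = FALSE]
  alns <- alns[ok]
  L <- amp$length
  bases <- matrix("", nrow = L, ncol = nrow(tab))
  ins_after <- matrix(FALSE, nrow = L, ncol = nrow(tab))
  for (i in seq_along(alns)) {
    r <- strsplit(alns[[i]]$read, "", fixed = TRUE)[[1]]
    s <- strsplit(alns[[i]]$ref, "", fixed = TRUE)[[1]]
    ref_gap <- s == "-"
    refpos <- cumsum(!ref_gap)
    bases[refpos[!ref_gap], i] <- r[!ref_gap]
    anchors <- refpos[ref_gap]
    ins_after[anchors[anchors >= 1L], i] <- TRUE
  }
  structure(list(amplicon = amp,
                 table = `rownames<-`(tab, NULL),
                 alignments = alns,
                 bases = bases, ins_after = ins_after,
                 rejected = `rownames<-`(rejected, NULL)),
            class = "gd_aligned_set")
}

#' @export
print.gd_aligned_set <- function(x, ...) {
  cat(sprintf("Aligned set: %d sequence(s) (%d reads) on amplicon '%s'; %d off-target sequence(s)\n",
              nrow(x$table), sum(x$table$count), x$amplicon$id,
              nrow(x$rejected)))
  invisible(x)
}

#' Call the target-site allele of an alignment
#'
#' Reports the left-normalised indel(s) whose reference footprint lies
#' within `window` bases of the cut site, in the field notation
#' `<start>-<deleted bases>` for deletions and `<position>+<inserted
#' bases>` for insertions (positions refer to the reference amplicon). A
#' gapless (or indel-free within the window) alignment yields `REF`;
#' substitutions never create an indel label. Reads with several indels in
#' the window are labelled `complex` with concatenated labels; those with
#' more than two are excluded from allele tables downstream but remain
#' counted.
#'
#' @param x a `gd_alignment` or a `gd_aligned_set`.
#' @param ... passed between methods.
#' @return a data frame with one row per sequence: `label`, `kind`
#'   (`reference`, `deletion`, `insertion` or `complex`), `start`,
#'   `sequence` (deleted/inserted bases), `net` (net length change),
#'   `frame_class`, `n_indels` (and `count` for a set).
#' @export
call_indels <- function(x, ...) UseMethod("call_indels")

#' @rdname call_indels
#' @param amp a [amplicon()] object.
#' @param window maximum distance (bp) between the cut site and an indel's
#'   reference footprint.
#' @export
call_indels.gd_alignment <- function(x, amp, window = 30, ...) {
  stopifnot(inherits(amp, "gd_amplicon"))
  ops <- .alignment_ops(x)
  if (ops$ref_len != amp$length) {
    stop("alignment does not span the full reference", call. = FALSE)
  }
  .call_from_ops(ops, amp, window)
}

.call_from_ops <- function(ops, amp, window) {
  cut <- amp$cut_after
  ref <- amp$sequence
  lo <- cut - window
  hi <- cut + window
  events <- list()
  if (nrow(ops$del)) {
    for (i in seq_len(nrow(ops$del))) {
      nd <- normalize_deletion(ref, ops$del$start[i], ops$del$length[i])
      if (nd$start <= hi && nd$start + ops$del$length[i] - 1 >= lo) {
        events[[length(events) + 1L]] <- data.frame(
          kind = "deletion", start = nd$start, sequence = nd$seq,
          net = -ops$del$length[i],
          label = paste0(nd$start, "-", nd$seq))
      }
    }
  }
  if (nrow(ops$ins)) {
    for (i in seq_len(nrow(ops$ins))) {
      ni <- normalize_insertion(ref, ops$ins$after[i], ops$ins$seq[i])
      if (ni$after >= lo && ni$after <= hi) {
        events[[length(events) + 1L]] <- data.frame(
          kind = "insertion", start = ni$after, sequence = ni$seq,
          net = nchar(ni$seq),
          label = paste0(ni$after, "+", ni$seq))
      }
    }
  }
  if (!length(events)) {
    return(data.frame(label = "REF", kind = "reference", start = NA_integer_,
                      sequence = NA_character_, net = 0L,
                      frame_class = "reference", n_indels = 0L))
  }
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$start), , drop = FALSE]
  if (nrow(ev) == 1L) {
    return(data.frame(label = ev$label, kind = ev$kind, start = ev$start,
                      sequence = ev$sequence, net = ev$net,
                      frame_class = classify_frame(ev$net),
                      n_indels = 1L))
  }
  net <- sum(ev$net)
  data.frame(label = paste(ev$label, collapse = ";"), kind = "complex",
             start = ev$start[1], sequence = NA_character_, net = net,
             frame_class = classify_frame(net), n_indels = nrow(ev))
}

#' @rdname call_indels
#' @export
call_indels.gd_aligned_set <- function(x, window = 30, ...) {
  rows <- lapply(x$alignments, function(a) {
    .call_from_ops(.alignment_ops(a), x$amplicon, window)
  })
  out <- do.call(rbind, rows)
  out$count <- x$table$count
  rownames(out) <- NULL
  out
}

#' Frame classification of an indel
#'
#' An edited allele is in-frame if and only if its net length change is a
#' multiple of 3; the reference allele has its own class.
#'
#' @param x either a numeric vector of net length changes or a variant data
#'   frame with columns `net` and `kind`.
#' @return character vector: `"in-frame"`, `"frameshift"` or
#'   `"reference"`.
#' @examples
#' classify_frame(c(-6, -4, 3))
#' @export
classify_frame <- function(x) {
  if (is.data.frame(x)) {
    out <- classify_frame(x$net)
    if (!is.null(x$kind)) out[x$kind == "reference"] <- "reference"
    return(out)
  }
  ifelse(x == 0, "reference",
         ifelse(x %% 3 == 0, "in-frame", "frameshift"))
}

#' Allele frequency table with low-frequency grouping
#'
#' Aggregates variant calls by allele label within each sample and converts
#' counts to frequencies among retained (non-drive) reads. Alleles staying
#' below `threshold` in every sample are merged into a single
#' `<threshold` row; reads with more than two indels in the window
#' (`n_indels > 2`) are excluded from the table but reported in the
#' `excluded_complex` attribute.
#'
#' @param variants data frame of calls as from [call_indels()] with a
#'   `count` column and optionally a `sample` column.
#' @param threshold grouping threshold as a proportion (default 0.01).
#' @param group_across_samples if `TRUE` (default) an allele is grouped
#'   only when below `threshold` in all samples; if `FALSE`, grouping is
#'   decided per sample.
#' @return data frame with columns `sample`, `label`, `kind`,
#'   `frame_class`, `count`, `frequency`, sorted by descending frequency
#'   within sample. Frequencies sum to 1 per sample (within 1e-9).
#' @export
allele_frequency_table <- function(variants, threshold = 0.01,
                                   group_across_samples = TRUE) {
  stopifnot(all(c("label", "count") %in% names(variants)),
            all(variants$count >= 0))
  v <- variants
  if (is.null(v$sample)) v$sample <- "sample1"
  excluded <- v[!is.na(v$n_indels) & v$n_indels > 2, , drop = FALSE]
  if (!is.null(v$n_indels)) v <- v[is.na(v$n_indels) | v$n_indels <= 2, ,
                                   drop = FALSE]
  if (!nrow(v) || sum(v$count) == 0) stop("no usable reads", call. = FALSE)
  if (is.null(v$kind)) v$kind <- NA_character_
  if (is.null(v$frame_class)) v$frame_class <- NA_character_

  agg <- stats::aggregate(count ~ sample + label, data = v, FUN = sum)
  meta <- v[!duplicated(v$label), c("label", "kind", "frame_class")]
  agg <- merge(agg, meta, by = "label", sort = FALSE)
  totals <- tapply(agg$count, agg$sample, sum)
  agg$frequency <- agg$count / as.vector(totals[agg$sample])

  maxfreq <- tapply(agg$frequency, agg$label, max)
  if (group_across_samples) {
    low <- names(maxfreq)[maxfreq < threshold]
    grouped <- agg$label %in% low
  } else {
    grouped <- agg$frequency < threshold
  }
  group_label <- sprintf("<%g%%", 100 * threshold)
  out <- agg[!grouped, , drop = FALSE]
  if (any(grouped)) {
    g <- agg[grouped, , drop = FALSE]
    gs <- stats::aggregate(cbind(count, frequency) ~ sample, data = g,
                           FUN = sum)
    gs$label <- group_label
    gs$kind <- "grouped"
    gs$frame_class <- NA_character_
    out <- rbind(out, gs[, names(out)])
  }
  out <- out[order(out$sample, -out$frequency, out$label),
             c("sample", "label", "kind", "frame_class", "count",
               "frequency")]
  rownames(out) <- NULL
  for (s in unique(out$sample)) {
    stopifnot(abs(sum(out$frequency[out$sample == s]) - 1) < 1e-9)
  }
  attr(out, "excluded_complex") <- excluded
  out
}

#' Call single-nucleotide variants from an aligned set
#'
#' Per reference position, read-weighted frequencies of alternative bases
#' among reads covering that position with a base (deleted positions do not
#' contribute). Positions whose most frequent alternative base reaches
#' `min_aaf` (inclusive) are reported.
#'
#' @param aligned a [align_collapsed()] result.
#' @param min_aaf minimum alternative allele frequency (default 0.025).
#' @return data frame with columns `position`, `ref`, `alt`, `frequency`,
#'   `coverage`.
#' @export
call_snvs <- function(aligned, min_aaf = 0.025) {
  stopifnot(inherits(aligned, "gd_aligned_set"))
  if (!nrow(aligned$table)) stop("empty aligned set", call. = FALSE)
  amp <- aligned$amplicon
  refb <- strsplit(amp$sequence, "", fixed = TRUE)[[1]]
  counts <- aligned$table$count
  out <- list()
  nt <- c("A", "C", "G", "T")
  for (pos in seq_len(amp$length)) {
    b <- aligned$bases[pos, ]
    covered <- b %in% nt
    if (!any(covered)) next
    cov <- sum(counts[covered])
    alt_b <- nt[nt != refb[pos]]
    freqs <- vapply(alt_b, function(a) sum(counts[covered & b == a]) / cov,
                    numeric(1))
    top <- which.max(freqs)
    if (freqs[top] >= min_aaf - 1e-12 && freqs[top] > 0) {
      out[[length(out) + 1L]] <- data.frame(position = pos, ref = refb[pos],
                                            alt = alt_b[top],
                                            frequency = freqs[[top]],
                                            coverage = cov)
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), frequency = numeric(0),
                      coverage = numeric(0)))
  }
  `rownames<-`(do.call(rbind, out), NULL)
}

#' Assign flanking-SNP haplotypes to reads carrying a focal allele
#'
#' Every retained read carrying the focal target-site allele is reduced to
#' its base string at the SNP panel positions; distinct strings are counted
#' and, when a colony haplotype pool is supplied, flagged as novel if
#' absent from it. Novel hybrid haplotypes are the signature of embryonic
#' homing (partial conversion of the haplotype around a cleaved wild-type
#' allele toward the haplotype around the resistant template).
#'
#' @param aligned a [align_collapsed()] result.
#' @param focal_label allele label to analyse (must be present).
#' @param snp_table data frame with column `position` (and usually `ref`,
#'   `alt`), as from [read_snp_panel()] or [call_snvs()].
#' @param pool optional colony haplotype pool with column `haplotype`.
#' @param window indel-calling window passed to [call_indels()].
#' @return data frame with columns `variant`, `haplotype`, `count`,
#'   `novel`, sorted by descending count.
#' @export
assign_haplotypes <- function(aligned, focal_label, snp_table, pool = NULL,
                              window = 30) {
  stopifnot(inherits(aligned, "gd_aligned_set"))
  if (!nrow(snp_table)) stop("empty SNP table", call. = FALSE)
  variants <- call_indels(aligned, window = window)
  sel <- which(variants$label == focal_label)
  if (!length(sel)) {
    stop("focal variant '", focal_label, "' not present in the aligned set",
         call. = FALSE)
  }
  pos <- snp_table$position
  strings <- vapply(sel, function(i) {
    paste(aligned$bases[pos, i], collapse = "")
  }, character(1))
  counts <- tapply(variants$count[sel], strings, sum)
  out <- data.frame(variant = focal_label, haplotype = names(counts),
                    count = as.integer(counts))
  out$novel <- if (is.null(pool)) NA else !(out$haplotype %in% pool$haplotype)
  out <- out[order(-out$count, out$haplotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Position-wise mutation profile
#'
#' For each reference position, the read-weighted fraction of retained
#' reads with that position deleted, with an insertion immediately after
#' it, or substituted.
#'
#' @param aligned a [align_collapsed()] result.
#' @return data frame with columns `position`, `del`, `ins`, `sub`.
#' @export
positionwise_profile <- function(aligned) {
  stopifnot(inherits(aligned, "gd_aligned_set"))
  if (!nrow(aligned$table)) stop("empty aligned set", call. = FALSE)
  amp <- aligned$amplicon
  refb <- strsplit(amp$sequence, "", fixed = TRUE)[[1]]
  counts <- aligned$table$count
  total <- sum(counts)
  nt <- c("A", "C", "G", "T")
  del <- as.vector((aligned$bases == "-") %*% counts) / total
  ins <- as.vector(aligned$ins_after %*% counts) / total
  subm <- (aligned$bases != "-") &
    (aligned$bases != matrix(refb, nrow = amp$length,
                             ncol = length(counts))) &
    matrix(aligned$bases %in% nt, nrow = amp$length)
  sub <- as.vector(subm %*% counts) / total
  data.frame(position = seq_len(amp$length), del = del, ins = ins, sub = sub)
}

#' Run the full amplicon analysis pipeline
#'
#' Convenience wrapper: merge read pairs (unless merged reads are given),
#' collapse and filter, align, call target-site alleles, build the
#' frequency table, call SNVs, assign haplotypes of the most abundant
#' edited allele, and compute the position-wise profile.
#'
#' @param amp a [amplicon()] object.
#' @param reads1,reads2 paired mate sequences (character vectors), or
#' @param merged already-merged sequences (overrides the pair input).
#' @param quals1,quals2 optional Phred+33 qualities for the pairs.
#' @param snp_table optional SNP panel; when absent, SNVs called de novo at
#'   `min_aaf` define the haplotype positions.
#' @param pool optional colony haplotype pool (column `haplotype`).
#' @param min_reads,min_aaf,threshold,window,min_overlap pipeline
#'   thresholds (read-support filter, SNV frequency cutoff, allele grouping
#'   threshold, indel window, merge overlap).
#' @return an object of class `gd_pipeline_result`: list with `alleles`,
#'   `snvs`, `haplotypes`, `profile`, `aligned`, and a `log` list of
#'   filtering counts.
#' @export
run_amplicon_pipeline <- function(amp, reads1 = NULL, reads2 = NULL,
                                  merged = NULL, quals1 = NULL,
                                  quals2 = NULL, snp_table = NULL,
                                  pool = NULL, min_reads = 100,
                                  min_aaf = 0.025, threshold = 0.01,
                                  window = 30, min_overlap = 20) {
  log <- list()
  if (is.null(merged)) {
    if (is.null(reads1) || is.null(reads2)) {
      stop("supply either merged reads or both mates", call. = FALSE)
    }
    mg <- merge_read_pairs(reads1, reads2, quals1, quals2,
                           min_overlap = min_overlap)
    log$n_pairs <- length(reads1)
    log$n_merge_failures <- sum(!mg$success)
    merged <- mg$sequence[mg$success]
  }
  log$n_merged_reads <- length(merged)
  collapsed <- collapse_reads(merged, min_reads = min_reads)
  log$n_kept_reads <- collapsed$n_kept_reads
  log$n_discarded_reads <- collapsed$n_discarded_reads
  log$n_kept_sequences <- collapsed$n_kept_sequences
  aligned <- align_collapsed(collapsed, amp)
  log$n_off_target_sequences <- nrow(aligned$rejected)
  variants <- call_indels(aligned, window = window)
  alleles <- allele_frequency_table(variants, threshold = threshold)
  log$n_excluded_complex <- nrow(attr(alleles, "excluded_complex"))
  snvs <- call_snvs(aligned, min_aaf = min_aaf)
  if (is.null(snp_table)) snp_table <- snvs
  haplotypes <- NULL
  edited <- alleles[!(alleles$label %in% c("REF")) &
                      alleles$kind != "grouped", , drop = FALSE]
  if (nrow(edited) && nrow(snp_table)) {
    haplotypes <- assign_haplotypes(aligned, edited$label[1], snp_table,
                                    pool = pool, window = window)
  }
  structure(list(alleles = alleles, snvs = snvs, haplotypes = haplotypes,
                 profile = positionwise_profile(aligned),
                 aligned = aligned, log = log),
            class = "gd_pipeline_result")
}

#' @export
print.gd_pipeline_result <- function(x, ...) {
  cat("Amplicon pipeline result\n")
  cat(sprintf("  %d allele row(s), %d SNV(s)\n", nrow(x$alleles),
              nrow(x$snvs)))
  print(utils::head(x$alleles, 10))
  invisible(x)
}
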