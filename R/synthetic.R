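#' Configuration for the synthetic cage-experiment generator
#'
#' Describes a synthetic pooled-amplicon sequencing experiment with known
#' truth: a random reference amplicon with a planted protospacer/PAM and a
#' microhomology pair flanking the cut, a colony haplotype pool over
#' flanking SNPs, a resistance-allele spectrum (MMEJ-derived deletions
#' mixed with random indels), drive/resistance dynamics from the
#' deterministic model, and error-bearing 2 x `read_length` paired-end
#' reads sampled multinomially (the non-saturating-PCR proportionality
#' assumption). Defaults emulate the study design: a 320-bp amplicon cut
#' after position 208, 50,000 reads per sampled generation, 2 x 250 bp
#' reads, substitution error rate 0.001, 12 pool haplotypes, and samples at
#' generations 2 and 12.
#'
#' @param seed integer seed; mandatory, drives every random choice.
#' @param amplicon_length reference length in bp (>= 50).
#' @param cut_after cut position (break after this base).
#' @param n_snps number of flanking SNPs.
#' @param n_haplotypes number of distinct colony haplotypes.
#' @param n_random_indels number of non-MMEJ indel alleles in the spectrum.
#' @param n_mmej_alleles number of MMEJ deletion candidates retained in the
#'   spectrum (the longest-microhomology candidates are kept).
#' @param w_mmej weight of MMEJ-derived deletions in the spectrum, `[0,1]`.
#' @param indel_mean_length mean of the geometric random-indel length.
#' @param reads_per_sample read pairs per sampled generation.
#' @param error_rate per-base substitution error probability.
#' @param read_length paired-end read length.
#' @param params a [model_params()] object for the trajectory.
#' @param generations generations at which pooled samples are sequenced.
#' @param het_fraction initial `W/H` fraction (see
#'   [initial_release_state()]).
#' @param focal_haplotype_count if set, the highest-weight in-frame allele
#'   is planted on exactly this many pool haplotypes (others are random).
#' @param plant_chimeras plant novel hybrid (chimeric) haplotypes on the
#'   focal allele — the positive control for the embryonic-homing novelty
#'   test.
#' @param chimera_fraction fraction of focal-allele reads made chimeric.
#' @return an object of class `gd_generator_config`.
#' @export
generator_config <- function(seed,
                             amplicon_length = 320,
                             cut_after = 208,
                             n_snps = 8,
                             n_haplotypes = 12,
                             n_random_indels = 10,
                             n_mmej_alleles = 6,
                             w_mmej = 0.5,
                             indel_mean_length = 8,
                             reads_per_sample = 50000,
                             error_rate = 0.001,
                             read_length = 250,
                             params = model_params(),
                             generations = c(2, 12),
                             het_fraction = 0.5,
                             focal_haplotype_count = NULL,
                             plant_chimeras = FALSE,
                             chimera_fraction = 0.01) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("an integer seed is mandatory", call. = FALSE)
  }
  if (amplicon_length < 50) {
    stop("amplicon_length below 50 bp is degenerate", call. = FALSE)
  }
  stopifnot(cut_after >= 20, cut_after <= amplicon_length - 15,
            n_snps >= 1, n_haplotypes >= 1, n_random_indels >= 0,
            n_mmej_alleles >= 0,
            w_mmej >= 0, w_mmej <= 1, indel_mean_length >= 1,
            reads_per_sample > 0, error_rate >= 0, error_rate <= 1,
            read_length >= 30, inherits(params, "gd_params"),
            all(generations >= 0), het_fraction >= 0, het_fraction <= 1,
            chimera_fraction >= 0, chimera_fraction <= 1)
  structure(list(seed = as.integer(seed),
                 amplicon_length = as.integer(amplicon_length),
                 cut_after = as.integer(cut_after),
                 n_snps = as.integer(n_snps),
                 n_haplotypes = as.integer(n_haplotypes),
                 n_random_indels = as.integer(n_random_indels),
                 n_mmej_alleles = as.integer(n_mmej_alleles),
                 w_mmej = w_mmej,
                 indel_mean_length = indel_mean_length,
                 reads_per_sample = as.integer(reads_per_sample),
                 error_rate = error_rate,
                 read_length = as.integer(read_length),
                 params = params,
                 generations = as.integer(sort(unique(generations))),
                 het_fraction = het_fraction,
                 focal_haplotype_count = focal_haplotype_count,
                 plant_chimeras = isTRUE(plant_chimeras),
                 chimera_fraction = chimera_fraction),
            class = "gd_generator_config")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference amplicon
#'
#' Random sequence of the configured length with a planted SpCas9-style
#' protospacer + NGG PAM around the cut (break between protospacer
#' positions 17 and 18) and a planted 3-bp microhomology pair flanking the
#' cut, guaranteeing that [enumerate_mmej()] is non-vacuous on every
#' generated reference. Deterministic under the config seed.
#'
#' @param config a [generator_config()].
#' @return a [amplicon()] object.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "gd_generator_config"))
  set.seed(config$seed)
  len <- config$amplicon_length
  cut <- config$cut_after
  b <- strsplit(.random_dna(len), "", fixed = TRUE)[[1]]
  b[cut + 5L] <- "G"          # NGG PAM 3' of the protospacer
  b[cut + 6L] <- "G"
  # plant a 3-bp microhomology: arm ending at the cut repeated after it,
  # giving a 9-bp (in-frame) MMEJ deletion candidate
  b[(cut + 7L):(cut + 9L)] <- b[(cut - 2L):cut]
  amp <- amplicon(paste(b, collapse = ""), cut_after = cut,
                  id = sprintf("synthetic_amplicon_seed%d", config$seed))
  stopifnot(nrow(enumerate_mmej(amp, min_mh = 2)) >= 1)
  amp
}

#' Generate a colony haplotype pool
#'
#' Chooses `n_snps` SNP positions outside the indel window around the cut,
#' assigns alternative bases, and draws `n_haplotypes` distinct SNP strings
#' (the first is the all-reference haplotype) with Dirichlet-distributed
#' frequencies.
#'
#' @param amp a [amplicon()] object.
#' @param config a [generator_config()].
#' @return list with `snp_table` (data frame `position`, `ref`, `alt`) and
#'   `haplotypes` (data frame `haplotype`, `frequency`).
#' @export
generate_haplotype_pool <- function(amp, config) {
  stopifnot(inherits(amp, "gd_amplicon"),
            inherits(config, "gd_generator_config"))
  set.seed(config$seed + 1L)
  len <- amp$length
  cut <- amp$cut_after
  margin <- 45L   # keep SNPs clear of the indel-reporting window
  candidates <- setdiff(5:(len - 5), (cut - margin):(cut + margin))
  if (length(candidates) < config$n_snps) {
    stop("amplicon too short for the requested SNP panel", call. = FALSE)
  }
  pos <- sort(sample(candidates, config$n_snps))
  refb <- strsplit(amp$sequence, "", fixed = TRUE)[[1]][pos]
  altb <- vapply(refb, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                          1), character(1), USE.NAMES = FALSE)
  snp_table <- data.frame(position = pos, ref = refb, alt = altb)
  n_h <- config$n_haplotypes
  strings <- paste(refb, collapse = "")   # all-reference background first
  tries <- 0L
  while (length(strings) < n_h) {
    flip <- stats::runif(config$n_snps) < 0.5
    s <- paste(ifelse(flip, altb, refb), collapse = "")
    strings <- unique(c(strings, s))
    tries <- tries + 1L
    if (tries > 1000L * n_h) {
      stop("cannot draw ", n_h, " distinct haplotypes over ",
           config$n_snps, " SNP(s)", call. = FALSE)
    }
  }
  freqs <- stats::rgamma(n_h, shape = 2)
  freqs <- freqs / sum(freqs)
  list(snp_table = snp_table,
       haplotypes = data.frame(haplotype = strings, frequency = freqs))
}

#' Sample the resistance-allele spectrum
#'
#' Builds the set of concrete end-joining alleles segregating in the
#' synthetic cage: MMEJ deletion candidates from [enumerate_mmej()]
#' (weighted toward longer microhomologies) carrying total weight `w_mmej`,
#' plus `n_random_indels` random indels at the cut (deletion or insertion,
#' geometric lengths) carrying the rest. Each allele is tagged `R1` if
#' in-frame, else `R2`, matching the model's functional split.
#'
#' @param amp a [amplicon()] object.
#' @param config a [generator_config()].
#' @return data frame with columns `label`, `kind`, `start`, `sequence`,
#'   `net`, `frame_class`, `class` (`R1`/`R2`), `weight`, `is_mmej`.
#' @export
sample_resistance_spectrum <- function(amp, config) {
  stopifnot(inherits(amp, "gd_amplicon"),
            inherits(config, "gd_generator_config"))
  set.seed(config$seed + 2L)
  cut <- amp$cut_after
  parts <- list()
  # deletions are kept within the +/-30 bp reporting window of the assay
  mmej <- enumerate_mmej(amp, min_mh = 2, max_del = 30)
  if (nrow(mmej) > config$n_mmej_alleles) {
    keep <- order(-mmej$mh_length, mmej$del_length)[seq_len(config$n_mmej_alleles)]
    mmej <- mmej[keep, , drop = FALSE]
  }
  w_mmej <- if (nrow(mmej)) config$w_mmej else 0
  if (nrow(mmej) && w_mmej > 0) {
    w <- 2^mmej$mh_length
    parts$mmej <- data.frame(label = mmej$label, kind = "deletion",
                             start = mmej$del_start,
                             sequence = mmej$del_seq,
                             net = -mmej$del_length,
                             frame_class = mmej$frame_class,
                             weight = w_mmej * w / sum(w),
                             is_mmej = TRUE)
  }
  n_r <- config$n_random_indels
  if (n_r > 0 && w_mmej < 1) {
    rows <- vector("list", n_r)
    for (i in seq_len(n_r)) {
      len <- min(1L + stats::rgeom(1, 1 / config$indel_mean_length), 30L)
      if (stats::runif(1) < 0.5) {  # deletion spanning/touching the cut
        start <- cut + 1L - sample.int(len, 1L)
        start <- max(1L, min(start, amp$length - len + 1L))
        nd <- normalize_deletion(amp$sequence, start, len)
        rows[[i]] <- data.frame(label = paste0(nd$start, "-", nd$seq),
                                kind = "deletion", start = nd$start,
                                sequence = nd$seq, net = -len,
                                frame_class = classify_frame(-len),
                                weight = NA_real_, is_mmej = FALSE)
      } else {                      # insertion at the cut
        ins <- .random_dna(len)
        ni <- normalize_insertion(amp$sequence, cut, ins)
        rows[[i]] <- data.frame(label = paste0(ni$after, "+", ni$seq),
                                kind = "insertion", start = ni$after,
                                sequence = ni$seq, net = len,
                                frame_class = classify_frame(len),
                                weight = NA_real_, is_mmej = FALSE)
      }
    }
    rnd <- do.call(rbind, rows)
    rnd <- rnd[!duplicated(rnd$label), , drop = FALSE]
    w <- stats::rgamma(nrow(rnd), shape = 1)
    rnd$weight <- (1 - w_mmej) * w / sum(w)
    parts$random <- rnd
  }
  out <- do.call(rbind, parts)
  if (is.null(out) || !nrow(out)) {
    stop("empty resistance spectrum: enable MMEJ weight or random indels",
         call. = FALSE)
  }
  out <- out[!duplicated(out$label), , drop = FALSE]  # MMEJ labels win
  out$weight <- out$weight / sum(out$weight)
  out$class <- ifelse(out$frame_class == "in-frame", "R1", "R2")
  rownames(out) <- NULL
  out
}

# apply one indel to the reference sequence
.apply_variant <- function(ref, kind, start, seq) {
  if (kind == "deletion") {
    paste0(substring(ref, 1, start - 1),
           substring(ref, start + nchar(seq), nchar(ref)))
  } else if (kind == "insertion") {
    paste0(substring(ref, 1, start), seq,
           substring(ref, start + 1, nchar(ref)))
  } else {
    ref
  }
}

# substitute SNP alternative bases for a haplotype string
.apply_haplotype <- function(ref, snp_table, haplotype) {
  b <- strsplit(ref, "", fixed = TRUE)[[1]]
  h <- strsplit(haplotype, "", fixed = TRUE)[[1]]
  b[snp_table$position] <- h
  paste(b, collapse = "")
}

# vectorised substitution errors at a fixed per-base rate
.add_substitution_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  nc <- nchar(reads)
  total <- sum(nc)
  n_err <- stats::rbinom(1, total, rate)
  if (n_err == 0) return(reads)
  at <- sort(sample.int(total, n_err))
  ends <- cumsum(nc)
  read_idx <- findInterval(at - 1L, ends) + 1L
  pos <- at - c(0L, ends)[read_idx]
  for (k in seq_len(n_err)) {
    i <- read_idx[k]
    p <- pos[k]
    old <- substring(reads[i], p, p)
    substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  reads
}

#' Generate a full synthetic cage dataset with known truth
#'
#' Runs the deterministic drive model, and for each sampled generation
#' draws `reads_per_sample` read pairs multinomially over (allele,
#' haplotype) classes: the wild-type allele in proportion `nondrive_W` over
#' pool haplotypes, and the concrete `R1`/`R2` indel alleles of the
#' spectrum in proportions `nondrive_R1`/`nondrive_R2` over per-allele
#' haplotype backgrounds. Paired 2 x `read_length` reads with i.i.d.
#' substitution errors are emitted together with complete truth tables.
#' Drive (`H`) alleles are never emitted: the assay only amplifies
#' non-drive alleles.
#'
#' @param config a [generator_config()].
#' @param outdir optional directory; when given, per-generation FASTQ
#'   mates, truth TSVs, the amplicon FASTA, the SNP panel and the haplotype
#'   pool are written there.
#' @return an object of class `gd_synthetic_dataset`: list with `amplicon`,
#'   `snp_table`, `pool`, `spectrum`, `trajectory` (summary data frame),
#'   `samples` (per sampled generation: `reads1`, `reads2`,
#'   `truth_alleles`, `truth_haplotypes`, `provenance`), `extinct` and
#'   `config`.
#' @examples
#' \donttest{
#' ds <- generate_cage_dataset(generator_config(seed = 1,
#'                                              reads_per_sample = 2000))
#' ds$samples[[1]]$truth_alleles
#' }
#' @export
generate_cage_dataset <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "gd_generator_config"))
  amp <- generate_reference(config)
  pool <- generate_haplotype_pool(amp, config)
  spectrum <- sample_resistance_spectrum(amp, config)
  amp$snps <- pool$snp_table

  traj <- simulate_drive(config$params,
                         initial = initial_release_state(config$het_fraction),
                         n_generations = max(config$generations))
  summ <- summarize_trajectory(traj)
  available <- summ$generation
  sampled <- intersect(config$generations, available)
  partial <- traj$extinct && length(sampled) < length(config$generations)
  if (!length(sampled)) {
    warning("population extinct before the first sampled generation;",
            " emitting truth tables only", call. = FALSE)
  }

  set.seed(config$seed + 3L)
  # fixed per-allele haplotype backgrounds, shared across generations
  n_h <- config$n_haplotypes
  focal <- NULL
  inframe <- which(spectrum$class == "R1")
  if (length(inframe)) focal <- inframe[which.max(spectrum$weight[inframe])]
  allele_haps <- lapply(seq_len(nrow(spectrum)), function(i) {
    if (!is.null(config$focal_haplotype_count) && !is.null(focal) &&
        i == focal) {
      # the focal allele recurs on the commonest backgrounds: plant it on
      # the k most frequent pool haplotypes
      k <- min(config$focal_haplotype_count, n_h)
      idx <- order(-pool$haplotypes$frequency)[seq_len(k)]
    } else {
      k <- sample.int(3L, 1L)  # most indels arise on one or a few backgrounds
      idx <- sample.int(n_h, min(k, n_h), prob = pool$haplotypes$frequency)
    }
    w <- pool$haplotypes$frequency[idx]
    data.frame(hap = idx, w = w / sum(w))
  })

  chimera_string <- NULL
  if (config$plant_chimeras && !is.null(focal)) {
    hs <- pool$haplotypes$haplotype
    half <- ceiling(config$n_snps / 2)
    for (a in seq_along(hs)) {
      for (b in seq_along(hs)) {
        if (a == b) next
        cand <- paste0(substring(hs[a], 1, half),
                       substring(hs[b], half + 1, config$n_snps))
        if (!(cand %in% hs)) {
          chimera_string <- cand
          break
        }
      }
      if (!is.null(chimera_string)) break
    }
    if (is.null(chimera_string)) {
      stop("could not construct a chimeric haplotype absent from the pool",
           call. = FALSE)
    }
  }

  samples <- list()
  for (g in sampled) {
    row <- summ[summ$generation == g, ]
    class_freq <- c(W = row$nondrive_W, R1 = row$nondrive_R1,
                    R2 = row$nondrive_R2)
    if (anyNA(class_freq)) {
      warning("no non-drive alleles left at generation ", g, "; skipped",
              call. = FALSE)
      next
    }
    # allele-level truth
    truth <- rbind(
      data.frame(label = "REF", class = "W", frequency = class_freq[["W"]],
                 stringsAsFactors = FALSE),
      do.call(rbind, lapply(c("R1", "R2"), function(cl) {
        idx <- which(spectrum$class == cl)
        if (!length(idx)) return(NULL)
        w <- spectrum$weight[idx] / sum(spectrum$weight[idx])
        data.frame(label = spectrum$label[idx], class = cl,
                   frequency = class_freq[[cl]] * w)
      })))
    truth <- truth[truth$frequency > 0, , drop = FALSE]
    truth$frequency <- truth$frequency / sum(truth$frequency)

    # (allele, haplotype) classes
    cls <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      lab <- truth$label[i]
      if (lab == "REF") {
        data.frame(label = lab, hap = seq_len(n_h),
                   p = truth$frequency[i] * pool$haplotypes$frequency)
      } else {
        ah <- allele_haps[[which(spectrum$label == lab)]]
        data.frame(label = lab, hap = ah$hap, p = truth$frequency[i] * ah$w)
      }
    }))
    cls$haplotype <- pool$haplotypes$haplotype[cls$hap]
    if (!is.null(chimera_string)) {
      fl <- spectrum$label[focal]
      take <- cls$label == fl
      moved <- sum(cls$p[take]) * config$chimera_fraction
      cls$p[take] <- cls$p[take] * (1 - config$chimera_fraction)
      cls <- rbind(cls, data.frame(label = fl, hap = NA_integer_,
                                   p = moved, haplotype = chimera_string))
    }
    counts <- as.vector(stats::rmultinom(1, config$reads_per_sample, cls$p))

    # class template sequences and reads
    templates <- vapply(seq_len(nrow(cls)), function(i) {
      s <- .apply_haplotype(amp$sequence, pool$snp_table, cls$haplotype[i])
      if (cls$label[i] == "REF") return(s)
      sp <- spectrum[spectrum$label == cls$label[i], ]
      .apply_variant(s, sp$kind, sp$start, sp$sequence)
    }, character(1))
    rl <- config$read_length
    r1_tpl <- substring(templates, 1, pmin(rl, nchar(templates)))
    r2_tpl <- .revcomp(substring(templates,
                                 pmax(1, nchar(templates) - rl + 1),
                                 nchar(templates)))
    reads1 <- rep(r1_tpl, counts)
    reads2 <- rep(r2_tpl, counts)
    provenance <- data.frame(read = seq_along(reads1),
                             generation = g,
                             allele = rep(cls$label, counts),
                             haplotype = rep(cls$haplotype, counts))
    reads1 <- .add_substitution_errors(reads1, config$error_rate)
    reads2 <- .add_substitution_errors(reads2, config$error_rate)

    hap_truth <- cls
    hap_truth$count <- counts
    hap_truth$novel <- !(hap_truth$haplotype %in% pool$haplotypes$haplotype)
    samples[[as.character(g)]] <- list(
      generation = g,
      reads1 = reads1, reads2 = reads2,
      truth_alleles = `rownames<-`(truth, NULL),
      truth_haplotypes = hap_truth[, c("label", "haplotype", "p", "count",
                                       "novel")],
      provenance = provenance)
  }

  out <- structure(list(amplicon = amp, snp_table = pool$snp_table,
                        pool = pool$haplotypes, spectrum = spectrum,
                        trajectory = summ, samples = samples,
                        extinct = traj$extinct, partial = partial,
                        config = config),
                   class = "gd_synthetic_dataset")
  if (!is.null(outdir)) .write_dataset(out, outdir)
  out
}

.write_dataset <- function(ds, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_amplicon_fasta(ds$amplicon, file.path(outdir, "amplicon.fasta"))
  write_tsv(ds$snp_table, file.path(outdir, "snp_panel.tsv"))
  write_tsv(ds$pool, file.path(outdir, "haplotype_pool.tsv"))
  write_tsv(ds$spectrum, file.path(outdir, "spectrum.tsv"))
  write_tsv(ds$trajectory, file.path(outdir, "trajectory.tsv"))
  for (s in ds$samples) {
    tag <- sprintf("g%d", s$generation)
    ids <- sprintf("%s_read%06d", tag, seq_along(s$reads1))
    write_fastq(s$reads1, file.path(outdir, paste0(tag, "_R1.fastq")),
                ids = ids)
    write_fastq(s$reads2, file.path(outdir, paste0(tag, "_R2.fastq")),
                ids = ids)
    write_tsv(s$truth_alleles,
              file.path(outdir, paste0(tag, "_truth_alleles.tsv")))
    write_tsv(s$truth_haplotypes,
              file.path(outdir, paste0(tag, "_truth_haplotypes.tsv")))
    write_tsv(s$provenance,
              file.path(outdir, paste0(tag, "_provenance.tsv")))
  }
  invisible(outdir)
}

#' @export
print.gd_synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic cage dataset (seed %d): %d sampled generation(s), %d spectrum allele(s), %d haplotype(s)\n",
    x$config$seed, length(x$samples), nrow(x$spectrum), nrow(x$pool)))
  invisible(x)
}
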