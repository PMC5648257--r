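#' Allele and genotype bookkeeping
#'
#' The model tracks four alleles at the drive target locus: `W` (wild type,
#' cleavable), `H` (the homing drive construct), `R1` (cleavage-resistant,
#' in-frame and functional) and `R2` (cleavage-resistant, frameshift and
#' non-functional). Diploid genotypes are unordered allele pairs; the
#' canonical ordering is `W < H < R1 < R2` with the lower allele written
#' first, giving the fixed 10-genotype index used by every frequency vector
#' in the package.
#'
#' @return `gd_alleles()` returns the four allele symbols; `gd_genotypes()`
#'   the ten canonical genotype labels (e.g. `"W/H"`, `"R1/R2"`).
#' @examples
#' gd_genotypes()
#' @export
gd_alleles <- function() c("W", "H", "R1", "R2")

#' @rdname gd_alleles
#' @export
gd_genotypes <- function() {
  a <- gd_alleles()
  out <- character(0)
  for (i in 1:4) for (j in i:4) out <- c(out, paste(a[i], a[j], sep = "/"))
  out
}

# 10x2 matrix of allele indices (lower first) for the canonical genotypes
.geno_pairs <- local({
  m <- matrix(0L, 10, 2)
  k <- 0L
  for (i in 1:4) for (j in i:4) {
    k <- k + 1L
    m[k, ] <- c(i, j)
  }
  m
})

# 4x4 lookup: unordered pair of allele indices -> genotype index
.pair_index <- local({
  m <- matrix(0L, 4, 4)
  for (k in 1:10) {
    p <- .geno_pairs[k, ]
    m[p[1], p[2]] <- k
    m[p[2], p[1]] <- k
  }
  m
})

# logical: genotype carries at least one drive allele
.carries_drive <- apply(.geno_pairs, 1, function(p) any(p == 2L))

#' Canonicalise a genotype label
#'
#' Accepts an unordered pair such as `"H/W"` or `"R2/R1"` and returns the
#' canonical label (`"W/H"`, `"R1/R2"`). Invalid allele symbols are an error.
#'
#' @param genotype a genotype string, two allele symbols separated by `/`.
#' @return the canonical genotype label.
#' @export
canonical_genotype <- function(genotype) {
  stopifnot(is.character(genotype), length(genotype) == 1L)
  parts <- strsplit(genotype, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !all(parts %in% gd_alleles())) {
    stop("invalid genotype: ", genotype, call. = FALSE)
  }
  idx <- sort(match(parts, gd_alleles()))
  paste(gd_alleles()[idx], collapse = "/")
}

# allele indices (sorted) of a genotype label, with validation
.genotype_indices <- function(genotype) {
  g <- canonical_genotype(genotype)
  sort(match(strsplit(g, "/", fixed = TRUE)[[1]], gd_alleles()))
}

#' Allele frequencies of a genotype-frequency vector
#'
#' @param freqs numeric vector of length 10 over the canonical genotypes.
#' @return named numeric vector of the four allele frequencies.
#' @export
allele_frequencies <- function(freqs) {
  stopifnot(length(freqs) == 10L)
  af <- numeric(4)
  for (k in 1:10) {
    p <- .geno_pairs[k, ]
    af[p[1]] <- af[p[1]] + freqs[k] / 2
    af[p[2]] <- af[p[2]] + freqs[k] / 2
  }
  names(af) <- gd_alleles()
  af
}
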