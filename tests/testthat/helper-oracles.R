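# Independent oracles used by the test suite. These deliberately do not
# reuse the package's transition machinery: the Monte-Carlo oracle samples
# individuals, the alignment oracle is a plain Gotoh DP, and the MMEJ
# oracle is a brute-force substring search with its own normalisation.

# ---- individual-based Monte-Carlo oracle for one model generation ----
# state: list(female, male) of length-10 genotype frequency vectors
# (canonical order W/W, W/H, W/R1, W/R2, H/H, H/R1, H/R2, R1/R1, R1/R2,
# R2/R2); params: list with e, gamma_m, gamma_e, beta, xi_m, xi_e, d.
# Returns the offspring genotype proportions from N simulated individuals.
mc_next_generation <- function(female, male, params, N = 1e6) {
  pairs <- rbind(c(1, 1), c(1, 2), c(1, 3), c(1, 4), c(2, 2), c(2, 3),
                 c(2, 4), c(3, 3), c(3, 4), c(4, 4))
  pair_idx <- matrix(0L, 4, 4)
  for (k in 1:10) {
    pair_idx[pairs[k, 1], pairs[k, 2]] <- k
    pair_idx[pairs[k, 2], pairs[k, 1]] <- k
  }
  # female fecundity: sterile H/H, H/R2, R2/R2; W/H reduced by d
  fec <- c(1, 1 - params$d, 1, 1, 0, 1, 0, 1, 1, 0)
  wf <- female * fec
  stopifnot(sum(wf) > 0)
  mothers <- sample.int(10, N, replace = TRUE, prob = wf)
  fathers <- sample.int(10, N, replace = TRUE, prob = male)
  gametes <- function(parent) {
    out <- integer(N)
    for (k in 1:10) {
      idx <- which(parent == k)
      if (!length(idx)) next
      if (k == 2L) {  # W/H: distorted segregation
        pr <- c((1 - params$e - params$gamma_m) / 2, (1 + params$e) / 2,
                params$xi_m * params$gamma_m / 2,
                (1 - params$xi_m) * params$gamma_m / 2)
        out[idx] <- sample.int(4, length(idx), replace = TRUE, prob = pr)
      } else {
        pick <- stats::runif(length(idx)) < 0.5
        out[idx] <- ifelse(pick, pairs[k, 1], pairs[k, 2])
      }
    }
    out
  }
  a1 <- gametes(mothers)
  a2 <- gametes(fathers)
  # embryonic modification in offspring of drive-carrying mothers
  exposed <- mothers %in% c(2L, 5L, 6L, 7L)
  modify <- function(a, homolog) {
    w <- which(exposed & a == 1L)
    if (!length(w)) return(a)
    u <- stats::runif(length(w))
    ge <- params$gamma_e
    be <- params$beta
    a[w] <- ifelse(u < params$xi_e * ge, 3L,
            ifelse(u < ge, 4L,
            ifelse(u < ge + be, homolog[w], 1L)))
    a
  }
  b1 <- modify(a1, a2)
  b2 <- modify(a2, a1)
  tabulate(pair_idx[cbind(b1, b2)], nbins = 10) / N
}

# ---- Gotoh affine-gap global alignment score (score only) ----
# gap of length L costs open + L * ext, matching the package's scheme
nw_score_oracle <- function(a, b, match = 2, mismatch = -4,
                            open = 10, ext = 1) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x)
  m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in y (vertical)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in x (horizontal)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 1) * ext
  for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 1) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# ---- brute-force MMEJ enumeration with independent normalisation ----
# returns the sorted set of canonical deletion labels
brute_mmej_labels <- function(ref, cut, min_mh, max_del) {
  n <- nchar(ref)
  del_string <- function(s, L) {
    paste0(substring(ref, 1, s - 1), substring(ref, s + L, n))
  }
  labels <- character(0)
  for (k in min_mh:max(min_mh, min(cut, n - cut))) {
    if (cut - k + 1 < 1 || cut + 1 > n - k + 1) next
    for (i in 1:(cut - k + 1)) {
      for (j in (cut + 1):(n - k + 1)) {
        if (j <= i || j - i > max_del) next
        if (substring(ref, i, i + k - 1) != substring(ref, j, j + k - 1)) next
        L <- j - i
        result <- del_string(i + k, L)
        # canonical label: leftmost deletion placement giving this result
        for (s in 1:(n - L + 1)) {
          if (del_string(s, L) == result) {
            labels <- c(labels, paste0(s, "-", substring(ref, s, s + L - 1)))
            break
          }
        }
      }
    }
  }
  sort(unique(labels))
}

# ---- sequence surgery used by construction oracles ----
delete_span <- function(s, from, to) {
  paste0(substring(s, 1, from - 1), substring(s, to + 1, nchar(s)))
}
insert_after <- function(s, pos, ins) {
  paste0(substring(s, 1, pos), ins, substring(s, pos + 1, nchar(s)))
}
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# paired reads from a template, as the sequencer would emit them
template_to_pair <- function(template, read_length = 250) {
  n <- nchar(template)
  r1 <- substring(template, 1, min(read_length, n))
  r2 <- substring(template, max(1, n - read_length + 1), n)
  r2 <- paste(rev(strsplit(chartr("ACGT", "TGCA", r2), "",
                           fixed = TRUE)[[1]]), collapse = "")
  list(r1 = r1, r2 = r2)
}

# random valid model parameter set for property tests
random_params <- function() {
  e <- stats::runif(1, 0, 0.99)
  model_params(e = e,
               gamma_m = stats::runif(1, 0, 1 - e),
               gamma_e = stats::runif(1, 0, 0.95),
               beta = 0,
               xi_m = stats::runif(1),
               xi_e = stats::runif(1),
               d = stats::runif(1))
}

random_state <- function() {
  f <- stats::rgamma(10, 1)
  m <- stats::rgamma(10, 1)
  population_state(f / sum(f), m / sum(m))
}
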