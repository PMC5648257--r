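#' Gamete distribution of a genotype under meiotic drive
#'
#' Alleles segregate Mendelian in every genotype except `W/H`, where the
#' germline nuclease distorts segregation: a fraction `e` of `W` alleles is
#' converted to `H` by homing and a fraction `gamma_m` to resistant alleles
#' by end-joining (split `xi_m : 1 - xi_m` between `R1` and `R2`), so that
#' \deqn{P(H) = (1+e)/2,\quad P(W) = (1-e-\gamma_m)/2,\quad
#'       P(R1) = \xi_m\gamma_m/2,\quad P(R2) = (1-\xi_m)\gamma_m/2.}
#'
#' @param genotype genotype label, e.g. `"W/H"` (order irrelevant).
#' @param params a [model_params()] object.
#' @return named probability vector over the four alleles, summing to 1.
#' @examples
#' gamete_distribution("W/H", model_params())  # P(H) = 0.992 at baseline
#' @export
gamete_distribution <- function(genotype, params) {
  stopifnot(inherits(params, "gd_params"))
  idx <- .genotype_indices(genotype)
  g <- numeric(4)
  names(g) <- gd_alleles()
  if (idx[1] == 1L && idx[2] == 2L) { # W/H: distorted segregation
    g["H"] <- (1 + params$e) / 2
    g["W"] <- (1 - params$e - params$gamma_m) / 2
    g["R1"] <- params$xi_m * params$gamma_m / 2
    g["R2"] <- (1 - params$xi_m) * params$gamma_m / 2
  } else {
    g[idx[1]] <- g[idx[1]] + 0.5
    g[idx[2]] <- g[idx[2]] + 0.5
  }
  g
}

# 10x4 gamete matrix, row = parental genotype
.gamete_matrix <- function(params) {
  t(vapply(gd_genotypes(), gamete_distribution, numeric(4), params = params))
}

#' Zygote modification by maternally deposited nuclease
#'
#' Eggs laid by drive-carrying mothers contain the nuclease regardless of
#' the egg's own genotype, so each `W` allele of the zygote is independently
#' cleaved and repaired: it becomes `R1` with probability `xi_e * gamma_e`,
#' `R2` with `(1 - xi_e) * gamma_e`, a copy of the homologous allele with
#' `beta` (embryonic homology-directed repair), and stays `W` otherwise.
#' `H`, `R1` and `R2` alleles are never modified. Offspring of drive-free
#' mothers are returned unchanged.
#'
#' @param zygote genotype label of the zygote at fertilisation.
#' @param mother_carries_drive logical: did the mother carry at least one
#'   `H` allele?
#' @param params a [model_params()] object.
#' @return named probability vector over the 10 genotypes, summing to 1.
#' @examples
#' embryo_modification("W/H", TRUE, model_params(gamma_e = 0.796, xi_e = 1/3))
#' @export
embryo_modification <- function(zygote, mother_carries_drive, params) {
  stopifnot(inherits(params, "gd_params"), is.logical(mother_carries_drive))
  idx <- .genotype_indices(zygote)
  out <- numeric(10)
  names(out) <- gd_genotypes()
  if (!mother_carries_drive) {
    out[.pair_index[idx[1], idx[2]]] <- 1
    return(out)
  }
  # per-allele fates: list of (allele index, probability)
  fates <- function(a, homolog) {
    if (a != 1L) return(list(c(a, 1)))
    list(c(3L, params$xi_e * params$gamma_e),
         c(4L, (1 - params$xi_e) * params$gamma_e),
         c(homolog, params$beta),
         c(1L, 1 - params$gamma_e - params$beta))
  }
  f1 <- fates(idx[1], idx[2])
  f2 <- fates(idx[2], idx[1])
  for (x in f1) {
    for (y in f2) {
      p <- x[2] * y[2]
      if (p > 0) {
        k <- .pair_index[x[1], y[1]]
        out[k] <- out[k] + p
      }
    }
  }
  out
}

# 10x10 embryo-modification transition matrix (rows: zygote, cols: outcome)
.embryo_matrix <- function(params) {
  t(vapply(gd_genotypes(), embryo_modification, numeric(10),
           mother_carries_drive = TRUE, params = params))
}

#' Relative female fecundity by genotype
#'
#' The drive disrupts a haplosufficient gene required for female fertility:
#' `H/H`, `H/R2` and `R2/R2` females are sterile (no functional copy),
#' `W/H` females have fecundity `1 - d` through leaky somatic nuclease
#' expression, and every genotype with an unencumbered functional allele
#' (`W` or `R1` paired with anything but the drive, plus `H/R1`) is fully
#' fertile. Males are unaffected.
#'
#' @param genotype genotype label.
#' @param params a [model_params()] object (only `d` is used).
#' @return relative fecundity in `[0, 1]`.
#' @export
female_fecundity <- function(genotype, params) {
  stopifnot(inherits(params, "gd_params"))
  g <- canonical_genotype(genotype)
  if (g %in% c("H/H", "H/R2", "R2/R2")) return(0)
  if (g == "W/H") return(1 - params$d)
  1
}

.fecundity_vector <- function(params) {
  vapply(gd_genotypes(), female_fecundity, numeric(1), params = params)
}

#' Construct a population state
#'
#' A state holds sex-specific genotype-frequency vectors over the 10
#' canonical genotypes. Frequencies must be non-negative and sum to 1 per
#' sex (they are renormalised if within `1e-9` of 1, rejected otherwise).
#'
#' @param female,male numeric vectors of length 10 (named vectors are
#'   matched to [gd_genotypes()]; unnamed vectors are taken in canonical
#'   order). `male` defaults to `female`.
#' @param generation non-negative integer generation index.
#' @return an object of class `gd_state`.
#' @examples
#' # the cage starting condition: 1:1 W/H heterozygotes and wild type
#' population_state(c("W/W" = 0.5, "W/H" = 0.5))
#' @export
population_state <- function(female, male = female, generation = 0L) {
  fix <- function(v, what) {
    if (!is.null(names(v))) {
      bad <- setdiff(names(v), gd_genotypes())
      if (length(bad)) stop("unknown genotype(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
      full <- numeric(10)
      names(full) <- gd_genotypes()
      full[names(v)] <- v
      v <- full
    }
    if (length(v) != 10L) stop(what, " must have length 10", call. = FALSE)
    if (any(v < 0)) stop(what, " frequencies must be non-negative", call. = FALSE)
    if (abs(sum(v) - 1) > 1e-9) stop(what, " frequencies must sum to 1",
                                     call. = FALSE)
    v <- v / sum(v)
    names(v) <- gd_genotypes()
    v
  }
  stopifnot(generation >= 0)
  structure(list(generation = as.integer(generation),
                 female = fix(female, "female"),
                 male = fix(male, "male")),
            class = "gd_state")
}

#' Initial state with a given heterozygote release fraction
#'
#' @param het_fraction fraction of `W/H` heterozygotes in both sexes at
#'   generation 0; the remainder is wild type `W/W`. Default 0.5, the caged
#'   1:1 heterozygote : wild-type release.
#' @return a `gd_state` at generation 0.
#' @export
initial_release_state <- function(het_fraction = 0.5) {
  stopifnot(het_fraction >= 0, het_fraction <= 1)
  v <- c("W/W" = 1 - het_fraction, "W/H" = het_fraction)
  population_state(v)
}

#' @export
print.gd_state <- function(x, ...) {
  cat(sprintf("Population state, generation %d\n", x$generation))
  m <- rbind(female = x$female, male = x$male)
  print(round(m[, colSums(m) > 0, drop = FALSE], 6))
  invisible(x)
}

.extinction_condition <- function() {
  structure(class = c("gd_extinction", "error", "condition"),
            list(message = paste("total female reproductive output is zero;",
                                 "the population is extinct"),
                 call = NULL))
}

#' Advance the population by one generation
#'
#' Mothers are drawn proportional to female genotype frequency times
#' [female_fecundity()], fathers proportional to male frequency. Offspring
#' zygotes are formed from the parental [gamete_distribution()]s, then
#' zygotes whose mother carried the drive pass through
#' [embryo_modification()]. The same offspring distribution is assigned to
#' both sexes (a 1:1 sex ratio with sex-independent viability).
#'
#' @param state a `gd_state`.
#' @param params a [model_params()] object.
#' @return the next `gd_state`. If every female genotype with non-zero
#'   frequency is sterile, a classed error condition `gd_extinction` is
#'   signalled instead of silently producing `NaN`.
#' @export
next_generation <- function(state, params) {
  stopifnot(inherits(state, "gd_state"), inherits(params, "gd_params"))
  eng <- .model_engine(params)
  out <- .step(state$female, state$male, eng)
  population_state(out, out, generation = state$generation + 1L)
}

# precomputed matrices for one parameter set
.model_engine <- function(params) {
  list(G = .gamete_matrix(params),
       E = .embryo_matrix(params),
       fec = .fecundity_vector(params))
}

# one recursion step on raw vectors; signals gd_extinction on zero output
.step <- function(female, male, eng) {
  wf <- female * eng$fec
  total <- sum(wf)
  if (total <= 0) stop(.extinction_condition())
  wf <- wf / total
  gm_h <- colSums(eng$G * (wf * .carries_drive))   # gametes from drive mothers
  gm_0 <- colSums(eng$G * (wf * !.carries_drive))
  gp <- colSums(eng$G * male)
  zygotes <- function(gm) {
    z <- numeric(10)
    for (i in 1:4) {
      for (j in 1:4) {
        k <- .pair_index[i, j]
        z[k] <- z[k] + gm[i] * gp[j]
      }
    }
    z
  }
  off <- as.vector(zygotes(gm_h) %*% eng$E) + zygotes(gm_0)
  off <- off / sum(off)
  names(off) <- gd_genotypes()
  off
}

#' Simulate the deterministic recursion
#'
#' Iterates [next_generation()] for `n_generations` steps from `initial`.
#' If all remaining fertile females are lost along the way the trajectory is
#' truncated at the last computable state and flagged `extinct`.
#'
#' @param params a [model_params()] object.
#' @param initial a `gd_state`; defaults to [initial_release_state()].
#' @param n_generations number of generations to iterate (>= 0).
#' @return an object of class `gd_trajectory`: a list with elements
#'   `states` (list of `gd_state`), `params`, and `extinct` (logical).
#' @examples
#' traj <- simulate_drive(model_params(), n_generations = 25)
#' head(summarize_trajectory(traj))
#' @export
simulate_drive <- function(params, initial = initial_release_state(),
                           n_generations = 25) {
  stopifnot(inherits(params, "gd_params"), inherits(initial, "gd_state"),
            n_generations >= 0)
  eng <- .model_engine(params)
  states <- vector("list", n_generations + 1)
  states[[1]] <- initial
  extinct <- FALSE
  fv <- initial$female
  mv <- initial$male
  if (n_generations > 0) {
    for (t in seq_len(n_generations)) {
      off <- tryCatch(.step(fv, mv, eng), gd_extinction = function(e) NULL)
      if (is.null(off)) {
        extinct <- TRUE
        states <- states[seq_len(t)]
        break
      }
      fv <- off
      mv <- off
      states[[t + 1]] <- population_state(fv, mv,
                                          generation = initial$generation + t)
    }
  }
  structure(list(states = states, params = params, extinct = extinct),
            class = "gd_trajectory")
}

#' Per-generation summaries of a trajectory
#'
#' @param trajectory a `gd_trajectory`.
#' @return a data frame with one row per generation: `generation`,
#'   `drive_carrier_fraction` (proportion of individuals carrying at least
#'   one `H` allele, sexes averaged), the four allele frequencies
#'   `freq_W`/`freq_H`/`freq_R1`/`freq_R2`, and the composition of non-drive
#'   alleles `nondrive_W`/`nondrive_R1`/`nondrive_R2` (fractions of all
#'   non-`H` alleles; `NA` when no non-drive allele remains).
#' @export
summarize_trajectory <- function(trajectory) {
  stopifnot(inherits(trajectory, "gd_trajectory"),
            length(trajectory$states) >= 1)
  rows <- lapply(trajectory$states, function(s) {
    carrier <- (sum(s$female[.carries_drive]) + sum(s$male[.carries_drive])) / 2
    af <- (allele_frequencies(s$female) + allele_frequencies(s$male)) / 2
    nd <- af[c("W", "R1", "R2")]
    nd_total <- sum(nd)
    nd <- if (nd_total > 0) nd / nd_total else rep(NA_real_, 3)
    data.frame(generation = s$generation,
               drive_carrier_fraction = carrier,
               freq_W = af[["W"]], freq_H = af[["H"]],
               freq_R1 = af[["R1"]], freq_R2 = af[["R2"]],
               nondrive_W = nd[[1]], nondrive_R1 = nd[[2]],
               nondrive_R2 = nd[[3]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.gd_trajectory <- function(x, ...) {
  cat(sprintf("Gene-drive trajectory: %d generation(s)%s\n",
              length(x$states) - 1,
              if (x$extinct) " [truncated: population extinct]" else ""))
  s <- summarize_trajectory(x)
  print(utils::head(round(s, 4), 8))
  if (nrow(s) > 8) cat("...", nrow(s) - 8, "more generation(s)\n")
  invisible(x)
}

#' Write a trajectory summary as TSV
#'
#' Columns are the [summarize_trajectory()] columns, numeric values with six
#' decimal places.
#'
#' @param trajectory a `gd_trajectory`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  s <- summarize_trajectory(trajectory)
  num <- vapply(s, is.numeric, logical(1)) & names(s) != "generation"
  s[num] <- lapply(s[num], function(v) sprintf("%.6f", v))
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
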