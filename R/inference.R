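#' Homing rate from a transmission proportion
#'
#' A heterozygous parent transmits the drive to a fraction `(1 + e) / 2` of
#' offspring, so an observed transmission `t` implies `e = 2 t - 1`.
#' Transmission below the Mendelian 0.5 (drive-negative distortion) is
#' outside the model and rejected.
#'
#' @param transmission proportion of marker-positive offspring, in
#'   `[0.5, 1]`.
#' @return the implied homing rate `e` in `[0, 1]`.
#' @examples
#' estimate_homing(0.975)  # 0.95
#' @export
estimate_homing <- function(transmission) {
  stopifnot(is.numeric(transmission), length(transmission) == 1L)
  if (is.na(transmission) || transmission < 0.5 || transmission > 1) {
    stop("transmission must lie in [0.5, 1]", call. = FALSE)
  }
  2 * transmission - 1
}

#' Embryonic end-joining rate from maternal- vs paternal-origin transmission
#'
#' Sons receiving the drive from their mother are exposed to maternally
#' deposited nuclease as embryos: a fraction `gamma_e` of their wild-type
#' target alleles is converted to cleavage-resistant alleles before germline
#' homing can act, diluting the transmission distortion they show as
#' parents. Comparing the apparent homing in such sons against the
#' embryo-free homing of grandsons carrying a paternal drive copy gives
#' \deqn{\hat\gamma_e = 1 - \frac{2 t_{maternal} - 1}{2 t_{paternal} - 1},}
#' the fraction of cleavable alleles lost to embryonic end-joining.
#'
#' @param transmission_maternal transmission proportion measured in
#'   maternal-origin drive carriers, in `(0.5, 1]`.
#' @param transmission_paternal transmission proportion in paternal-origin
#'   carriers (no embryonic exposure), in `(0.5, 1]` and larger than the
#'   maternal value.
#' @return the estimated embryonic end-joining rate `gamma_e`.
#' @examples
#' estimate_embryonic_ej(0.596, 0.975)  # ~0.798
#' @export
estimate_embryonic_ej <- function(transmission_maternal,
                                  transmission_paternal) {
  for (v in c(transmission_maternal, transmission_paternal)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v > 1) {
      stop("transmission proportions must be single values <= 1", call. = FALSE)
    }
  }
  if (transmission_paternal <= 0.5) {
    stop("paternal-origin transmission <= 0.5 carries no homing signal",
         call. = FALSE)
  }
  if (transmission_maternal <= 0.5) {
    stop("maternal-origin transmission <= 0.5 is outside the model",
         call. = FALSE)
  }
  if (transmission_paternal < transmission_maternal) {
    stop("expected transmission_paternal >= transmission_maternal",
         call. = FALSE)
  }
  1 - (2 * transmission_maternal - 1) / (2 * transmission_paternal - 1)
}

#' Read a transmission-count table
#'
#' TSV with columns `lineage`, `origin` (`maternal` or `paternal`),
#' `n_positive`, `n_total`.
#'
#' @param path path to the TSV file.
#' @return a validated data frame.
#' @export
read_transmission_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lineage", "origin", "n_positive", "n_total")
  if (!all(need %in% names(x))) {
    stop("transmission table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(x$origin %in% c("maternal", "paternal")),
            all(x$n_total > 0), all(x$n_positive >= 0),
            all(x$n_positive <= x$n_total))
  x
}

#' Rate estimates from pooled transmission counts
#'
#' Pools counts across lineages within each parental origin (the pooled
#' totals, not the per-lineage means, are the canonical estimator input),
#' then applies [estimate_homing()] to the paternal-origin rate and
#' [estimate_embryonic_ej()] to the pair.
#'
#' @param transmission a data frame as returned by [read_transmission_tsv()].
#' @return a list with `transmission_maternal`, `transmission_paternal`,
#'   `e_hat` and `gamma_e_hat`.
#' @export
estimate_rates <- function(transmission) {
  pooled <- function(origin) {
    sub <- transmission[transmission$origin == origin, , drop = FALSE]
    if (!nrow(sub)) stop("no ", origin, "-origin records", call. = FALSE)
    sum(sub$n_positive) / sum(sub$n_total)
  }
  tm <- pooled("maternal")
  tp <- pooled("paternal")
  list(transmission_maternal = tm,
       transmission_paternal = tp,
       e_hat = estimate_homing(tp),
       gamma_e_hat = estimate_embryonic_ej(tm, tp))
}

#' Read observed cage trajectories
#'
#' TSV with columns `generation`, `drive_carrier_fraction` and optionally
#' `cage`; generations must be strictly increasing within a cage.
#'
#' @param path path to the TSV file.
#' @return a validated data frame (with a `cage` column, single cage
#'   `"cage1"` if absent in the file).
#' @export
read_observed_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("generation", "drive_carrier_fraction")
  if (!all(need %in% names(x))) {
    stop("observed table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(x$cage)) x$cage <- "cage1"
  for (cg in unique(x$cage)) {
    g <- x$generation[x$cage == cg]
    if (any(diff(g) <= 0)) {
      stop("generations must be strictly increasing within cage ", cg,
           call. = FALSE)
    }
  }
  stopifnot(all(x$drive_carrier_fraction >= 0),
            all(x$drive_carrier_fraction <= 1))
  x
}

#' Least-squares fit of the fertility-cost dominance
#'
#' Holds every parameter except the dominance `d` fixed, simulates the
#' deterministic recursion for each grid value of `d`, and minimises the
#' unweighted sum of squared differences between observed and predicted
#' drive-carrier fractions at the observed generations (cages are fitted
#' jointly against the one deterministic trajectory). Ties are broken
#' toward smaller `d`; a minimum on the grid boundary is flagged as poorly
#' identified.
#'
#' @param observed data frame with columns `generation`,
#'   `drive_carrier_fraction` and optionally `cage` (see
#'   [read_observed_tsv()]); at least two observed generations.
#' @param params a [model_params()] object supplying all fixed parameters
#'   (its `d` is ignored).
#' @param grid increasing vector of candidate `d` values in `[0, 1]`.
#' @param initial initial `gd_state` for the simulations.
#' @return an object of class `gd_dominance_fit`: list with `d_hat`,
#'   `sse_profile` (data frame `d`, `sse`), `poorly_identified`, and
#'   `n_obs`.
#' @examples
#' obs <- summarize_trajectory(simulate_drive(model_params(d = 0.7), n_generations = 20))
#' fit <- fit_dominance(obs, model_params())
#' fit$d_hat
#' @export
fit_dominance <- function(observed, params = model_params(),
                          grid = seq(0, 1, by = 0.005),
                          initial = initial_release_state()) {
  stopifnot(inherits(params, "gd_params"))
  if (!length(grid)) stop("empty dominance grid", call. = FALSE)
  if (any(grid < 0) || any(grid > 1) || is.unsorted(grid)) {
    stop("grid must be increasing within [0, 1]", call. = FALSE)
  }
  need <- c("generation", "drive_carrier_fraction")
  if (!all(need %in% names(observed))) {
    stop("observed needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(observed$generation)) < 2) {
    stop("need observations at >= 2 generations", call. = FALSE)
  }
  horizon <- max(observed$generation)
  if (any(observed$generation < initial$generation)) {
    stop("observations precede the initial state", call. = FALSE)
  }
  sse <- vapply(grid, function(d) {
    p <- model_params(e = params$e, gamma_m = params$gamma_m,
                      gamma_e = params$gamma_e, beta = params$beta,
                      xi_m = params$xi_m, xi_e = params$xi_e, d = d)
    tr <- simulate_drive(p, initial = initial,
                         n_generations = horizon - initial$generation)
    s <- summarize_trajectory(tr)
    pred <- s$drive_carrier_fraction[match(observed$generation, s$generation)]
    if (anyNA(pred)) return(Inf)  # extinct before an observed generation
    sum((observed$drive_carrier_fraction - pred)^2)
  }, numeric(1))
  best <- which.min(sse)  # first minimum = smallest d on ties
  structure(list(d_hat = grid[best],
                 sse_profile = data.frame(d = grid, sse = sse),
                 poorly_identified = best == 1L || best == length(grid),
                 n_obs = nrow(observed)),
            class = "gd_dominance_fit")
}

#' @export
print.gd_dominance_fit <- function(x, ...) {
  cat(sprintf("Dominance fit: d_hat = %g (SSE = %.6g, n = %d)%s\n",
              x$d_hat, min(x$sse_profile$sse), x$n_obs,
              if (x$poorly_identified) " [boundary minimum: poorly identified]"
              else ""))
  invisible(x)
}

#' Clutch-size and hatching-rate summaries
#'
#' Arithmetic mean and sample standard deviation of per-female egg counts
#' and hatch proportions. Records from unmated females are expected to be
#' excluded upstream. With a single record the standard deviations are
#' reported as `NA`.
#'
#' @param clutches data frame with columns `eggs` (count per clutch) and
#'   `hatch` (hatching proportion in `[0, 1]`).
#' @return data frame with rows `clutch_size` and `hatch_rate` and columns
#'   `mean`, `sd`, `n`.
#' @examples
#' fecundity_summary(data.frame(eggs = c(100, 140), hatch = c(0.8, 0.7)))
#' @export
fecundity_summary <- function(clutches) {
  if (!nrow(clutches)) stop("no clutch records", call. = FALSE)
  stopifnot(all(c("eggs", "hatch") %in% names(clutches)),
            all(clutches$eggs >= 0),
            all(clutches$hatch >= 0), all(clutches$hatch <= 1))
  summ <- function(v) c(mean = mean(v),
                        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                        n = length(v))
  out <- rbind(clutch_size = summ(clutches$eggs),
               hatch_rate = summ(clutches$hatch))
  as.data.frame(out)
}
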