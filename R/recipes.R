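#' Run a named analysis recipe
#'
#' Recipes wire the package modules into the headline computations, each
#' producing a machine-readable JSON report (plus a one-line human summary
#' on standard error). Every report embeds the recipe name, package
#' version, seed and parameters.
#'
#' Available recipes:
#' \describe{
#'   \item{`baseline-trajectory`}{25-generation deterministic trajectory at
#'     the baseline parameters; reports peak and final drive-carrier
#'     fractions and writes the trajectory TSV when `out_tsv` is given.}
#'   \item{`g12-composition`}{composition of non-drive alleles at
#'     generation 12; reports `nondrive_W_at_G12` (percent).}
#'   \item{`embryonic-ej`}{embryonic end-joining estimate from
#'     maternal/paternal-origin transmission rates; reports `gamma_e_hat`.}
#'   \item{`dominance-fit`}{least-squares dominance fit to an observed
#'     trajectory (`observed` data frame or `observed_tsv` path).}
#'   \item{`synthetic-roundtrip`}{generates a seeded synthetic dataset,
#'     runs the amplicon pipeline on it, and reports frequency-recovery
#'     error against truth.}
#' }
#'
#' @param name recipe name (see above).
#' @param config named list of recipe settings; common keys: `seed`
#'   (default 1), `params` (a [model_params()] or a parameter file path),
#'   `out` (JSON report path). Recipe-specific keys: `generations`,
#'   `het_fraction`, `out_tsv`; `transmission_maternal`,
#'   `transmission_paternal` or `transmission_tsv`; `observed` /
#'   `observed_tsv`, `grid`; `reads_per_sample`, `error_rate`.
#' @return the report, invisibly, as a named list.
#' @examples
#' rep <- run_recipe("embryonic-ej",
#'                   list(transmission_maternal = 0.596,
#'                        transmission_paternal = 0.975))
#' rep$results$gamma_e_hat
#' @export
run_recipe <- function(name, config = list()) {
  recipes <- c("baseline-trajectory", "g12-composition", "embryonic-ej",
               "dominance-fit", "synthetic-roundtrip")
  if (length(name) != 1L || !(name %in% recipes)) {
    stop("unknown recipe '", paste(name, collapse = ","),
         "'; available: ", paste(recipes, collapse = ", "), call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- config$params
  if (is.null(params)) params <- model_params()
  if (is.character(params)) params <- read_model_params(params)
  stopifnot(inherits(params, "gd_params"))

  results <- switch(name,
    "baseline-trajectory" = {
      n_gen <- if (is.null(config$generations)) 25L
               else as.integer(config$generations)
      het <- if (is.null(config$het_fraction)) 0.5 else config$het_fraction
      tr <- simulate_drive(params, initial_release_state(het), n_gen)
      s <- summarize_trajectory(tr)
      if (!is.null(config$out_tsv)) write_trajectory_tsv(tr, config$out_tsv)
      list(n_generations = n_gen,
           peak_carrier_fraction = max(s$drive_carrier_fraction),
           peak_generation = s$generation[which.max(s$drive_carrier_fraction)],
           final_carrier_fraction = s$drive_carrier_fraction[nrow(s)],
           final_freq_R1 = s$freq_R1[nrow(s)],
           final_freq_R2 = s$freq_R2[nrow(s)],
           extinct = tr$extinct)
    },
    "g12-composition" = {
      het <- if (is.null(config$het_fraction)) 0.5 else config$het_fraction
      tr <- simulate_drive(params, initial_release_state(het), 12L)
      s <- summarize_trajectory(tr)
      g12 <- s[s$generation == 12L, ]
      list(nondrive_W_at_G12 = 100 * g12$nondrive_W,
           nondrive_R1_at_G12 = 100 * g12$nondrive_R1,
           nondrive_R2_at_G12 = 100 * g12$nondrive_R2)
    },
    "embryonic-ej" = {
      if (!is.null(config$transmission_tsv)) {
        est <- estimate_rates(read_transmission_tsv(config$transmission_tsv))
      } else {
        tm <- config$transmission_maternal
        tp <- config$transmission_paternal
        if (is.null(tm) || is.null(tp)) {
          stop("embryonic-ej needs transmission_maternal/paternal or ",
               "transmission_tsv", call. = FALSE)
        }
        est <- list(transmission_maternal = tm, transmission_paternal = tp,
                    e_hat = estimate_homing(tp),
                    gamma_e_hat = estimate_embryonic_ej(tm, tp))
      }
      est
    },
    "dominance-fit" = {
      observed <- config$observed
      if (is.null(observed) && !is.null(config$observed_tsv)) {
        observed <- read_observed_tsv(config$observed_tsv)
      }
      if (is.null(observed)) {
        stop("dominance-fit needs observed or observed_tsv", call. = FALSE)
      }
      grid <- if (is.null(config$grid)) seq(0, 1, by = 0.005) else config$grid
      fit <- fit_dominance(observed, params, grid = grid)
      list(d_hat = fit$d_hat, sse_min = min(fit$sse_profile$sse),
           poorly_identified = fit$poorly_identified, n_obs = fit$n_obs)
    },
    "synthetic-roundtrip" = {
      gc_args <- list(seed = seed, params = params)
      for (k in c("reads_per_sample", "error_rate", "generations",
                  "n_haplotypes", "focal_haplotype_count")) {
        if (!is.null(config[[k]])) gc_args[[k]] <- config[[k]]
      }
      ds <- do.call(generator_config, gc_args)
      data <- generate_cage_dataset(ds)
      errs <- numeric(0)
      n_novel <- 0L
      for (s in data$samples) {
        res <- run_amplicon_pipeline(data$amplicon,
                                     reads1 = s$reads1, reads2 = s$reads2,
                                     snp_table = data$snp_table,
                                     pool = data$pool)
        truth <- s$truth_alleles
        truth <- truth[truth$frequency >= 0.01, ]
        rec <- res$alleles$frequency[match(truth$label, res$alleles$label)]
        rec[is.na(rec)] <- 0
        errs <- c(errs, abs(rec - truth$frequency))
        if (!is.null(res$haplotypes)) {
          n_novel <- n_novel + sum(res$haplotypes$novel, na.rm = TRUE)
        }
      }
      list(n_samples = length(data$samples),
           max_abs_error = if (length(errs)) max(errs) else NA,
           mean_abs_error = if (length(errs)) mean(errs) else NA,
           n_novel_haplotypes = n_novel)
    })

  report <- list(schema_version = 1L,
                 recipe = name,
                 package_version = as.character(utils::packageVersion("gdresist")),
                 seed = seed,
                 params = unclass(params),
                 results = results)
  if (!is.null(config$out)) {
    jsonlite::write_json(report, config$out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  message(sprintf("[gdresist] recipe '%s' done (seed %d)", name, seed))
  invisible(report)
}
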