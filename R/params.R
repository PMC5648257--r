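#' Model parameters for the four-allele gene-drive recursion
#'
#' Bundles every rate and fitness parameter of the deterministic model. The
#' defaults are the experimentally estimated baseline values for the caged
#' *Anopheles gambiae* drive at AGAP007280: meiotic homing rate `e = 0.984`,
#' meiotic end-joining rate `gamma_m = 0.01`, embryonic end-joining rate
#' `gamma_e = 0.796` (maternally deposited nuclease acting in the zygote),
#' and dominance `d = 0.907` of the female fertility cost in `W/H`
#' heterozygotes. The split of end-joining products between functional
#' in-frame `R1` and frameshift `R2` alleles defaults to `xi_m = xi_e = 1/3`,
#' the fraction expected when indel lengths are uniform modulo 3. Embryonic
#' homology-directed repair (`beta`) defaults to 0.
#'
#' @param e meiotic homing rate: fraction of `W` alleles in a `W/H` germline
#'   converted to `H`, in `[0,1]`.
#' @param gamma_m meiotic end-joining rate: fraction of `W` alleles in a
#'   `W/H` germline converted to a resistant allele, in `[0,1]`;
#'   `e + gamma_m <= 1`.
#' @param gamma_e embryonic end-joining rate: per-`W`-allele probability of
#'   conversion to a resistant allele in embryos laid by drive-carrying
#'   mothers, in `[0,1]`.
#' @param beta embryonic homology-directed repair rate: per-`W`-allele
#'   probability of conversion to a copy of the homologous allele in the same
#'   embryos, in `[0,1]`; `gamma_e + beta <= 1`.
#' @param xi_m,xi_e fraction of meiotic / embryonic end-joining events that
#'   yield a functional in-frame `R1` allele (the remainder are `R2`).
#' @param d dominance of the female fertility cost: `W/H` females have
#'   relative fecundity `1 - d`.
#' @return an object of class `gd_params` (a validated named list).
#' @examples
#' model_params()                      # study baseline
#' model_params(e = 0, gamma_m = 0)    # Mendelian limit
#' @export
model_params <- function(e = 0.984, gamma_m = 0.01, gamma_e = 0.796,
                         beta = 0, xi_m = 1 / 3, xi_e = 1 / 3, d = 0.907) {
  p <- list(e = e, gamma_m = gamma_m, gamma_e = gamma_e, beta = beta,
            xi_m = xi_m, xi_e = xi_e, d = d)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("parameter '", nm, "' must be a single value in [0, 1]",
           call. = FALSE)
    }
  }
  if (p$e + p$gamma_m > 1 + 1e-12) {
    stop("e + gamma_m must not exceed 1", call. = FALSE)
  }
  if (p$gamma_e + p$beta > 1 + 1e-12) {
    stop("gamma_e + beta must not exceed 1", call. = FALSE)
  }
  structure(p, class = "gd_params")
}

#' @export
print.gd_params <- function(x, ...) {
  cat("Gene-drive model parameters\n")
  cat(sprintf("  homing e = %g, meiotic EJ gamma_m = %g (R1 fraction xi_m = %g)\n",
              x$e, x$gamma_m, x$xi_m))
  cat(sprintf("  embryonic EJ gamma_e = %g (R1 fraction xi_e = %g), embryonic HDR beta = %g\n",
              x$gamma_e, x$xi_e, x$beta))
  cat(sprintf("  dominance of W/H female fertility cost d = %g\n", x$d))
  invisible(x)
}

#' Read model parameters from a JSON or YAML file
#'
#' The file must contain a mapping whose keys are a subset of the
#' [model_params()] argument names; missing keys take the baseline defaults.
#' Format is chosen by extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param path path to the configuration file.
#' @return a `gd_params` object.
#' @export
read_model_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported parameter file extension: ", ext, call. = FALSE)
  )
  known <- names(formals(model_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(model_params, lapply(vals, as.numeric))
}
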