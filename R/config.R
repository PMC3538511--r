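## Run configuration: the full set of epidemiological parameters of a
## simulation, assembled either programmatically or from a YAML file whose
## keys mirror the standard parameter names (disease prevalence, DPLs,
## high-risk alleles, genotypic RR, dominance, environmental factor OR,
## noise variables, G x E model, epistasis, sample sizes, seed).

#' Assemble a simulation run configuration
#'
#' @param prevalence disease prevalence `m`, in `(0, 1)`.
#' @param dpl_a,dpl_b `locus_spec` objects for the two disease-predisposing
#'   loci.
#' @param env an `environment_spec` (Gaussian causal exposure and its
#'   per-unit odds ratio).
#' @param gxe_model one of `"ADD"`, `"GEM"`, `"GEN"`, `"ENV"`.
#' @param epistasis an `epistasis_spec` (default: none).
#' @param noise list of `noise_spec` objects.
#' @param n_individuals size of the simulated base population.
#' @param panel list of haplotype-panel options: `block_lengths` (loci per
#'   block; at least two blocks so the DPLs are unlinked),
#'   `within_block_r2`, `background_freq` (alternate-allele frequency of
#'   non-DPL markers), `pool_size`.
#' @param genotype_file optional path to an external genotype table (then
#'   no panel is generated); see [read_genotype_table()].
#' @param genotype_dialect `"phased"` or `"genotypic"`, for
#'   `genotype_file`.
#' @param subsample optional list `n_cases`, `n_controls`, `n_replicates`.
#' @param seed master integer seed.
#' @param output_format `"phased"` or `"genotypic"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(prevalence, dpl_a, dpl_b, env,
                       gxe_model = c("ADD", "GEM", "GEN", "ENV"),
                       epistasis = epistasis_spec(), noise = list(),
                       n_individuals = 10000L,
                       panel = list(), genotype_file = NULL,
                       genotype_dialect = c("phased", "genotypic"),
                       subsample = NULL, seed = 1L,
                       output_format = c("genotypic", "phased")) {
  check_number(prevalence, "prevalence", 0, 1, strict_lower = TRUE,
               strict_upper = TRUE)
  stopifnot(inherits(dpl_a, "locus_spec"), inherits(dpl_b, "locus_spec"),
            inherits(env, "environment_spec"))
  if (dpl_a$marker_id == dpl_b$marker_id)
    stop_gxe("the two DPLs must be distinct markers",
             class = "gxesim_validation_error")
  gxe_model <- match.arg(gxe_model)
  epistasis <- validate_epistasis_spec(epistasis)
  stopifnot(all(vapply(noise, inherits, logical(1), "noise_spec")))
  n_individuals <- check_count(n_individuals, "n_individuals")
  pdef <- list(block_lengths = c(5L, 5L), within_block_r2 = 0.5,
               background_freq = 0.25, pool_size = 10000L)
  panel <- utils::modifyList(pdef, panel)
  if (is.null(genotype_file) && length(panel$block_lengths) < 2L)
    stop_gxe("the panel needs at least two blocks so the DPLs are unlinked",
             class = "gxesim_validation_error")
  if (!is.null(subsample)) {
    stopifnot(all(c("n_cases", "n_controls") %in% names(subsample)))
    if (is.null(subsample$n_replicates)) subsample$n_replicates <- 1L
  }
  structure(list(
    prevalence = prevalence, dpl_a = dpl_a, dpl_b = dpl_b, env = env,
    gxe_model = gxe_model, epistasis = epistasis, noise = noise,
    n_individuals = n_individuals, panel = panel,
    genotype_file = genotype_file,
    genotype_dialect = match.arg(genotype_dialect),
    subsample = subsample, seed = check_count(seed, "seed", min = 0L),
    output_format = match.arg(output_format)
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Simulation configuration: n = %d, prevalence = %.4g, %s model\n",
              x$n_individuals, x$prevalence, x$gxe_model))
  print(x$dpl_a); print(x$dpl_b)
  cat(sprintf("Environment: Gaussian(%.4g, %.4g), OR per unit = %.4g\n",
              x$env$mean, x$env$sd, x$env$or_per_unit))
  if (nrow(x$epistasis))
    cat(sprintf("Epistasis: %d user-specified cell(s)\n", nrow(x$epistasis)))
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the standard epidemiological parameter names:
#' `disease_prevalence`, `dpls` (two marker ids), `high_risk_alleles`,
#' `genotypic_rr`, `dominance`, `target_allele_freq`, `environment`
#' (`mean`, `sd`, `or_per_unit`), `noise_variables`, `gxe_model`,
#' `epistasis` (list of `row`/`col`/`percent`), `panel`, `n_individuals`,
#' `subsample`, `seed`, `output_format`, and optionally `genotype_file` /
#' `genotype_dialect`.
#'
#' @param path path to the YAML file.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- function(key) {
    if (is.null(y[[key]]))
      stop_gxe("config is missing required key \"%s\"", key,
               class = "gxesim_validation_error")
    y[[key]]
  }
  dpls <- need("dpls")
  if (length(dpls) != 2L)
    stop_gxe("config key \"dpls\" must name exactly two markers",
             class = "gxesim_validation_error")
  hra <- need("high_risk_alleles")
  rr <- as.numeric(need("genotypic_rr"))
  w <- as.numeric(need("dominance"))
  qf <- as.numeric(y[["target_allele_freq"]] %||% c(NA, NA))
  mk <- function(k) locus_spec(dpls[[k]], hra[[k]],
                               if (is.na(qf[k])) 0.5 else qf[k],
                               rr[k], w[k])
  ey <- need("environment")
  env <- environment_spec(ey$mean %||% 0, ey$sd %||% 1,
                          ey$or_per_unit %||% 1)
  noise <- lapply(y$noise_variables %||% list(), function(nv)
    do.call(noise_spec, nv))
  epi <- if (is.null(y$epistasis)) epistasis_spec() else
    epistasis_spec(y$epistasis)
  panel <- y$panel %||% list()
  if (!is.null(panel$block_lengths))
    panel$block_lengths <- as.integer(panel$block_lengths)
  run_config(
    prevalence = need("disease_prevalence"),
    dpl_a = mk(1L), dpl_b = mk(2L), env = env,
    gxe_model = y$gxe_model %||% "ADD", epistasis = epi, noise = noise,
    n_individuals = y$n_individuals %||% 10000L, panel = panel,
    genotype_file = y$genotype_file,
    genotype_dialect = y$genotype_dialect %||% "phased",
    subsample = y$subsample, seed = y$seed %||% 1L,
    output_format = y$output_format %||% "genotypic"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
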