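## End-to-end orchestration: genotype/exposure generation on one side,
## parameter translation (penetrance matrices and logistic coefficients) on
## the other, joined by the stochastic status assignment.

# Build the haplotype panel implied by a run configuration: one LD block
# per entry of block_lengths, each DPL placed at the centre of its own
# block (blocks are mutually unlinked, so the DPLs are not in LD).
panel_from_config <- function(config, seed) {
  p <- config$panel
  bl <- p$block_lengths
  L <- sum(bl)
  block <- rep(seq_along(bl), bl)
  ids <- paste0("bg", seq_len(L))
  freqs <- rep(p$background_freq, L)
  others <- rep(c("C", "G", "T"), length.out = L)
  alleles <- rbind(ref = rep("A", L), alt = others)
  place <- function(spec, block_no) {
    idx <- which(block == block_no)
    j <- idx[ceiling(length(idx) / 2)]
    ids[j] <<- spec$marker_id
    freqs[j] <<- spec$allele_freq
    alleles[2L, j] <<- spec$high_risk_allele
    alleles[1L, j] <<- if (spec$high_risk_allele == "A") "G" else "A"
  }
  place(config$dpl_a, 1L)
  place(config$dpl_b, 2L)
  generate_haplotype_panel(block_lengths = bl,
                           within_block_r2 = p$within_block_r2,
                           allele_freqs = freqs, pool_size = p$pool_size,
                           seed = seed, marker_ids = ids, alleles = alleles)
}

#' Translate epidemiological parameters into the penetrance model
#'
#' The parameterisation branch of the pipeline: genotype frequencies (from
#' the population if given, else Hardy-Weinberg at the specified allele
#' frequencies), single-locus marginal risks, the independent penetrance
#' matrix, the epistatic deformation, and the multi-logistic coefficients
#' for the chosen G x E model, together with the prevalence diagnostic.
#'
#' @param config a `run_config`.
#' @param pop optional `gxe_population` from which to take observed
#'   genotype frequencies.
#' @return list with `freqs_a`, `freqs_b`, `marginal`, `tr_independent`,
#'   `delta`, `tr_epistatic`, `coefficients`, `prevalence_check`.
#' @export
parameterize <- function(config, pop = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(pop)) {
    fa <- hwe_genotype_freqs(config$dpl_a$allele_freq)
    fb <- hwe_genotype_freqs(config$dpl_b$allele_freq)
  } else {
    fa <- estimate_dpl_freqs(pop, "a")
    fb <- estimate_dpl_freqs(pop, "b")
  }
  marg <- marginal_risks_from_rr(config$dpl_a, config$dpl_b, fa, fb,
                                 config$prevalence)
  tri <- independent_tr(marg)
  delta <- complete_delta(tri, config$epistasis)
  tre <- apply_delta(tri, delta)
  coeffs <- solve_coefficients(tre, config$env, config$gxe_model,
                               beta_ab = beta_from_or(config$env$or_per_unit))
  chk <- check_prevalence(coeffs, fa, fb, config$env, config$prevalence)
  list(freqs_a = fa, freqs_b = fb, marginal = marg, tr_independent = tri,
       delta = delta, tr_epistatic = tre, coefficients = coeffs,
       prevalence_check = chk)
}

#' Run a full simulation
#'
#' Executes both branches of the pipeline: (1) generate the haplotype pool,
#' sample individuals and assign exposures (or ingest an external genotype
#' table), (2) translate the epidemiological parameters into multi-logistic
#' coefficients, then (3) assign disease status and, if requested, draw
#' case-control replicates.  Every stochastic stage consumes a sub-seed
#' derived from `config$seed`, so the whole run is reproducible.
#'
#' @param config a `run_config`.
#' @return an object of class `gxe_run`: the `config`, the `population`,
#'   the `panel` (if generated), the parameterisation `artifacts`, the
#'   `samples` (if subsampling was requested), derived `seeds`, and
#'   per-stage `timings` in seconds.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- stats::setNames(split_seed(config$seed, 5L),
                           c("panel", "individuals", "exposures", "status",
                             "subsample"))
  timings <- c()
  tic <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    attr(v, "gxe_elapsed") <- proc.time()[["elapsed"]] - t0
    v
  }
  panel <- NULL
  if (is.null(config$genotype_file)) {
    panel <- tic(panel_from_config(config, seeds[["panel"]]))
    timings["panel"] <- attr(panel, "gxe_elapsed")
    pop <- tic(sample_individuals(panel, config$n_individuals,
                                  config$dpl_a, config$dpl_b,
                                  seeds[["individuals"]]))
  } else {
    pop <- tic(read_genotype_table(config$genotype_file,
                                   dialect = config$genotype_dialect,
                                   dpl_a = config$dpl_a,
                                   dpl_b = config$dpl_b))
  }
  timings["individuals"] <- attr(pop, "gxe_elapsed")
  pop <- tic(assign_exposures(pop, config$env, config$noise,
                              seeds[["exposures"]]))
  timings["exposures"] <- attr(pop, "gxe_elapsed")
  art <- tic(parameterize(config, pop))
  timings["parameterize"] <- attr(art, "gxe_elapsed")
  pop <- tic(assign_status(pop, art$coefficients, seeds[["status"]]))
  timings["status"] <- attr(pop, "gxe_elapsed")
  samples <- NULL
  if (!is.null(config$subsample)) {
    ss <- config$subsample
    samples <- tic(subsample_case_control(pop, ss$n_cases, ss$n_controls,
                                          ss$n_replicates,
                                          seeds[["subsample"]]))
    timings["subsample"] <- attr(samples, "gxe_elapsed")
  }
  structure(list(config = config, population = pop, panel = panel,
                 artifacts = art, samples = samples, seeds = seeds,
                 timings = timings),
            class = "gxe_run")
}

#' @export
print.gxe_run <- function(x, ...) {
  cat("Completed simulation run\n")
  print(x$config)
  print(x$population)
  cat(sprintf("Implied prevalence %.6g (designed %.6g, residual %.2e)\n",
              x$artifacts$prevalence_check$implied,
              x$artifacts$prevalence_check$designed,
              x$artifacts$prevalence_check$residual))
  if (!is.null(x$samples))
    cat(sprintf("%d case-control replicate(s) drawn\n", length(x$samples)))
  invisible(x)
}
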