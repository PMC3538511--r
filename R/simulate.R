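## Joining the two branches of the simulation: each individual's disease
## risk is the logistic risk curve of its combined genotype evaluated at
## its exposure, and disease status is assigned by comparing the risk with
## a uniform random draw.

#' Assign disease status to a population
#'
#' Computes each individual's disease risk by evaluating the logistic risk
#' curve of its combined genotype at its causal exposure, then draws the
#' affected/unaffected label by comparing the risk with a uniform random
#' number.  Deterministic given the seed.
#'
#' @param pop a `gxe_population` with genotypes and exposures assigned.
#' @param coeffs an `mlm_coefficients` object.
#' @param seed integer seed.
#' @return the population with `risk` and `status` (1 = affected,
#'   0 = unaffected) filled in.
#' @export
assign_status <- function(pop, coeffs, seed) {
  stopifnot(inherits(pop, "gxe_population"),
            inherits(coeffs, "mlm_coefficients"))
  if (is.null(pop$exposure))
    stop_gxe("exposures must be assigned before disease status",
             class = "gxesim_validation_error")
  if (is.null(pop$genotype_a) || is.null(pop$genotype_b))
    stop_gxe("DPL genotypes must be assigned before disease status",
             class = "gxesim_validation_error")
  idx <- cbind(pop$genotype_a, pop$genotype_b)
  risk <- logistic_risk(coeffs$alpha[idx], coeffs$beta[idx], pop$exposure)
  set.seed(split_seed(seed, 1L))
  pop$risk <- risk
  pop$status <- as.integer(stats::runif(pop$n) < risk)
  pop
}

#' Observed penetrance per combined genotype
#'
#' Tabulates the affected fraction among carriers of each combined genotype
#' -- the empirical mirror of the designed penetrance matrix, useful for
#' expected-versus-observed convergence checks.
#'
#' @param pop a `gxe_population` with status assigned.
#' @return a list with `penetrance` (3 x 3; `NA` where no carriers) and
#'   `carriers` (3 x 3 counts).
#' @export
empirical_penetrance <- function(pop) {
  stopifnot(inherits(pop, "gxe_population"))
  if (is.null(pop$status))
    stop_gxe("disease status has not been assigned",
             class = "gxesim_validation_error")
  carriers <- affected <- matrix(0, 3, 3,
                                 dimnames = list(ga = paste0("g", 1:3),
                                                 gb = paste0("g", 1:3)))
  for (i in 1:3) for (j in 1:3) {
    sel <- pop$genotype_a == i & pop$genotype_b == j
    carriers[i, j] <- sum(sel)
    affected[i, j] <- sum(pop$status[sel])
  }
  pen <- affected / carriers
  pen[carriers == 0] <- NA_real_
  list(penetrance = pen, carriers = carriers)
}

#' Observed single-locus penetrance
#'
#' Affected fraction per genotype code at one DPL, marginally over the
#' other locus.
#'
#' @param pop a `gxe_population` with status assigned.
#' @param which `"a"`, `"b"`, or a DPL marker id.
#' @return numeric vector of length 3.
#' @export
marginal_penetrance <- function(pop, which = "a") {
  stopifnot(inherits(pop, "gxe_population"))
  if (is.null(pop$status))
    stop_gxe("disease status has not been assigned",
             class = "gxesim_validation_error")
  g <- if (identical(which, "a") || identical(which, pop$dpl_a$marker_id))
    pop$genotype_a else pop$genotype_b
  vapply(1:3, function(k) mean(pop$status[g == k]), numeric(1))
}

#' Draw case-control replicates from a simulated population
#'
#' Each replicate draws the requested numbers of affected and unaffected
#' individuals without replacement (within the replicate; replicates are
#' drawn independently of each other, as in bootstrapping across data sets
#' with identical design).
#'
#' @param pop a `gxe_population` with status assigned.
#' @param n_cases,n_controls requested counts per replicate.
#' @param n_replicates number of replicates.
#' @param seed integer seed; each replicate consumes its own sub-seed.
#' @return list of `case_control_sample` objects, each with `cases`,
#'   `controls` (individual indices) and `replicate_id`.
#' @export
subsample_case_control <- function(pop, n_cases, n_controls,
                                   n_replicates = 1L, seed) {
  stopifnot(inherits(pop, "gxe_population"))
  if (is.null(pop$status))
    stop_gxe("disease status has not been assigned",
             class = "gxesim_validation_error")
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  n_replicates <- check_count(n_replicates, "n_replicates")
  aff <- which(pop$status == 1L); unaff <- which(pop$status == 0L)
  if (length(aff) < n_cases || length(unaff) < n_controls)
    stop_gxe(paste0("population cannot supply the requested sample: %d ",
                    "affected available (%d requested), %d unaffected ",
                    "available (%d requested); re-simulate with a larger ",
                    "base population"),
             length(aff), n_cases, length(unaff), n_controls,
             class = "gxesim_validation_error")
  seeds <- split_seed(seed, n_replicates)
  lapply(seq_len(n_replicates), function(r) {
    set.seed(seeds[r])
    structure(list(cases = sort(sample(aff, n_cases)),
                   controls = sort(sample(unaff, n_controls)),
                   replicate_id = r),
              class = "case_control_sample")
  })
}

#' @export
print.case_control_sample <- function(x, ...) {
  cat(sprintf("Case-control replicate %d: %d cases, %d controls\n",
              x$replicate_id, length(x$cases), length(x$controls)))
  invisible(x)
}
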