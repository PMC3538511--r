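## Constructors for the epidemiological input specifications.
## Genotype code convention used throughout the package: at each
## disease-predisposing locus (DPL) code 1 is the low-risk homozygote,
## code 2 the heterozygote and code 3 the high-risk homozygote.

#' Specify a disease-predisposing locus
#'
#' A DPL is a bi-allelic marker whose genotype influences disease risk.  Its
#' effect is parameterised the way epidemiologists report it: the genotypic
#' relative risk `rr` of the high-risk homozygote over the low-risk
#' homozygote, and a dominance weight `w` placing the heterozygote risk
#' between the homozygote risks (`w = 0` dominant high-risk allele, `w = 1`
#' recessive, intermediate values co-dominant).
#'
#' @param marker_id marker identifier (must exist in the genotype panel).
#' @param high_risk_allele one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param allele_freq frequency of the high-risk allele, in `[0, 1]`.
#' @param rr genotypic relative risk, strictly positive.
#' @param w dominance weight in `[0, 1]`.
#' @return an object of class `locus_spec`.
#' @examples
#' locus_spec("rs1", "C", allele_freq = 0.3, rr = 1.6, w = 0.5)
#' @export
locus_spec <- function(marker_id, high_risk_allele, allele_freq, rr, w) {
  stopifnot(is.character(marker_id), length(marker_id) == 1L)
  if (!high_risk_allele %in% c("A", "C", "G", "T"))
    stop_gxe("high_risk_allele must be one of A, C, G, T (got \"%s\")",
             high_risk_allele, class = "gxesim_validation_error")
  check_number(allele_freq, "allele_freq", 0, 1)
  check_number(rr, "rr", 0, Inf, strict_lower = TRUE)
  check_number(w, "w", 0, 1)
  structure(list(marker_id = marker_id, high_risk_allele = high_risk_allele,
                 allele_freq = allele_freq, rr = rr, w = w),
            class = "locus_spec")
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("DPL %s: high-risk allele %s (freq %.4g), RR = %.4g, W = %.4g\n",
              x$marker_id, x$high_risk_allele, x$allele_freq, x$rr, x$w))
  invisible(x)
}

#' Specify the causal environmental exposure
#'
#' The causal exposure is Gaussian with the given mean and standard
#' deviation; its effect on disease risk is given as the odds ratio for a
#' one-unit increase in exposure.
#'
#' @param mean,sd parameters of the Gaussian exposure distribution (`sd > 0`).
#' @param or_per_unit odds ratio per unit exposure, strictly positive.
#' @return an object of class `environment_spec`.
#' @examples
#' environment_spec(mean = 0, sd = 1, or_per_unit = 1.2)
#' @export
environment_spec <- function(mean = 0, sd = 1, or_per_unit = 1) {
  check_number(mean, "mean")
  check_number(sd, "sd", 0, Inf, strict_lower = TRUE)
  check_number(or_per_unit, "or_per_unit", 0, Inf, strict_lower = TRUE)
  structure(list(mean = mean, sd = sd, or_per_unit = or_per_unit),
            class = "environment_spec")
}

#' Specify a non-causal (noise) environmental variable
#'
#' Noise exposures are written to the output alongside the causal exposure
#' but never enter the risk model; they act as confounding background for
#' feature-selection benchmarks.
#'
#' @param name column name in the output table.
#' @param family one of `"gaussian"`, `"uniform"`, `"binomial"`.
#' @param mean,sd gaussian parameters.
#' @param low,high uniform bounds (`low < high`).
#' @param size,prob binomial parameters (`size >= 1`, `prob` in `[0, 1]`).
#' @return an object of class `noise_spec`.
#' @examples
#' noise_spec("smoking", "binomial", size = 1, prob = 0.3)
#' @export
noise_spec <- function(name, family = c("gaussian", "uniform", "binomial"),
                       mean = 0, sd = 1, low = 0, high = 1,
                       size = 1, prob = 0.5) {
  stopifnot(is.character(name), length(name) == 1L)
  family <- match.arg(family)
  params <- switch(family,
    gaussian = {
      check_number(sd, "sd", 0, Inf, strict_lower = TRUE)
      list(mean = check_number(mean, "mean"), sd = sd)
    },
    uniform = {
      check_number(low, "low"); check_number(high, "high")
      if (low >= high)
        stop_gxe("uniform noise variable \"%s\" needs low < high", name,
                 class = "gxesim_validation_error")
      list(low = low, high = high)
    },
    binomial = {
      list(size = check_count(size, "size"),
           prob = check_number(prob, "prob", 0, 1))
    })
  structure(list(name = name, family = family, params = params),
            class = "noise_spec")
}
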