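## The multi-logistic model (MLM): one logistic risk curve in the
## environmental exposure per combined two-locus genotype, and the
## construction of the independent (no-epistasis) penetrance matrix from
## prevalence, genotypic relative risks and dominance weights.
##
## Sign convention: risk(x) = [1 + exp(-(alpha + beta x))]^-1, so that the
## slope beta is exactly the natural logarithm of the odds ratio per unit
## increase in exposure (odds(x + 1) / odds(x) = exp(beta)).

#' Logistic disease risk
#'
#' Evaluates the MLM risk curve `1 / (1 + exp(-(alpha + beta * x)))`.
#' Under this parameterisation `exp(beta)` is the odds ratio per unit
#' increase of `x`.
#'
#' @param alpha,beta logistic intercept and slope (vectorised).
#' @param x exposure level(s).
#' @return risk in `(0, 1)` for finite inputs.
#' @examples
#' logistic_risk(0, log(1.2), 1)  # 1.2 / 2.2
#' @export
logistic_risk <- function(alpha, beta, x) {
  stats::plogis(alpha + beta * x)
}

#' Expected penetrance under a Gaussian exposure
#'
#' Computes the total risk `TR = E[risk(X)]` for `X ~ N(mean, sd^2)`, i.e.
#' the integral of the logistic risk curve against the Gaussian exposure
#' density, by Gauss-Hermite quadrature on the untruncated real line.  The
#' integrand is smooth, so 96 nodes give accuracy far beyond 1e-10 for the
#' parameter magnitudes this model produces.
#'
#' @param alpha logistic intercept(s); vectorised.
#' @param beta logistic slope(s); vectorised (recycled against `alpha`).
#' @param env an `environment_spec` (its `or_per_unit` is not used here).
#' @param n_nodes number of quadrature nodes.
#' @return expected penetrance in `(0, 1)`, same length as `alpha`/`beta`.
#' @examples
#' env <- environment_spec(0, 1)
#' expected_penetrance(0, 2, env)  # 0.5 by symmetry
#' @export
expected_penetrance <- function(alpha, beta, env, n_nodes = 96L) {
  stopifnot(inherits(env, "environment_spec"))
  k <- max(length(alpha), length(beta))
  alpha <- rep_len(alpha, k); beta <- rep_len(beta, k)
  gh <- gh_rule(n_nodes)
  x <- env$mean + sqrt(2) * env$sd * gh$x     # substitution for the N(mu, sd)
  w <- gh$w / sqrt(pi)
  # rows: quadrature nodes; cols: (alpha, beta) pairs
  eta <- outer(x, beta) + rep(alpha, each = length(x))
  as.vector(w %*% stats::plogis(eta))
}

#' Single-locus marginal risks from relative risk and dominance
#'
#' For each locus, the three genotype risks are `TR_1 = t`, `TR_3 = rr * t`
#' and `TR_2 = w * TR_1 + (1 - w) * TR_3` (so `w = 0` gives the heterozygote
#' the high-risk homozygote's risk -- dominant high-risk allele -- and
#' `w = 1` the low-risk homozygote's risk -- recessive).  The scale `t` is
#' fixed by requiring the genotype-frequency-weighted mean risk to equal the
#' disease prevalence `m`.
#'
#' @param spec_a,spec_b `locus_spec` objects for the two DPLs.
#' @param freqs_a,freqs_b genotype frequency vectors (length 3, summing
#'   to 1), e.g. from [hwe_genotype_freqs()] or [estimate_dpl_freqs()].
#' @param m disease prevalence, in `(0, 1)`.
#' @return an object of class `marginal_risks` with fields `tr_a`, `tr_b`
#'   (length-3 risk vectors) and `m`.
#' @examples
#' f <- hwe_genotype_freqs(0.5)
#' s <- locus_spec("rs1", "C", 0.5, rr = 2, w = 1)
#' marginal_risks_from_rr(s, s, f, f, m = 0.1)$tr_a  # c(0.08, 0.08, 0.16)
#' @export
marginal_risks_from_rr <- function(spec_a, spec_b, freqs_a, freqs_b, m) {
  stopifnot(inherits(spec_a, "locus_spec"), inherits(spec_b, "locus_spec"))
  check_number(m, "m", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  one_locus <- function(spec, p, label) {
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop_gxe("genotype frequencies for locus %s must be 3 non-negative values summing to 1",
               label, class = "gxesim_validation_error")
    rel <- c(1, spec$w + (1 - spec$w) * spec$rr, spec$rr)
    t0 <- m / sum(rel * p)
    tr <- rel * t0
    if (any(tr > 1 + 1e-12))
      stop_gxe(paste0("infeasible parameters at locus %s: implied genotype ",
                      "risk %.4g exceeds 1 (prevalence %.3g, RR %.3g)"),
               spec$marker_id, max(tr), m, spec$rr,
               class = "gxesim_infeasible_error")
    stats::setNames(pmin(tr, 1), c("g1", "g2", "g3"))
  }
  structure(list(tr_a = one_locus(spec_a, freqs_a, "A"),
                 tr_b = one_locus(spec_b, freqs_b, "B"),
                 freqs_a = freqs_a, freqs_b = freqs_b, m = m),
            class = "marginal_risks")
}

#' @export
print.marginal_risks <- function(x, ...) {
  cat(sprintf("Marginal genotype risks (prevalence m = %.4g)\n", x$m))
  cat("  locus A:", sprintf("%.5g", x$tr_a), "\n")
  cat("  locus B:", sprintf("%.5g", x$tr_b), "\n")
  invisible(x)
}

new_penetrance_matrix <- function(tr, kind, marg) {
  dimnames(tr) <- list(ga = paste0("g", 1:3), gb = paste0("g", 1:3))
  structure(list(tr = tr, kind = kind,
                 tr_a = marg$tr_a, tr_b = marg$tr_b,
                 freqs_a = marg$freqs_a, freqs_b = marg$freqs_b,
                 m = marg$m),
            class = "penetrance_matrix")
}

#' Independent (no-epistasis) penetrance matrix
#'
#' Builds the 3 x 3 matrix of combined-genotype total risks under the
#' independent polygenic model, `TR(ga, gb) = TR_ga * TR_gb / m`.  The
#' construction preserves both sets of single-locus marginal risks and the
#' prevalence by algebra.
#'
#' @param marg a `marginal_risks` object.
#' @return an object of class `penetrance_matrix` with `kind =
#'   "independent"`.
#' @export
independent_tr <- function(marg) {
  stopifnot(inherits(marg, "marginal_risks"))
  tr <- outer(marg$tr_a, marg$tr_b) / marg$m
  if (any(tr > 1 + 1e-12))
    stop_gxe("infeasible parameters: independent-model risk %.4g exceeds 1",
             max(tr), class = "gxesim_infeasible_error")
  new_penetrance_matrix(tr, "independent", marg)
}

#' @export
print.penetrance_matrix <- function(x, ...) {
  cat(sprintf("Penetrance matrix (%s), prevalence m = %.4g\n", x$kind, x$m))
  print(round(x$tr, 6))
  invisible(x)
}

#' Prevalence and marginals implied by a penetrance matrix
#'
#' Recomputes the prevalence `sum TR(ga, gb) P_ga P_gb` and the two sets of
#' single-locus marginal risks from a penetrance matrix; used to check that
#' deformations preserve them.
#'
#' @param pm a `penetrance_matrix`.
#' @return list with `prevalence`, `tr_a`, `tr_b`.
#' @export
penetrance_summary <- function(pm) {
  stopifnot(inherits(pm, "penetrance_matrix"))
  pa <- pm$freqs_a; pb <- pm$freqs_b
  list(prevalence = as.numeric(pa %*% pm$tr %*% pb),
       tr_a = as.vector(pm$tr %*% pb),
       tr_b = as.vector(pa %*% pm$tr))
}
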