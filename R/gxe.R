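## Translation of a target penetrance matrix + environmental spec + G x E
## model into per-combined-genotype logistic coefficients (alpha, beta),
## by inverting the Gaussian-expectation constraint
##   E[ logistic(alpha + beta X) ] = TR(ga, gb)   for each cell.
##
## The four predefined interaction models:
##   GEN - risk depends on genetics only: beta = 0 everywhere.
##   ENV - risk depends on environment only: one shared (alpha, beta_ab);
##         requires a constant TR matrix.
##   GEM - modulative: shared alpha (same basal risk), per-cell beta
##         (genotype modulates environmental sensitivity).
##   ADD - additive: per-cell alpha, one shared slope beta_ab.
## By convention beta_ab = log(OR per unit exposure) is attached to the
## combined genotype with the highest total risk.

#' Environmental slope from an odds ratio
#'
#' Converts the per-unit odds ratio of the environmental exposure into the
#' logistic slope `beta_ab = log(OR)` that is attached, by convention, to
#' the highest-risk combined genotype.
#'
#' @param or_per_unit odds ratio, strictly positive.
#' @return `log(or_per_unit)`.
#' @examples
#' beta_from_or(1.2)
#' @export
beta_from_or <- function(or_per_unit) {
  check_number(or_per_unit, "or_per_unit", 0, Inf, strict_lower = TRUE)
  log(or_per_unit)
}

# cell carrying beta_ab: argmax of TR, ties broken toward (3,3) then
# row-major order
.highest_risk_cell <- function(tr) {
  mx <- max(tr)
  if (abs(tr[3, 3] - mx) < 1e-15) return(c(3L, 3L))
  for (i in 1:3) for (j in 1:3)
    if (abs(tr[i, j] - mx) < 1e-15) return(c(i, j))
  c(3L, 3L)
}

# solve expected_penetrance(alpha, beta, env) = target for alpha
# (strictly increasing in alpha)
.solve_alpha <- function(target, beta, env) {
  f <- function(a) expected_penetrance(a, beta, env) - target
  lo <- stats::qlogis(target) - abs(beta) * env$sd - 1
  hi <- stats::qlogis(target) + abs(beta) * env$sd + 1
  while (f(lo) > 0) lo <- lo - 5
  while (f(hi) < 0) hi <- hi + 5
  stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
}

# solve expected_penetrance(alpha, beta, env) = target for beta, preferring
# the sign of beta_ab; returns NA if no root exists on either branch
.solve_beta <- function(target, alpha, env, prefer_sign = 1) {
  g <- function(bt) expected_penetrance(alpha, bt, env) - target
  if (abs(g(0)) < 1e-13) return(0)
  signs <- if (prefer_sign >= 0) c(1, -1) else c(-1, 1)
  for (s in signs) {
    # bracket along s * magnitude
    lo <- 0; hi <- 1 / env$sd
    found <- FALSE
    for (k in 1:60) {
      if (g(s * lo) * g(s * hi) <= 0) { found <- TRUE; break }
      lo <- hi; hi <- hi * 2
      if (hi > 1e6) break
    }
    if (found)
      return(s * stats::uniroot(function(m) g(s * m), c(lo, hi),
                                tol = 1e-13)$root)
  }
  NA_real_
}

#' Solve the multi-logistic coefficients for a G x E model
#'
#' Finds, for every combined genotype, the pair `(alpha, beta)` whose
#' Gaussian-expected penetrance equals the target total risk `TR(ga, gb)`,
#' under the constraints of the chosen interaction model.  `GEN` is solved
#' in closed form (`alpha = logit(TR)`); `ADD` is nine independent
#' one-dimensional root-finds in `alpha` with the shared slope fixed; `GEM`
#' first determines the shared `alpha` from the highest-risk cell (which
#' carries `beta_ab`) and then root-finds each remaining cell's slope;
#' `ENV` requires a constant matrix and solves a single intercept.
#'
#' @param tr a `penetrance_matrix` with entries strictly inside `(0, 1)`.
#' @param env an `environment_spec`.
#' @param model one of `"ADD"`, `"GEM"`, `"GEN"`, `"ENV"`.
#' @param beta_ab slope for the highest-risk genotype; defaults to
#'   `beta_from_or(env$or_per_unit)`.
#' @return an object of class `mlm_coefficients` with 3 x 3 matrices
#'   `alpha`, `beta`, the `model`, `beta_ab` and the `anchor` cell.
#' @export
solve_coefficients <- function(tr, env, model = c("ADD", "GEM", "GEN", "ENV"),
                               beta_ab = NULL) {
  stopifnot(inherits(tr, "penetrance_matrix"), inherits(env, "environment_spec"))
  model <- match.arg(model)
  if (is.null(beta_ab)) beta_ab <- beta_from_or(env$or_per_unit)
  TR <- tr$tr
  if (any(TR <= 0) || any(TR >= 1))
    stop_gxe(paste0("cannot solve logistic coefficients: a total risk of ",
                    "%.3g is outside (0, 1)"),
             TR[which(TR <= 0 | TR >= 1)[1]], class = "gxesim_infeasible_error")
  anchor <- .highest_risk_cell(TR)
  alpha <- beta <- matrix(0, 3, 3, dimnames = dimnames(TR))

  if (model == "GEN") {
    alpha[] <- stats::qlogis(TR)          # beta = 0: closed form
  } else if (model == "ENV") {
    if (diff(range(TR)) > 1e-10)
      stop_gxe(paste0("ENV model requires a constant penetrance matrix ",
                      "(risk range %.3g .. %.3g); set RR = 1 at both loci ",
                      "and no epistasis"),
               min(TR), max(TR), class = "gxesim_model_error")
    a <- .solve_alpha(mean(TR), beta_ab, env)
    alpha[] <- a; beta[] <- beta_ab
  } else if (model == "ADD") {
    beta[] <- beta_ab
    for (i in 1:3) for (j in 1:3)
      alpha[i, j] <- .solve_alpha(TR[i, j], beta_ab, env)
  } else { # GEM
    a <- .solve_alpha(TR[anchor[1], anchor[2]], beta_ab, env)
    alpha[] <- a
    for (i in 1:3) for (j in 1:3) {
      if (i == anchor[1] && j == anchor[2]) { beta[i, j] <- beta_ab; next }
      bt <- .solve_beta(TR[i, j], a, env, prefer_sign = sign(beta_ab))
      if (is.na(bt))
        stop_gxe(paste0("GEM model infeasible for this configuration: no ",
                        "slope reproduces TR(%d,%d) = %.4g from the shared ",
                        "basal risk %.4g (exposure mean %.3g, sd %.3g); the ",
                        "modulative model needs the basal risk below every ",
                        "cell's total risk"),
                 i, j, TR[i, j], stats::plogis(a), env$mean, env$sd,
                 class = "gxesim_infeasible_error")
      beta[i, j] <- bt
    }
  }
  co <- structure(list(alpha = alpha, beta = beta, model = model,
                       beta_ab = beta_ab, anchor = anchor, env = env),
                  class = "mlm_coefficients")
  achieved <- matrix(expected_penetrance(as.vector(alpha), as.vector(beta),
                                         env), 3, 3)
  if (max(abs(achieved - TR)) > 1e-8)
    stop_gxe("coefficient solve did not converge (max residual %.3g)",
             max(abs(achieved - TR)), class = "gxesim_numeric_error")
  co
}

#' @export
print.mlm_coefficients <- function(x, ...) {
  cat(sprintf("Multi-logistic coefficients (%s model, beta_ab = %.6g at cell (%d,%d))\n",
              x$model, x$beta_ab, x$anchor[1], x$anchor[2]))
  cat("alpha:\n"); print(round(x$alpha, 6))
  cat("beta:\n"); print(round(x$beta, 6))
  invisible(x)
}

#' Check the prevalence implied by solved coefficients
#'
#' Recomputes the population prevalence implied by the multi-logistic
#' coefficients -- the expected penetrance of every combined genotype,
#' weighted by the product of its genotype frequencies -- and reports the
#' residual against the designed prevalence.
#'
#' @param coeffs an `mlm_coefficients` object.
#' @param freqs_a,freqs_b genotype frequency vectors for the two loci.
#' @param env an `environment_spec`.
#' @param m designed prevalence.
#' @return list with `implied`, `designed`, `residual`, and `pass`
#'   (`TRUE` iff `|residual| < 1e-7`).
#' @export
check_prevalence <- function(coeffs, freqs_a, freqs_b, env, m) {
  stopifnot(inherits(coeffs, "mlm_coefficients"))
  tr <- matrix(expected_penetrance(as.vector(coeffs$alpha),
                                   as.vector(coeffs$beta), env), 3, 3)
  implied <- as.numeric(freqs_a %*% tr %*% freqs_b)
  res <- implied - m
  list(implied = implied, designed = m, residual = res,
       pass = abs(res) < 1e-7)
}
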