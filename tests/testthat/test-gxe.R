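# Independent bisection oracle on the Gaussian-expectation constraint,
# integrating with stats::integrate rather than the package quadrature.
bisect_alpha <- function(target, beta, env, tol = 1e-10) {
  ev <- function(a) stats::integrate(function(x)
    stats::dnorm(x, env$mean, env$sd) * stats::plogis(a + beta * x),
    -Inf, Inf, rel.tol = 1e-12)$value
  lo <- -30; hi <- 30
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ev(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

test_that("environmental slope is the log odds ratio", {
  expect_equal(beta_from_or(1), 0)
  expect_equal(beta_from_or(exp(1)), 1)
  expect_equal(beta_from_or(1.2), log(1.2))
  expect_error(beta_from_or(0), class = "gxesim_validation_error")
  expect_error(beta_from_or(-2), class = "gxesim_validation_error")
})

test_that("GEN and ADD solve the symmetric midpoint in closed form", {
  f <- hwe_genotype_freqs(0.5)
  marg <- marginal_risks_from_rr(locus_spec("rsA", "C", 0.5, 1, 0.5),
                                 locus_spec("rsB", "G", 0.5, 1, 0.5),
                                 f, f, m = 0.5)
  half <- independent_tr(marg)   # constant matrix at 0.5
  gen <- solve_coefficients(half, std_env(), "GEN")
  expect_equal(gen$alpha, matrix(0, 3, 3), ignore_attr = TRUE)
  expect_equal(gen$beta, matrix(0, 3, 3), ignore_attr = TRUE)

  add <- solve_coefficients(half, std_env(), "ADD", beta_ab = log(1.7))
  expect_equal(add$alpha, matrix(0, 3, 3), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(add$beta, matrix(log(1.7), 3, 3), ignore_attr = TRUE)
})

test_that("ADD intercepts agree with a bisection oracle and round-trip", {
  env <- std_env()
  tri <- std_tri()
  co <- solve_coefficients(tri, env, "ADD")
  a_oracle <- bisect_alpha(tri$tr[1, 1], log(1.2), env)
  expect_equal(co$alpha[1, 1], a_oracle, tolerance = 1e-8)
  achieved <- matrix(expected_penetrance(as.vector(co$alpha),
                                         as.vector(co$beta), env), 3, 3)
  expect_equal(achieved, tri$tr, ignore_attr = TRUE, tolerance = 1e-8)
  # higher target risk means higher intercept under this sign convention
  # (ties in TR give tied intercepts)
  ord <- order(as.vector(tri$tr))
  expect_true(all(diff(as.vector(co$alpha)[ord]) >= -1e-12))
  expect_equal(order(as.vector(co$alpha)), order(as.vector(tri$tr)))
})

test_that("every G x E model round-trips its penetrance targets", {
  env0 <- std_env()
  envm <- environment_spec(mean = 2, sd = 0.5, or_per_unit = 1.3)
  f <- hwe_genotype_freqs(0.3)
  flat <- independent_tr(marginal_risks_from_rr(
    locus_spec("rsA", "C", 0.3, 1, 0.5), locus_spec("rsB", "G", 0.3, 1, 0.5),
    f, f, 0.1))
  cases <- list(
    list(tr = std_tri(), env = env0, model = "GEN"),
    list(tr = std_tri(), env = env0, model = "ADD"),
    list(tr = std_tri(rr = 1.3), env = env0, model = "ADD"),
    list(tr = std_tri(), env = envm, model = "GEM"),
    list(tr = flat, env = env0, model = "ENV")
  )
  for (cs in cases) {
    co <- solve_coefficients(cs$tr, cs$env, cs$model)
    achieved <- matrix(expected_penetrance(as.vector(co$alpha),
                                           as.vector(co$beta), cs$env), 3, 3)
    expect_equal(achieved, cs$tr$tr, ignore_attr = TRUE, tolerance = 1e-8,
                 label = paste("round-trip", cs$model))
    # model structure constraints
    if (cs$model == "GEN") expect_true(all(co$beta == 0))
    if (cs$model == "ADD") expect_true(all(co$beta == co$beta_ab))
    if (cs$model == "GEM") expect_equal(diff(range(co$alpha)), 0)
    if (cs$model == "ENV") {
      expect_equal(diff(range(co$alpha)), 0)
      expect_true(all(co$beta == co$beta_ab))
    }
  }
})

test_that("GEM with a constant matrix collapses to a common slope", {
  f <- hwe_genotype_freqs(0.3)
  flat <- independent_tr(marginal_risks_from_rr(
    locus_spec("rsA", "C", 0.3, 1, 0.5), locus_spec("rsB", "G", 0.3, 1, 0.5),
    f, f, 0.1))
  co <- solve_coefficients(flat, std_env(), "GEM")
  expect_lt(diff(range(co$beta)), 1e-6)
  expect_equal(co$beta[3, 3], log(1.2))
})

test_that("model inconsistencies and unattainable risks are rejected", {
  expect_error(solve_coefficients(std_tri(), std_env(), "ENV"),
               class = "gxesim_model_error")
  # a modulative solve whose basal risk exceeds a cell's target risk
  expect_error(solve_coefficients(std_tri(), std_env(), "GEM"),
               class = "gxesim_infeasible_error")
  bad <- std_tri()
  bad$tr[1, 1] <- 1
  expect_error(solve_coefficients(bad, std_env(), "ADD"),
               class = "gxesim_infeasible_error")
})

test_that("prevalence diagnostic accepts solutions and detects tampering", {
  f <- hwe_genotype_freqs(0.3)
  flat <- independent_tr(marginal_risks_from_rr(
    locus_spec("rsA", "C", 0.3, 1, 0.5), locus_spec("rsB", "G", 0.3, 1, 0.5),
    f, f, 0.1))
  co <- solve_coefficients(flat, std_env(), "ADD")
  chk <- check_prevalence(co, f, f, std_env(), 0.1)
  expect_true(chk$pass)
  expect_lt(abs(chk$implied - 0.1), 1e-8)

  co$alpha[2, 2] <- co$alpha[2, 2] + 0.1
  chk2 <- check_prevalence(co, f, f, std_env(), 0.1)
  expect_false(chk2$pass)

  # after an epistatic deformation the residual stays below 1e-7
  tri <- std_tri()
  tre <- apply_delta(tri, complete_delta(tri, epistasis_spec(
    data.frame(row = 3, col = 3, percent = 20))))
  co3 <- solve_coefficients(tre, std_env(), "ADD")
  f3 <- hwe_genotype_freqs(0.3)
  expect_true(check_prevalence(co3, f3, f3, std_env(), 0.1)$pass)
})
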