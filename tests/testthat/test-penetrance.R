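test_that("logistic risk obeys the odds-ratio parameterisation", {
  expect_equal(logistic_risk(0, 0, 5), 0.5)
  expect_equal(logistic_risk(0, log(1.2), 1), 1.2 / 2.2)
  # monotone increasing in exposure for positive slope
  grid <- seq(-6, 6, length.out = 50)
  expect_true(all(diff(logistic_risk(-1, 0.7, grid)) > 0))
  # odds(x + 1) / odds(x) = exp(beta) exactly
  for (ab in list(c(-2, 0.3), c(0.5, -1.2), c(1, 2))) {
    x <- c(-3, 0, 1.7)
    odds <- function(p) p / (1 - p)
    ratio <- odds(logistic_risk(ab[1], ab[2], x + 1)) /
      odds(logistic_risk(ab[1], ab[2], x))
    expect_equal(ratio, rep(exp(ab[2]), 3))
  }
})

test_that("Gaussian-expected penetrance matches independent integration", {
  env <- std_env()
  # symmetry: alpha = 0 under a mean-zero exposure gives exactly 1/2
  expect_equal(expected_penetrance(0, 1.7, env), 0.5, tolerance = 1e-12)
  # constant integrand when beta = 0
  expect_equal(expected_penetrance(-1.3, 0, env), plogis(-1.3),
               tolerance = 1e-12)
  # trapezoid-rule oracle over mean +/- 8 sd, randomized parameter sweep
  set.seed(99)
  for (k in 1:12) {
    a <- runif(1, -4, 2); b <- runif(1, -1.5, 1.5)
    mu <- runif(1, -2, 2); sdv <- runif(1, 0.3, 2)
    e <- environment_spec(mu, sdv, 1)
    x <- seq(mu - 8 * sdv, mu + 8 * sdv, length.out = 4001)
    f <- dnorm(x, mu, sdv) * plogis(a + b * x)
    trap <- sum((f[-1] + f[-length(f)]) / 2) * diff(x[1:2])
    expect_equal(expected_penetrance(a, b, e), trap, tolerance = 1e-6)
  }
  # Monte-Carlo oracle within 3 standard errors
  set.seed(7)
  draws <- plogis(-1 + 0.5 * rnorm(2e6))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(expected_penetrance(-1, 0.5, env) - mean(draws)), 3 * se)
})

test_that("marginal risks reproduce RR and dominance by hand algebra", {
  f <- hwe_genotype_freqs(0.5)
  rec <- marginal_risks_from_rr(std_locus(rr = 2, w = 1, freq = 0.5),
                                std_locus("rsB", "G", 0.5, 2, 1),
                                f, f, m = 0.1)
  expect_equal(unname(rec$tr_a), c(0.08, 0.08, 0.16), tolerance = 1e-12)

  dom <- marginal_risks_from_rr(std_locus(rr = 2, w = 0, freq = 0.5),
                                std_locus("rsB", "G", 0.5, 2, 0),
                                f, f, m = 0.1)
  expect_equal(unname(dom$tr_a), c(0.1 / 1.75, 0.2 / 1.75, 0.2 / 1.75),
               tolerance = 1e-12)

  null <- marginal_risks_from_rr(std_locus(rr = 1, w = 0.3, freq = 0.5),
                                 std_locus("rsB", "G", 0.5, 1, 0.8),
                                 f, f, m = 0.1)
  expect_equal(unname(null$tr_a), rep(0.1, 3))
  expect_equal(unname(null$tr_b), rep(0.1, 3))

  # marginal-constraint invariant: weighted sum equals prevalence
  expect_equal(sum(rec$tr_a * f), 0.1, tolerance = 1e-12)

  # infeasible: implied high-homozygote risk above 1
  expect_error(marginal_risks_from_rr(std_locus(rr = 50, w = 1, freq = 0.05),
                                      std_locus("rsB", "G", 0.5, 1, 0.5),
                                      hwe_genotype_freqs(0.05), f, m = 0.4),
               class = "gxesim_infeasible_error")
})

test_that("independent penetrance matrix is the product/prevalence rule", {
  f <- hwe_genotype_freqs(0.5)
  marg <- marginal_risks_from_rr(std_locus(rr = 2, w = 1, freq = 0.5),
                                 std_locus("rsB", "G", 0.5, 2, 1),
                                 f, f, 0.1)
  tri <- independent_tr(marg)
  expect_equal(tri$tr[3, 3], 0.16 * 0.16 / 0.1)

  # one locus null: every row equals the other locus' marginal vector... and
  # the matrix rows are constant at tr_a
  margn <- marginal_risks_from_rr(std_locus(rr = 2, w = 1, freq = 0.5),
                                  std_locus("rsB", "G", 0.5, 1, 0.5),
                                  f, f, 0.1)
  trin <- independent_tr(margn)
  for (j in 1:3) expect_equal(unname(trin$tr[, j]), unname(margn$tr_a))

  # algebraic identities: prevalence and both marginals recovered
  s <- penetrance_summary(tri)
  expect_equal(s$prevalence, 0.1, tolerance = 1e-12)
  expect_equal(s$tr_a, unname(marg$tr_a), tolerance = 1e-10)
  expect_equal(s$tr_b, unname(marg$tr_b), tolerance = 1e-10)
})
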