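test_that("Hardy-Weinberg expansion matches hand-computed frequencies", {
  expect_equal(unname(hwe_genotype_freqs(0.5)), c(0.25, 0.50, 0.25))
  expect_equal(unname(hwe_genotype_freqs(0)), c(1, 0, 0))
  expect_equal(unname(hwe_genotype_freqs(0.3)), c(0.49, 0.42, 0.09))
  expect_equal(sum(hwe_genotype_freqs(0.123)), 1)
  expect_error(hwe_genotype_freqs(1.2), class = "gxesim_validation_error")
  expect_error(hwe_genotype_freqs(-0.1), class = "gxesim_validation_error")
})

test_that("haplotype panel reproduces the requested LD structure", {
  # independence limit
  p0 <- generate_haplotype_panel(c(3, 3), within_block_r2 = 0,
                                 allele_freqs = 0.3, pool_size = 10000,
                                 seed = 5)
  expect_lt(hap_r2(p0$haplo, 1, 2), 0.01)
  expect_lt(hap_r2(p0$haplo, 4, 5), 0.01)

  # duplication limit: equal frequencies, r2 = 1 means perfect copies
  p1 <- generate_haplotype_panel(c(3, 3), within_block_r2 = 1,
                                 allele_freqs = 0.3, pool_size = 2000,
                                 seed = 5)
  expect_identical(p1$haplo[, 1], p1$haplo[, 2])
  expect_equal(hap_r2(p1$haplo, 2, 3), 1)

  # intermediate target recovered empirically
  p8 <- generate_haplotype_panel(c(4, 4), within_block_r2 = 0.8,
                                 allele_freqs = 0.3, pool_size = 20000,
                                 seed = 7)
  adj <- rbind(c(1, 2), c(2, 3), c(3, 4), c(5, 6), c(6, 7), c(7, 8))
  r2s <- apply(adj, 1, function(ij) hap_r2(p8$haplo, ij[1], ij[2]))
  expect_lt(abs(mean(r2s) - 0.8), 0.05)

  # no LD across blocks (the DPL-independence assumption)
  cross <- expand.grid(1:4, 5:8)
  r2x <- mapply(function(i, j) hap_r2(p8$haplo, i, j), cross[, 1], cross[, 2])
  expect_lt(max(r2x), 0.01)

  # per-locus frequencies honoured within sampling error
  expect_lt(max(abs(colMeans(p8$haplo) - 0.3)), 0.02)

  # determinism and validation
  p8b <- generate_haplotype_panel(c(4, 4), within_block_r2 = 0.8,
                                  allele_freqs = 0.3, pool_size = 20000,
                                  seed = 7)
  expect_identical(p8$haplo, p8b$haplo)
  expect_error(generate_haplotype_panel(c(2, 2), 0.5, 0.3, 100, 1,
                                        n_loci = 5),
               class = "gxesim_validation_error")
})

test_that("sampling individuals gives HWE genotype codes at the DPLs", {
  da <- std_locus("rsA", "C", 0.5)
  db <- std_locus("rsB", "G", 0.5)
  panel <- generate_haplotype_panel(c(3, 3), 0.5, 0.5, pool_size = 40000,
                                    seed = 3,
                                    marker_ids = c("bg1", "rsA", "bg2",
                                                   "bg3", "rsB", "bg4"),
                                    alleles = rbind(rep("A", 6),
                                                    c("C", "C", "G",
                                                      "T", "G", "C")))
  expect_error(sample_individuals(panel, 0, da, db, 1),
               class = "gxesim_validation_error")

  pop <- sample_individuals(panel, 50000, da, db, 11)
  props <- tabulate(pop$genotype_a, 3) / pop$n
  expect_lt(max(abs(props - c(0.25, 0.5, 0.25))), 0.01)
  expect_true(all(pop$genotype_b %in% 1:3))
  expect_true(all(pop$gender %in% 1:2))

  # degenerate pool: a single haplotype carrying the high-risk allele
  panel$haplo <- matrix(1L, nrow = 1, ncol = 6)
  pop1 <- sample_individuals(panel, 20, da, db, 1)
  expect_true(all(pop1$genotype_a == 3L))
  expect_true(all(pop1$genotype_b == 3L))
})

test_that("exposure assignment follows the declared distributions", {
  panel <- generate_haplotype_panel(c(2, 2), 0, 0.3, pool_size = 500,
                                    seed = 1,
                                    marker_ids = c("rsA", "b1", "rsB", "b2"),
                                    alleles = rbind(rep("A", 4),
                                                    c("C", "T", "G", "T")))
  pop <- sample_individuals(panel, 100000, std_locus(), std_locus("rsB", "G"),
                            seed = 2)

  tight <- assign_exposures(pop, environment_spec(3, 1e-9, 1.2), seed = 4)
  expect_lt(max(abs(tight$exposure - 3)), 1e-6)

  pop <- assign_exposures(pop, std_env(),
                          noise = list(noise_spec("bin", "binomial",
                                                  size = 1, prob = 0.3),
                                       noise_spec("uni", "uniform",
                                                  low = -1, high = 1)),
                          seed = 4)
  expect_lt(abs(mean(pop$exposure)), 0.02)
  expect_lt(abs(stats::sd(pop$exposure) - 1), 0.02)
  expect_lt(abs(mean(pop$noise$bin) - 0.3), 0.01)
  expect_true(all(pop$noise$uni >= -1 & pop$noise$uni <= 1))

  # bit-for-bit reproducibility under the same seed
  pop2 <- assign_exposures(pop, std_env(),
                           noise = list(noise_spec("bin", "binomial",
                                                   size = 1, prob = 0.3),
                                        noise_spec("uni", "uniform",
                                                   low = -1, high = 1)),
                           seed = 4)
  expect_identical(pop$exposure, pop2$exposure)
  expect_identical(pop$noise, pop2$noise)
})

test_that("observed DPL genotype frequencies are exact count ratios", {
  pop <- tiny_population(ga = rep(2, 10), gb = rep(1, 10))
  expect_equal(unname(estimate_dpl_freqs(pop, "a")), c(0, 1, 0))

  pop2 <- tiny_population(ga = rep(1:3, c(49, 42, 9)),
                          gb = rep(1, 100))
  expect_equal(unname(estimate_dpl_freqs(pop2, "a")), c(0.49, 0.42, 0.09))
  expect_equal(sum(estimate_dpl_freqs(pop2, "rsA")), 1)
  expect_error(estimate_dpl_freqs(pop2, "nope"),
               class = "gxesim_validation_error")
  expect_error(estimate_dpl_freqs(tiny_population(integer(), integer())),
               class = "gxesim_validation_error")
})
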