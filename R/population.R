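## Generation (or ingestion) of individual-level genotype and exposure data
## with the statistical structure the penetrance model assumes: Hardy-
## Weinberg equilibrium within each locus, tunable LD between background
## markers, and no LD between the two disease-predisposing loci.

#' Hardy-Weinberg genotype frequencies
#'
#' Expands an allele frequency into the three genotype frequencies under
#' Hardy-Weinberg equilibrium, ordered by high-risk allele count:
#' `((1 - q)^2, 2 q (1 - q), q^2)` where `q` is the high-risk allele
#' frequency.
#'
#' @param allele_freq frequency of the high-risk allele, in `[0, 1]`.
#' @return numeric vector of length 3 summing to 1, named `g1`, `g2`, `g3`.
#' @examples
#' hwe_genotype_freqs(0.3)  # c(0.49, 0.42, 0.09)
#' @export
hwe_genotype_freqs <- function(allele_freq) {
  q <- check_number(allele_freq, "allele_freq", 0, 1)
  c(g1 = (1 - q)^2, g2 = 2 * q * (1 - q), g3 = q^2)
}

#' Generate a pool of phased haplotypes with block LD structure
#'
#' Builds a haplotype pool as a block mosaic: loci within a block form a
#' first-order Markov chain whose adjacent-pair correlation is
#' `sqrt(within_block_r2)` (so adjacent r-squared is `within_block_r2` and
#' r-squared decays geometrically with distance), while loci in different
#' blocks are independent.  Each locus keeps its requested allele frequency
#' exactly in expectation.  This stands in for demographic forward-time
#' simulation: downstream, the penetrance model only needs realistic allele
#' frequencies and tunable LD, and it assumes the two DPLs are unlinked,
#' which is guaranteed by placing them in different blocks.
#'
#' When the requested adjacent correlation is infeasible for a pair of
#' unequal allele frequencies (the Frechet bounds on the joint probability),
#' the correlation is clamped to the closest attainable value and a warning
#' is issued.
#'
#' @param block_lengths integer vector, number of loci per block.
#' @param within_block_r2 target adjacent-pair r-squared within a block, in
#'   `[0, 1]`.
#' @param allele_freqs per-locus frequency of the coded (alternate) allele,
#'   each in `(0, 1)`; recycled if scalar.
#' @param pool_size number of haplotypes in the pool.
#' @param seed integer seed; the pool is deterministic given the seed.
#' @param n_loci optional; if given, must equal `sum(block_lengths)`.
#' @param marker_ids optional marker identifiers (default `snp1`, `snp2`, ...).
#' @param alleles optional 2 x n_loci character matrix of allele symbols;
#'   row 2 is the coded allele.  Defaults to a deterministic A/C, A/G, ...
#'   rotation.
#' @return an object of class `hap_panel` with fields `n_loci`, `marker_ids`,
#'   `block`, `positions`, `alleles`, `freq`, and the 0/1 pool matrix
#'   `haplo` (`pool_size` rows; 1 codes the alternate allele).
#' @examples
#' p <- generate_haplotype_panel(c(3, 3), within_block_r2 = 0.8,
#'                               allele_freqs = 0.3, pool_size = 1000,
#'                               seed = 1)
#' dim(p$haplo)
#' @export
generate_haplotype_panel <- function(block_lengths, within_block_r2,
                                     allele_freqs, pool_size, seed,
                                     n_loci = NULL, marker_ids = NULL,
                                     alleles = NULL) {
  block_lengths <- vapply(block_lengths, check_count, integer(1),
                          name = "block_lengths")
  L <- sum(block_lengths)
  if (!is.null(n_loci) && check_count(n_loci, "n_loci") != L)
    stop_gxe("n_loci (%d) does not match sum(block_lengths) (%d)",
             n_loci, L, class = "gxesim_validation_error")
  check_number(within_block_r2, "within_block_r2", 0, 1)
  if (length(allele_freqs) == 1L) allele_freqs <- rep(allele_freqs, L)
  if (length(allele_freqs) != L)
    stop_gxe("allele_freqs must have length 1 or %d", L,
             class = "gxesim_validation_error")
  for (q in allele_freqs)
    check_number(q, "allele_freqs", 0, 1, strict_lower = TRUE,
                 strict_upper = TRUE)
  pool_size <- check_count(pool_size, "pool_size")

  if (is.null(marker_ids)) marker_ids <- paste0("snp", seq_len(L))
  if (anyDuplicated(marker_ids))
    stop_gxe("marker_ids must be unique", class = "gxesim_validation_error")
  if (is.null(alleles)) {
    others <- rep(c("C", "G", "T"), length.out = L)
    alleles <- rbind(ref = rep("A", L), alt = others)
  }
  stopifnot(nrow(alleles) == 2L, ncol(alleles) == L)

  block <- rep(seq_along(block_lengths), block_lengths)
  # 1-based coordinates, strictly increasing within each block region
  positions <- unlist(lapply(block_lengths, function(k) {
    1000L + 5000L * (seq_len(k) - 1L)
  }), use.names = FALSE)

  r_adj <- sqrt(within_block_r2)
  set.seed(split_seed(seed, 1L))
  H <- matrix(0L, nrow = pool_size, ncol = L)
  for (b in seq_along(block_lengths)) {
    idx <- which(block == b)
    q1 <- allele_freqs[idx[1L]]
    H[, idx[1L]] <- as.integer(stats::runif(pool_size) < q1)
    for (j in idx[-1L]) {
      qp <- allele_freqs[j - 1L]; qc <- allele_freqs[j]
      # joint P(prev = 1, cur = 1) achieving correlation r_adj, clamped to
      # the Frechet feasibility bounds
      p11 <- r_adj * sqrt(qp * (1 - qp) * qc * (1 - qc)) + qp * qc
      lo <- max(0, qp + qc - 1); hi <- min(qp, qc)
      if (p11 > hi + 1e-12 || p11 < lo - 1e-12)
        warning(sprintf(
          "adjacent r2 %.3g infeasible for freqs (%.3g, %.3g); clamped",
          within_block_r2, qp, qc))
      p11 <- min(max(p11, lo), hi)
      p_given1 <- if (qp > 0) p11 / qp else 0
      p_given0 <- if (qp < 1) (qc - p11) / (1 - qp) else 0
      u <- stats::runif(pool_size)
      prev <- H[, j - 1L]
      H[, j] <- as.integer(u < ifelse(prev == 1L, p_given1, p_given0))
    }
  }
  structure(list(n_loci = L, marker_ids = marker_ids, block = block,
                 positions = positions, alleles = alleles,
                 freq = allele_freqs, within_block_r2 = within_block_r2,
                 haplo = H),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf(
    "Haplotype panel: %d loci in %d block(s), pool of %d haplotypes\n",
    x$n_loci, length(unique(x$block)), nrow(x$haplo)))
  invisible(x)
}

# number of copies of the high-risk allele coded by each pool entry value
.risk_indicator <- function(panel, marker_id, high_risk_allele) {
  j <- match(marker_id, panel$marker_ids)
  if (is.na(j))
    stop_gxe("marker \"%s\" not found in the panel", marker_id,
             class = "gxesim_validation_error")
  if (!high_risk_allele %in% panel$alleles[, j])
    stop_gxe("high-risk allele %s is not an allele of marker %s (%s/%s)",
             high_risk_allele, marker_id, panel$alleles[1L, j],
             panel$alleles[2L, j], class = "gxesim_validation_error")
  list(col = j, alt_is_risk = panel$alleles[2L, j] == high_risk_allele)
}

#' Sample diploid individuals from a haplotype pool
#'
#' Each individual receives two haplotypes drawn independently and uniformly
#' (with replacement) from the pool -- random union of gametes, so each locus
#' is in Hardy-Weinberg proportions at the pool's realised allele frequency.
#' DPL genotypes are coded 1/2/3 as 1 + number of high-risk alleles carried.
#' Gender is assigned Bernoulli(0.5) with labels 1/2; it never enters the
#' risk model.
#'
#' @param panel a `hap_panel`.
#' @param n number of individuals, `>= 1`.
#' @param dpl_a,dpl_b `locus_spec` objects naming the two DPLs; must refer
#'   to markers present in the panel (and should lie in different blocks so
#'   that the no-LD-between-DPLs assumption holds).
#' @param seed integer seed.
#' @return an object of class `gxe_population`.
#' @export
sample_individuals <- function(panel, n, dpl_a, dpl_b, seed) {
  stopifnot(inherits(panel, "hap_panel"),
            inherits(dpl_a, "locus_spec"), inherits(dpl_b, "locus_spec"))
  n <- check_count(n, "n")
  if (nrow(panel$haplo) < 1L)
    stop_gxe("haplotype pool is empty", class = "gxesim_validation_error")
  ia <- .risk_indicator(panel, dpl_a$marker_id, dpl_a$high_risk_allele)
  ib <- .risk_indicator(panel, dpl_b$marker_id, dpl_b$high_risk_allele)
  if (panel$block[ia$col] == panel$block[ib$col] && ia$col != ib$col)
    warning("both DPLs lie in the same LD block; the model assumes unlinked DPLs")

  set.seed(split_seed(seed, 1L))
  i1 <- sample.int(nrow(panel$haplo), n, replace = TRUE)
  i2 <- sample.int(nrow(panel$haplo), n, replace = TRUE)
  gender <- 1L + stats::rbinom(n, 1L, 0.5)
  h1 <- panel$haplo[i1, , drop = FALSE]
  h2 <- panel$haplo[i2, , drop = FALSE]

  risk_copies <- function(ind) {
    a <- h1[, ind$col] + h2[, ind$col]       # copies of the alternate allele
    if (ind$alt_is_risk) a else 2L - a
  }
  structure(list(
    n = n,
    panel = panel[c("n_loci", "marker_ids", "block", "positions",
                    "alleles", "freq")],
    h1 = h1, h2 = h2,
    dpl_a = dpl_a, dpl_b = dpl_b,
    genotype_a = 1L + risk_copies(ia),
    genotype_b = 1L + risk_copies(ib),
    exposure = NULL, noise = NULL,
    gender = gender, status = NULL
  ), class = "gxe_population")
}

#' @export
print.gxe_population <- function(x, ...) {
  cat(sprintf("Simulated population: %d individuals, %d markers\n",
              x$n, length(x$panel$marker_ids)))
  cat(sprintf("  DPLs: %s, %s\n", x$dpl_a$marker_id, x$dpl_b$marker_id))
  if (!is.null(x$exposure)) cat("  exposures assigned\n")
  if (!is.null(x$status))
    cat(sprintf("  disease status assigned (%d affected)\n", sum(x$status)))
  invisible(x)
}

#' Assign environmental exposures to a population
#'
#' Draws the causal exposure i.i.d. from the Gaussian distribution in `env`
#' and each noise variable i.i.d. from its declared family.  Deterministic
#' given the seed; each variable consumes its own sub-seed.
#'
#' @param pop a `gxe_population`.
#' @param env an `environment_spec`.
#' @param noise list of `noise_spec` objects (may be empty).
#' @param seed integer seed.
#' @return the population with `exposure` and `noise` filled in.
#' @export
assign_exposures <- function(pop, env, noise = list(), seed) {
  stopifnot(inherits(pop, "gxe_population"), inherits(env, "environment_spec"))
  seeds <- split_seed(seed, 1L + length(noise))
  set.seed(seeds[1L])
  pop$exposure <- stats::rnorm(pop$n, env$mean, env$sd)
  pop$env <- env
  if (length(noise)) {
    cols <- vector("list", length(noise))
    for (k in seq_along(noise)) {
      nv <- noise[[k]]
      stopifnot(inherits(nv, "noise_spec"))
      set.seed(seeds[1L + k])
      cols[[k]] <- switch(nv$family,
        gaussian = stats::rnorm(pop$n, nv$params$mean, nv$params$sd),
        uniform  = stats::runif(pop$n, nv$params$low, nv$params$high),
        binomial = stats::rbinom(pop$n, nv$params$size, nv$params$prob))
    }
    names(cols) <- vapply(noise, `[[`, character(1), "name")
    pop$noise <- as.data.frame(cols)
  } else {
    pop$noise <- NULL
  }
  pop
}

#' Observed genotype frequencies at a DPL
#'
#' Tabulates the genotype code proportions (1 = low-risk homozygote,
#' 2 = heterozygote, 3 = high-risk homozygote) observed in the population at
#' one of the two DPLs.
#'
#' @param pop a `gxe_population` with genotypes assigned.
#' @param which `"a"`, `"b"`, or a DPL marker id.
#' @return numeric vector of length 3 summing to 1.
#' @export
estimate_dpl_freqs <- function(pop, which = "a") {
  stopifnot(inherits(pop, "gxe_population"))
  if (pop$n < 1L)
    stop_gxe("population is empty", class = "gxesim_validation_error")
  g <- if (identical(which, "a") || identical(which, pop$dpl_a$marker_id)) {
    pop$genotype_a
  } else if (identical(which, "b") || identical(which, pop$dpl_b$marker_id)) {
    pop$genotype_b
  } else {
    stop_gxe("unknown locus selector \"%s\"", which,
             class = "gxesim_validation_error")
  }
  counts <- tabulate(g, nbins = 3L)
  stats::setNames(counts / sum(counts), c("g1", "g2", "g3"))
}
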