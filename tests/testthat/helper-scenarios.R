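# Shared builders for the standard two-locus scenario used across tests:
# prevalence 0.1, allele frequency 0.3 at both DPLs, RR = 1.6, W = 0.5
# (co-dominant), Gaussian(0, 1) exposure with OR 1.2 per unit.

std_locus <- function(id = "rsA", allele = "C", freq = 0.3, rr = 1.6,
                      w = 0.5) {
  locus_spec(id, allele, freq, rr, w)
}

std_env <- function(or = 1.2) environment_spec(mean = 0, sd = 1,
                                               or_per_unit = or)

std_tri <- function(rr = 1.6, w = 0.5, q = 0.3, m = 0.1) {
  f <- hwe_genotype_freqs(q)
  independent_tr(marginal_risks_from_rr(std_locus("rsA", "C", q, rr, w),
                                        std_locus("rsB", "G", q, rr, w),
                                        f, f, m))
}

std_config <- function(n = 20000, rr = 1.6, w = 0.5, q = 0.3, m = 0.1,
                       or = 1.2, model = "ADD",
                       epistasis = epistasis_spec(), seed = 1,
                       pool_size = 10000, ...) {
  run_config(m, std_locus("rsA", "C", q, rr, w),
             std_locus("rsB", "G", q, rr, w), std_env(or),
             gxe_model = model, epistasis = epistasis,
             n_individuals = n, panel = list(pool_size = pool_size),
             seed = seed, ...)
}

# Empirical r^2 between two 0/1 haplotype columns
hap_r2 <- function(h, i, j) stats::cor(h[, i], h[, j])^2

# Minimal hand-built population for counting-level tests
tiny_population <- function(ga, gb, exposure = rep(0, length(ga)),
                            status = NULL) {
  n <- length(ga)
  structure(list(
    n = n,
    panel = list(n_loci = 2L, marker_ids = c("rsA", "rsB"),
                 block = 1:2, positions = c(1L, 1L),
                 alleles = cbind(c("A", "C"), c("A", "G")),
                 freq = c(0.3, 0.3)),
    h1 = NULL, h2 = NULL,
    dpl_a = std_locus("rsA", "C"), dpl_b = std_locus("rsB", "G"),
    genotype_a = as.integer(ga), genotype_b = as.integer(gb),
    exposure = exposure, noise = NULL,
    gender = rep(1L, n), status = status),
    class = "gxe_population")
}

# Constant-coefficient MLM object (bypasses the solver) for degenerate
# status-assignment checks
const_coeffs <- function(alpha, beta = 0, env = std_env()) {
  structure(list(alpha = matrix(alpha, 3, 3), beta = matrix(beta, 3, 3),
                 model = "GEN", beta_ab = beta, anchor = c(3L, 3L),
                 env = env),
            class = "mlm_coefficients")
}

# Variance of relative increments over the non-user cells: the objective
# the epistasis completion minimises (recomputed independently here)
delta_objective <- function(delta_vec, tri_vec, free_idx) {
  r <- delta_vec[free_idx] / tri_vec[free_idx]
  mean(r^2) - mean(r)^2
}

# Independent grid-search oracle for the completion problem: parameterise
# the affine feasible set by its null-space coordinates (via SVD) and
# minimise the variance-of-ratios objective by a coarse grid with repeated
# local refinement.
oracle_delta_objective <- function(tri, spec) {
  TRI <- tri$tr; pa <- tri$freqs_a; pb <- tri$freqs_b
  A <- matrix(0, 6, 9)
  for (i in 1:3) for (j in 1:3) {
    v <- (j - 1) * 3 + i
    A[i, v] <- pb[j]; A[3 + j, v] <- pa[i]
  }
  dvec <- rep(0, 9); fixed <- rep(FALSE, 9)
  for (k in seq_len(nrow(spec))) {
    v <- (spec$col[k] - 1) * 3 + spec$row[k]
    fixed[v] <- TRUE
    dvec[v] <- spec$percent[k] / 100 * TRI[spec$row[k], spec$col[k]]
  }
  free <- which(!fixed)
  Af <- A[, free, drop = FALSE]
  b <- as.vector(-A[, fixed, drop = FALSE] %*% dvec[fixed])
  sv <- svd(Af, nu = nrow(Af), nv = ncol(Af))
  r <- sum(sv$d > max(sv$d) * 1e-10)
  xp <- sv$v[, 1:r] %*% ((t(sv$u[, 1:r]) %*% b) / sv$d[1:r])
  N <- sv$v[, seq(r + 1, ncol(Af)), drop = FALSE]
  lo <- pmax(-1, -as.vector(TRI))[free]
  up <- pmin(1, 1 - as.vector(TRI))[free]
  obj <- function(z) {
    x <- xp + N %*% z
    if (any(x < lo - 1e-9) || any(x > up + 1e-9)) return(Inf)
    d <- dvec; d[free] <- x
    delta_objective(d, as.vector(TRI), free)
  }
  ndim <- ncol(N)
  centre <- rep(0, ndim); width <- 0.4
  best <- obj(centre); bestz <- centre
  for (lev in 1:6) {
    pts <- as.matrix(expand.grid(rep(list(seq(-width, width,
                                              length.out = 7)), ndim)))
    for (p in seq_len(nrow(pts))) {
      z <- centre + pts[p, ]
      v <- obj(z)
      if (v < best) { best <- v; bestz <- z }
    }
    centre <- bestz; width <- width / 3
  }
  best
}

# One random feasible completion instance (shared by the module and
# acceptance property suites)
random_delta_instance <- function() {
  q1 <- runif(1, 0.2, 0.8); q2 <- runif(1, 0.2, 0.8)
  rr1 <- runif(1, 1, 2); rr2 <- runif(1, 1, 2)
  w1 <- runif(1); w2 <- runif(1); m <- runif(1, 0.05, 0.15)
  f1 <- hwe_genotype_freqs(q1); f2 <- hwe_genotype_freqs(q2)
  tri <- independent_tr(marginal_risks_from_rr(
    locus_spec("rsA", "C", q1, rr1, w1),
    locus_spec("rsB", "G", q2, rr2, w2), f1, f2, m))
  nu <- sample(0:2, 1)
  spec <- if (nu == 0) epistasis_spec() else if (nu == 1) {
    epistasis_spec(data.frame(row = sample(3, 1), col = sample(3, 1),
                              percent = runif(1, -30, 30)))
  } else {
    r0 <- sample(3, 1); cs <- sample(3, 2)
    epistasis_spec(data.frame(row = r0, col = cs,
                              percent = runif(2, -30, 30)))
  }
  list(tri = tri, spec = spec, f1 = f1, f2 = f2)
}
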