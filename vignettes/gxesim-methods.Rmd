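---
title: "Designing two-locus gene-environment simulations with gxesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing two-locus gene-environment simulations with gxesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxesim)
```

# The model and its assumptions

`gxesim` simulates a complex disease whose risk depends on two bi-allelic
disease-predisposing loci (DPLs) and one continuous environmental exposure.
Risk is a *multi-logistic model*: each of the nine combined genotypes
$(g_a, g_b)$ owns a logistic curve in the exposure $x$,

$$P(\text{affected} \mid g_a, g_b, x) =
  \left[1 + e^{-(\alpha(g_a,g_b) + \beta(g_a,g_b)x)}\right]^{-1}.$$

Three structural assumptions underlie the parameter translation:

1. genetics can act directly on risk or by modulating the environmental
   effect;
2. the two loci either act independently or interact epistatically, the
   latter expressed as a deformation of the independent model;
3. the two DPLs are not in linkage disequilibrium with each other (the
   built-in genotype generator enforces this by placing them in separate,
   mutually independent haplotype blocks).

**Sign convention.** We parameterise the logistic with $-(\alpha + \beta x)$
in the exponent, so that $\text{odds}(x+1)/\text{odds}(x) = e^{\beta}$
holds exactly and the user-facing statement "$\beta_{AB}$ is the natural
logarithm of the per-unit odds ratio" is literally true. With the opposite
sign the odds would *decrease* in $\alpha + \beta x$, contradicting the
odds-ratio semantics of the input; every printed coefficient table states
risks under this convention.

# From epidemiological inputs to the penetrance matrix

## Marginal risks

Each locus is described by its genotypic relative risk $RR$ (high-risk over
low-risk homozygote) and a dominance weight $W \in [0, 1]$. The heterozygote
risk is interpolated linearly between the homozygote risks,

$$TR_2 = W \cdot TR_1 + (1 - W) \cdot TR_3,$$

which reproduces the stated endpoints: $W = 0$ makes the high-risk allele
dominant (heterozygote risk equals the high-risk homozygote's), $W = 1$
recessive, and intermediate values co-dominant. The overall scale is pinned
by the prevalence constraint $\sum_g TR_g P_g = m$, where the genotype
frequencies $P_g$ are Hardy-Weinberg expansions of the allele frequencies
(or observed frequencies when a population is supplied). If the implied
high-homozygote risk exceeds 1 the configuration is rejected as infeasible
rather than truncated.

## The independent two-locus matrix

Under conditional independence of the two loci given disease status,
$TR^I(g_a, g_b) = TR_{g_a} TR_{g_b} / m$. This matrix reproduces both sets
of single-locus marginals and the prevalence by construction; the package
re-verifies these identities to 1e-10 after every build.

## Epistasis as constrained deformation

An epistasis specification assigns percent changes to at most three cells
of $TR^I$; pairs of specified cells must share a row or a column. The
increment matrix $\Delta$ must satisfy, for every row $g_a$ and column
$g_b$,

$$\sum_{g_b} \Delta(g_a, g_b) P_{g_b} = 0, \qquad
  \sum_{g_a} \Delta(g_a, g_b) P_{g_a} = 0,$$

together with $0 \le TR^I + \Delta \le 1$. These conditions are exactly
marginal-risk (and hence prevalence) preservation. User cells are fixed at
$\Delta = (\text{percent}/100) \cdot TR^I$ and never projected; remaining
cells minimise the variance of the relative increments
$\Delta / TR^I$ over the non-user cells, so that unconstrained genotypes
keep their mutual risk relationships as far as possible.

Numerically this is a convex quadratic program in at most nine variables:
the equality constraints are eliminated against the objective through a
dense KKT solve, and the box constraints are handled by an active-set loop
(add the most violated bound, re-solve, release wrongly-signed multipliers).
Determinism follows from convexity: whenever the feasible set is non-empty
the unique minimiser is returned, and an inconsistent specification — for
example a fully fixed row whose weighted sum cannot vanish — raises a
structured infeasibility error instead of silently relaxing user values.

A counting remark: the six weighted-sum conditions have rank five, so with
$k$ user cells the feasible set generically has $4 - k$ degrees of freedom.
Three user entries therefore do *not* always pin a unique completion — a
valid triple occupies a full row or column and must itself satisfy that
line's zero-sum condition; when it does, the optimizer simply returns the
(often one-dimensional family's) variance minimiser. We trust this
constraint algebra throughout and let the optimizer resolve any residual
freedom.

Cells with $TR^I = 0$ are excluded from the objective (their relative
increment is undefined) and pinned to $\Delta = 0$ with a warning.

# Solving the logistic coefficients

The total risk of a cell under a Gaussian exposure $X \sim N(\mu, \sigma^2)$
is $TR = E[\text{logistic}(\alpha + \beta X)]$, evaluated by 96-node
Gauss-Hermite quadrature on the untruncated real line. The integrand is
smooth, and at the coefficient magnitudes this model produces
($|\alpha|, |\beta\sigma| \lesssim 20$) the quadrature error is far below
1e-10; the test suite cross-checks it against trapezoid integration over
$\mu \pm 8\sigma$ and Monte-Carlo sampling.

The four gene-environment models constrain the nine $(\alpha, \beta)$ pairs
as follows, with $\beta_{AB} = \ln(\text{OR per unit})$ attached by
convention to the highest-risk cell (ties broken toward $(3,3)$, then
row-major order):

* **GEN** — genetics only: $\beta \equiv 0$, $\alpha = \text{logit}(TR)$ in
  closed form.
* **ENV** — environment only: one shared $(\alpha, \beta_{AB})$; requires a
  constant $TR$ matrix (set $RR = 1$ at both loci, no epistasis), otherwise
  a model-inconsistency error is raised.
* **ADD** — additive: shared slope $\beta_{AB}$, per-cell intercepts; nine
  independent one-dimensional root-finds in $\alpha$ (the expectation is
  strictly increasing in $\alpha$; bracketed bisection to 1e-13).
* **GEM** — modulative: shared intercept, per-cell slopes. The anchor cell's
  equation involves only $\alpha$ and $\beta_{AB}$ and so determines the
  shared intercept by a single root-find; each remaining cell's slope then
  solves its own one-dimensional equation, preferring the sign of
  $\beta_{AB}$. This sequential scheme solves the coupled system exactly —
  the anchor equation is the only one binding $\alpha$ — and is more robust
  than a joint Newton iteration on nine unknowns.

**A feasibility caveat for GEM.** With a mean-zero exposure, varying the
slope at fixed intercept can only move a cell's total risk from the basal
value $\text{logit}^{-1}(\alpha)$ toward 0.5. If the anchor cell's risk is,
say, 0.18 under a modest odds ratio, the shared basal risk sits just below
0.18, and cells with much smaller targets are unreachable: the modulative
model is then genuinely infeasible, and the solver says so with a
diagnostic rather than returning a best fit. GEM configurations become
solvable when the exposure mean is displaced from zero (the slope then also
shifts the effective intercept); the round-trip tests exercise GEM with a
$N(2, 0.5^2)$ exposure for this reason.

Every solve is verified by round-tripping: the quadrature of the returned
coefficients must reproduce each target cell to 1e-8, and the implied
prevalence is re-checked to 1e-7.

# The synthetic genotype generator

The built-in generator produces a pool of phased haplotypes organised in
blocks. Within a block, loci form a first-order Markov chain whose
adjacent-pair correlation is $\sqrt{r^2_{\text{target}}}$ — the joint
probability of adjacent alternate alleles is set from the exact binary-
correlation formula and clamped to the Fréchet bounds when the requested
correlation is infeasible for unequal frequencies — so adjacent $r^2$
matches the request and decays geometrically with distance. Blocks are
mutually independent, and the two DPLs are placed in different blocks,
which is what the penetrance model's no-LD-between-DPLs assumption needs.
Individuals are formed by random union of two gametes drawn uniformly from
the pool, giving Hardy-Weinberg genotype proportions at every locus.

This emulates the features downstream code relies on — controllable allele
frequencies, tunable local LD, unlinked DPLs — but *not* demographic
history: no recombination maps, no allele-frequency spectra from drift, no
population structure, no long-range LD. Passing tests therefore demonstrate
correctness of the risk model and its parameter translation on idealised
genetic backgrounds, not robustness to the LD complexity of real cohorts;
users who need realistic backgrounds can ingest external genotype tables
(`read_genotype_table()`), which are accepted as-is without enforcing
Hardy-Weinberg equilibrium or cross-locus independence.

Defaults: two blocks of five loci, background alternate-allele frequency
0.25, within-block adjacent $r^2 = 0.5$, pool of 10,000 haplotypes — a
small flanking-marker panel typical of a fine-mapped region, large enough
that pool-resampling noise is negligible next to gamete-sampling noise.

# Exposures, status, and subsampling

The causal exposure is i.i.d. Gaussian; validation experiments standardise
on $N(0, 1)$, since only the pair $(\beta\sigma, \alpha + \beta\mu)$ is
identified — any other choice rescales coefficients without changing the
realised risks. Noise exposures (Gaussian, uniform or binomial) and a
Bernoulli(0.5) gender label are carried through to the output but never
enter the risk model. Disease status is assigned by comparing each
individual's risk — its genotype's logistic curve evaluated at its exposure
— with one uniform draw.

Case-control replicates are drawn **without replacement within a
replicate** and independently across replicates, matching case-control
study design while letting replicate sets act as bootstrap resamples of the
same design; requested counts are enforced exactly, and a population that
cannot supply them produces an error (the documented remedy is a larger
base population, not silent re-simulation).

Reproducibility: one master seed is split into per-stage sub-seeds (pool,
gametes, each exposure variable, status, each replicate) by a fixed integer
recurrence, so the entire run — including every output file — is
deterministic given the configuration, and any stage can be replayed in
isolation.

# Validation design and problem sizes

The shipped checks run three experiment families, chosen to probe each
claim of the design at sizes where binomial error bars are decisive while
keeping the suite quick:

* *solver mathematics* — exact checks (deformation ratios, marginal
  conservation to 1e-9, quadrature round-trips to 1e-8) and agreement of
  the completion with an independent grid-search oracle on twenty random
  small instances;
* *environmental effect* — logistic regression of status on exposure and
  genotype codes in an additive-model population of 50,000 recovers the
  designed odds ratio (estimated standard error ≈ 0.018 on the OR scale);
* *genetic and epistatic effects* — observed homozygote penetrance ratios
  at n = 200,000 recover the designed relative risk, and a pure-epistasis
  design ($RR = 1$, +20% on the $(3,3)$ cell) shows flat marginals with the
  designed excess confined to the $(3,3)$ genotype.

# Known limitations

* Exactly two DPLs and one causal exposure; the exposure must be Gaussian.
* The four predefined interaction models are exhaustive; no user-defined
  coupling surfaces.
* GEM is infeasible for spread-out penetrance matrices under mean-zero
  exposures (see above) — this is a property of the model, not of the
  solver.
* Risks do not vary with gender or age; gender is a passive output column.
* The genotype generator's LD is first-order within blocks; it cannot
  reproduce empirical LD maps.
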