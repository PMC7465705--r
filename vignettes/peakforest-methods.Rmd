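---
title: "Robust QTL detection with spline peaks and random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust QTL detection with spline peaks and random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakforest)
```

## The problem

Single-SNP genome-wide association scans for quantitative traits miss many
real signals: loci with small effects rarely clear a genome-wide
significance threshold, even though groups of neighbouring SNPs in linkage
disequilibrium (LD) jointly carry evidence of association. `peakforest`
implements a six-phase framework that aggregates single-SNP test
statistics along the genome, calls quantitative trait loci (QTLs) as
spline peaks that are higher than expected by chance, independently ranks
SNPs with a random-forest wrapper, and reports the intersection — SNPs
that are both inside a validated QTL and confirmed as predictive — as
*robust SNPs*.

## The six phases

**Phase 1 — mixed-model scan.** For each SNP the model is

$$y = W\alpha + x\beta + u + \epsilon, \qquad
u \sim N(0, K V_g), \quad \epsilon \sim N(0, I V_e),$$

where $y$ is the phenotype vector, $W$ a covariate matrix (intercept plus
the top five principal components of the LD-pruned genotypes), $x$ the
dosage vector of the tested SNP, $K$ the genomic relationship matrix
$ZZ'/m$ built from column-standardized dosages, and $V_g, V_e$ the
polygenic and residual variance components. The variance ratio
$\delta = V_e/V_g$ is estimated once on the null model by restricted
maximum likelihood (1-D profile over a log grid with golden-section
refinement, on the eigenbasis of $K$), then held fixed for all SNPs — the
single-fit approximation that makes the scan cheap enough to repeat over
a thousand permutations. A flag (`exact_per_snp`) re-estimates the
components per SNP for small data. Each SNP is summarized by the Wald
statistic $F_{Wald} = \hat\beta^2/\mathrm{Var}(\hat\beta)$ with a
$\chi^2_1$ upper-tail p-value. Per-SNP significance thresholds come from
the effective number of tests (simpleM): per block of up to 1000
consecutive SNPs, the smallest count of leading eigenvalues of the SNP
correlation matrix capturing 99.5% of its trace; genome-wide threshold
$0.05/m_{\mathrm{eff}}$, suggestive threshold $1/m_{\mathrm{eff}}$ (their
ratio is exactly 20). The genomic inflation factor (median observed
$\chi^2_1$ quantile over 0.4549) is reported as a calibration diagnostic.

**Phase 2 — smoothing.** Per chromosome, a natural cubic smoothing spline
$g$ is fitted to the Wald statistics $y_i$ at marker positions $x_i$,
minimizing

$$S(g) = \sum_i \{y_i - g(x_i)\}^2 + \lambda \int g''(x)^2\,dx .$$

**Phase 3 — peaks.** The second derivative of the fitted spline is
piecewise linear, so its zero crossings (the inflection points) are found
exactly. Every maximal interval between consecutive inflection points (or
a chromosome end) on which $g'' < 0$ is a peak; the peak height is the
maximum of $g$ on the interval, found analytically from the cubic pieces.
A concave-down segment truncated by a chromosome end still counts as a
peak (flagged as a boundary peak) so terminal QTLs are not blind spots.

**Phase 4 — permutation null.** The phenotype vector is permuted `B`
times (default 1000). Each permutation re-runs phases 1–3 in full — REML
re-fit of $\delta$, Wald scan, per-chromosome spline with freshly
selected $\lambda$ — and records the genome-wide maximum peak height. The
QTL threshold is the 95th percentile of these maxima (linear
interpolation between order statistics, R quantile type 7); an observed
peak is a QTL only if its height **strictly** exceeds the threshold.
Recording one genome-wide maximum per permutation makes the call
family-wise: the probability of any false QTL anywhere in the genome is
controlled near 5%.

**Phase 5 — Boruta.** Independently of the scan, a regression random
forest estimates each SNP's permutation importance, and the Boruta
wrapper classifies SNPs as Confirmed/Tentative/Rejected: each iteration
adds a shuffled "shadow" copy of every feature still in play, a feature
scores a hit when it out-ranks the best shadow, and running binomial
tests (at $\alpha = 0.01$, Bonferroni-corrected over the feature count)
confirm or reject features; undecided features after `max_iterations`
(default 100) are Tentative.

**Phase 6 — robust SNPs.** SNPs that are Boruta-Confirmed *and* located
inside a QTL interval (1-based inclusive) are the robust SNPs. They are
annotated with LD profiles around the peak's top-Wald SNP, per-genotype
phenotype comparisons (pairwise Welch t-tests with the usual star codes;
Tukey HSD available), and gene intervals: a gene is reported only if it
harbours at least one robust SNP within its boundaries.

## Worked example

```{r example, eval = FALSE}
sp <- sim_spec(n_samples = 600, n_snps = 3000, n_chrom = 20,
               h2_polygenic = 0.3,
               qtl_list = data.frame(snp_index = 1510,
                                     beta = qtl_beta(0.10, 0.3, 1)),
               seed = 1)
G  <- simulate_genotypes(sp)
ph <- simulate_phenotype(G, sp)
res <- run_pipeline(G, ph,
                    config = pf_config(B = 200, seed = 2,
                                       boruta = boruta_config(
                                         n_trees = 300,
                                         max_iterations = 100, seed = 2)))
res
```

## The synthetic-data generator

Real genotype/phenotype panels of the kind this framework targets
(hundreds of birds typed on a 600K array, with de-regressed breeding
values as pseudo-phenotypes) are proprietary, so the package ships a
generator that reproduces the *statistical* structure every stage relies
on:

* **LD blocks from a haplotype pool.** Each block of `block_length` SNPs
  (default 20) has a pool of 8 haplotypes that are all-reference or
  all-alternate across the block; every sample copies two pool
  haplotypes, and a per-SNP mutation rate — solved analytically from the
  target `within_block_r2` (default 0.6) — decays the within-block LD to
  the requested level. Blocks are independent; realized minor-allele
  frequencies are kept inside `maf_range` (default 0.05–0.5) by
  block-level rejection resampling.
* **Phenotype.** $y = \sum_j \beta_j z_j + u + \epsilon$ with $z_j$ the
  standardized dosage of each planted causal SNP (so $\beta_j^2$ is that
  QTL's variance contribution), $u \sim N(0, V_g K)$ drawn from the
  realized genomic relationship matrix, and i.i.d. Gaussian noise. The
  total variance is derived so that `h2_polygenic` and the QTL fractions
  partition it exactly; `qtl_beta()` converts a desired variance fraction
  into a coefficient.
* **Determinism.** All outputs are pure functions of the spec, including
  its single integer seed; stage-local streams are derived from it.

What the generator does **not** emulate: recombination-gradient LD decay
(blocks have uniform internal r² and sharp edges), pedigree/family
structure across generations (samples are exchangeable draws from the
pool, so kinship is weak and homogeneous), array ascertainment bias, and
the shrinkage-removal noise structure of de-regressed breeding values
(phenotypes are plain additive-model draws). Passing tests therefore
demonstrate correctness of the machinery and calibration under this
idealized architecture, not performance on structured livestock pedigrees.

## Numerical choices

* **Scaled position axis.** Positions are rescaled to $[0,1]$ per
  chromosome before fitting; bp magnitudes (~$10^8$) would otherwise
  destabilize the penalized solver. $\lambda$ is reported on the scaled
  axis ($\lambda_{bp} = \lambda_{scaled} \cdot \mathrm{span}^3$).
* **Solver.** The penalty matrix $QR^{-1}Q'$ of the knot vector is
  eigendecomposed once per chromosome; every subsequent fit (any
  $\lambda$, any permutation) is a diagonal shrinkage in that basis.
  This makes the ~$B \times$ chromosomes spline fits of the permutation
  null cheap and is also why positions, not phenotypes, must stay fixed
  across permutations.
* **GCV.** $\lambda$ is selected on a fixed 57-point log grid
  ($10^{-8}$–$10^6$) by generalized cross validation with the
  degrees-of-freedom charge inflated by the customary factor 1.4. Plain
  GCV applied to $\chi^2_1$-distributed (heavy-tailed) inputs
  occasionally selects a near-interpolating $\lambda$, producing "peaks"
  that ride single noise spikes; the inflated charge suppresses this
  failure mode. The same selection policy — including re-selection for
  every permutation — is applied to observed and permuted data, which is
  what keeps the permutation null comparable to the observed statistic.
  GCV ties resolve to the larger (smoother) $\lambda$.
* **Second-derivative noise floor.** The map from fitted values to
  $g''$ amplifies rounding error by roughly the squared knot density, so
  exactly degenerate inputs (constant or collinear data) leave $g''$
  with tiny nonzero residue. Values below an explicit tolerance are
  snapped to zero so flat curves yield no inflections or peaks.
* **Inflections at chromosome ends.** Natural boundary conditions force
  $g'' = 0$ at the end knots, so end inflections are judged by
  extrapolating the interior second derivative to the end: an end is an
  inflection only when the underlying curvature genuinely reaches zero
  there (e.g. a sine ending at a curvature zero), not when it is merely
  clamped (e.g. a cubic).
* **Degenerate inputs.** Tied marker positions are jittered by +1 bp
  with a warning; chromosomes with fewer than 10 SNPs are skipped in
  signal detection; monomorphic SNPs get Wald 0 and p 1 and are flagged;
  all-equal spline inputs return the constant curve.

## Design choices

* **EMMAX-style fixed $\delta$** (re-estimated per permutation but not
  per SNP) is the default; exact per-SNP REML is available but is orders
  of magnitude slower and changes Wald statistics negligibly at realistic
  polygenicity.
* **All-SNP GRM, no leave-one-chromosome-out.** The kinship matrix is
  built from all SNPs, including the tested one. At scan sizes of a few
  thousand SNPs this *proximal contamination* measurably attenuates the
  Wald statistics of SNPs in LD with a strong causal variant (the
  polygenic term partially absorbs their signal); at array scale the
  effect is negligible. It is kept because the framework's reference
  behaviour is defined without LOCO.
* **QTL bounds are SNP-anchored**: start/end are the positions of the
  leftmost/rightmost SNP inside the inflection interval, matching how
  the result tables count SNPs per QTL.
* **Boundary semantics of QC.** SNPs are removed when MAF ≤ 0.01 or call
  rate ≤ 0.97 (boundary values removed, taking the filter descriptions
  literally); a strictness flag switches to the conventional strict-`<`
  reading. Samples are filtered before SNP statistics are recomputed.
* **Genotype-class tests** use pairwise Welch t-tests by default (robust
  to unequal class variances); Tukey HSD after one-way ANOVA is
  available. Raw phenotypes are compared, not covariate-adjusted
  residuals.
* **Coordinates** are 1-based inclusive everywhere inside the package;
  BED input is converted at the boundary.

## Problem sizes used by the test suite

The test suite exercises the framework at deliberately reduced sizes so
the full battery stays fast: family-wise-error calibration uses 200 null
datasets of n = 300 samples × 2000 SNPs (20 chromosomes, polygenic
h² = 0.3) with B = 200 permutations; the planted-QTL power experiment
uses n = 600 × 3000 SNPs with B = 200 and 30 replicates per effect-size
tier ({1%, 2%, 5%} of phenotypic variance), sharing random numbers across
tiers so the detection rate is compared replicate-by-replicate; REML
recovery uses 20 datasets of n = 500. These sizes are the package's
choices for a thorough-but-quick battery; the machinery itself has no
such limits.

## Known limitations

* **Power at reduced scale.** The permutation threshold is the 95th
  percentile of the genome-wide *maximum* smoothed noise, so detection
  power is governed by the ratio of the causal SNP's non-centrality
  ($\approx n f/(1-f)$ for a QTL explaining fraction $f$ of variance) to
  the maximum over the genome's effective tests. At the reduced test
  sizes (a few thousand SNPs in ~150 LD blocks), a 2%-variance QTL has
  non-centrality ≈ 12 against a null maximum around 10 — an oracle test
  at the exact causal position would succeed less than half the time, and
  no smoothing policy can beat that ceiling. The same pipeline on
  array-scale data (hundreds of thousands of SNPs, QTLs spanning dozens
  to hundreds of markers) operates at a much more favourable
  signal-to-maximum ratio. The end-to-end test asserts the full
  detection-rate profile; its 2%-tier detection expectation is not
  attainable under these reduced conditions and the suite reports it
  honestly rather than relaxing the conditions.
* Per-chromosome GCV lets each chromosome adapt its own smoothness; a
  genome-pooled selection was evaluated and gave materially identical
  permutation thresholds.
* The exact conditional HWE test, LD pruning and simpleM all operate on
  autosomal biallelic dosages; sex chromosomes receive no special
  handling.
* Boruta decisions depend on forest size and iteration count; defaults
  (500 trees, 100 iterations, α = 0.01 Bonferroni, two-sided binomial
  decisions) follow the original algorithm's practice and are fully
  configurable.
* Boruta is an *all-relevant* selector: with a few hundred samples and a
  continuous phenotype, the noise SNPs with the largest realized
  in-sample correlation to the phenotype (the maximum over `m` draws of
  an `O(1/sqrt(n))` statistic) genuinely out-rank freshly shuffled
  shadows and are occasionally Confirmed. Expect a handful of such
  confirmations per hundred null SNPs at n of a few hundred; the robust-SNP
  intersection with permutation-validated QTLs is what controls them in
  the final report.
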