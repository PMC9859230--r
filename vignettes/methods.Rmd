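---
title: "Methods: population-genetic analysis of livestock SNP-chip data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genetic analysis of livestock SNP-chip data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenchip)
```

`popgenchip` analyses diploid autosomal SNP-array genotypes from small
livestock populations: quality control, the minor-allele-frequency
spectrum, linkage-disequilibrium (LD) decay, LD-based historical
effective population size (Ne), genomic relationships and population
structure, and genomic heritability of quantitative traits. This
vignette describes each model, its assumptions, the tunable parameters,
and the design choices made where several defensible options existed.

## Quality control

Markers and samples pass a battery with the conventional thresholds for
livestock arrays, all exposed in `qc_config()`:

* sample missingness ≤ 5% (applied first, before any variant filter);
* variant call rate ≥ 90%;
* minor allele frequency (MAF) ≥ 1%;
* Hardy–Weinberg exact p ≥ 1e-6;
* removal of monomorphic markers;
* near-duplicate pruning: within each chromosome, scanning in position
  order, a variant whose genotype r² with the last retained variant
  exceeds 0.998 is dropped, so the lower-position member of a duplicate
  run survives deterministically.

The Hardy–Weinberg test is the plain two-sided conditional exact test:
all heterozygote counts compatible with the observed allele counts are
enumerated and the p-value sums the probabilities of outcomes no more
probable than the observed one. No mid-p adjustment is used, matching
the default behaviour of standard GWAS tooling; the test is checked
against an independent enumeration oracle in the test suite.

Each removed variant is attributed to the *first* rule it fails, in the
order call rate → MAF → Hardy–Weinberg → monomorphic. One wrinkle: a
variant with MAF exactly 0 is labelled "monomorphic" rather than
"low_maf" so reports distinguish "no variation" from "rare", although
the removed set is identical either way.

Remaining missing calls are imputed by a deliberately simple seeded
draw from Binomial(2, f̂), with f̂ the variant's observed allele
frequency. This ignores LD, unlike haplotype-HMM imputers, and is
justified only because post-QC missingness is low (< 10% per variant):
a mask-and-recover test shows imputed allele frequencies within ±0.02
of truth at n = 222, and downstream statistics are insensitive at that
level. For datasets with substantial missingness a proper haplotype
imputer should be run upstream instead.

## LD: r² by two-locus EM

For loci i and j, r² = (p_ij − p_i p_j)² / (p_i(1−p_i) p_j(1−p_j)),
with p_ij the frequency of the gamete carrying the B allele at both
loci. Chip genotypes are unphased, so gamete frequencies are estimated
by maximum likelihood: every two-locus genotype determines its gametes
except the double heterozygote, and an EM iteration splits those
between coupling and repulsion phase. The EM initialises at linkage
equilibrium (making it deterministic), converges on |Δp_ij| < 1e-10,
and caps at 1,000 iterations (non-convergence is flagged and the last
iterate returned; with the equilibrium start the likelihood is
unimodal in practice and the cap is not reached on real-scale data).
A genotype-correlation ("composite") r² is available as a labelled
cross-check (`r2_composite`), but the EM estimator is the default
everywhere because the definition of r² is stated in haplotype
frequencies.

Pairs are enumerated within chromosomes up to 1 Mb apart (and at most
99,999 markers apart), and the decay curve averages r² arithmetically
in half-open 2.5 kb bins out to 500 kb. Two conventions for "mean r²
over 0–50 kb" exist in the literature — weighting every pair equally
or averaging bin means — and differ when pair counts vary across bins;
`mean_r2_range()` implements both, labelled.

## Historical Ne from LD

Under drift–recombination equilibrium the expected r² at recombination
fraction c reflects the effective size roughly t = 1/(2c) generations
ago. The package inverts the Sved-type relation

E[r²] = 1 / (α + 4 Ne c),  Ne = (1/r²_adj − α) / (4c)

per distance bin, after two corrections:

* **Map correction.** Physical distance converts to c through
  Haldane's function c = (1 − e^(−2m))/2 with m = d · rate · 1e-8
  Morgans. The rate defaults to 1 cM/Mb, the bovine genome-wide
  average, and is configurable.
* **Finite-sample floor.** A sample of n diploids shows nonzero r²
  even at linkage equilibrium. The floor depends on the estimator: the
  EM estimator effectively recovers 2n gametes and floors at 1/(2n)
  (verified in a constant-Ne simulation experiment, where subtracting
  1/(2n) removes essentially all of the inversion bias at moderate c);
  the composite genotype-correlation estimator floors at 1/n. The
  package subtracts the floor matching the estimator in use.

**Choice of α.** Sved's original derivation gives α = 1; the
Hill–Weir equilibrium expectation for a randomly mating monoecious
population without mutation is ≈ (10+ρ)/((2+ρ)(11+ρ)) with ρ = 4Nec,
which is numerically close to 1/(2+ρ), i.e. the Sved form with α = 2.
Forward-simulation experiments here reproduce the Hill–Weir curve, and
α = 1 leaves a ~30% upward Ne bias at small c while α = 2 recovers a
constant Ne = 100 within ~±25%. The default is therefore α = 2,
configurable to 1.

The estimator reports one (t, Ne) point per non-empty bin up to a
200-generation horizon, with optional rolling-median smoothing
(window 5) to damp bin noise — the per-bin estimates invert a noisy
mean, which is a convex transform, so individual narrow bins are
biased upward and the median window is the cheap remedy. Known
limitations: a mild residual upward trend at the smallest c remains
(Sved vs Hill–Weir disagreement grows as ρ → 0), and with a realistic
1 cM/Mb map the ≤1 Mb pair window only reaches c ≤ 0.01, i.e.
t ≥ 50 — recent generations are simply not observable from such data
with a per-bin inversion, which is exactly why genetic-algorithm
demographic fitters exist. This package deliberately implements the
transparent per-bin estimator, not such a fitter.

## Genomic relationships and PCA

The relationship matrix is the first VanRaden form
G = ZZ′ / (2Σ p_i(1−p_i)), where Z is the genotype matrix centered at
twice the allele frequency (Z = M − 2P). Centering is essential — an
uncentered cross-product is not a relationship matrix — and absorbs
A/B label flips, so G is invariant to allele relabelling and marker
order. Frequencies come from the analysed samples themselves (no base
population is available), which constrains row sums of ZZ′ to ~0 and
therefore forces the mean off-diagonal to ≈ −mean(diag)/(n−1): a mean
"kinship" computed this way is a relative, not absolute, quantity.
Both the G scale and the G/2 (kinship) scale of the off-diagonal mean
are reported, since usage varies. A warning is raised below 2,500
markers, where relationship estimates get noticeably noisy.

PCA is an eigendecomposition of G (equivalent to PCA of the centered,
scaled genotypes); variance fractions clamp negative eigenvalues to
zero in the denominator but report them raw.

## Genomic REML heritability

Each trait is fitted with the animal model y = Xβ + g + e,
g ~ N(0, G σ²_a), e ~ N(0, I σ²_e). Because there is a single random
effect, one eigendecomposition of G diagonalises the problem: rotating
y and X by the eigenvectors turns the covariance into
σ²_e(λD + I) with λ = σ²_a/σ²_e, σ²_e profiles out analytically, and
the restricted likelihood is maximised by a one-dimensional Brent
search over log₁₀λ ∈ [−10, 10]. This is exact (no EM/AI iteration
schedule to tune); every fit is verified against a 21-point grid in
the test suite. A ridge of 1e-6 on the diagonal of G guards rank
deficiency when n exceeds the effective marker dimension. Standard
errors of h² = σ²_a/(σ²_a+σ²_e) come from the observed information of
the unprofiled restricted likelihood (central-difference Hessian in
(σ²_a, σ²_e)) via the delta method; replicate experiments show the
reported SE and the replicate SD agree within ~±40%. Optima at the λ
search boundary are flagged — h² near 0 or 1 should be read as a
boundary estimate, and its delta-method SE is unreliable there.

Phenotypes are cleaned by a single (not iterated) three-standard-
deviation rule using the mean and SD of the full input; fixed effects
(sex, farm, birth year, treatment-coded with aliased columns dropped)
are fitted *inside* the REML model rather than pre-corrected, which is
statistically dominant; a pre-correction mode (OLS residuals) exists
for comparison. Coefficients of variation use the n−1 SD.

## The synthetic-data generator

No real chip data ship with the package; every stage is exercised
against a Wright–Fisher forward simulator with recombination:

* founder haplotypes draw marker frequencies from a Beta(0.5, 0.5)
  spectrum truncated to [0.01, 0.99], in linkage equilibrium;
* each generation, offspring gametes pick a random diploid parent and
  recombine its two haplotypes with a Poisson(map length) crossover
  count at uniform positions (Haldane model, no interference);
* the population size follows a configurable piecewise-constant epoch
  list; after the last epoch one extra "census" generation of
  2·n_samples gametes is bred from the final effective pool, so the
  genotyped sample may exceed the effective size, as in a real herd;
* phenotypes draw n_causal causal markers with normal effects rescaled
  to var(BV) = h²σ², Gaussian residuals, and sex/farm/birth-year fixed
  effects; true breeding values are recorded.

There is no mutation, selection or migration: the object of study is
standing chip variation over ≤ 200 generations, where mutational input
is negligible. Consequences worth knowing: (i) long simulations lose
diversity monotonically, and (ii) the folded frequency spectrum after
~180 generations of drift is drift-shaped regardless of the founder
spectrum — the strong excess of rare alleles seen on real indicine
chip data is an ascertainment feature the generator does not emulate,
so spectrum tests assert the mean MAF (≈ 0.2, the realistic target for
an indigenous cattle panel) rather than the skew. Passing tests
therefore demonstrate correctness of the estimators under neutral
drift with known truth, not robustness to chip ascertainment.

The packaged preset (`dabieshan_preset()`) emulates a small indigenous
herd at desk scale: two epochs (Ne 1000 for 160 generations, then
Ne 86 for 20), five 10 Mb chromosomes at ~30 kb marker spacing
(1,670 markers), 235 individuals with an 85/15 female/male split over
three farms and four birth years, 2% missingness, and the nine
body-measurement/weight traits with heritabilities 0.12–0.54 and
coefficients of variation ~6–20%. Chromosome count and marker density
are scaled down ~6× and ~50× from a real 29-autosome 80 K panel purely
for runtime; a full-scale configuration is a parameter change.

Problem sizes used by the test suite and the acceptance script were
chosen to keep a complete run in minutes on one core: heritability
recovery uses n = 500 with 5,000 linked markers over 20 replicates per
level (related individuals from a Ne = 300 herd — relatedness variance
is what gives GREML its precision; with unrelated samples the same
experiment has a ~0.2 replicate SD and would need far larger n);
Ne recovery uses 100 diploids on a 10 cM/Mb compressed map so that the
≤1 Mb pair window covers t ∈ [5, 50].

## Numerical conventions

* Positions are 1-based; all intervals (LD bins, MAF bins) are
  half-open [lo, hi).
* Genotype codes count copies of the B allele; on file import B is the
  observed minor allele, with f = 0.5 ties broken lexicographically.
  Missing is a distinct sentinel (`NA`), never conflated with 0.
* All stochastic steps (simulation, imputation, masking) take explicit
  seeds; a pipeline run is byte-reproducible from (config, seed).
* Degenerate inputs fail loudly: all-missing variants, empty genotype
  matrices, non-identifiable G ∝ I, zero GRM denominators and
  sub-three-record trait vectors are errors, not silent results.
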