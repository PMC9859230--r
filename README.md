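# popgenchip

Population-genetic analysis of livestock SNP-chip data in R, built for
small indigenous breeding populations genotyped on medium-density
arrays (a few hundred animals, ~80 K autosomal SNPs). It covers the
standard question set a breed-characterisation study asks:

* **QC** — call rate, MAF, Hardy–Weinberg exact test, sample
  missingness, near-duplicate pruning, seeded binomial imputation;
* **MAF spectrum** — counts and proportions in the conventional
  five frequency categories;
* **LD decay** — pairwise r² from EM-estimated haplotype frequencies
  (r² = (p_ij − p_i p_j)²/(p_i(1−p_i)p_j(1−p_j))), averaged in 2.5 kb
  distance bins to 500 kb;
* **Historical Ne** — per-bin inversion of the Sved-type relation
  E[r²] = 1/(α + 4Ne·c) with Haldane map correction and a
  finite-sample r² floor, giving a trajectory over ≤ 200 generations;
* **Genomic relationships** — VanRaden G = ZZ′/(2Σp(1−p)), mean
  genomic kinship, PCA of population structure;
* **Heritability** — single-trait genomic REML of the animal model
  y = Xβ + g + e, g ~ N(0, G·σ²ₐ), solved exactly by
  eigendecomposition plus a 1-D profile-likelihood search, with
  delta-method standard errors of h² = σ²ₐ/(σ²ₐ+σ²ₑ).

Because chip datasets of this kind are rarely deposited, the package
ships a seeded Wright–Fisher forward simulator (recombination,
piecewise-constant Ne, phenotypes with known h² and sex/farm/year
fixed effects) so every estimator is tested against known truth.

## Worked example

Simulate a herd-like dataset and run the whole pipeline:

```r
library(popgenchip)
cfg <- run_config(out_dir = "demo_run", sim = dabieshan_preset(seed = 1),
                  seed = 1)
mf <- run_pipeline(cfg)
```

The run logs each stage; with seed 1 it prints:

```
read: 235 samples x 1670 variants
qc:   retained 235 samples x 1074 variants
maf:  mean MAF 0.228
ld:   21851 pairs; mean r2 0.110 at 0-50 kb
ne:   Ne 408 at t=100.8 ... 699 at t=199.5
grm:  mean kinship (off-diagonal of G) -0.0042
pca:  PC1+PC2 explain 8.90% of variance
reml: fitted 9 trait(s); h2 range 0.06-0.64
```

Reading those numbers: QC dropped ~600 markers that drifted rare or
monomorphic through the simulated bottleneck; mean r² at 0–50 kb
reflects the recent small-Ne epoch; the Ne trajectory only reaches
back to t ≈ 50–200 because with a 1 cM/Mb map, pairs within 1 Mb carry
no information about more recent generations; the mean off-diagonal of
G is pinned near −1/(n−1) by the use of sample allele frequencies; and
the nine REML heritabilities straddle their simulated values
(0.12–0.54) with SEs of ~0.1 at n = 235. Per-stage tables
(`qc_report.tsv`, `ld_decay.tsv`, `ne_trajectory.tsv`,
`heritability.tsv`, ...) land in `demo_run/`.

Individual pieces are plain functions, e.g.

```r
em_haplotype_freqs(g$calls[, 1], g$calls[, 2])$r2   # one LD value
hwe_exact_test(25, 50, 25)                           # exact HWE p
heritability(16.523, 42.488)                         # 0.28
```

A thin CLI wrapper lives at `inst/scripts/popgenchip-cli.R`
(`simulate` and `all` subcommands).

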