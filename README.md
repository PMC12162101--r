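# tmskit

Analytics for benchmarking **targeted enzymatic methylation sequencing
(TMS)** — hybrid-capture enrichment of CpG panels with enzymatic
methyl conversion — against whole-genome, reduced-representation and
array-based DNA methylation assays. The package is aimed at groups
evaluating capture-based methylation protocols: it implements the
computational layer such a benchmark needs (capture-efficiency interval
analytics, count-matrix filtering, power simulation, cross-technology
concordance, tissue-specificity testing) together with a synthetic-data
module that generates every input with known ground truth, so each stage
is testable without access to raw sequencing data.

## What it computes

**Capture efficiency.** The capture target is the probe footprint ±200 bp,
merged (`expand_merge`). A site or fragment is *on-target* iff its gap to
the nearest probe is ≤ 200 bp (`proximity_mask`); the same primitive gives
the fraction of probes covered by ≥1 fragment (tol = 0). Per-base depth
over the target, expected CpG counts of a probe set mapped to a new
genome, and CpG island shore (±2 kb) / shelf (2–4 kb) derivation round out
the interval analytics, all validated against per-base brute-force
oracles.

**Matrix filtering.** Per-sample cytosine reports are strand-collapsed to
one `(M, U)` pair per CpG dinucleotide and assembled into a sites ×
samples count matrix (union semantics, zero fill). The study filter keeps
sites covered ≥5× in ≥75% of samples inside the target, with a relaxed
≥1 read in ≥⅔ samples variant for tiny groups.

**Power simulation.** For sample size *n*, effect *δ* and coverage
multiplier *k*: per simulated site, coverages `c_i` are drawn with
replacement from an empirical coverage pool (×k), methylated counts

    M_i ~ Binomial(c_i, p0 + δ·g_i),   g_i ∈ {0,1} balanced,

and the site is tested with the likelihood-ratio test of the
logistic-binomial group model (closed form in the group-pooled counts;
χ², 1 df). Power is the fraction of testable sites with p < 0.001.
Defaults mirror the benchmark design: 1,000 sites per cell, n ∈ {100,
200, 400}, δ ∈ [0, 0.20], k ∈ {1, 2, 4} around a ~20× empirical pool.

**Concordance.** OLS fits of per-site mean levels between technologies
(R², slope, intercept); per-sample matched-vs-permuted R² distributions
(the permuted null uses a derangement, so no sample pairs with itself),
compared by Welch's t; and array-style beta values
`β = M / (M + U + offset)`, whose positive offset makes β = 1 impossible
and depresses the hypermethylated-subset R² — the signature bias of
array/sequencing comparisons.

**Tissue-specific differential methylation.** Per variably methylated site
(median level strictly between 10% and 90%), a beta-binomial model with
logit mean `b0 + b1·focal` and shared overdispersion ρ is fitted by
maximum likelihood for each focal tissue against all others; p-values come
from the LRT of `b1 = 0`, standardized effects are `b1/se(b1)`, BH FDR is
applied at 5%, and overlap between technologies is quantified as a Fisher
exact log₂ odds ratio with Haldane correction.

## Worked example

```r
library(tmskit)

# a synthetic study system with known truth
ref <- gen_reference(n_chroms = 2, chrom_length = 1e6,
                     cpg_rate = 0.01, probes_per_chrom = 5, seed = 1)
fr  <- gen_fragments(ref$probes, 20000, ref$chrom_lengths,
                     on_target_prob = 0.785, seed = 2)
proximity_mask(fr, ref$probes, tol = 200)$summary$fraction_on_target
#> [1] 0.7837

# per-site group test: hand-checkable closed-form LRT
site_pvalue(M = c(3, 7), c = c(10, 10), groups = c(0, 1))
#> $stat
#> [1] 3.291315
#> $p
#> [1] 0.06964722

# power at the study grid (empirical ~20x pool)
set.seed(7)
pool <- rnbinom(5000, mu = 20, size = 2)
cfg  <- power_config(n_sites = 5000, sample_sizes = c(100, 400),
                     deltas = c(0.05, 0.1), multipliers = c(1, 4))
tab  <- estimate_power(cfg, pool, seed = 42)
subset(tab, delta == 0.05, select = c(n, k, power))
#>     n k  power
#> 1 100 1 0.1402
#> 3 100 4 0.8786
#> 5 400 1 0.8814
#> 7 400 4 1.0000
```

The on-target fraction recovers the 0.785 mixing probability; the LRT
reproduces the hand-computed deviance 3.2914 (p ≈ 0.0696); and the power
table shows the characteristic attenuation — quadrupling coverage lifts
power by ~0.74 at n = 100 but only ~0.12 at n = 400, because at large n
power comes from the sample, not the depth.

The `analysis/` directory holds the full narrative workflow as numbered
scripts (`01_simulate.R` … `06_differential.R`); each writes its tables
under `results/`.

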