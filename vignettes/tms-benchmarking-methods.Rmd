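---
title: "Methods: benchmarking targeted enzymatic methylation sequencing"
author: "tmskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking targeted enzymatic methylation sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmskit)
```

# Scope and model of the data

Targeted methylation sequencing (TMS) enriches a panel of capture probes
(on the order of 550k probes tiling ~4M CpG sites) from enzymatically
converted libraries, producing per-cytosine reports: counts of methylated
(`M`) and unmethylated (`U`) reads at each cytosine, with strand and
trinucleotide context. `tmskit` implements the computational layer of a
benchmarking study of this assay class: capture-efficiency interval
analytics, count-matrix filtering, a coverage-conditioned power simulator,
cross-technology concordance (including the microarray beta-value offset
bias), and beta-binomial tissue-specificity testing — all exercisable on
synthetic data with known ground truth.

Coordinates follow the BED convention internally: 0-based half-open
intervals, with CpG sites keyed by the 0-based position of the plus-strand
C of the dinucleotide. Cytosine reports are 1-based; the single conversion
point is `collapse_strands()` (a minus-strand record at 1-based `p` belongs
to the plus-strand C at `p - 1`). CpG methylation is palindromic, so
collapsing the two strands of a dinucleotide into one count pair is the
default; per-strand records are preserved for CHH-based QC, which is
strand-specific by nature. Whether the upstream study collapsed strands
before filtering is not documented; collapse is this package's convention
and the count-conservation invariant (`sum(M + U)` unchanged) is tested.

Chromosome matching is exact string equality. A `normalize_chrom()` helper
handles the UCSC `chr` prefix, but it is never applied implicitly — silent
aliasing is a classic source of silent data loss when mixing probe and
report files.

# The synthetic-data generator

All pipelines here are validated against simulated inputs whose ground
truth is known, because the raw sequencing data such a benchmarking design
rests on are not available at desk scale. The generator mimics the
statistical structure the analyses assume:

* **Genome and probes** (`gen_reference()`): chromosomes whose only CG
  dinucleotides are planted at a target density (default 0.02/bp, the CpG
  density of capture-panel neighborhoods rather than the genomic ~0.01
  average), with 120 bp probes each anchored on a CpG.
* **Methylomes** (`gen_methylome()`): per-site baseline methylation drawn
  from a two-component beta mixture, default `0.5 * Beta(1, 10) + 0.5 *
  Beta(10, 1)`. This produces the bimodal hypo/hyper profile characteristic
  of mammalian methylomes; the mixture is this generator's choice, as the
  baseline distribution of the original power design is not documented.
  Per cell (site x sample), coverage is negative-binomial (default mean
  20, matching the ~20x regime of a 96-plex run; size 2 gives the heavy
  right tail seen in capture data) and the methylated count is binomial
  with success probability `pi (1 - e_inv) + (1 - pi) e`, where `e` is the
  conversion-failure rate (default 0.005, inside the 0.1-0.27% to <1%
  band expected of enzymatic conversion; the inverse error defaults to 0
  because CHH-based QC measures only the failed-conversion direction).
  CHH records with methylation probability `e` are emitted alongside, so
  `chh_conversion()` can recover the planted rate.
* **Group effects**: effect sites carry an exact `+delta` shift in group 1.
  Requesting `n_effect` sites samples them among sites where `pi + delta
  <= 1`; passing explicit sites that violate this errors, since a
  truncated effect would no longer be the effect size it claims.
* **Fragments** (`gen_fragments()`): an on/off-target mixture with default
  on-target probability 0.785 — the average on-target read fraction of a
  well-performing capture. On-target fragments land within 200 bp of a
  uniformly chosen probe; off-target fragments land uniformly. Coverage is
  drawn independently per cell; site-level coverage correlation along the
  genome is not modeled, so tests passing here say nothing about
  correlated-coverage pathologies in real data.
* **Array betas** (`gen_array_betas()`): `beta = S_m / (S_m + S_u +
  offset)` with intensities proportional to the methylation level plus
  truncated Gaussian noise. The offset default is 100, the conventional
  microarray intensity offset; the assay class documents that an offset
  exists but not its value, so it is a parameter.
* **MspI digest** (`msp1_digest()`): cuts at `C^CGG`, retains 180-2000 bp
  fragments, and marks every CpG on a retained fragment as covered. Read
  ends are not modeled: the purpose is to reproduce reduced-representation
  site selection (CpG-dense, island-enriched), not per-read coverage
  geometry.

All generators are seed-deterministic; fixed seeds give byte-identical
output.

# Capture-efficiency analytics

The capture target is the probe footprint expanded by a flank (default
200 bp) and merged (`expand_merge()`). "Within 200 bp" is interpreted as
*gap* at most 200 bp, overlap included — the interpretation a
`bedtools closest`-style computation produces; center-to-center distance
would be a different and stricter rule. One consequence, verified in
tests, is that testing sites against per-probe expansions or against the
merged target is equivalent.

`proximity_mask()` serves all three fractions the benchmarking design
needs with one primitive: site on-target fraction (`tol = 200`), fragment
on-target fraction (`tol = 200`, a fragment being the R1-start to R2-end
interval), and the probes-covered fraction (probes as query, fragments as
reference, `tol = 0`). Improper pairs (end at or before start) are
rejected by the interval constructor.

`expected_cpg_count()` expands and merges first, so a CpG under two nearby
probes is counted once, and counts a CG straddling a region boundary iff
its C lies inside — consistent with keying sites by the plus-strand C.

Island shores are the bases within 2 kb of an island boundary outside any
island; shelves the 2-4 kb band outside islands and shores. When bands
from neighboring islands collide, precedence is island > shore > shelf;
the annotation sources the field uses do not document a collision rule, so
the precedence convention is made explicit and checked against a per-base
oracle.

Every interval operation is tested against brute-force per-base oracles on
random instances; the merged/sorted representation is an optimization, not
a semantic.

# Matrix assembly and filtering

`assemble_matrix()` takes the union of sites across samples and fills
absent cells with `(0, 0)`: with intersection semantics a missingness
filter would be vacuous. The study filter keeps sites covered at >=5x in
>=75% of samples within the expanded target; for three-sample designs the
relaxed rule (>=1 read in >=2/3 of samples) applies. Both comparators are
explicit (`ge`/`gt`) because ">5X" in methods prose is ambiguous between
inclusive and strict; the default is inclusive, matching common practice.
Filtering is order-preserving and idempotent, and is verified cell-by-cell
against a double-loop reference across all four comparator combinations.

Methylation level is `M / (M + U)` with explicit missing at zero coverage.
A site is "variable" iff its mean lies strictly between 10% and 90%
(strict, per the defining wording); hypo/hypermethylated split at 50%.
Annotation summaries report the median of per-site medians (not pooled
cells) per label, and a site overlapping several labels contributes to
each.

# The power simulator

The power module reproduces the study's design: per simulated site, draw
per-sample coverages with replacement from an empirical pool (the observed
per-cell coverage distribution; multiplied by 2 or 4 to emulate 40x/80x),
assign a balanced binary predictor, draw methylated counts binomially with
group probabilities `p0` and `p0 + delta`, test each site, and report
power as the fraction of testable sites with `p < 0.001`. Defaults: 1,000
sites per cell, sample sizes 100/200/400, effects 0-0.20, multipliers
1/2/4.

Design choices the original description leaves open:

* **The per-site test.** The default is the likelihood-ratio test of the
  logistic-binomial group model. With a single binary predictor the group
  MLEs are the pooled group proportions, so the deviance has a closed form
  in four sums — no iterative fit, exact behavior under complete
  separation, and fast enough to run 20,000-site grids in seconds. A
  pooled two-sided Fisher exact test is available as an alternative; the
  two agree in rejection decisions at moderate counts (tested).
* **Baseline `p0`.** Default symmetric: `p0 = 0.5 - delta/2`, placing the
  two groups symmetrically around 50% so that cells with different deltas
  are comparable in baseline information; a fixed-`p0` scheme is available.
* **Resampling unit.** Coverage is drawn i.i.d. per cell from the pooled
  empirical distribution.
* **Coupling.** Within a sample size, the same base coverage draws are
  reused across effect sizes and multipliers, so the monotonicity of power
  in `delta` and `k` is checked on positively coupled simulations — much
  tighter than independent runs at the same Monte Carlo size.
* **Degenerate sites** (a group with zero total coverage) are excluded
  from the power denominator and counted separately, not scored as
  non-significant.

Calibration is tested at the null (power within the exact binomial 99% CI
of 0.001 at 20,000 sites), and the attenuation claim — extra coverage
helps less at large sample size — is verified as a strict inequality of
k=4 vs k=1 power gains at n=100 vs n=400.

# Concordance analytics

`ols_fit()` is the concordance primitive: simple least squares over
pairwise-complete pairs, `r2 = 1 - SS_res / SS_tot`, undefined (not an
error) below 3 points or at zero variance. Axes follow the convention of
comparison technology on x, TMS on y.

The per-sample matched-versus-permuted comparison pairs each sample's
per-site levels across two technologies; the permuted null re-pairs
samples by a seeded *derangement*, so no sample is ever compared with
itself. A plain random permutation would leave fixed points that dilute
the null upward; whether the original analysis excluded them is unknown,
and the derangement makes the contrast clean. The two distributions are
compared with Welch's t (wrapping `t.test`, with the zero-variance corner
cases given defined results).

The array-bias emulation generates betas with a positive intensity offset
from the same truth as the sequencing-style levels: the offset caps betas
strictly below 1 and compresses the top of the range, so the regression
slope against truth falls below 1 and the hypermethylated-subset r2 drops
below the all-sites r2 — the qualitative signature expected when comparing
sequencing to array measurements. `subset_compare()` applies the same fit
under arbitrary named masks (variable sites, islands/shores/shelves,
hypo/hyper, probe types).

# Beta-binomial tissue-specificity testing

Per variably methylated site (per-site *median* level strictly between 10%
and 90%), the focal-tissue-vs-rest model is a beta-binomial with logit
mean `b0 + b1 * focal` and one shared intra-class correlation `rho`
(shape parameters `a = mu (1 - rho) / rho`, `b = (1 - mu)(1 - rho) /
rho`), fitted by bounded quasi-Newton optimization on `(b0, b1,
logit rho)` with a derivative-free restart when the line search fails near
the dispersion boundary. The boundary itself is handled by profiling down:
the closed-form binomial maximum (arm proportions) is always evaluated and
taken when it beats the interior optimum, so `rho -> 0` never destabilizes
the likelihood ratio. The p-value is the LRT of `b1 = 0` against
chi-square(1); the "standardized effect" is `b1 / se(b1)` with the
standard error from the observed information (or the binomial closed form
at the boundary) — the natural reading of a standardized effect size, as
the original figure does not define its standardization. Non-converged
sites are excluded and counted, never silently dropped.

The likelihood is verified to 1e-8 against a rising-factorial product
oracle; calibration (null FDR-hit fraction), power (planted logit-2
effects at 16 samples/tissue recovered at >=80%), label-permutation
nullification, and sample-order invariance are all tested.

`bh_fdr()` is the Benjamini-Hochberg step-up with missing p-values
propagated and excluded from the effective test count.
`overlap_enrichment()` builds the 2x2 overlap table over a tested-site
universe; the odds ratio is `ad/bc` with Haldane +0.5 applied only when a
cell is zero, the CI is Wald on the log scale (reported in log2 units),
and the p-value is always the exact hypergeometric test on the uncorrected
table. Repeated individuals across tissues are *not* modeled (no random
effects), matching the single-dispersion fixed-effect description of the
assay comparison this mirrors.

# QC utilities

CHH methylation percent estimates conversion failure (mammalian CHH is
essentially unmethylated); thresholds 1% (warn) and 5% (fail) follow the
conventional cutoffs and are configurable. `nx_stat()` returns the first
length at which the descending cumulative sum reaches `x` of the total —
the standard N50/N90 convention; the tie/boundary convention of any
particular upstream implementation is unverifiable, so the standard one is
used and oracle-tested. `thin_counts()` thins a count matrix at read level
(binomial coverage, hypergeometric methylated split), so thinned matrices
remain valid integer count matrices with expectation `f * c`;
`coverage_curve()` confirms the linear depth-vs-reads relationship with a
through-the-origin fit.

# Problem sizes and numerical choices

The test suite simulates at sizes chosen to keep Monte Carlo standard
errors well below the margins being asserted while remaining quick on a
laptop: 20,000 sites for null calibration (SE of the type-I rate ~0.0002),
5,000 per grid cell for monotonicity (SE <= 0.007), 100 random instances
per interval oracle, 2,000 sites for differential-null calibration. The
acceptance script (`scripts/acceptance.R`) re-runs the same computations
from scratch at these sizes under a caller-supplied seed.

Numerical details worth knowing: deviances are floored at zero before the
chi-square tail (guarding tiny negative round-off); `0 log 0 = 0`
throughout the closed-form likelihoods; logit means are clamped to
`[1e-10, 1 - 1e-10]` inside the beta-binomial objective; the derangement
is drawn by rejection (expected <3 attempts at any n, and n = 1 is an
error since no derangement exists).

# Known limitations

* Synthetic coverage is independent across sites and samples; real capture
  data have strong site-level coverage structure (probe GC, mappability).
* The digest emulation covers whole retained fragments, overstating
  per-read coverage uniformity of real reduced-representation data.
* No covariates or random effects in the tissue model; repeated donors
  across tissues violate independence in ways the fixed-effect model
  ignores.
* Headline concordance values of any real TMS/EPIC/WGBS comparison depend
  on the raw data of that experiment; this package reproduces the
  *procedures* and their qualitative signatures, with all quantitative
  claims made on synthetic truth.
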