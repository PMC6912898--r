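---
title: "Methods: windowed divergence scans and demographic ABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed divergence scans and demographic ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

divscan compares the genomes of two closely related populations or sister
species — the motivating system is a pair of tidal-marsh sparrows, a
saltmarsh specialist and its sister that spans a saline–freshwater
ecotone — from cohort resequencing data, and asks two questions: *where*
is divergence concentrated (windowed scan and outlier detection), and
*what demographic history* produced the genome-wide background
(coalescent simulation plus approximate Bayesian computation). This
vignette explains the models, the defaults and the numerical choices.

## Site filtering

The scan operates on biallelic SNPs with per-sample genotypes (and
optionally depths). Filters mirror standard cohort-level practice:

* **Minor allele frequency** < 5% (default), computed over the pooled
  called alleles of both populations. The pooled choice follows what a
  cohort-level VCF filter does; a per-population MAF filter would also
  remove fixed differences, which are the object of study. Planted fixed
  differences always have pooled MAF 0.5 and are never lost here.
* **Missingness** > 20% of genotypes at a site (default).
* **Depth screen**: site mean depth below 3× or more than 2 SD above the
  genome-wide mean of site mean depths. The genome-wide mean and SD are
  computed once, on the input matrix, before any other filter, so the
  report is reproducible regardless of rule order; the screen is skipped
  with a warning when depths are absent.
* **Scaffold exclusion list**: sex-linked scaffolds are supplied by the
  user (e.g. from a synteny mapping to a karyotyped reference); divscan
  does not infer linkage itself.

Missing genotypes are excluded from every allele count; no imputation is
performed, so the per-site sample size varies.

## Window statistics

Scaffolds are tiled with nonoverlapping 100-kb windows, 1-based with
inclusive ends: `[1, 100000]`, `[100001, 200000]`, … A site at position
*p* belongs to window `floor((p-1)/L)`. Per window, divscan reports:

* **F~ST~** — the Weir & Cockerham (1984) estimator for two populations.
  Per-site variance components *a* (among populations), *b* (among
  individuals) and *c* (within individuals) are computed from called
  individuals, allele frequencies and observed heterozygote frequencies;
  the window value is the weighted "ratio of sums" Σa / Σ(a+b+c). Sites
  where either population has fewer than two called individuals are
  skipped. Negative values are reported as computed, not truncated —
  the convention of the standard VCF tooling. A mean-of-ratios column is
  emitted alongside for comparison, since windowed F~ST~ summaries differ
  between the two conventions.
* **D~xy~** — per-site absolute divergence p̂₁(1−p̂₂) + p̂₂(1−p̂₁). The
  primary output averages over variant sites (`dxy_per_snp`); a per-bp
  variant divides by window length. The per-SNP denominator is primary
  because genome-wide D~xy~ values near 0.44 on variant-only SNP data are
  only obtainable by averaging over variant sites, not per bp.
* **π** — per-bp nucleotide diversity from the unbiased per-site pairwise
  estimator 2·c~ref~·c~alt~/(n(n−1)) over called alleles n.
* **Tajima's D** per population, from S (segregating sites) and k (mean
  pairwise differences). With missing data the constants need a single
  sample size per window: n is taken as twice the modal number of called
  individuals in the window; sites with other call counts still
  contribute to S and k. This keeps the constants well-defined without
  discarding data.
* **Heterozygosity** — `h_obs` is the mean observed heterozygote
  frequency across sites and populations; `h_exp` uses the unbiased
  within-population genic diversity n(1−Σp²)/(n−1), averaged across
  populations, for consistency with the genic diversity used by the ABC
  summary statistics.
* **Fixed differences** — a site is *fixed* when the called allele sets
  of the two populations are disjoint (each population monomorphic, for
  different alleles); `df` is the count per bp of window. By
  construction `df × window_length` is an integer.

## Outlier windows and candidate genes

Windows with fewer than 10 SNPs are discarded, then scaffolds
contributing fewer than 2 retained windows ("regions with less than two
windows": scaffold is the only grouping available before outlier
detection, so it is read as a scaffold-level rule). On the retained
distribution, the empirical 99th percentile of F~ST~ and of df are
computed with linear interpolation between order statistics (R quantile
type 7). "Above the threshold" is strict inequality, so ties at the
threshold are never flagged; with *N* retained windows at most
⌈0.01 N⌉ windows (plus exact ties) can be flagged per criterion. The
*elevated* set is the intersection of the two single-criterion sets.
Adjacent elevated windows merge into regions for gene-proximity
reporting, but window counts are always reported pre-merge, because both
window and scaffold tallies are standard in scan reports.

Genes within 50 kb of an elevated region (inclusive interval
intersection) are reported. Candidate-gene regions are the gene ± 20 kb;
their mean F~ST~ is the same ratio-of-sums estimator over region sites
(per-site ratios would up-weight low-information sites), and a region is
called *exceeding* when its mean F~ST~ is above the upper bound of the
genome-wide 95% confidence interval, computed as a normal approximation
mean ± 1.96·SD over window F~ST~ values. A block-bootstrap CI would
respect autocorrelation along scaffolds; the normal approximation is
used because the scan treats windows as the sampling unit everywhere
else, and the interval is a descriptive yardstick rather than a test.

The "percentage of fixed sites" column for candidate genes is computed
as 100 × fixed / variable sites in the region. Published per-gene tables
of this kind sometimes use a denominator that cannot be reconstructed
from the printed columns (the printed percentages are consistent with
neither fixed/variable nor any integer rescaling of it), so the
denominator choice is explicit here and the variable-site version is the
default.

## The synthetic genome generator

The generator exists so every scan stage can be validated against known
truth. It emulates the observed cohort structure: 10 + 10 diploid
individuals, multi-scaffold genomes in 100-kb windows, background
between-population divergence near F~ST~ ≈ 0.32, background fixed-SNP
density ≈ 0.00022/bp, planted elevated windows (defaults F~ST~ 0.6,
fixed density 0.0013/bp), ≤ 20% missing genotypes (default rate 0.1)
and negative-binomial per-genotype depths (mean 10, size 1.1, matching a
mean SNP depth near 10 with SD near 10). The default SNP density is
6 × 10⁻³/bp — the study's realized genome-wide SNP density — so fixed
differences are a few percent of SNPs, as observed.

Background sites follow a **Balding–Nichols** model: ancestral frequency
p ~ U(0.05, 0.95) (bounded away from the boundaries so the MAF filter
removes a predictable small fraction), population frequencies
Beta(p(1−F)/F, (1−p)(1−F)/F) drawn independently per population, and
genotypes Binomial(2, p_pop). Balding–Nichols is used instead of a
coalescent because the scan needs site-level frequency control and
window-level truth, not genealogical realism; the ABC module carries the
genealogy-dependent testing. The differentiation parameter F is
**calibrated by bisection** so the realized mean window Weir–Cockerham
F~ST~ of a probe genome (5,000 sites, same probe seed at every
evaluation so the bisection target is monotone in F) hits the requested
value within ±0.01. Planted windows use a second calibrated F for their
elevated target plus extra fixed sites at their configured density.
Note that a planted window's *realized* window F~ST~ exceeds its BN
target because the planted fixed differences also enter the estimator —
the target controls the polymorphic background of the window.

What the generator does **not** emulate: linkage disequilibrium within
windows (sites are independent), sequencing error, allele-frequency
correlation along scaffolds, or selection at linked sites. Passing the
planted-recovery tests therefore demonstrates that the scan machinery
identifies frequency-differentiated windows correctly, not that real
divergence islands have this clean structure.

## Demographic scenarios and the coalescent simulator

Three histories are modeled for the pair (SALS = saltmarsh lineage,
NESP = sampled Nelson's lineage), all with an unsampled ghost lineage
that splits from the ancestral NESP population at T₂ and is otherwise
absent (no samples, no migration, size never used):

1. **simple split** — NESP merges into the ancestral NESP population at
   T₂ (backward in time), which merges with SALS into the common
   ancestor at T₁ (T₂ < T₁).
2. **size change** — as (1), with a piecewise-constant NESP size path:
   N_NESP until T_fall, N_largeNESP on (T_fall, T_rise), N_smallNESP on
   (T_rise, T₂), enforcing T_fall < T_rise < T₂.
3. **admixture** — as (1), plus a pulse at T_admix < T₂ in which each
   sampled-NESP lineage derives from the parental NESP lineage with
   probability r, else from SALS. r labels the *parental NESP* share;
   the labeling is symmetric under r → 1−r and is a configuration
   convention.

All priors are uniform (times in years, converted continuously to
generations at 2.3 years/generation; diploid sizes): T₁ 0.4–1.5 M,
T₂ 0.1–0.5 M with T₂ < T₁ by whole-vector rejection, N_SALS 20–150 k,
N_NESP 1–50 k, N_AncestralNESP 1–150 k, N_Ancestral 100–500 k, T_rise
50–200 k, T_fall 10–50 k, N_smallNESP 1–50 k, N_largeNESP 50–100 k,
T_admix 0–100 k (the stated prior is only an upper bound, so 0 is the
natural lower bound; T_admix < T₂ holds automatically given the T₂
prior but is enforced anyway), r 0.001–0.999. The per-generation
mutation rate 7.59 × 10⁻⁹ (= 3.3 × 10⁻³ subs/site/Myr × 2.3 yr) is an
interpretive scaling constant; the SNP-locus simulation itself needs no
mutation rate.

Each unlinked locus is a structured Kingman coalescent (pairwise
coalescence rate 1/(2N) per generation within a population,
piecewise-constant sizes, merges and the admixture pulse at their event
times), implemented in C++ with R's RNG so a single `set.seed()` governs
everything. One mutation is placed per locus on a branch chosen
proportionally to branch length, so every locus is variable in the
pooled sample.

**SNP ascertainment.** A locus ascertained as "variable" in sequence
data is observed with probability proportional to its total genealogy
length. The simulator therefore emits a Poisson(λ·L) number of loci per
simulated genealogy (length-biased ascertainment; marginally exact for
any λ, which is set from a 16-genealogy pilot so that on average one
locus is emitted per genealogy). Without this, placing one mutation per
unweighted genealogy over-represents short genealogies and distorts the
site-frequency spectrum away from the neutral SNP expectation ∝ 1/i by
several percent in the singleton classes — a real, chi-square-detectable
bias at 50,000 loci, even though it is the shortcut some established
simulation tools use for fixed-SNP loci. The package's tests verify the
∝ 1/i spectrum directly.

## ABC: summary statistics, model choice, estimation

Ten summary statistics are computed per dataset: for each population the
mean and variance of nonzero per-locus genic diversity
(n(1−Σp²)/(n−1)) and the proportion of zero-diversity loci; the mean
and variance of nonzero per-locus Weir–Cockerham F~ST~; and the mean
and variance of nonzero per-locus Nei distance
−ln(J₁₂/√(J₁·J₂)). Zero or undefined values (e.g. infinite Nei distance
at fixed differences) are excluded from the nonzero means/variances; a
family with no nonzero values reports 0.

**Model choice** pools the per-scenario reference tables, standardizes
each statistic by its pooled median absolute deviation (falling back to
the SD, then to 1, when degenerate — the exact normalization used by the
reference GUI tool is not published), ranks rows by Euclidean distance
to the observed vector, retains the closest 1% and fits a multinomial
logistic regression of scenario label on the statistic differences with
Epanechnikov weights in distance. Posterior probabilities are the fitted
class probabilities at zero difference. A scenario absent from the
retained set is reported with probability 0.

**Parameter estimation** retains the closest 1% of the chosen scenario's
table and applies the Beaumont local-linear regression adjustment, with
times and sizes log-transformed (back-transformed afterwards) and the
admixture proportion adjusted on its natural scale and clipped to
[0, 1]. Intervals are equal-tailed 2.5–97.5% weighted quantiles of the
adjusted draws; they stand in for HPD intervals (for the near-unimodal
posteriors involved the difference is small) and are labeled as such in
the output metadata. A singular regression design falls back to the
unadjusted rejection posterior with a warning.

**Posterior predictive error** resamples (scenario, parameters) pairs
from the 500 pooled rows nearest the observed vector, simulates a fresh
dataset for each, reclassifies it, and reports the misclassification
fraction.

**SNP selection for observed data** mirrors the neutrality and quality
filters: no missing genotypes, depth ≥ 5 in every individual, mean depth
strictly between 8 and 12, per-SNP F~ST~ within 1 SD of the genome-wide
mean, spacing ≥ 20 kb enforced greedily after a seeded shuffle, then
disjoint sets drawn without replacement ("without replacement" is read
as disjoint across sets; the alternative reading would allow re-use
between sets).

## Problem sizes and numerical choices

Desk-scale defaults used by the test-suite and the acceptance script —
chosen as the smallest sizes at which the stochastic checks are stable:
reference tables of 10⁴ simulations × 2000 loci per scenario; 50
replicates for scenario-recovery and coverage experiments; 100
pseudo-observed datasets for the error rate; synthetic genomes of 10 ×
10-Mb scaffolds (1000 windows, ≈ 600 SNPs/window); 50,000 loci for the
site-frequency-spectrum check. The full-scale analysis (10⁶ simulations
per scenario, three SNP sets) uses exactly the same code paths via
`run_abc(config, scale = 1)`.

Other numerical details: empirical quantiles are type 7; the bisection
calibration tolerance is 0.01 on realized F~ST~; rejection sampling of
constrained priors redraws whole vectors (preserving marginal uniformity
of unconstrained parameters); per-row seeds in reference tables allow
exact replay of any row; TSV outputs encode NA as "." and all outputs
are byte-identical under a fixed config and seed.

## Known limitations

* Two populations only; no migration besides the single admixture pulse;
  no recombination within loci (appropriate for the unlinked-SNP design,
  not for haplotype statistics).
* The scan's windows are independent units: no kernel smoothing, no
  autocorrelation modelling, no haplotype-based statistics.
* The genome-wide CI and the percentile thresholds inherit the usual
  caveats of empirical outlier scans: they describe the tail of the
  realized distribution, they do not test a null model of neutrality.
* ABC results are conditional on the three candidate scenarios; model
  choice cannot favor a history that was never simulated.
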