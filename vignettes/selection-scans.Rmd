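---
title: "Predictability, drift and selection: the models behind predscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictability, drift and selection: the models behind predscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predscan)
```

predscan connects three layers of evidence about local adaptation in
pond-dwelling, cyclically parthenogenetic zooplankton: how predictable each
habitat is, how life-history traits vary among populations, and where in the
genome allele frequencies depart from neutral expectations. This vignette is
the package's own account of the models, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not show.

## Environmental predictability

A lake's regime is summarized from a monthly wet/dry series spanning many
years. `build_contingency()` tabulates states (wet, dry) against calendar
months; `colwell_indices()` decomposes predictability information-theoretically.
With column totals $X_j$, row totals $Y_i$, grand total $Z$ and $s = 2$
states,

$$C = 1 - \frac{H(Y)}{\log s}, \qquad
  M = \frac{H(X) + H(Y) - H(XY)}{\log s}, \qquad P = C + M,$$

where $H(\cdot)$ are Shannon entropies with $0\log 0 := 0$. Constancy $C$ is
high when the lake is almost always in the same state; contingency $M$ is
high when the state is strongly month-dependent; predictability $P$ is their
sum and lies in $[0,1]$, with $P = C + M$ holding exactly for every table.
Natural logarithms are used internally; the base cancels in all normalized
quantities. A permanently inundated lake has $C = 1, M = 0, P = 1$; a
strictly seasonal lake has $C = 0, M = 1, P = 1$; an unpredictable
coin-flip lake has $P \to 0$ as the series grows. Months missing from the
record simply contribute no counts — nothing is imputed, matching how such
tables are built from intermittent satellite coverage.

The hydroperiod is the wet fraction of all observations.

## The genotype layer and quality control

Analyses start from a clones-by-SNPs dosage matrix with per-genotype read
depth (`geno_matrix()`, read from VCF with `read_geno_vcf()`). Depth-based
genotype masking (`mask_low_depth()`, default: calls supported by fewer than
six reads become missing) precedes five sequential site filters
(`apply_site_filters()`):

1. call rate at least 50% **within every population** (the strict reading of
   a per-population requirement);
2. pooled minor allele frequency strictly above 1%;
3. exactly two alleles;
4. mean read depth over called genotypes strictly below 150 (guards against
   collapsed repeats in a reduced-representation assay);
5. heterozygote fraction strictly below 60% (same guard, pooled over
   populations by default — whether the original rule was pooled or
   per-population is not documented, so the per-population variant is a
   config switch).

Filters are applied in this order and the attrition report attributes each
removed SNP to the first filter it fails. Inequalities are exactly as
stated: ties at a threshold (a genotype at depth 6, a SNP with 60%
heterozygotes) resolve by the strict/non-strict rules above.

## Population-genetic summaries

Expected heterozygosity uses Nei's unbiased small-sample correction
$\tfrac{2n}{2n-1}(1 - \sum_k p_k^2)$; $F_{IS} = 1 - H_o/H_e$ is averaged
over polymorphic loci only. $F_{ST}$ is Weir and Cockerham's $\theta$
throughout, combined across loci as the ratio of summed variance components
(ratio of averages), the standard multilocus combination. Tajima's D is
computed per window (default: the whole scaffold), because D is undefined
for a single SNP, and every SNP inherits its window's value; with
missingness the window uses the median called-allele count. Hardy-Weinberg
is tested with the exact conditional test on heterozygote counts, Bonferroni
corrected over SNP-by-population tests. The heterozygosity/lake-area
relationship is a Pearson correlation of $H_e$ against $\log_{10}$ area;
the primary p-value is one-sided because larger lakes proxy larger
effective population sizes (the printed `t = 2.15, df = 7, p = 0.034`
corresponds to the one-sided tail); both tails are reported. The base of
the logarithm does not affect the correlation.

## The F-model outlier scan

`fit_f_model()` decomposes locus-by-population differentiation as

$$\mathrm{logit}(F_{ij}) = \alpha_i + \beta_j,$$

with a reversible-jump MCMC toggling each locus effect $\alpha_i$ in and
out of the model at prior odds for neutrality of 10 (prior inclusion
$1/11$). Included positive $\alpha$ marks above-background differentiation
(diversifying selection), negative below-background (balancing or
purifying). Population frequencies follow the Balding–Nichols beta model
around an ancestral frequency $\pi_i$; unlike samplers that carry the
latent $p_{ij}$, the beta layer is integrated out analytically, so the
likelihood of the minor-allele counts is beta-binomial. This is exact,
removes $L \times J$ latent variables, and mixes faster at desk scale.

Priors are the conventional ones for this model family:
$\alpha \sim N(0,1)$, $\beta_j \sim N(-1,1)$, $\pi_i$ uniform (sampled on
the logit scale with the Jacobian). The reversible-jump birth proposal is
the $\alpha$ prior itself, so the proposal density cancels the prior in the
acceptance ratio. Random-walk scales are tuned by pilot runs toward a
25–45% acceptance window; acceptance outside $[0.1, 0.6]$ after tuning
raises a diagnostic warning. The full-scale chain shape (20 pilots × 1,000;
10,000 burn-in; 2,000 samples at thinning 10) is the default; the tests and
the worked examples use reduced chains (4–5 pilots × 150–200; 1,200–1,500
burn-in; 500–600 samples at thinning 2), which finish in tens of seconds on
a few hundred loci on one CPU.

q-values follow the Bayesian FDR convention: sort loci by decreasing
posterior inclusion probability; a locus's q is the mean posterior
probability of neutrality over all loci at least as extreme. Selection is
called at q < 0.05 and classified by the sign of the posterior mean
$\alpha$. For the below-background class, two balancing-consistency flags
separate balancing from purifying interpretations: minor allele frequency
above the mean MAF of non-outlier SNPs (the non-outlier complement is used
as background), and positive Tajima's D.

## Environmental association with population covariance

`bayes_factor_scan()` models standardized population frequency deviations
$z_j = (\hat p_{ij} - \bar p_i)/\sqrt{\bar p_i (1 - \bar p_i)}$ as
multivariate normal with a neutral population covariance $\Omega$; the
alternative adds a linear effect $\beta E_j$ of the standardized variable
to the mean. The Bayes factor integrates the likelihood ratio over a
symmetric uniform prior on $\beta$ (default support $[-0.3, 0.3]$, 201
fixed quadrature nodes — the prior on the effect is not documented for this
model family, so support and density are config knobs). Pooled frequencies
are shrunk toward $1/2$ by one pseudo-allele to avoid $0/1$ degeneracy.

$\Omega$ is estimated by the moment estimator — the average over loci of
outer products of standardized deviations — with seeded bootstrap
resampling over loci providing ten variants; this replaces the MCMC
covariance estimation of the published tool family with something
deterministic and testable, while still giving the downstream rank
statistic genuine run-to-run variability. Twenty scan runs cycle through
the ten matrices; because the quadrature is deterministic, runs sharing a
matrix give identical Bayes factors, so the effective variability is the
ten bootstrap draws.

Per run, Bayes factors are rank-scaled to $[0,1]$ (ties get average ranks,
so an uninformative run contributes 0.5 everywhere), averaged across runs,
and SNPs with mean rank above 0.99 are flagged. The mean rank is invariant
to any monotone transform of the Bayes factors within a run.

## Stratification-corrected association (GWAS)

`eigenstrat_scan()` residualizes both the phenotype and every SNP dosage on
the top $k$ principal components of the mean-imputed, centred genotype
matrix and refers $(n - k - 1)\,r^2$ of the residual correlation to a 1-df
chi-square. $k$ defaults to 10 (the methodology's convention; the choice is
a parameter and a sensitivity sweep over $k \in \{2, 5, 10\}$ is a
one-liner with `purrr::map()`). Missing dosages are mean-imputed before PCA
and residualization, keeping $n$ constant. Bonferroni correction is over
tested SNPs; the genomic-inflation factor $\lambda$ is reported but never
applied. With $k = 0$ the statistic reduces to an Armitage-trend-style
test.

## Gene context

SNPs are assigned to every gene whose 1-based inclusive interval, extended
symmetrically by 0, 2.5 or 5 kb, contains their position; strand is ignored
because the flanking convention is symmetric. SNPs with no gene at the
widest flank are reported with the distance to the nearest gene on their
scaffold. GO enrichment is a two-tailed Fisher exact test per term with
Benjamini–Hochberg correction across terms, over a universe that defaults
to the annotated gene set (the universe choice is configurable — using all
gene models instead is defensible and changes only the margins).

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults encode the study design the analyses are calibrated
against: nine populations, 30 diploid clones each, a few thousand unlinked
biallelic SNPs, island-model differentiation at $F_{ST} = 0.18$,
negative-binomial read depth (GBS depth is overdispersed, and the depth
filters need realistic tails), and uniform random missingness. Ancestral
frequencies are uniform on $[0.05, 0.95]$; Balding–Nichols is the
generative counterpart of the F-model the scan fits, which makes parameter
recovery a well-posed test. Selected classes enter as logit shifts of the
differentiation ($\pm$`alpha_effect`), environmental correlation as a
logit-scale mean shift of `env_beta` per standard deviation of the
gradient. Clones are simulated as unrelated Hardy–Weinberg draws — real
clones hatched from an egg bank may be related, and nothing here emulates
linkage, selective sweeps' footprints, allele-frequency clines from
isolation by distance, or reference-bias in genotyping. Passing recovery
tests therefore shows the estimators invert their own generative model
correctly, not that they are robust to every feature of real GBS data.

## Power: what a desk-scale test can and cannot detect

Two power profiles, mapped during the design of the test suite, shape which
scenarios the recovery tests use:

- **F-model recovery.** With nine demes, the realized per-locus $\theta$
  of a locus with $\alpha = 2$ spreads so widely (Balding–Nichols draws
  across only nine populations) that roughly a quarter to a third of such
  loci land inside the neutral distribution; recovery at FDR 0.05 plateaus
  near 55–80% regardless of chain length or background $F_{ST}$ — the
  limit is information in the data, not the sampler. Recovery reaches
  81–83% at 12 demes and 85–88% at 16. The power test therefore runs a
  16-deme design, where a correct implementation clears an 80% bar with
  margin and a failure indicates a defect rather than seed luck; FDR
  calibration stays at the nine-population, $F_{ST} = 0.18$ study design.
- **Environmental association.** A logit shift of 0.8 per gradient-SD
  produces a systematic standardized-frequency signal of roughly 0.37 per
  SD, against drift noise of sd $\approx \sqrt{F_{ST}}$. At the study's
  $F_{ST} = 0.18$ only ~30% of such loci exceed the 0.99 mean-rank
  threshold — consistent with the general caveat that outlier and
  association scans lose power under high neutral differentiation. At
  $F_{ST} = 0.05$ recovery is a borderline 67–78%; at $F_{ST} = 0.02$ it
  is a robust 87–100%. The recovery test runs the weak-drift design
  ($F_{ST} = 0.02$, 0.5% of loci environmental so the ~1%-capacity rank
  threshold is not saturated), averaged over three seeds.

Both profiles, including the study-condition numbers, are reproducible from
the generator; the figures quoted here are the ones the test suite and the
acceptance script themselves compute.

## Numerical conventions and degenerate inputs

- Dosages are minor/ALT-allele counts 0/1/2 with `NA` for missing; depth 0
  is a valid (uncalled) observation.
- Monomorphic loci: excluded from $F_{IS}$ averages, given p = 1 by the
  HWE test, rejected by `fit_f_model()` (the scan cannot place a locus
  with no frequency information) — the pipeline drops them after
  filtering.
- `q_values()` gives tied inclusion probabilities the worst q of their tied
  block, so ties cannot straddle the FDR threshold.
- Ranks within a Bayes-factor run use average ranks for ties; an all-tied
  run is uninformative (0.5 everywhere) rather than arbitrary.
- Mantel p-values are one-sided with the `(count >= observed + 1)/(n_perm + 1)`
  convention; permutations are seeded.
- PCA drops all-missing SNP columns with a warning; per-axis variance
  percentages sum to 100 by construction.
- All stochastic stages draw from seeds derived from a single master seed;
  rerunning a `run_config()` reproduces every output byte for byte.

## Known limitations

- The F-model is biallelic only; multiallelic sites must be filtered
  upstream (the QC cascade does).
- Tajima's D per SNP is the window value; per-SNP D is not defined, and
  the window convention (whole scaffold by default) is a documented choice,
  not an inference.
- The geographic distance matrix of the original nine-lake system is not
  packaged (it was never printed), so isolation-by-distance results on the
  real system are not reproducible here; `mantel_ibd()` is validated on
  simulated and fixture matrices instead.
- With few populations the covariance-aware scan's power is intrinsically
  low (see the power section); a non-significant scan on nine demes is
  weak evidence of absence.
- The GWAS stage reports, but does not correct by, genomic inflation; a
  mixed model with kinship is out of scope.
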