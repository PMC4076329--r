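---
title: "Trans-ethnic fine-mapping by LD-cluster partitioning and proxy-set filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trans-ethnic fine-mapping by LD-cluster partitioning and proxy-set filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finemapld)
```

## The problem

A GWAS hit at a locus like *FTO* intron 1 is not one variant but a block of
dozens of SNPs in strong linkage disequilibrium (LD), all carrying nearly
the same association signal. Statistical fine-mapping tries to shrink that
block to the subset that can plausibly contain the causal variant(s).
`finemapld` implements a systematic two-part procedure:

1. **Partition**: select index SNPs by greedy LD clumping, bin every
   associated SNP with the index it correlates with most strongly, then
   screen clusters with pairwise conditional regression and haplotype-dosage
   association.
2. **Filter**: in each ancestry group, expand the retained indices into
   proxy sets (SNPs above an r² threshold) and intersect the sets across
   groups. Because LD decays differently in different ancestries, the
   intersection is smaller than any single-population candidate list.

Both parts operate on ordinary data frames and a light genotype container,
so every stage can also be driven separately.

## Models and statistics

**LD estimation.** Pairwise haplotype frequencies are estimated from
unphased genotypes by maximum likelihood: the familiar two-locus EM that
splits double heterozygotes between the coupling and repulsion phases in
proportion to their expected frequencies. To avoid the (rare) local optima
of this likelihood on small samples, three deterministic starting points
are used — linkage equilibrium and near-extreme coupling/repulsion — and
the best converged likelihood is kept. From the fitted frequencies,

$$D = f_{AB} - p_A p_B,\qquad r^2 = \frac{D^2}{p_A q_A p_B q_B},\qquad
D' = \frac{|D|}{D_{max}},$$

with $D_{max} = \min(p_A q_B, q_A p_B)$ for $D > 0$ and
$\min(p_A p_B, q_A q_B)$ otherwise.

**Quality control.** SNPs are screened by the conditional exact test of
Hardy–Weinberg equilibrium (enumeration over heterozygote counts given the
allele counts, no mid-p correction), with the conventional retention rule
p > 0.01. Failing SNPs are flagged, not silently removed.

**Association.** The quantitative trait (BMI) is rank-transformed to
normality separately within each sex using Blom scores,
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$ (the transform is cited in the
GWAS literature without a constant; 3/8 is the standard choice), then
regressed on the additive 0/1/2 effect-allele count with age and
age-squared as covariates. Disease status uses additive logistic regression
adjusted for sex; the coefficient is a log odds ratio. An association
counts as significant only when p < 0.05 *and* the direction matches the
established risk allele — the direction-consistency rule that guards
against winner's-curse sign flips in replication cohorts.

**Conditional screening.** For each pair of index SNPs, both genotypes
enter one regression. A SNP *loses* to a partner when its conditional p
exceeds the Bonferroni-adjusted level (0.05 divided by the number of SNPs
screened — 0.0056 for nine) while the partner's does not. A SNP that loses
against every other SNP is excluded: it is a weaker tag of the causal
variant than all of its neighbours. By default the rule is re-applied to
the surviving set (with the same pairwise results) until nothing more can
be excluded; a single pass — which can exclude at most the globally weakest
tag — is available via `iterate = FALSE`. Conditional models are fitted per
population with the marginal covariate sets and combined by fixed-effect
meta-analysis; the per-population level is the default because pooling
across ancestries would confound allele-frequency differences with trait
differences.

**Meta-analysis.** Inverse-variance fixed effect:
$w_i = 1/se_i^2$, $\hat\beta = \sum w_i \beta_i / \sum w_i$,
$se = (\sum w_i)^{-1/2}$, with Cochran's
$Q = \sum w_i(\beta_i - \hat\beta)^2 \sim \chi^2_{k-1}$ for heterogeneity.
Two-level combining (panels within population, then populations) is
algebraically identical to one-shot combining, and the tests assert this.
Random-effects models are out of scope: the procedure's decisions are made
on fixed-effect estimates.

**Haplotype analysis.** Multilocus haplotypes over up to 12 SNPs are
phased by EM with exhaustive diplotype expansion, uniform initialisation
over observed-compatible haplotypes, convergence at $10^{-8}$ on the
frequencies (cap 5,000 iterations), and pruning of haplotypes below
$10^{-4}$. The per-sample posterior over *ordered* diplotypes is retained,
making the haplotype dosage (posterior expected copy count) sum to exactly
2 over haplotypes for every sample. Trait association is regression on
this dosage, per population, meta-combined as above. A coalescent-informed
phaser would be more accurate for weak LD and many sites; for a short,
strongly structured block the EM MLE is adequate and deterministic.

**Haplotype phylogeny.** Rooted at the ancestral haplotype (all-ancestral
alleles), built by greedy minimum-mutation attachment: repeatedly attach
the unplaced haplotype closest in Hamming distance to any placed node,
labelling the edge with the differing SNPs; ties go to the
higher-frequency parent, then the parent closer to the root. Afterwards
any haplotype writable as a single crossover of two other placed
haplotypes — with strictly fewer implied events than its mutation edge —
is re-labelled as a recombination edge with its breakpoint interval. For
the *FTO* principal haplotypes this reproduces the published topology: the
protective lineage acquires one substitution (rs9939609) then another
(rs9941349), while the risk haplotype H1 descends from the ancestral
haplotype independently via the six cluster-A substitutions.

**The recombinant flank site.** rs7206790 lies beyond an ancestral
recombination breakpoint: both of its alleles ride on most haplotypes, and
the reference table can only record each haplotype's majority allele.
Treating those majority alleles as haplotype-defining would turn crossover
shuffling into phantom "mutations", so allele comparisons and the
phylogeny skip recombinant-flagged sites by default
(`skip_recombinant = FALSE` restores the raw comparison), and the site is
excluded from haplotype construction in the pipeline. This mirrors the
usual practice of restricting haplotype analysis to a non-recombining
block.

## The synthetic-data generator

No genotype accession accompanies the published analysis, so validation
rests on two generators with planted ground truth.

`simulate_panel()` emulates the *FTO* haplotype architecture: two
haplotypes per individual drawn i.i.d. from the configured frequencies
(the defaults are the published per-population estimates for H1–H4 and the
sub-haplotypes, normalised; "Low" entries become 0.002), genotypes derived
from the diplotype, and phenotypes generated under the additive model —
BMI as an age/sex baseline plus `bmi_beta_per_h1` (default 0.064 z-units,
the published combined H1 effect) per H1 copy plus N(0, `noise_sd`²)
noise, disease as Bernoulli with logit
`qlogis(baseline_prevalence) + t2d_logor_per_h1 × copies` (default
log 1.221). Ages are uniform on 35–74 and sex is Bernoulli(½): the real
cohorts' demographics are not emulated beyond covariate presence.
`baseline_prevalence` defaults to 0.3, a case share typical of the
enriched case-control panels used for disease association rather than a
population prevalence.

Filler proxy SNPs copy their core SNP's allele on each haplotype with
switch probability $\varepsilon = (1 - \sqrt{r^2_{target}})/2$, keeping
the haplotype structure coherent for phasing tests. The target is attained
exactly at matched allele frequency; for rare alleles the realised r² is
attenuated by $p(1-p)/q(1-q)$ (the filler drifts toward frequency
$p(1-2\varepsilon)+\varepsilon$), and the tests assert the analytic value
rather than the nominal target.

`simulate_cluster_panel()` plants *independent* LD clusters (core SNPs are
independent Bernoulli haplotype draws) for the partitioning and filtering
stages, with optional population-private proxies of the causal core —
exactly the SNPs a cross-population intersection should discard.

What passing these tests shows — and does not show. The generators produce
random-mating panels with block LD, no genotyping error, no missingness
beyond what tests inject, no admixture and no recombination maps. Recovery
under them validates the estimators and the decision logic, not robustness
to the full messiness of real cohort data (imputation error, relatedness,
ancestry stratification), which the procedure inherits from its inputs.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| index-selection p threshold | 0.05 with direction rule | the published "certain level of significance" is unspecified; nominal significance plus direction matches the screening use |
| `r2_independence` | 0.9 | the published working threshold: lower merges real clusters, higher makes indices conditionally indistinguishable at realistic n |
| proxy-set r² | 0.9 (array density), 0.95 (sequencing density) | the thresholds used for the published proxy listings |
| `alpha_adj` | 0.05 / #SNPs screened | recomputed from the input, never hard-coded |
| `freq_floor` (phylogeny) | 0.004 | the "Low" frequency cut in the published haplotype table |
| phasing caps | tol 1e-8, 5,000 iters, prune 1e-4 | frequencies are reported to ~3 decimals; the tolerance is far below that |
| LD window | 500 kb | the intron-1 region of interest is ~60 kb; the window only guards against pathological inputs |

## Numerical and design choices

- Missing genotypes are handled complete-case per test (per SNP, SNP pair,
  or phased SNP set); no imputation.
- Multi-allelic VCF records are rejected rather than split — the analysis
  is defined for biallelic SNPs.
- Logistic separation is detected after the fit (diverging log-OR or SE)
  and raised as an error rather than returning a meaningless estimate.
- Tie-breaks are all deterministic and documented: clumping ties by
  (p, position, id); cluster-assignment ties toward the physically nearer
  index, then lexicographic; phylogeny ties toward the higher-frequency
  parent, then the parent closer to the root.
- The pipeline expands one global seed into per-stage seeds with a
  counter-based scheme, so adding a stage never perturbs earlier stages'
  randomness; identical config and seed give byte-identical reports.
- Index candidates are restricted to SNPs present in every population
  panel, since indices must be conditioned on and proxied in each group.
  Population-private SNPs still enter their own group's proxy sets — and
  are then removed by the intersection, which is the point of the design.
  SNPs tagging population-specific haplotypes are *not* otherwise removed;
  the intersection cannot exonerate them.

Two validation-design choices deserve a note. The conditional-screen
simulations plant an effect of 0.15 z-units at n = 20,000 — chosen by
power analysis (conditional SE ≈ 0.017 against a 0.0056 threshold) so that
replicate success rates measure the method, not sampling luck. And the
exclusion-screen ground truth uses a Markov chain of proxies (each SNP a
noisy copy of the previous) rather than star-shaped proxies of one causal
SNP: with star LD every proxy retains residual signal given any *other*
proxy, so no proxy loses to every partner and one pass can only remove the
single weakest tag — which is precisely the behaviour seen on real data,
where a single SNP was excluded per trait. The chain structure is the
cleanest situation in which iterated exclusion provably isolates the
causal SNP.

## Problem sizes in the test-suite and acceptance script

Simulated panels use n = 400–5,000 for distributional checks, n = 10,000
(quantitative trait) and n = 20,000 (disease) for the 100-replicate
recovery rates, 1,000 replicates for Cochran's Q calibration, and the
published per-population sample sizes (10,659 / 3,324 / 3,029) for the
combined haplotype-effect estimates. These sizes keep every estimate's
sampling error well inside its test tolerance.

## Known limitations

- EM phasing is exhaustive in the diplotype space; beyond ~12 SNPs it is
  not usable and no partition-ligation fallback is provided.
- The exact HWE p-value is conservative (discrete support), so uniformity
  checks are one-sided.
- The phylogeny classifier considers single crossovers only; recurrent
  mutation and double crossovers are indistinguishable from extra
  substitution events, and sub-haplotype placement depends on event-cost
  assumptions that the greedy rule does not fully pin down.
- Printed cross-population heterogeneity p-values are generally not
  reproducible from rounded per-population tables (the originals used
  unrounded panel-level estimates); the package reports its own Q on
  whatever inputs it is given.
- Genotype imputation, functional annotation lookups and credible-set
  (Bayesian) fine-mapping are out of scope.
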