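# finemapld

Trans-ethnic statistical fine-mapping of an associated GWAS locus, for
geneticists who have an established hit region — think *FTO* intron 1 and
BMI / type 2 diabetes — and want to shrink a block of correlated SNPs to
the candidates that can actually contain the causal variant(s).

The package implements a two-part procedure on top of a tidy,
data-frame-first API:

1. **Partition.** Select index ("top hit") SNPs by greedy LD clumping:
   sort significant SNPs by p-value and accept a SNP as a new index only
   if its r² to every accepted index is below an independence bound
   (default 0.9). Assign every associated SNP to the index it correlates
   with most strongly. Screen clusters by (a) the direction-consistency
   significance rule (p < 0.05 *and* the established risk allele), (b)
   pairwise conditional regression — a SNP whose conditional p exceeds the
   Bonferroni level `0.05 / n_SNPs` against every partner, while each
   partner stays significant, is excluded as a weaker tag — and (c)
   EM-phased haplotype-dosage association.
2. **Filter.** In each ancestry group, expand the retained indices into
   proxy sets `{s : r²(s, index) ≥ threshold}` and intersect across
   groups. LD decays differently across ancestries, so the intersection is
   the smallest defensible candidate list.

The statistical core: two-locus and multilocus EM haplotype-frequency
estimation from unphased genotypes (r², D′, posterior diplotypes and
dosages), the exact conditional Hardy–Weinberg test, sex-stratified
rank-based inverse-normal transformation (Blom scores), additive
linear/logistic single-SNP models, inverse-variance fixed-effect
meta-analysis with Cochran's Q

```
w_i = 1/se_i²,  β = Σ w_i β_i / Σ w_i,  se = (Σ w_i)^{-1/2},
Q = Σ w_i (β_i − β)² ~ χ²(k−1)
```

and an ancestral-rooted haplotype phylogeny with greedy minimum-mutation
attachment and single-crossover recombination classification.

A synthetic-data module generates multi-population panels with the *FTO*
haplotype architecture (H1–H4 plus recombinant sub-haplotypes at the
published per-population frequencies) or independent planted LD clusters,
with additive phenotype effects — so every pipeline stage is validated
against known ground truth.

## Worked example

Reproduce a published-style combined estimate from per-population summary
statistics (three Asian cohorts, beta in z-score units):

```r
library(finemapld)
fixed_effect_meta(beta = c(0.072, 0.039, 0.098),
                  se   = c(0.017, 0.027, 0.031))
#>     beta    se      z p q_stat q_df p_hetero k
#> 1 0.0689 0.013 5.2799 0 2.1408    2   0.3429 3
```

The combined 0.069 (0.013) is the inverse-variance pooled per-allele BMI
effect. The haplotype phylogeny of the locus, rooted at the ancestral
haplotype:

```r
build_phylogeny(default_haplotypes())
#> <hap_phylogeny> 4 haplotypes rooted at H2
#>   H2 -> H3 (rs9939609)
#>   H3 -> H4 (rs9941349)
#>   H2 -> H1 (rs1421085,rs3751812,rs9941349,rs56137030,rs17817964,rs12149832)
```

H3 and H4 derive successively from the ancestral H2 by one substitution
each, while the risk haplotype H1 descends from H2 independently through
the six cluster-A substitutions. End to end, on three simulated
populations sharing one planted causal cluster (each population also
carries two private proxies of the causal SNP):

```r
cfg <- list(
  seed = 11,
  populations = list(
    list(name = "ASN1", n_samples = 1500, n_clusters = 3,
         fillers_per_cluster = 2, within_r2 = 0.98, private_fillers = 2),
    list(name = "ASN2", n_samples = 1500, n_clusters = 3,
         fillers_per_cluster = 2, within_r2 = 0.98, private_fillers = 2),
    list(name = "ASN3", n_samples = 1500, n_clusters = 3,
         fillers_per_cluster = 2, within_r2 = 0.98, private_fillers = 2)),
  proxy_r2 = 0.9)
run <- run_pipeline(cfg)
run$candidates
#> <candidate_set> 3 candidate SNP(s) in the 3-group intersection
#>   ASN1 (r2 >= 0.90): 5 SNPs
#>   ASN2 (r2 >= 0.90): 5 SNPs
#>   ASN3 (r2 >= 0.90): 5 SNPs
#> # A tibble: 4 × 2
#>   pattern        count
#>   <chr>          <int>
#> 1 ASN1&ASN2&ASN3     3
#> 2 ASN1               2
#> 3 ASN2               2
#> 4 ASN3               2
```

Each population's proxy set holds five SNPs (the three shared
causal-cluster SNPs plus its two private proxies); the three-way
intersection removes the private tags and returns exactly the planted
causal cluster. `tidy(run)` gives the per-SNP meta-analysed association
table with cluster labels, `glance(run)` a one-row run summary, and
`autoplot()` works on cluster assignments, candidate sets and phylogenies.

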