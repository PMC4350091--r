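# rvburden

Case–control rare-variant association analysis for targeted sequencing
panels, from read-level evidence to pathway enrichment.

The package addresses a common situation in the genetics of severe,
reproductively selected phenotypes (its motivating application is
non-obstructive azoospermia, sequenced over ~650 candidate genes in 757
cases and 709 fertile controls): almost all variation discovered is rare
(>85 % of sites below 1 % minor-allele frequency), no single variant
survives multiple-testing correction, and the signal only becomes visible
when rare alleles are aggregated per gene and per biological process.
`rvburden` re-implements that whole analysis as a reusable, testable
pipeline:

1. **Variant calling from genotype likelihoods** — per-sample genotype
   log-likelihood triples from allele-supporting read counts and base
   qualities; maximum-likelihood population allele frequency by EM under
   Hardy–Weinberg priors; a site is called when the likelihood-ratio
   statistic `2·(ℓ(p̂) − ℓ(0))` exceeds 24; Bayesian genotype calls use
   the HWE prior at `p̂`, masking samples below 8× depth. A filter bank
   removes sites with degraded minor-allele base qualities (one-sided
   rank-sum, P < 1e-5), strand bias (two-sided Fisher, P < 1e-5), or
   extreme depth / low mapping quality (mean ± 3 SD, MAPQ ≥ 20).
2. **Single-marker tests** (MAF ≥ 1 %) — logistic regression
   `status ~ age + dosage` with Wald statistics and label-permutation
   p-values, after differential call-rate/depth QC between groups.
3. **Gene-based rare-variant tests** — BURDEN (case minor-allele count),
   FRQWGT (control-frequency weights `1/sqrt(n_ctrl·q_j(1−q_j))` with
   pseudocounted `q_j`), VT (maximum standardized burden over MAF
   thresholds), UNIQ (case alleles at control-free loci), each with an
   adaptive permutation p-value `p = (r+1)/(b+1)` that stops once `r`
   exceedances accumulate; plus per-gene carrier frequencies, odds
   ratios and two-sided Fisher p.
4. **Gene-set aggregation** — per-gene and total counts of all /
   group-exclusive variant alleles and distinctive loci; Fisher exact
   tests of allele counts against total chromosomes (2N per group);
   carrier-based Fisher test; the normalized loci ratio
   `R = (loci_case/N_case)/(loci_ctrl/N_ctrl)`.
5. **Pathway enrichment** — hypergeometric over-representation
   `P(X ≥ k)` of nominally associated genes (empirical p < 0.05 on any
   test) in pathways with more than 10 sequenced genes, adjusted by
   Benjamini–Hochberg.
6. **Synthetic cohorts** — a calibrated generator (Beta(0.1, 20) MAF
   spectrum truncated to (0, 0.5], HWE genotypes, logistic carrier
   disease model, Poisson read depths) with full truth tables, so every
   stage above is testable without any patient-level data.

## Worked example

Reproduce the published gene-set burden test from the bundled summary
table, then run the gene scan on a simulated cohort:

```r
library(rvburden)

pub  <- published_table("geneset_counts")
rare <- pub[pub$stratum == "rare", ]
tab  <- aggregate_table(rare$gene, rare$all_case, rare$all_ctrl,
                        rare$excl_case, rare$excl_ctrl,
                        rare$loci_case, rare$loci_ctrl, 757, 709)
f <- fisher_allele_burden(tab, "all")
sprintf("allele burden: OR = %.2f, two-sided Fisher p = %.2g",
        f$odds_ratio, f$p_value)
#> "allele burden: OR = 1.87, two-sided Fisher p = 5.5e-07"
sprintf("loci ratio R = %.2f", normalized_loci_ratio(tab))
#> "loci ratio R = 1.81"
```

So cases carry 197 rare non-silent alleles in the gene set versus 105 in
controls — 1.9-fold enrichment per chromosome, far beyond chance — and
1.8 times more distinct variant sites per capita.

```r
cfg <- sim_config(n_cases = 150, n_controls = 150, n_genes = 25,
                  sites_per_gene = 8, carrier_odds_ratio = 3, seed = 7)
sim <- simulate_cohort(cfg)
gb  <- gene_burden_scan(sim$gm, sim$cohort, B_max = 2000, seed = 7)
head(gb[order(gb$p_BURDEN),
        c("gene", "p_BURDEN", "p_UNIQ", "carrier_freq_case",
          "carrier_freq_ctrl", "odds_ratio")], 3)
#>     gene p_BURDEN p_UNIQ carrier_freq_case carrier_freq_ctrl odds_ratio
#> 2  G0007   0.0274 0.0216              3.33              0.00      11.38
#> 1  G0003   0.1782 0.3861              1.33              0.00       5.07
#> 7  G0016   0.1980 1.0000              2.67              0.67       4.08
```

The top-ranked gene, `G0007`, is one of the simulated risk genes
(`sim$truth$causal_gene`); empirical p-values come from adaptive
permutation, and the carrier columns mirror the per-gene summary layout
of the published study.

A command-line interface covering every stage
(`simulate`, `call`, `assoc`, `burden`, `aggregate`, `enrich`, `run`)
ships in `inst/cli/rvburden.R`.

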