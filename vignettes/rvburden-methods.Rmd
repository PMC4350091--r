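---
title: "rvburden: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rvburden: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

`rvburden` implements a complete case–control rare-variant analysis for
targeted resequencing panels. This vignette documents the statistical
models, the tunable parameters and their defaults, what the synthetic
cohort generator does and does not emulate, and the numerical choices
made where the published description left the design open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Variant calling from genotype likelihoods

**Per-read error model.** Each read carries a Phred base quality $Q$,
giving an error probability $e = 10^{-Q/10}$. Sites are strictly
bi-allelic (the panel's downstream analyses never use a third allele),
and we collapse miscalls onto the other allele: a ref-template read is
observed as alt with probability $e$ and vice versa. The per-sample
genotype log-likelihoods are then

$$\ell(g) = \sum_{\text{reads}} \log P(\text{base} \mid g),\qquad
P(\text{alt read} \mid \text{het}) = \tfrac12(1-e) + \tfrac12 e = \tfrac12 .$$

The alternative convention $e' = e/3$ (miscalls uniform over the three
other bases) changes likelihoods by $O(e)$; we chose the bi-allelic
collapse because it matches the generative model of the simulator
exactly, making calibration checks exact rather than approximate. A
sample with zero reads gets a flat triple and is ignored by estimation.

**Population allele frequency.** The frequency $p$ is estimated by EM
under Hardy–Weinberg priors: the E-step computes genotype posteriors at
the current $p$, the M-step sets $p$ to half the posterior-mean dosage
over samples with data. Defaults: tolerance $10^{-8}$ on the update,
at most 100 iterations, initialization $p_0 = 0.05$ — chosen for robust
convergence at rare-variant frequencies; the suite verifies against a
grid-search maximizer (step $10^{-5}$) that the EM fixed point is the
marginal-likelihood maximum to within $10^{-4}$, and that the marginal
log-likelihood is non-decreasing across iterations.

**Site calling.** A site is polymorphic when
$2(\ell(\hat p) - \ell(0)) > 24$, a likelihood-ratio test against the
monomorphic-reference null. The null $p = 0$ is the standard no-variant
null; the threshold is strict (a statistic of exactly 24 is not called).
Genotypes are posterior modes under the HWE prior at $\hat p$; ties are
broken toward the smaller dosage. Samples below `min_depth = 8` reads
are set missing regardless of likelihood.

**Filter bank.** Three site-level filters, each applied to evidence
pooled across all individuals (the alternative — combining
per-individual tests — is not implemented; pooling follows the
description "across all individuals"):

* base quality: one-sided Wilcoxon rank-sum, minor-allele qualities
  smaller than major; remove at $p < 10^{-5}$. Because base qualities
  are heavily tied, the test enumerates rank assignments exactly when
  the pool is small ($\binom{n}{n_x} \le 2\times10^5$) and otherwise
  uses the tie-corrected normal approximation with continuity
  correction.
* strand bias: two-sided Fisher's exact test on the pooled
  allele × strand table; remove at $p < 10^{-5}$.
* depth / mapping quality: keep sites whose pooled depth lies within
  mean ± 3 SD of the cohort site-depth distribution (floored at 0) and
  whose mean MAPQ is ≥ 20. "Extremely high or low" is not quantified in
  the source description; 3 SD and MAPQ 20 are conventional and
  configurable. With fewer than two candidate sites the depth filter is
  disabled with a warning.

## 2. Single-marker association

Variants with combined-cohort MAF ≥ 1 % (low-frequency and common
strata) are tested by logistic regression `status ~ age + dosage`
(IRLS via `glm`), reporting the Wald $z^2$ on the dosage coefficient.
Rare variants are left entirely to the gene-based tests. Monomorphic
dosages, non-convergent fits and separation (dosage SE > 50) are
*flagged*, not raised. Permutation p-values shuffle phenotype labels
only — each sample keeps its age, preserving the covariate structure —
with $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(B+1)$ and $B = 10{,}000$
by default. The Wald statistic was preferred to score or LRT because it
is the cheapest to recompute per permutation; the choice is a function
argument away from being swapped.

Differential QC removes variants whose call rates (two-sided Fisher on
missing × group) or per-sample depths (two-sided rank-sum by group)
differ between cases and controls at $p < 10^{-5}$. The depth statistic
operates on the per-sample depth distributions (not group means): it is
the stronger check and the natural reading of a group comparison.

## 3. Gene-based rare-variant tests

MAF strata partition $[0, 0.5]$ with inclusive lower bounds: rare
$< 0.01$, low-frequency $[0.01, 0.05)$, common $\ge 0.05$. MAF is
computed on the combined cohort (a control-only option exists).
Missing genotypes count as zero minor alleles — conservative, and
standard for collapsing tests. All four statistics are one-sided for
excess burden in cases:

* **BURDEN**: total minor-allele count in cases.
* **FRQWGT**: weighted sum with
  $w_j = 1/\sqrt{n_{\text{ctrl}}\, q_j (1-q_j)}$,
  $q_j = (\text{ctrl minor alleles} + 1)/(2 n_{\text{ctrl}} + 2)$.
  Weights are recomputed from the permuted control group in every
  permutation, keeping the statistic a fixed function of data and
  labels.
* **VT**: for each observed variant MAF $t$, the case burden over
  variants with MAF ≤ $t$ is standardized by its
  sampling-without-replacement mean and SD under label exchange; the
  statistic is the maximum $z(t)$.
* **UNIQ**: minor alleles carried by cases at variants where controls
  carry none.

Empirical p-values come from adaptive permutation: labels are permuted
in batches (default 100) and the scan stops once $r \ge r_{\text{stop}}$
permuted statistics reach the observed one, reporting
$p = (r+1)/(b+1)$; otherwise it runs to $B_{\max}$. Defaults
$r_{\text{stop}} = 10$, $B_{\max} = 10^5$ are not dictated by the
published description and are exposed in the configuration. Ties with
the observed statistic count as exceedances (within a relative
$10^{-9}$ float guard), which keeps the p-value valid.

Per-gene carrier summaries use the cross-product odds ratio on the
carrier × group table, with a 0.5 continuity correction (flagged) when
a cell is zero, and the two-sided Fisher exact p in the
probability-sum convention — the convention under which the published
aggregate values (OR 1.9, $p = 5.5\times10^{-7}$, etc.) reproduce
exactly at printed precision, as the acceptance suite verifies.

## 4. Gene-set aggregation and enrichment

The aggregate table counts, per gene and in total: all qualifying minor
alleles per group; alleles at *group-exclusive* loci (zero minor
alleles in the other group — exclusivity is defined at the locus level,
the allele count then sums dosages there); and *distinctive loci*
(sites where the group carries ≥ 1 minor allele). Allele burdens are
tested against total chromosomes ($2N$ per group); the normalized loci
ratio is $R = (L_{\text{case}}/N_{\text{case}})/(L_{\text{ctrl}}/N_{\text{ctrl}})$,
reported as undefined when the control count is zero.

A gene is *nominal* when its minimum empirical p over the four tests is
strictly below 0.05. Pathways with **more than** 10 sequenced member
genes are tested by the hypergeometric upper tail $P(X \ge k)$ and
adjusted by Benjamini–Hochberg across the analyzed rows. BH is used
because applying it to the twelve published pathway p-values reproduces
every printed FDR entry exactly at printed precision (0.024, 0.06,
0.63, 0.73, 0.87) — the publication never names its FDR procedure.

When reconstructing integer counts from printed percentages (carrier
tables), `reconstruct_count()` inverts the rounding and *errors unless
the preimage is unique*, so no acceptance quantity rests on an
ambiguous reconstruction.

## 5. The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
with defaults fixed to the study design: 757 cases, 709 controls, 650
genes (12 sites each, 60/25/15 % non-silent/silent/UTR), ages uniform
on 22–45 (age is only a covariate and its true distribution is
unreported), Poisson(30) depths, 0.5 % base error.

* **MAF spectrum**: Beta(0.1, 20) truncated to $(0, 0.5]$ via inverse-CDF
  sampling. Only two spectrum fractions are stated for the real panel
  (> 85 % of sites below 1 % MAF, > 90 % below 5 %); this Beta gives
  ≈ 88 % and ≈ 98 %, satisfying both with margin. The parameters were
  fixed before any acceptance measurement and are unit-tested against
  the two fractions.
* **Genotypes**: Hardy–Weinberg at each site's true MAF, sites
  independent. No linkage disequilibrium, no population structure, no
  indels — so a green calibration test says nothing about robustness to
  stratification or LD, only about the statistics' null behavior and
  power under the stated model.
* **Disease model**: logistic on the carrier indicator — carrying ≥ 1
  rare (true MAF < 1 %) non-silent allele in a risk gene multiplies the
  disease odds by `carrier_odds_ratio` (default 1.9, the aggregate
  effect size of the motivating study) over a 10 % baseline. Individuals
  are simulated and case–control sampled until both quotas fill;
  retrospective sampling preserves the odds ratio, which is how the
  suite checks parameter recovery. For efficiency, carrier/disease
  status is drawn from the causal sites only and the disease-independent
  non-causal genotypes are filled in afterwards for the selected
  individuals — distributionally identical to simulating everyone.
* **Reads**: per sample × site, Poisson depth; heterozygote templates
  pick either allele with probability ½; miscalls flip the allele with
  the configured error probability; strands are fair coin flips; every
  base quality equals the Phred encoding of the error rate (capped at
  Q60). Real base-quality heterogeneity is *not* emulated; the
  base-quality filter is therefore exercised by construction rather
  than by realistic noise.

All randomness derives from a single master seed through per-stage
streams (`derive_seed`), so outputs are bit-reproducible and adding
permutations to one stage cannot perturb another.

## 6. Testing scale-downs and known limitations

Two acceptance properties are scaled for runtime, without loosening
their bands: the type-I-error check runs 200 replicate null genes with
$B_{\max} = 400$ permutations (ample resolution at $\alpha = 0.05$;
permutation p-values are discrete and hence conservative, so the lower
edge of the binomial band carries a small allowance), and the
carrier-OR recovery check simulates 60-gene panels at full cohort size —
the carrier model involves only the 8 risk genes, so null genes beyond
those needed for realism do not affect the recovered OR.

Known limitations: the ten-genotype (full diploid ACGT) likelihood
model is reduced to bi-allelic triples; no LD-based genotype refinement
(the matrix passes downstream unphased and unrefined); no BAM/CRAM
input (read evidence arrives as per-site summaries); no
covariate-adjusted burden tests and no variance-component (SKAT-type)
tests; single-marker analysis applies no stratification correction.
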