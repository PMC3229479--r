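# msrisksim

Polygenic risk-model simulation for multiple sclerosis (MS) prediction.

MS susceptibility is spread over one strong MHC locus (HLA-DRB1\*15:01,
tagged by rs3135388, per-allele OR ≈ 3) and dozens of common variants with
per-allele odds ratios of 1.08–1.2. This package asks how much predictive
power such panels can deliver, working entirely from published summary
statistics — no patient-level data. It is aimed at statistical geneticists
and epidemiologists who want a tested, reproducible implementation of the
classic Bayes likelihood-ratio simulation approach to genetic risk
prediction.

## The model

For variant *j* with control risk-allele frequency *q<sub>j</sub>* and
per-allele odds ratio OR<sub>j</sub>, genotypes follow Hardy–Weinberg
equilibrium in controls; the case allele frequency satisfies
*q\*/(1−q\*) = OR · q/(1−q)*; and the likelihood ratio of genotype
*g ∈ {0,1,2}* is LR<sub>j</sub>(g) = P(g|case)/P(g|control). A person's
posterior odds of disease are

```
posterior odds = p/(1−p) × Π_j LR_j(g_j),      risk = odds/(1+odds)
```

with *p* = 0.001 the lifetime MS risk, assuming independent multiplicative
effects. Discrimination is the AUC — the probability that a random case
outscores a random control — estimated two ways: exactly, by enumerating all
3<sup>K</sup> genotype combinations, and by Monte Carlo over simulated
populations of 100,000 individuals (100 replicates, Mann–Whitney statistic
with midrank ties, Bernoulli disease assignment from each individual's
posterior risk).

On top of the forward model the package provides:

* **Inverse design** (`required_or`, `table4_grid`): bisection with common
  random numbers for the per-allele OR that *k* added variants of a given
  frequency must carry to reach a target mean AUC.
* **Synthetic cohorts** (`generate_cohort`): case-control tables emulating a
  591-case/600-control study (demographics, per-genotype missingness,
  genotypes HWE within strata at OR-scaled frequencies).
* **Empirical-style pipeline**: per-SNP logistic association, weighted
  risk-allele scores (ln OR weights), risk-allele-count bins versus the
  cohort's a-priori risk via weighted sum-to-zero logistic coding, and the
  cohort AUC.

Packaged panels: `panel_6`, `panel_24`, `panel_53` (replicated + novel GWAS
loci) and `panel_empirical_6` (cohort-observed parameters).

## Worked example

```r
library(msrisksim)

# exact enumeration for the six replicated variants
analytic_auc(build_risk_model(builtin_panel("panel_6"), 0.001))
#> [1] 0.6755689

# Monte-Carlo AUC for the 53-variant panel (reduced size for illustration)
run_scenario(builtin_panel("panel_53"),
             study_config(n_individuals = 20000, n_reps = 10, master_seed = 1))
#> <auc_distribution> panel_53: mean AUC 0.7013 (SD 0.0796) over 10 replicate(s)

# synthetic cohort, analysed like a candidate-gene study
cohort <- generate_cohort(cohort_spec(seed = 7))
scores <- weighted_scores(cohort, builtin_panel("panel_empirical_6"))
round(a_priori_risk(cohort), 2)
#> [1] 0.51
round(cohort_auc(scores), 2)
#> [1] 0.69
binned_or_vs_prior(scores, n_variants = 6)[, c("bin_label", "n", "or_vs_prior")]
#>   bin_label   n or_vs_prior
#> 1       0-5 255   0.4470861
#> 2         6 285   0.7178470
#> 3         7 277   1.4401683
#> 4         8 206   1.5391947
#> 5         9  85   2.0298732
#> 6     10-12  31   4.9251327
```

The enumeration value says a six-variant model concentrates only modest
discrimination (AUC ≈ 0.68 under these published effect sizes); the cohort
block shows the familiar risk-allele-count gradient — subjects carrying
10–12 risk alleles have several-fold higher odds than the cohort-average
(a-priori) risk, those with 0–5 alleles about half — while the weighted
score's cohort AUC stays far below clinical usefulness.

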