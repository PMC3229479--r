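---
title: "Simulating multi-SNP risk models for multiple sclerosis prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multi-SNP risk models for multiple sclerosis prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msrisksim)
```

## The scientific question

Multiple sclerosis (MS) is a polygenic disease: one strong susceptibility
locus in the MHC (tagged by rs3135388, a proxy for HLA-DRB1\*15:01) and a
growing catalogue of common variants with per-allele odds ratios between
about 1.08 and 1.2. This package asks the question every genome-wide
association wave re-raises: if we genotype all of these variants in a
healthy person, how well can we predict whether they will develop MS — and
how much better could we do if more variants were discovered?

The package works entirely from published summary statistics (control
risk-allele frequencies and per-allele odds ratios) plus one epidemiological
anchor, the lifetime MS risk, taken as 0.1%. No individual-level patient
data are used anywhere; the empirical-style analyses run on a synthetic
cohort generator that emulates the summary structure of a real 591-case /
600-control candidate-gene study.

## The risk model

Each variant $j$ is a biallelic locus with control risk-allele frequency
$q_j$ and per-allele odds ratio $\mathrm{OR}_j$. Genotypes (risk-allele
counts $g \in \{0,1,2\}$) follow Hardy–Weinberg equilibrium (HWE) in
controls, $P(g \mid \bar D) = \binom{2}{g} q_j^g (1-q_j)^{2-g}$. The case
allele frequency follows by scaling the allele odds,
$q_j^\ast/(1-q_j^\ast) = \mathrm{OR}_j \, q_j/(1-q_j)$, and cases are HWE at
$q_j^\ast$ — equivalently, case genotype frequencies are proportional to
control frequencies times $\mathrm{OR}_j^g$, the multiplicative (log-additive)
per-allele model. The likelihood ratio of a genotype is

$$\mathrm{LR}_j(g) = \frac{P(g \mid D)}{P(g \mid \bar D)},$$

and a person's posterior disease odds are, assuming independent effects (no
linkage disequilibrium, no interactions),

$$\mathrm{odds}_{post} = \frac{p}{1-p} \prod_j \mathrm{LR}_j(g_j), \qquad
  \mathrm{risk} = \frac{\mathrm{odds}}{1+\mathrm{odds}},$$

with $p = 0.001$ the lifetime risk. `build_variant_lr()` performs the
calibration, `posterior_risk()` the update (accumulated in log space), and
two identities are enforced exactly by construction and checked in the test
suite: $\sum_g P(g \mid D) = 1$ and
$E_{\bar D}[\mathrm{LR}_j] = \sum_g P(g \mid \bar D)\,\mathrm{LR}_j(g) = 1$.

A useful consequence of HWE in both strata is that the per-variant log
likelihood ratio is affine in the allele count, with slope
$\log \mathrm{OR}_j$. The Bayes posterior therefore ranks individuals exactly
as the familiar weighted risk-allele score with $\ln \mathrm{OR}$ weights
does, which is why the cohort pipeline's score and the simulation's
posterior measure the same discrimination.

## Discriminative accuracy

Discrimination is summarised by the AUC: the probability that a random case
outscores a random control, ties counted half. Two estimators are provided:

* `analytic_auc()` enumerates all $3^K$ genotype combinations (capped at
  K = 12) and computes the case/control pair probability exactly — the
  oracle against which the simulation is validated. Scores tied to within
  $10^{-12}$ on the log-odds axis are treated as equal.
* `run_scenario()` is the Monte-Carlo route: per replicate, genotypes for
  N individuals are drawn from the control distribution (at $p = 0.001$ the
  population is indistinguishable from controls), disease status is assigned
  by a Bernoulli draw from each individual's posterior risk, and the AUC is
  the Mann–Whitney rank statistic with midrank ties. The default study
  conditions are N = 100,000 and 100 replicates.

Replicate seeds derive from one master seed by a fixed counter scheme
(`derive_seed` in the sources; stream 0 for genotypes, stream 1 for status),
so a whole run reproduces from one integer and a replicate that draws zero
cases — possible at Np = 100 expected cases — is re-drawn under a shifted
counter (at most 5 times, then an error).

At these sizes a replicate's AUC has a sampling SD of roughly 0.03
(dominated by the ~100 cases), so the mean over 100 replicates is stable to
about ±0.003.

## What the model gives for the packaged panels

The packaged tables are transcribed from the replicated and novel MS loci of
the 2011 international GWAS collaboration (24 replicated variants including
the HLA tag at OR 3.08 / RAF 0.13; 29 novel variants), plus the six-variant
candidate panel with its cohort-observed parameters (HLA OR 2.53 / RAF
0.14). Under the model above, the exact enumeration gives AUC 0.676 for the
six replicated variants, and the Monte-Carlo estimates are ≈ 0.69 for the
24-variant panel and ≈ 0.72 for all 53 variants. The source study printed
0.64 / 0.66 / 0.69 for these panels. We examined the gap carefully: it is
not explained by prevalence choices, by dominant or carrier genotype
codings, by reading the frequencies as case frequencies, or by
parametric-AUC shortcuts, and the study's own *increments* between panels
match the per-allele model closely. We therefore implement the procedure as
specified — per-allele odds scaling under HWE — and report what it yields,
rather than re-tuning any input toward the printed values. The qualitative
conclusion is unchanged: five dozen common variants leave MS risk
discrimination far below clinical usefulness.

## Inverse design: what would future variants need?

`required_or()` answers the design question in reverse: given the 53-variant
base panel, what per-allele OR must k additional variants (all sharing one
control allele frequency) carry for the mean AUC to reach a target? Because
the objective is a Monte-Carlo average, the search uses common random
numbers — every candidate OR is evaluated under the same derived replicate
seeds — which makes the objective monotone in the OR up to coupling noise.
The upper bracket grows geometrically from OR 2 only as far as the target
requires (capped at 20); probing extreme ORs directly is avoided because a
many-variant panel at a very large OR concentrates the prevalence mass on
genotype profiles so rare that a finite population of 100,000 realizes no
cases at all. Bisection then stops when the bracket is narrower than 0.05
and the midpoint is reported to one decimal, the resolution of the
published requirement grid; 20 replicates per evaluation mirror that grid's
own convention. `table4_grid()` sweeps frequencies {0.05, 0.30, 0.50}, counts
{1, 5, 20, 50, 100} and targets {0.70, 0.75, 0.80, 0.85}. When the base
panel already meets the target the reported OR is 1.0 by convention. Within
a column (fixed frequency and target) the required OR is nonincreasing in
the number of added variants; across frequencies at only 20 replicates the
published grid itself shows Monte-Carlo wobble, so no cross-frequency
monotonicity is enforced.

## The synthetic cohort and the empirical-style pipeline

`generate_cohort()` produces a case-control table with the summary structure
of the empirical study: 591 cases / 600 controls; control genotypes HWE at
the observed control allele frequencies and case genotypes HWE at the
OR-scaled case frequencies; ages truncated-normal on [18, 90] with moments
45 (12) and 49 (17) years; 71% / 55% female; and independent per-genotype
missingness. The default missingness rate, 0.0065 per genotype call, was
chosen once so that a six-variant panel leaves about 568 cases and 577
controls with complete data, close to the study's 564 / 581; the real
study's missingness pattern (which assays failed in which subjects) is
unknowable from summary data, so independence is an explicit simplification.
Age and sex are generated independently of genotype — the generator encodes
no confounding — so crude and adjusted ORs coincide in expectation and the
cohort-observed (age/sex-adjusted) ORs serve as generative crude targets.
That approximation, and sampling noise at ~1,200 subjects, are why the
pipeline is validated by parameter recovery (CI coverage of the generative
ORs across repeated cohorts) rather than by point-matching the study's
empirical estimates, which depended on the unavailable patient data.

The pipeline itself mirrors the study's analysis plan:

* `per_snp_association()` — per-allele logistic regression (optionally
  age/sex-adjusted) with Wald CIs and a Bonferroni flag at 0.05/6 = 0.008;
  separation is flagged, not silently estimated.
* `weighted_scores()` — risk-allele counts weighted by $\ln \mathrm{OR}$
  (raw-OR weighting available behind a flag for sensitivity), computed only
  for subjects with complete genotypes.
* `a_priori_risk()` — the case fraction among complete subjects, the
  reference probability: 564 cases / (564+581) subjects prints as 49%.
* `binned_or_vs_prior()` — subjects grouped by total risk-allele count
  (default bins {0–5, 6, 7, 8, 9, 10–12} with the HLA variant, {0–5, 6, 7,
  8–10} without; interior singleton boundaries are our choice, the extreme
  bins are the published ones; bins are a parameter). Each bin's OR against
  the cohort-average odds comes from a logistic regression with *weighted*
  sum-to-zero coding of the bin factor, so the intercept is the
  bin-size-weighted mean log-odds (the a-priori reference) and each bin
  coefficient is directly the log OR versus it; adjusted for age and sex by
  default, matching the study's convention. This yields an exact identity —
  the size-weighted bin effects sum to zero — which the tests verify, and
  CIs follow from the coefficient covariance by linear combination.
* `cohort_auc()` — Mann–Whitney AUC of the weighted score.

## Numerical and design choices

* Log-space accumulation of LR products; no underflow at 100+ variants.
* Control frequencies stand in for population frequencies throughout: at
  $p = 0.001$ the relative error is below $10^{-3}$.
* An independent penetrance-based calibration (`build_variant_lr_penetrance`,
  heterozygote OR = per-allele OR, homozygote OR = its square, marginal risk
  solved to machine tolerance) agrees with the allele-odds route to three
  decimals in AUC and acts as a cross-check, never as the primary path.
* Genotype draws use one uniform per individual per variant, so augmenting
  a panel with OR-1 variants provably leaves the base panel's genotype
  stream — and hence the AUC — unchanged, which the tests exploit.
* Ages are drawn by inverse-CDF truncation, so moments are those of the
  truncated, not the parent, normal; with these parameters the shift is
  small (< 1 year for cases).
* The test suite and the examples here use reduced problem sizes (populations
  of 10–50 thousand, a handful of replicates) for the unit layers, and the
  full study conditions (100,000 × 100 replicates) only in the end-to-end
  acceptance layer.

## Limitations

The generator and simulator deliberately omit linkage disequilibrium,
gene–gene and gene–environment interaction, population stratification,
genotyping batch effects and informative missingness. Passing tests
therefore demonstrate that the *procedure* is implemented correctly and
recovers its own generative parameters — not that the multiplicative
independence model is biologically true, nor that the synthetic cohort can
reproduce estimates that depended on the real patient-level data.

## A worked example

```{r example, eval = FALSE}
library(msrisksim)

# exact AUC of the six replicated variants
analytic_auc(build_risk_model(builtin_panel("panel_6"), 0.001))

# Monte-Carlo AUC of the full 53-variant panel (reduced size for the vignette)
run_scenario(builtin_panel("panel_53"),
             study_config(n_individuals = 20000, n_reps = 10, master_seed = 1))

# what OR must 20 added common variants carry to reach AUC 0.80?
required_or(search_spec(builtin_panel("panel_53"), 20, 0.30, 0.80),
            study_config(master_seed = 1))

# synthetic cohort, analysed like the empirical study
cohort <- generate_cohort(cohort_spec(seed = 7))
scores <- weighted_scores(cohort, builtin_panel("panel_empirical_6"))
binned_or_vs_prior(scores, n_variants = 6)
cohort_auc(scores)
```
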