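---
title: "Mapping genetic variation in lead sensitivity with leadsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping genetic variation in lead sensitivity with leadsens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Individual susceptibility to lead toxicity has a genetic component, but it is
hard to map in human populations: exposure is uncontrolled, genetic
backgrounds vary, and sample sizes are limited. Panels of fully inbred,
fully sequenced *Drosophila* lines (the DGRP design) sidestep these
problems: each line is a single genotype that can be measured repeatedly
under controlled exposure, so genotype-by-environment interaction — the
statistical signature of genetic variation in sensitivity — is directly
estimable, and line means can be used for genome-wide association.

`leadsens` implements that inference chain as a tested, reusable pipeline:

1. a synthetic-panel generator with the statistical structure the analysis
   assumes, so every stage is testable end to end without any download;
2. mixed-model ANOVA variance partitioning and broad-sense heritability;
3. single-marker association of sensitivity phenotypes, with covariate
   adjustment, MAF filtering, QQ diagnostics and pairwise LD;
4. good/poor performer classification with logistic allele enrichment under
   Bonferroni correction;
5. candidate-gene subnetwork extraction under a one-bridge rule, with a
   largest-cluster randomization test;
6. mutant-validation ANOVA with a combined-SEM sensitivity statistic.

## The model

For development time and activity, observed on both sexes, the variance
partition uses

$$Y = \mu + L + S + T + L{\times}S + L{\times}T + S{\times}T +
L{\times}S{\times}T + \varepsilon,$$

with line $L$ random and sex $S$ and treatment $T$ (control vs 0.5 mM lead
acetate) fixed. Viability is measured on unsexed larvae, so its model is
$Y = \mu + L + T + L{\times}T + \varepsilon$. Broad-sense heritability is

$$H^2 = \sigma^2_G/\sigma^2_P, \qquad
\sigma^2_G = \sigma^2_L + \sigma^2_{L\times S} + \sigma^2_{L\times T} +
\sigma^2_{L\times T\times S}, \qquad
\sigma^2_P = \sigma^2_G + \varepsilon,$$

with the component set reduced accordingly for the unsexed and
within-treatment models.

The *sensitivity phenotype* of a line is the difference of its treatment
cell means with the fixed convention `control − lead`; every downstream
report states this convention. A line lethal on lead medium has no lead
cell mean, so its sensitivity is missing and it drops out of the
association scan — mirroring how non-viable lines are handled in practice.

## Estimators and numerical choices

**REML and EMS.** `fit_anova()` offers two estimators. The default REML
path (lme4, with Type III fixed-effect F tests and Satterthwaite
denominator degrees of freedom via lmerTest — the reason the error df are
non-integer) constrains variance components to be non-negative. The
`"ems"` path solves the expected mean squares of the balanced design
(method of moments) and therefore *can* return negative estimates, which
published variance-component tables sometimes print; `broad_sense_h2()`
uses components exactly as estimated, sums them raw, and clamps the final
ratio to $[0, 1]$ (the unclamped value is co-reported). On balanced data
with an interior optimum the two estimators coincide; our tests assert
equality at $10^{-6}$ relative tolerance for the closed-form one-way case
and $10^{-4}$ for the four-random-term full model, where the optimizer's
convergence tolerance dominates. Degenerate inputs with zero within-cell
variance everywhere are rejected rather than fitted, and lines missing an
entire required cell are dropped before fitting (their ids are kept on the
result).

**Association.** The scan is ordinary least squares of the per-line
phenotype on the 0/1 genotype code plus covariates — Wolbachia infection as
one binary column, each inversion as a categorical indicator — implemented
as one QR residualization of the covariate design followed by a vectorized
per-variant t test. Because lines are homozygous, the 0/1 code is the
allele count. Sexed traits can be scanned per sex, as the unweighted
average of female and male values, or as their difference. Perfect fits
(zero residual with real signal) and genotype–covariate collinearity are
flagged rather than given fabricated p-values; a constant phenotype yields
p = 1, not a "perfect fit". No multiple-testing correction is applied
inside the scan: the fixed reporting threshold (default $10^{-5}$, chosen
from QQ behaviour in the source study design) plays that role, and
Bonferroni correction appears only in the performer-enrichment stage. MAF
filtering is boundary-inclusive ("at least" 0.05). LD uses the fact that
for homozygous lines haplotype frequencies equal joint line frequencies, so
$r^2 = D^2/(f_A f_a f_B f_b)$ is computed directly from the line codes.

**Performers.** Per-line classification uses a Welch (unequal-variance)
two-sample t test between lead and control replicates; the test's sidedness
was an open choice, resolved as a two-sided test plus a direction check:
*poor* means significantly different *and* worse on lead (slower
development, lower viability). Lines significantly *better* on lead are
good performers, as in the source design. No correction is applied across
lines. Enrichment of alleles among good performers is logistic regression
of class on genotype with a likelihood-ratio p-value; quasi-complete
separation — likely in inbred panels with few poor lines — is detected from
the class-by-genotype table and handled with a hand-rolled Firth
(Jeffreys-penalized) fit, always flagged.

**Annotation.** A variant is assigned to every gene whose interval lies
within 1 kb (distance zero inside the gene, otherwise distance to the
nearest interval edge), so one polymorphism can annotate several genes and
vice versa. Coordinates are 1-based inclusive internally; BED input is
converted from its 0-based half-open convention and the conversion is
tested. Strand is deliberately ignored — the rule is purely metric — and
ties assign to all tied genes.

**Network.** The extracted subnetwork retains an edge iff it is a direct
candidate–candidate connection or one of the two legs of a path
$c_1 - x - c_2$ through a single non-candidate bridge gene; bridge genes
with at least two candidate neighbours are the recruited intermediates.
The randomization test draws gene sets of the same size as the *mapped*
candidate set, uniformly without replacement from the graph's full node
universe, and compares largest-cluster sizes. The literal estimator counts
strict exceedances (`>`); because the conventional estimator uses `>=`,
both tails are always co-reported (inclusive ≥ strict, tested as an
invariant), and an add-one $(k+1)/(B+1)$ option exists but is never the
default. The number of randomizations defaults to 1,000 — the source
study does not state its count — and a seed is mandatory.

**Mutants.** Validation fits the fixed-effects two-way ANOVA
$Y = \mu + L + T + L{\times}T + Rep(L{\times}T) + \varepsilon$ per mutant
(vs its co-isogenic control) and per sex; with one observation per
replicate the replicate stratum and the residual merge, which is the
default, and `rep_stratum = TRUE` separates them when replicates are vials
containing several measured flies. The sensitivity statistic is the
difference-of-differences of cell means,
$(\mathrm{Pb}[M - C]) - (\mathrm{Reg}[M - C])$, with combined SEM
$\sqrt{SE_l^2 + SE_r^2}$ where $SE_l$ and $SE_r$ are the standard errors of
the mutant-minus-control difference on lead and regular food (each the
root-sum-of-squares of the two cell-mean SEs — the published formula names
only "SE on lead and regular food", and this is the quantity whose
difference the statistic takes). The validation rate averages the per-sex
success fractions: $((f/n) + (m/n))/2 \times 100$.

## What the generator emulates — and what it does not

Defaults are the study conditions: 200 lines, 5 replicate vials of 50
larvae for development time and viability, 20 flies per sex for activity,
~53% Wolbachia-infected lines, a handful of segregating inversions, about
6% of lines non-viable on lead (plus a few producing only male offspring,
injectable via `inject_lethality()`). Development-time defaults use the
published full-model components (σ²_L = 1.728, σ²_L×S = 0.003,
σ²_L×T = 1.913, σ²_L×S×T truncated to 0 from a small negative printed
value, ε = 0.920; grand mean 10.7 d, +3.0 d lead shift) and activity uses
the published activity components. Random effects are zero-mean Gaussian —
the distributional law is not specified by the source analyses, and
Gaussian ANOVA plus binomial trials is the minimal structure matching the
models fitted. Viability is a logit-latent Gaussian mapped to a binomial
survival probability out of 50 larvae; since the published viability
components are on the proportion scale and the latent scale is logit, its
defaults (base survival 0.60 control / 0.35 lead, σ²_L = 0.5,
σ²_L×T = 0.4) were chosen once as a realistic G×E structure rather than
transcribed. Causal variants can act on the trait level or directly on the
control-minus-lead contrast, which is how true "sensitivity" signal is
injected for power studies. Missingness is an explicit flag, never a
sentinel value.

The generator does **not** emulate linkage disequilibrium between variants
(genotypes are drawn independently per variant), population structure or
relatedness beyond the Wolbachia/inversion covariates, shared genetic
effects between traits (so the simulated development–viability sensitivity
correlation is near zero, unlike in real data where lines slow to develop
also tend to be less viable), dose–response (dose is a label only), or any
egg-laying/developmental mechanism. Passing tests therefore demonstrate
the correctness and calibration of the *statistical machinery* under the
assumed model, not robustness to the correlation structure of real panels.

## Problem sizes used by the tests

The automated checks run the variance-component recovery at the full design
scale (20 seeded panels of 200 lines × 2 sexes × 2 treatments × 5
replicates, with estimates checked against exact chi-square sampling
intervals of the balanced-design estimator), the null association scan at
200,000 variants × 200 lines, the network extractor exhaustively against a
brute-force two-path enumerator over every graph on four labelled nodes and
every candidate subset (plus seeded random seven-node graphs), the mutant
interaction test over 1,000 null assays, and all file formats through
write–read round trips. These sizes keep a complete run of the suite
within a couple of minutes on a single core while leaving the statistical
assertions well-powered.

## Known limitations

* REML cannot reproduce negative printed variance components; use
  `method = "ems"` when that bookkeeping matters.
* The association model includes exactly the named covariates (Wolbachia,
  inversions); no polygenic relatedness adjustment is attempted.
* The Firth fallback reports Wald p-values under separation and is always
  flagged; flagged estimates should be interpreted qualitatively.
* `trait_correlation()` averages over sex before correlating; other
  weightings must be applied upstream.
* The randomization universe is the interaction graph's full node set;
  degree-matched sampling is not implemented.
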