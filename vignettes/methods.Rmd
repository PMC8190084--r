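---
title: "Methods: penetrance and expressivity of monogenic metabolic conditions"
author: "VariantPenetrance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penetrance and expressivity of monogenic metabolic conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind the package, the
meaning and defaults of every simulator parameter, the deliberate limits of
the synthetic-cohort generator, and the numerical choices made in the
estimators. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The scientific question

For a rare variant classified as clinically significant, two quantities
describe its impact in an unselected population:

* **Penetrance** — the probability that a carrier manifests the condition,
  operationalized here as a dichotomized biomarker (for example LDL
  cholesterol at or above 190 mg/dL) or diabetes status. With $k$ affected
  among $n$ evaluable carriers, the estimate is $k/n$ with an exact
  Clopper–Pearson 95% interval.
* **Expressivity** — the quantitative effect among carriers, estimated as a
  covariate-adjusted regression coefficient of the trait on carrier status.

Both are biased upward when carriers are found by sequencing people selected
for an extreme phenotype ("phenotype-first" ascertainment) rather than by
genotyping an unselected cohort ("genotype-first"). The package quantifies
that bias with a truncated-normal model and reproduces it by simulation.

# Data model

Real biobank genotype–phenotype data of this kind is access-restricted, so
the package ships a generator, `simulateCohort()`, that emulates the
*statistical structure* the estimators assume:

$$
y_i \;=\; \mu \;+\; \beta\, c_i \;+\; g_i \;+\; \varepsilon_i,
\qquad
g_i \sim \mathcal N(0,\, h^2 \sigma^2),\quad
\varepsilon_i \sim \mathcal N(0,\, (1-h^2) \sigma^2),
$$

where $c_i \in \{0,1\}$ is the carrier indicator drawn Bernoulli with the
condition's carrier frequency, $g_i$ is the polygenic component (stored per
individual, so polygenic-score analyses have an exact internal truth), and
$\varepsilon_i$ is the residual. Binary outcomes (diabetes) follow a
logistic liability in age, sex, a diabetes polygenic deviate, and the
carrier log-odds.

## Conditions and default parameters

`defaultConditions()` encodes six monogenic conditions with gene panels,
carrier frequencies and additive effects taken from large published biobank
estimates of the same design (high/low LDL cholesterol, high HDL
cholesterol, high triglycerides, monogenic obesity, MODY). Carrier
frequencies are expressed as published carrier counts over the cohort size
in which they were observed (roughly 38,600 exomes), which keeps simulated
carrier counts in the published 7–90 range at that cohort size. Effects are
in trait units (mg/dL, kg/m²) except MODY, whose effect is a diabetes
log-odds ratio.

`simulationConfig()` exposes, with defaults chosen as follows:

* `h2` — per-trait fractions of variance captured by the polygenic score:
  TG 0.1525, LDL 0.1347, HDL 0.1572 (the LD-score estimates reported for
  the trained scores this package's polygenic module emulates) and BMI 0.2
  (a round conventional value; no matching published score estimate).
* `traitMeans` / `traitSds` — LDL 130/33, HDL 52/15, TG 140/70 mg/dL, BMI
  27/4.5 kg/m², typical of a middle-aged cohort. These are reporting
  conveniences, not claims about any specific cohort; every estimator reads
  them from data, never from the config.
* `medIntercept`, `medSlope` — lipid-lowering treatment is assigned with
  probability $\mathrm{logit}^{-1}(a + b\,( \mathrm{LDL}_{raw}-160)/10)$,
  so treatment probability rises with the untreated LDL. Observed LDL and
  TG of treated individuals are then *masked* by the usual statin factors
  (×0.7 and ×0.85); the unmasked values are retained in `ldl_raw`/`tg_raw`
  so harmonization can be tested against exact ground truth.
* `diabetesPrevalence` — baseline non-carrier prevalence, default 10%. The
  source material does not state this value for either cohort; it is
  configurable and never inferred.
* Ages are drawn uniformly on 40–75 because the analyses this package
  implements exclude younger individuals by design.

## What the generator deliberately does not model

No linkage disequilibrium, relatedness, ancestry structure, longitudinal
visits (a separate collapser, `collapseVisits()`, handles repeat-visit
tables), assay batch effects, or genotype error beyond the explicit QC-fail
fraction in `writeCohortVcf()`. The generator is a fixture factory for the
estimators, not a population-genetics simulator; conclusions about real
cohorts should never be drawn from its output.

## Variant fixtures

`simulateVariantAnnotations()` places, for every panel gene, a suite of
variants at controlled transcript positions so that every branch of both
rule engines is reachable: a clean mid-CDS truncation, last-exon stops on
both sides of the 25% truncation override, a penultimate-exon-tail stop,
splice variants with in-frame rescue sites at 4 and 15 bp, a low-pext
truncation, a gnomAD-flagged frameshift, and ClinVar submissions from
registry and non-registry laboratories with report dates straddling
2017-01-01 (including benign, conflicting, stale and too-common records).

Two exon layouts are used (alternating by gene) because a single transcript
cannot contain both a penultimate-exon-tail stop that truncates at most 25%
of the CDS and a last-exon stop that truncates more than 25%: with the
last exon comprising fraction $f$ of the CDS, the first requires the
penultimate tail at CDS fraction $\ge 0.75$, hence $f \le 0.25$, while the
second requires $f > 0.25$.

# Rule engines

## ClinVar triage

A laboratory enters the high-confidence registry when it has more than
15,000 ClinVar submissions and has updated on or after 2017-01-01;
laboratories on an exclusion list are removed regardless. Triage then
proceeds in a fixed order: the allele-frequency gate first (cohort-adjusted
gnomAD frequency above the per-condition cut-off excludes outright), then
pathogenic/likely-pathogenic registry reports dated on or after 2017-01-01
accept, benign/likely-benign registry reports exclude, conflicting
qualifying assertions are never silently resolved (manual review), and
variants with no qualifying registry submission go to manual review. The
adjusted frequency subtracts the analysis cohort's own carriers from the
gnomAD allele count (floored at zero), because such cohorts are largely
contained in gnomAD.

## Predicted loss-of-function curation

Five ordered classes: `not_LoF < likely_not_LoF < uncertain < likely_LoF <
LoF`. LOFTEE high-confidence is a gate; truncations in the NMD-escape
region (last exon, or final 50 coding bases of the penultimate exon) drop
to `not_LoF` unless they remove more than 25% of the coding sequence
(interpreted as CDS fraction, not genomic span, because the pathogenicity
argument is about lost protein); splice variants with an in-frame
alternative site within 6 bp are `likely_not_LoF`, between 6 and 21 bp
`uncertain` unless externally validated; low pext and gnomAD filter
flags/site blacklisting each downgrade one class. The engine is a pure
function with an ordered evidence trail, and weakening evidence can never
upgrade a variant toward `LoF` (tested as a monotonicity property).

# Estimators and numerical choices

## Firth penalized logistic regression

Carrier counts of a few per ten thousand with high penetrance put logistic
regression in the separation regime, where maximum likelihood diverges.
The package maximizes the Jeffreys-penalized likelihood
$\ell(\beta) + \tfrac12 \log\det I(\beta)$ by Newton iteration on the
modified score $U^*(\beta) = X^\top(y - p + h(\tfrac12 - p))$ ($h$ the
hat-matrix leverages), with step-halving whenever a step would decrease the
penalized likelihood. No suitable implementation was available in the
environment, so the solver is written here and validated two independent
ways: against the half-cell-augmentation closed form, which the Firth
estimate equals exactly for a saturated 2×2 design, and against a
brute-force nested grid search over the penalized likelihood surface. The
p-value is the penalized likelihood-ratio test of the carrier term
(refitting with the carrier coefficient constrained to zero); the default
confidence interval is the profile penalized likelihood, which is markedly
better than Wald near separation, with `ci = "wald"` available for
replicate loops where profiling cost dominates.

## Exact binomial intervals

`clopperPearson()` uses the Beta-quantile closed form,
$[\,q_{\mathrm{Beta}}(\alpha/2;\,k,\,n-k+1),\;
q_{\mathrm{Beta}}(1-\alpha/2;\,k+1,\,n-k)\,]$, with the boundary cases
pinned to 0 and 1. Exactness matters here: typical carrier denominators
are 7–22, where normal approximations are badly anticonservative.
Carriers with missing or indeterminate phenotype are excluded from
denominators, never imputed.

## Polygenic module

Scores are weighted sums of effect-allele dosages (the standard additive
scoring), with allele-flip reconciliation via $2-d$, per-variant mean
imputation of missing dosages, and z-standardization on the analysis
subset after the age restriction. The tail-equivalence computation inverts
the truncated-normal tail mean
$\mathrm{shift}(q) = \sqrt{h^2}\,\sigma\,\phi(z_q)/q$ by bracketed root
finding on $q \in (10^{-8}, 1-10^{-8})$; the forward map is strictly
decreasing in $q$, so the root is unique when it exists, and unattainable
shifts raise an error rather than returning a boundary value. Power
planning uses the Fisher z-approximation
$n = \lceil ((z_{1-\alpha}+z_{\mathrm{power}})/\mathrm{atanh}\,r)^2 + 3
\rceil$, one-sided by default; the exact-t calculation gives a slightly
smaller $n$ for the same inputs (the test suite pins both), so the
approximation errs conservative.

## Ascertainment model

Selecting individuals above the population's $1-q$ quantile and then
computing carrier means is modelled by the truncated normal: the expected
ascertained carrier mean is $\mu_c + \sigma_c \phi(a)/(1-\Phi(a))$ with
$a = (t - \mu_c)/\sigma_c$ for threshold $t$. `ascertainmentContrast()`
reports the empirical ascertained and unascertained carrier means next to
this closed form. Whether the induced inflation exceeds the carrier effect
itself depends on the parameters: the inflation is
$\sigma\,\lambda(z_{1-q} - \beta/\sigma)$ (with $\lambda$ the inverse
Mills ratio), which exceeds $\beta$ only when $\beta/\sigma$ is small
enough; the test suite evaluates this at the stated parameters rather than
asserting it universally.

## Determinism

A single master seed derives per-stream child seeds
(`childSeed(seed, stream)`) so every stage can be rerun independently and
still reproduce. The pipeline writes plain per-stage TSVs plus a manifest
with per-file checksums and the seed; a rerun with the same configuration
is bit-identical, which the test suite checks by hashing.

# Worked example

```{r}
library(VariantPenetrance)

cfg <- simulationConfig(20000, seed = 1)
out <- runPipeline(cfg, outDir = tempfile("penexome"))

out$associations     # Table-1-style per-condition burden estimates
out$penetrance       # k-of-n penetrance with exact intervals
out$ascertainment    # phenotype-first vs genotype-first carrier means
```

# Limitations

* The generator's defaults are published point estimates, not a fitted
  model of any cohort; only the *relationships* between modules (planted
  effect in, estimate out) are meaningful.
* Two-reviewer curation, manual read review, and external splice
  validation are collapsed into deterministic rules or configuration
  flags; the `uncertain` class marks exactly the places where a human
  would intervene.
* The Firth solver handles the designs used here (carrier indicator plus a
  dozen well-conditioned covariates); it is not a general-purpose GLM
  replacement and errors on rank-deficient or unconverged fits rather than
  returning approximate answers.
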