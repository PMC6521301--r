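---
title: "Methods: genetic risk scores for the triglyceride response to omega-3 supplementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic risk scores for the triglyceride response to omega-3 supplementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grspipe)
```

## The problem

Plasma triglyceride (TG) lowering under high-dose omega-3 fatty acid
(EPA + DHA) supplementation is strikingly heterogeneous: in a six-week
2.7 g/day intervention in young Mexican adults, about 59% of
participants saw their TG fall while 41% saw no change or an increase.
`grspipe` implements the analysis chain used to ask how much of that
heterogeneity is genetic: classify responders, quality-control a panel
of candidate SNPs, code each SNP's minor allele as risk-increasing or
protective from its responder/non-responder odds ratio, sum the signed
allele counts into an unweighted genetic risk score (GRS), estimate the
share of the TG-response variance the score explains after adjusting
for age, sex and BMI, refine the panel by stepwise selection, and probe
the extreme-response subsets by a retrenchment sweep.

## Responder definition and descriptive comparison

The response is `delta_tg = tg_post - tg_pre` in mg/dL. A participant
is a **responder** when `delta_tg < 0`, strictly; `delta_tg = 0` counts
as non-response. Group percentages are reported to one decimal. The
descriptive table compares the groups with paired two-sided Student
t-tests within groups (pre vs post) and two-sample pooled-variance
Student t-tests between groups (Welch available behind a flag, since
the pooled form is what a plain "Student t-test" denotes). A
zero-variance contrast — for example a subgroup whose TG did not change
at all — is reported as p = 1 with a degenerate-input flag rather than
an error, so batch reports stay total.

## Genotype quality control

Genotypes are biallelic minor-allele dosages (0/1/2). The per-SNP
report computes the minor allele frequency (MAF) on complete calls,
folding to 0.5 or below and recording any allele relabelling, and tests
Hardy-Weinberg equilibrium (HWE) with the one-degree-of-freedom Pearson
chi-square of the three genotype counts against `n(p^2, 2pq, q^2)`,
allele frequencies estimated in-sample, no continuity correction.
**HWE failures are flagged but never removed**: the published analysis
retained an out-of-equilibrium SNP (rs17150341) in its final model, so
equilibrium was evidently a report, not a filter, and the package
follows that. Allele frequencies of two cohorts are compared with the
Pearson chi-square of the 2x2 allele-count table (1 df, no continuity
correction). When the second cohort is only available as a printed
frequency, counts are reconstructed as `round(maf * 2n)` and the row is
flagged approximate — printed two-decimal frequencies cannot recover
exact counts, which is why published cross-cohort chi-squares are only
approximately reproducible.

## Score construction

For each SNP the allele-level 2x2 table (minor/major allele counts by
non-responder/responder) gives the odds ratio of carrying the minor
allele among non-responders versus responders. Minor alleles with
OR > 1 are coded +1 (at-risk: enriched where TG failed to fall), OR < 1
coded -1 (protective), major alleles 0; OR exactly 1 or undefined
contributes nothing. Zero cells get the Haldane-Anscombe +0.5
correction, flagged. The GRS of a participant is the sum of
`direction x dosage` over the panel, so a heterozygote moves the score
by one unit and a minor-allele homozygote by two; a carrier-coded
variant (one unit per carrier) is available behind a flag. Two
orientation choices are not stated in the published description and are
therefore explicit package assumptions: the OR is oriented to
non-response as the adverse outcome (so a positive score means more
at-risk alleles), and the table is allelic (2n alleles), matching the
basic allelic association test of standard GWAS tooling.

Participants missing any panel genotype are left unscored rather than
imputed — which is exactly how a 191-participant cohort yields a
190-participant five-SNP score distribution. Directions are estimated
once on the full cohort and frozen before any subsetting.

## Variance explained and panel refinement

The score's contribution to the response is estimated by ordinary least
squares of `delta_tg` on the score plus age, sex (single male
indicator) and BMI. "Percent of TG variance explained by the GRS" is
implemented as the **incremental R-squared**, `100 (R2_full -
R2_covariates)`; the partial eta-squared reading, `(R2_full -
R2_cov) / (1 - R2_cov)`, is reported alongside because the source
analyses never define the quantity. The score's p-value is the
two-sided t-test of its coefficient. The incremental definition is
nested-consistent (never negative) and equals the squared semipartial
correlation of the score with the response given the covariates, which
the test suite checks in closed form.

Panel refinement is classic bidirectional stepwise regression on
individual SNP dosages with the three covariates forced: add the
candidate with the smallest p-value under the entry threshold, then
repeatedly remove the worst included SNP over the stay threshold; stop
when no action is possible. Both thresholds default to 0.15, the
customary stepwise entry/stay levels of the software family the
published analysis names. Ties are broken by smaller p then
lexicographic rsid, making the procedure order-independent; the test
suite holds it to an exhaustive-refit oracle step by step.

## Retrenchment

The retrenchment sweep asks whether the score explains more variance
among extreme responses. The first step excludes enough members of the
larger group — responders with the least-negative `delta_tg` — to
reach 50:50; each further step removes ten more from each group,
always the weakest response magnitudes, until fewer than 30
participants would remain. From group sizes (113, 78) this reproduces
the published participant counts 156, 136, 116, 96, 76, 56, 36. The
model is refit on each nested subset with score weights frozen from
the full cohort. "Weakest" non-responders are those closest to zero by
default (`ranking = "magnitude"`, retaining the largest TG increases);
ranking by largest increase first is available because the published
wording ("eliminating participants with lower delta TG") does not fix
the non-responder ordering.

A caution the package makes measurable: the expected incremental
R-squared of even a pure-noise regressor is roughly `1/(n - k)`, so a
sweep from n = 156 down to n = 36 mechanically inflates the percentage
from about 0.7% to about 3% under the null. The acceptance suite
compares null-cohort sweeps against a pure-noise Monte-Carlo
expectation at each n and requires no trend beyond that inflation;
a rising trend well above it — as on cohorts where extreme responders
carry extreme scores — is the genuine signal the sweep is designed to
surface.

## The synthetic cohort generator

No individual-level data accompany the study, so the generator is the
package's test bed. It emulates the study conditions: 191 participants;
103 biallelic SNPs drawn `binomial(2, MAF)` independently (HWE by
construction, no linkage disequilibrium — LD pruning happened upstream
of the published panel and is out of scope); MAFs from the 91 published
Mexican frequencies, folded to 0.5 or below, with the remaining 12
resampled from the same set; sex ~ Bernoulli(0.37 male); age and BMI
truncated normals on the trial's inclusion ranges (18-40 years,
18.5-30 kg/m^2); baseline TG log-normal, moment-matched to the pooled
subgroup moments (97.9 +/- 53.6 mg/dL — TG is right-skewed and the
printed SDs are about half the means, so a normal would put mass below
zero). The response is

`delta_tg = intercept + sum(effect_j * dosage_j) + covariate terms +
baseline coupling + noise`,

with the noise variance solved so the planted genetic term's expected
share of the response variance equals `target_grs_partial_r2` (default
0.11); infeasible combinations error with the offending parameters
named. The baseline-coupling coefficient (default -0.15) reproduces the
observed pattern that responders start from higher TG. Responder status
is never drawn directly — it emerges from the sign of the simulated
response.

Two defaults deserve their rationale:

* **Intercept -8 mg/dL.** The solved total response SD at the default
  planted fraction is ~34.4 mg/dL; an intercept of -8 then gives an
  expected non-responder share of 40.8%, the study's observed split.
  The pooled mean change derived from the subgroup means (-4.1 mg/dL)
  cannot hold simultaneously under a symmetric error model (it would
  imply ~45% non-responders); the split was kept because the
  retrenchment procedure depends on it, and the real response
  distribution is evidently asymmetric in a way a single Gaussian term
  cannot be.
* **Five equal-magnitude causal effects (+/-8 mg/dL per allele) at the
  refined-panel loci.** Equal magnitudes make the unweighted signed-
  dosage GRS exactly proportional to the planted genetic term, so the
  incremental R-squared of the truth-direction score is an estimator of
  the planted fraction — that is what the parameter-recovery suite
  checks (mean over 200 cohorts within +/-2 points of 11%). In-cohort
  direction estimation adds sign-error attenuation and, across a wide
  panel, in-sample inflation; those are covered by separate power and
  dilution properties rather than mixed into the recovery check.

What the generator does **not** emulate — LD structure, population
admixture, genotyping error, asymmetric response distributions,
gene-diet interactions — bounds what green tests mean: they validate
the estimators and procedures under the stated model, not the
biological claims on real data.

## Numerical and degenerate-input choices

* Chi-square tests: plain Pearson, no continuity correction anywhere.
* Monomorphic SNPs: HWE statistic 0, flagged, never an error.
* Odds-ratio zero cells: Haldane-Anscombe +0.5, flagged.
* Constant or collinear score in the model fit: flagged inestimable,
  fit still returned.
* Ties: stepwise by (p, rsid); retrenchment exclusion by
  (response magnitude, participant id). Both make reruns and row
  permutations bit-reproducible.
* All randomness flows from one integer seed per cohort/pipeline run;
  identical config + seed gives byte-identical artifacts.
* Post-intervention TG is floored at 1 mg/dL to keep simulated values
  physical.

## Problem sizes used by the test and acceptance suites

Simulated checks use the study-scale cohort (n = 191, 103 SNPs) with
200 replicate seeds for recovery and null-trend properties, 1000
permutations for the null rejection rate, 100-instance random-table
sweeps for the oracle-equivalence checks, and n = 500-10000 for
convergence properties. These sizes keep every Monte-Carlo standard
error well inside the asserted bands.

## Known limitations

* The published cross-cohort chi-squares are reproducible only up to
  frequency-rounding, and the discovery cohort's size is not printed,
  so those statistics are validated against oracles, not against the
  printed table.
* In-sample direction estimation makes a wide panel's apparent
  variance explained optimistic (winner's-curse-like); the package
  reports the in-sample quantity, as the source analysis did, and the
  vignette's null expectation quantifies the inflation.
* The generator's independence assumptions (no LD) mean stepwise
  selection faces an easier problem than on real, correlated panels.
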