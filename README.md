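# grspipe

Genetic risk scores for the plasma triglyceride (TG) response to
omega-3 fatty acid supplementation.

High-dose EPA/DHA supplementation lowers plasma TG on average, but the
individual response is heterogeneous — a substantial minority of
participants see no change or an increase. `grspipe` is for
nutrigenetics researchers who want to quantify how much of that
heterogeneity is captured by a panel of candidate SNPs. It implements
the full analysis chain around an **unweighted, odds-ratio-directed
genetic risk score (GRS)**:

* **Responder classification** — response `ΔTG = TG_post − TG_pre`;
  responder ⇔ `ΔTG < 0`; descriptive tables with within-group (paired)
  and between-group Student t-tests.
* **Genotype QC** — minor allele frequencies (folded, complete-call),
  Hardy–Weinberg equilibrium by 1-df Pearson χ², cross-cohort allele
  frequency comparison on 2×2 allele tables. HWE failures are flagged,
  never removed.
* **Score construction** — per SNP, the allelic odds ratio of the minor
  allele in non-responders vs responders sets a direction
  `w ∈ {−1, 0, +1}` (OR > 1 → +1, OR < 1 → −1, else 0); the score is
  `GRS_i = Σ_j w_j · d_ij` over a panel, with `d_ij` the minor-allele
  dosage. Participants missing a panel genotype are left unscored.
* **Variance explained** — OLS of `ΔTG` on GRS + age + sex + BMI;
  the GRS contribution is the incremental R²,
  `100 · (R²_full − R²_covariates)`, with partial η² reported
  alongside.
* **Panel refinement** — bidirectional stepwise selection over SNP
  dosages with forced covariates (entry/stay p = 0.15 by default).
* **Retrenchment** — progressively exclude the weakest responses to
  reach and keep a 50:50 responder:non-responder ratio, refitting the
  refined score model on each nested subset.
* **Synthetic cohorts** — a generator that plants known causal SNPs
  and a target variance fraction under the study's conditions, so the
  whole chain is testable without access to trial data.

## Worked example

```r
library(grspipe)

coh <- simulate_cohort(simulation_config(seed = 42))
ph  <- classify_responders(coh$phenotypes)
attr(ph, "summary")
#> $n_responders        [1] 114
#> $n_non_responders    [1] 77
#> $percent_non_responders  [1] 40.3
#> $percent_responders      [1] 59.7

w    <- compute_weights(coh$genotypes, ph)   # per-SNP OR -> direction
grs  <- compute_grs(coh$genotypes, w)        # 103-SNP score
fit_grs_model(ph, grs)
#> grs_fit (panel all): n = 191
#>   score explains 14.78% of delta-TG variance (p = 9.44e-09)
#>   R2 full = 0.2397, R2 covariates only = 0.0920

sw <- stepwise_select(ph, coh$genotypes)     # refine the panel
refit_refined_grs(coh$genotypes, ph, sw$selected, w)
#> grs_fit (panel refined_16): n = 191
#>   score explains 24.27% of delta-TG variance (p = 3.07e-14)

grs_r <- compute_grs(coh$genotypes, w, panel = sw$selected)
retrench_and_refit(ph, grs_r)
#>   excl_responders excl_non_responders n_included grs_percent_variance
#> 1               0                   0        191              24.2685
#> 2              37                   0        154              26.5812
#> 3              47                  10        134              27.5647
#> 4              57                  20        114              29.0505
#> 5              67                  30         94              29.5911
#> ...
```

Reading the output: 40.3% of this simulated cohort did not respond; the
in-cohort-directed 103-SNP score explains 14.8% of the adjusted
response variance (in-sample); stepwise refinement concentrates that
into a smaller panel; and the retrenchment sweep shows the variance
explained growing as the weakest responses are excluded — the
qualitative signature of extreme responders carrying extreme scores.
Baseline rows of the sweep always reproduce `fit_grs_model()` exactly.

The whole chain also runs as one call (or from the shell via
`inst/cli/grspipe.R`):

```r
run_pipeline(list(simulation = list(), out_dir = "run1", seed = 42))
```

which writes QC, weights, scores, fits, the stepwise log, the
retrenchment table, score-distribution figures and a `summary.json`
under `run1/`, byte-identical across reruns with the same seed.

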