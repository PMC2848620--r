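# regsync

Regional gene synchrony analysis for paired-tissue expression data.

## The problem

When the same gene is measured in two tissues of the same subjects — say the
amygdala and the anterior cingulate cortex of a postmortem brain cohort —
its transcript levels are often *synchronised*: high-expressing subjects in
one region tend to be high-expressing in the other. For gene *g* with
log-scale expression vectors `a_g` (region A) and `b_g` (region B) across
the same *n* subjects, the synchrony statistic is the genewise Pearson
correlation

    r_g = cor(a_g, b_g)

computed across subjects. Across thousands of genes the distribution of
`r_g` is strongly right-shifted in real cohorts, and group differences in
`r_g` (e.g. depressed vs. control subjects) flag genes whose cross-region
coordination is gained or lost in disease — a signal invisible to ordinary
differential expression.

`regsync` implements the full inferential pipeline around this statistic:

- **Bootstrap estimation** — subjects are resampled with replacement
  (keeping each subject's A/B pair intact); per-gene bootstrap medians and
  percentile confidence intervals (`bootstrap_synchrony()`).
- **Permutation null** — the subject linkage across regions is scrambled
  with derangements (no subject keeps its own pair), destroying
  within-subject coordination while preserving the marginals
  (`permutation_null()`); the global right-shift is tested with a one-sided
  rank-sum test (`global_shift_test()`) plus a conservative subject-level
  permutation companion (`permutation_median_p()`).
- **Age detrending** — per-gene OLS residuals on age, re-fitted *inside
  every bootstrap resample*, to show synchrony is not an artefact of shared
  age trends (`bootstrap_synchrony_detrended()`, `age_contribution_report()`).
- **Differential synchrony** — genes with `|r| >= 0.7` in at least one
  group are tested for a group shift with two-sided percentile-bootstrap
  p-values (independent within-group resampling), Benjamini–Hochberg FDR
  control, and gain/loss classification at high/low magnitude thresholds
  0.7 / 0.2 (`run_differential_pipeline()`).
- **Synthetic cohorts** — a latent-factor generator with exact per-gene
  target correlations, age confounding and group-specific rewiring
  (`generate_paired_cohort()`, `emulate_control_cohort()`), so every stage
  can be validated against ground truth.

## Worked example

A control-like cohort: 14 subjects, 10,000 genes, true cross-region
correlations drawn with median 0.32.

```r
library(regsync)

cc   <- emulate_control_cohort(seed = 42, n_genes = 10000)
r    <- genewise_synchrony(cc$dataset)
null <- permutation_null(cc$dataset,
                         analysis_config(n_permutations = 100, rng_seed = 43))
median(r)                  # 0.337  — right-shifted observed distribution
print(null)                # null mean r = -0.0235, centred near zero
global_shift_test(r, null) # ~0 (underflows; far below 1e-6)
```

The observed genewise correlations sit far to the right of the
scrambled-linkage null, so the within-subject pairing — not the marginal
expression distributions — carries the signal.

A two-group comparison with designed rewiring (60 gains, 40 losses among
2,000 genes, 14 subjects per group):

```r
cfg <- sim_config(n_genes = 2000, n_subjects_per_group = 14,
                  n_gain = 60, n_loss = 40,
                  gain_rho = c(0, 0.9), loss_rho = c(0.9, 0),
                  rho_distribution = rho_dist_with_median(0.32),
                  rng_seed = 44)
sim <- generate_paired_cohort(cfg)
res <- run_differential_pipeline(sim$datasets$control, sim$datasets$mdd,
                                 analysis_config(n_bootstrap = 2000,
                                                 rng_seed = 45, fdr_q = 0.2))
print(res)
#> <differential_result> 502 of 2000 genes selected (|r| >= cutoff in >= 1 group)
#>   gain/loss counts by FDR level:
#>  fdr n_significant n_gain n_loss
#>  0.1           123     37     25
#>  0.2           172     41     32
#>  0.3           230     44     36
```

Top genes by adjusted p-value:

```
   gene  r_ctrl r_case delta p_boot    q_bh          label
 g00002  0.0942  0.958 0.864  5e-04 0.00411           gain
 g00006  0.3783  0.961 0.583  5e-04 0.00411 not_classified
 g00010 -0.0539  0.913 0.967  5e-04 0.00411           gain
 g00011  0.1254  0.915 0.789  5e-04 0.00411           gain
 g00012 -0.0328  0.959 0.992  5e-04 0.00411           gain
```

`delta = r_case - r_ctrl`; a `gain` label means the gene's synchrony
magnitude rose from `<= 0.2` to `>= 0.7` between groups with a significant
bootstrap shift (`g00006` is significant but keeps moderate control
synchrony, so it stays `not_classified`). Most of the designed gains and
losses are recovered at 20% FDR; see the vignette for the power and
calibration characteristics, including the known caveats of the
percentile bootstrap at n = 14.

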