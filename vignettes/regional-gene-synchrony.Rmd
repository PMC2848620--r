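---
title: "Methods: regional gene synchrony, its null models, and their small-sample behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional gene synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regsync)
```

## The statistic and its sampling unit

For gene $g$ measured in two regions of the same $n$ subjects, synchrony is
the Pearson correlation $r_g = \mathrm{cor}(a_g, b_g)$ of the two expression
vectors across subjects. Two points follow from this definition and drive
every design choice in the package:

1. **The subject is the sampling unit.** Each subject contributes one
   *pair* of profiles. Resampling therefore always moves whole subjects:
   the bootstrap resamples subject indices with replacement and applies the
   same indices to both regions, and the permutation null permutes which
   subject's region-B profile is attached to each subject's region-A
   profile.
2. **Genes are not independent.** The same $n$ subjects underlie every
   $r_g$, so the $r_g$ are correlated across genes. Tests that pool over
   genes (the rank-sum global shift test) are computed on correlated
   observations; we keep the genewise test for its resolution and pair it
   with a strictly subject-level companion (below).

Inputs are assumed to be already-normalised log2-scale intensities
(GCRMA-like); the package performs no normalisation, and correlations are
computed on the values as given. Missing values are rejected at read time
rather than imputed — imputation would manufacture or destroy exactly the
covariation being measured.

## Bootstrap estimation

`bootstrap_synchrony()` draws `n_bootstrap` resamples of subjects with
replacement (default 20,000, where p-values stabilise; validation runs in
this package use 300–2,000 to keep suites fast — those sizes are stated with
each test) and summarises each gene's resampled $r$ by its median and a
percentile interval at `ci_level` (default 0.95). Resamples in which a gene
becomes degenerate (zero variance, e.g. a resample that happens to draw
near-identical values) are recorded as missing for that gene and excluded
from its quantiles; the count is attached to the result. Degenerate genes
are flagged, never fatal: constant probesets are a fact of array data.

**Known limitation — undercoverage at small $n$.** The percentile bootstrap
interval for a correlation undercovers at small sample sizes: at $n = 14$
the validation suite measures roughly 91% coverage for nominal 95%
intervals, and an independent plain-loop oracle reproduces the same figure,
so this is a property of the method rather than of the implementation.
Users who need calibrated intervals at $n \approx 14$ should treat the CI
as descriptive; the permutation null, not the CI, is the package's primary
inferential device for the global question.

## The permutation null

The null of "no within-subject coordination" is built by scrambling the
subject linkage: region-B columns are permuted and genewise $r$ recomputed,
pooling over `n_permutations` permutations. Permutations are
**derangements** (no fixed points, drawn by rejection — the acceptance rate
tends to $1/e$). With a uniform random permutation at small $n$, a
meaningful fraction of subjects would keep their own pair and leak true
linkage into the null; derangements remove that leakage at the cost of a
small negative bias of order $-1/(n-1)$ in the null mean, visible as a null
centred slightly below zero at $n = 14$ and immaterial for the one-sided
shift question.

`global_shift_test()` is a one-sided Wilcoxon rank-sum test of observed
genewise $r$ against the pooled null values. Because genes are correlated,
its p-value overstates the effective information; on realistic synchrony
structure the separation is so large that the p-value underflows, and the
conclusion does not rest on its literal magnitude. The conservative
companion `permutation_median_p()` compares the observed median $r$ with
the permutation medians and is floored at $1/(P+1)$ — it treats the cohort,
not the gene, as the unit, and is the number to quote when resolution
matters less than validity.

## Age detrending inside the resampling loop

Subjects span a wide age range and many genes have linear age trends in
both regions, so shared age trends can induce cross-region correlation that
has nothing to do with within-subject coordination. `detrend_age()` removes
the per-gene OLS fit on age (intercept included); residuals have exactly
zero sample correlation with age by orthogonality (tested to 1e-10). Only a
first-order model is fitted — the aim is to remove *linear* age trends, and
higher-order fits at $n = 14$ would mostly absorb noise.

Detrending is performed **inside each bootstrap resample**, re-fitting on
the resample's own ages (a subject drawn twice contributes its age twice),
rather than once up front. The two orders differ: per-resample detrending
propagates the uncertainty of the age fit into the bootstrap distribution,
which is the honest accounting. On full data (no resampling) the detrended
synchrony equals the partial correlation of the two regions given age; the
test suite verifies this closed form to 1e-10.

One subtlety the validation exposed: for genes whose correlation is purely
age-driven, raw and detrended genewise $r$ remain positively correlated
across genes even though detrended $r$ collapses to zero in location — both
statistics share the same residual sampling noise. The informative
summaries are the location collapse of detrended $r$ and the *drop* in the
raw-vs-detrended correlation relative to an age-free cohort, not its
absolute value.

## Differential synchrony

The group comparison pipeline is: genewise $r$ per group → selection of
genes with $|r| \ge$ `selection_cutoff` (default 0.7) in at least one group
→ two-sided percentile-bootstrap p-values for
$\Delta r = r_\text{case} - r_\text{ctrl}$ → Benjamini–Hochberg adjustment
*within the selected set* → gain/loss classification.

Choices made where the design was genuinely open:

- **Selection uses the plain $r$**, not the bootstrap median; the two are
  close, and the plain estimate keeps selection independent of the
  bootstrap seed. Selection can be disabled (`select = FALSE`) for
  sensitivity analysis.
- **Two-sided p-values**, $p = 2\min(\Pr(\Delta r^* \le 0),
  \Pr(\Delta r^* \ge 0))$, floored at $1/(B+1)$ and capped at 1: gains and
  losses are equally interesting, so sidedness should not be baked in.
- **Groups are resampled independently** — subjects are not paired across
  groups.
- **Classification is by magnitude**: a *loss* is $|r_\text{ctrl}| \ge 0.7$
  falling to $|r_\text{case}| \le 0.2$; a *gain* is the mirror image. Using
  $|r|$ lets negatively synchronised genes (anti-coordinated regulation)
  classify by the size of their coordination. A consequence is that the
  signed `delta` of a classified gain need not be positive (a gene moving
  from $0.1$ to $-0.8$ gains magnitude with negative `delta`); the
  magnitude difference is what the label guarantees. Both thresholds are
  configurable, and results in our validation are insensitive to ±0.1
  shifts of the cutoff.
- **Determinism and symmetry**: each group's resample-index stream is
  seeded from the configuration seed together with that group's (sorted)
  subject identifiers. This makes p-values invariant to gene order and
  subject order, bitwise reproducible, and exactly antisymmetric under
  swapping the group arguments — the swapped analysis reuses each group's
  own index stream, so every resampled $\Delta r$ is negated exactly.

**Known limitations.** Two caveats are measured directly by the validation
suite rather than assumed away. First, the lower tail of the percentile
bootstrap p-value is anticonservative at $n = 14$: the bulk of the null
p-value distribution is uniform (KS-clean), but far-tail probabilities
exceed their nominal values severalfold, so BH control is reliable at
stringent levels ($q \le 0.1$ in the suite) and degrades at loose levels
($q = 0.3$). Second, the high-$|r|$ pre-selection is a winner's-curse
filter: stable genes that pass it have noise-inflated $|r|$ in one group
and hence inflated $|\Delta r|$, so the empirical false discovery
proportion among *classified* genes exceeds the nominal $q$. Both effects
are intrinsic to the select-then-bootstrap design at this sample size;
reporting results across an FDR grid (the `summary` attribute spans
10–30%) and quoting the classification thresholds alongside the labels is
the intended usage.

## The synthetic cohort generator

`generate_paired_cohort()` implements a Gaussian latent-factor model: for
gene $g$, subject $s$ with age $a_s \sim U(\text{age range})$, shared
latent $z \sim N(0,1)$ and independent residuals $e^A, e^B \sim N(0,1)$,

$$A_{gs} = \mu_g + \beta^A_g a_s + \sigma\left(\sqrt{|\rho_g|}\,z +
\sqrt{1-|\rho_g|}\,e^A\right),\qquad
B_{gs} = \mu_g + \beta^B_g a_s + \sigma\left(\mathrm{sign}(\rho_g)
\sqrt{|\rho_g|}\,z + \sqrt{1-|\rho_g|}\,e^B\right),$$

so the age-free cross-region correlation equals $\rho_g$ *exactly* —
negative targets are obtained by sign-flipping the shared component in one
region. This construction was chosen over, say, drawing from an explicit
bivariate normal per gene because it extends cleanly to the age-confounded
case: `age_driven` genes set $\rho_g = 0$ with a shared-sign slope
$|\beta| = 0.1$ expression units/year in both regions, making age the
*sole* source of raw correlation and giving exactly zero partial
correlation given age by construction.

Defaults emulate the reference study conditions: 14 subjects per group,
ages uniform on 30–70 years (a neutral choice; the emulated cohorts'
age lists are not public), baselines $\mu_g \sim N(7, 1)$ on the log2
scale, unit noise ($\sigma = 1$), and — in `emulate_control_cohort()` —
10,000 genes with $\rho_g$ drawn from a Beta distribution rescaled to
$(-0.4, 0.9)$ whose second shape is solved numerically so the median is
0.32, reproducing the right-shifted synchrony distribution with a negative
tail. The dispersion of $\rho_g$ is a free parameter (the emulated study
reports the median of its $r$ distribution, not its spread); the default
first shape 2.8 gives a visually comparable unimodal shape.

What the generator deliberately does *not* emulate: probe-level
hybridisation noise, batch and site effects, non-Gaussian expression
marginals, within-region gene–gene correlation structure, and non-linear
age trends. Passing tests therefore demonstrate that the inferential
machinery recovers truth under a clean generative model of the stated
correlation structure — not that real postmortem array data meet these
assumptions.

## Numerical conventions

- Degenerate (zero-variance) vectors yield `NA` correlations, detected with
  a relative tolerance on the centred sum of squares; `NA`s are excluded
  from quantiles, pooled nulls and tests, with counts logged.
- Computed correlations are clamped to $[-1, 1]$ against floating-point
  overshoot.
- All stage seeds are derived from the user seed and a stage/data key by a
  polynomial string hash modulo $2^{31}-1$, so stages and groups draw from
  distinct reproducible streams and no stage perturbs the session RNG
  (streams are saved and restored around every seeded computation).
- Bootstrap quantiles use the default type-7 empirical quantile; p-value
  ties at the floor are kept (no randomised tie-breaking), which is
  conservative by one resample at most.

## Problem sizes used in validation

The shipped suites run the global shift checks at 10,000 genes × 14
subjects × 100 permutations, detrending checks at 3,000 genes × B = 500,
calibration at 1,000 genes × B = 1,000 over 12 replicate cohorts, and
power/coverage at 200–2,000 genes × B = 1,000–2,000 — sizes at which the
Monte Carlo tolerances quoted in each test are comfortably resolved while
the whole suite stays fast on a single core.
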