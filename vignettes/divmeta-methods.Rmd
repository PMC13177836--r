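---
title: "Methods: mean-and-variability meta-analysis of host genetic diversity effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mean-and-variability meta-analysis of host genetic diversity effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divmeta)
```

## The question and the data

Host populations with little genetic variation are widely believed to
suffer larger disease outbreaks than diverse populations. Under
matching-alleles-like infection genetics, however, the prediction is
richer: host diversity should lower *mean* parasite success most clearly
for specialist (single-host) parasites, and its effect on the
*between-population variability* of parasite success should flip sign with
the genetic diversity of the parasite population — low parasite diversity
makes outcomes lottery-like across uniform host populations (host
diversity reduces that variability), while high parasite diversity makes
diverse host populations the more idiosyncratic ones (host diversity
increases variability). `divmeta` implements the estimation machinery for
this question.

The unit of analysis is a **comparison**: summary statistics (mean, SD,
replicate-population count) of one parasite-success metric for a
high-diversity and a low-diversity group of host populations, nested in
experiments, nested in studies, annotated with a host genus and ten
categorical moderators. Parasite success is anything that quantifies
spread (prevalence, transmission), replication (load), or host killing
(virulence/mortality).

## Harmonisation

Raw extractions arrive in several shapes; four operations put them into
the canonical comparison table:

* **Pooling** (`pool_groups()`): when several groups must be collapsed
  (multiple high-diversity groups against a shared reference; several
  populations forming one diversity category), the pooled n is the total,
  the pooled mean the n-weighted mean, and the pooled variance the
  *total-sum-of-squares* variance of the concatenated sample,
  $[\sum_i (n_i{-}1)s_i^2 + \sum_i n_i(m_i-\bar m)^2]/(\sum_i n_i - 1)$.
  Pooling a single group is the identity, and the result is invariant to
  the order of the groups.
* **Median dichotomisation** (`dichotomise_continuous()`): studies
  reporting a continuous diversity gradient over populations are split at
  the median into equal-sized low and high groups, each then pooled. With
  an odd count the median population is dropped — equal group sizes are
  required and there is no unbiased side to give the median to. Boundary
  ties are broken by stable input order. A gradient with all scores equal
  has no defined split and is an error, not a silent guess.
* **Survival reversal** (`survival_to_mortality()`): host survival runs
  opposite to parasite success. Proportions are complemented
  (mean → 1 − mean; the SD of a complemented proportion is unchanged).
  Non-proportion survival metrics (e.g. survival time) have no defensible
  mean/SD transformation, so the record is flagged and only the SMD sign
  is negated downstream (d(−x) = −d(x)); lnCVR is undefined on a shifted
  scale and is refused for such records.
* **Log-safety offset** (`apply_offset()`): 0.001 is added to means and
  SDs of both groups before effect computation so logarithms exist for
  zero summaries. It is applied to *all* records, not only those with
  zeros (a `offset_zero_only` switch supports sensitivity checks), and it
  never changes the sign of a mean difference.

## Effect sizes

`effect_smd()` computes Hedges-corrected SMD with
$J = 1 - 3/(4(n_H+n_L-2)-1)$ and large-sample variance
$(n_H+n_L)/(n_H n_L) + g^2/(2(n_H+n_L))$; a `variance_denom = "2N-3.94"`
variant exists for cross-checks against implementations using that
denominator. `effect_lncvr()` computes the log CV ratio with the
$1/(2(n-1))$ small-sample corrections and the *independence form* of the
variance: the mean–SD correlation term of the full published formula
requires replicate-level series, which group summaries do not provide, so
it is zero by default (`mean_sd_cor` re-enables it). Positive values of
either effect mean higher (more variable) parasite success under high
host diversity.

Comparisons sharing a low-diversity control group are sampling-correlated.
`build_vcv()` fills the off-diagonals within each shared-control block
either as $r\sqrt{v_i v_j}$ with fixed $r = 0.5$ (the conventional choice
when the true correlation is unreported; outputs are labelled with the r
used) or, for SMD, with the structural form
$1/n_C + g_i g_j / (2N)$. The matrix is *validated* positive semidefinite
— a violation is an error naming the offending blocks, never silently
repaired, because a non-PSD sampling matrix indicates a data error
upstream.

## The multilevel model

For each effect kind separately (mean and variability are different
estimands; a joint bivariate model is out of scope), `fit_reml()`
maximises the restricted likelihood of

$$y = X\beta + u_{study} + u_{genus} + u_{exp} + \varepsilon, \qquad
\Sigma = V + \tau^2_s Z_sZ_s' + \tau^2_g Z_gZ_g' +
\tau^2_e[(1-\rho)I + \rho Z_eZ_e']$$

with $V$ the sampling VCV. Study and genus are exchangeable intercepts
(the genus effect is deliberately plain — no phylogenetic correlation
structure beyond genus identity). The experiment level is
compound-symmetric across the comparisons of an experiment: multiple
timepoints or multiple metrics from the same experimental contrast are
correlated with estimated $\rho$. At $\rho = 1$ this collapses to an
exchangeable experiment intercept; at $\rho = 0$ to comparison-level
noise.

Numerical choices:

* Variance components are searched on the log scale (lower bound
  effectively 0, estimates below 1e−8 reported as 0); $\rho$ through a
  scaled logistic transform bounded to [0, 0.999]. Negative
  within-experiment correlation is not allowed; it has no generative
  interpretation here.
* The REML objective is evaluated blockwise over the connected components
  of the grouping structure (union of study/genus/experiment factors and
  nonzero sampling covariances) in a compiled kernel — the likelihood is
  exactly block-diagonal, so this is a factorisation choice, not an
  approximation. Log-likelihoods follow the Harville convention
  (including $+\tfrac12\ln|X'X|$), making them directly comparable to
  standard REML implementations.
* Optimisation uses bounded quasi-Newton (`nlminb`, objective change
  tolerance 1e−12) from up to five dispersed starts seeded by a
  method-of-moments heterogeneity estimate; the search stops early once
  two starts agree to 1e−6. The reported convergence diagnostic is the
  numerical gradient norm; finite differences on an objective of this
  magnitude have a noise floor near 1e−4, so formal convergence is the
  optimiser's objective-change criterion, with a warning above a gradient
  norm of 1e−3.
* With no random levels the estimator short-circuits to exact
  inverse-variance GLS; with a rank-deficient design the aliased columns
  are named and the fit refused.
* Wald inference is normal (z), matching common meta-analytic practice
  for this model class; the test suite verifies its coverage against the
  generator's truth.

`i2_decompose()` attributes variance shares by level against the typical
sampling variance $\bar v = (k-1)\sum w_i /((\sum w_i)^2-\sum w_i^2)$;
components sum to the total, and the alternative decomposition excluding
$\bar v$ (share of heterogeneity alone) is attached as an attribute.
Note one identifiability caveat: when genus is nearly one-to-one with
study, the study/genus split of I² sits on a flat likelihood ridge; the
combined between-study share is the stable quantity. `qm_test()`,
`contrast()`/`contrast_family()` (Holm-corrected via `stats::p.adjust`)
and `prediction_interval()`
($\hat\beta \pm z_{0.975}\sqrt{SE^2+\sum\hat\tau^2}$) complete inference.

## Bias diagnostics and sensitivity

`egger_association()` reports the effect–SE association as a Pearson
correlation with Fisher-z CI — the form in which such tests are commonly
reported for multilevel data — with the classical weighted Egger
regression (standardised effect on precision) behind a flag. The
correlation is unweighted; this is stated in the output rather than
hidden. `funnel_table()` exports plot-ready funnel data with the model
mean attached. `leave_one_out()` refits the model omitting one study (or
one independent comparison set: effects sharing a control group count as
one set, membership derived from the shared-control key) at a time, and
averages estimate, SE, z, p and CI bounds *arithmetically* across
iterations — the averaged CI bounds are means of bounds, not a CI of the
average — with a precision-weighted mean estimate exported alongside.
Failed refits are recorded, flagged and excluded from averages.

## The synthetic generator

`generate_dataset()` draws a full comparison table with known truth. Per
comparison, the true SMD and lnCVR are the 2×2 cell effect (parasite
genetic diversity × host range, assigned at study level, which mirrors the
strong study-level clustering of these attributes in real compilations)
plus study, genus and experiment deviations; experiment deviations are
compound-symmetric with correlation `rho_experiment`, and the genus map
duplicates a genus across studies for a configurable fraction (default
10%) so the genus level is exercised. The low group has population mean
`control_mean` and CV `control_cv`; the high group's population parameters
are implied by the true effects — $CV_H = CV_L e^{\theta_{lnCVR}}$ and
$\mu_H$ solving $\mu_H = \mu_L + \theta_{SMD}\, s_{pool}(\mu_H)$, a
quadratic solved exactly (at extreme effect/CV combinations with no
positive root the mean is floored and the realised truth recorded).
Observed summaries are then drawn from the *exact* Gaussian sampling
distributions — mean $\sim N(\mu, \sigma^2/n)$, variance
$\sim \sigma^2\chi^2_{n-1}/(n-1)$ — which makes the analytic sampling
variances of both effect sizes exactly right and gives the calibration
tests a clean target. Because parasite-success summaries are positive by
definition, a draw with non-positive mean is redrawn; at the default
parameters this truncation is negligible. With `sampling_noise = FALSE`
the observed summaries equal their population values (the analytic limit
used by exactness tests, paired with the uncorrected-d option since
Hedges' J < 1 at finite n). A single integer seed drives one named,
versioned RNG stream; regeneration is bit-identical and the caller's RNG
state is untouched.

Default parameters of `diversity_uncertainty_preset()`:

| parameter | default | rationale |
|---|---|---|
| `n_studies` / experiments / comparisons | 48 / 1–4 per study / 1–3 per experiment | matches the scale of the motivating compilations (~48 studies, ~110 experiments, ~210 comparisons) |
| cell SMD (spec/low, spec/high, gen/low, gen/high) | −0.54, −0.76, −0.42, −0.23 | anchored to reported subgroup estimates of this literature; magnitudes illustrative and configurable |
| cell lnCVR | −0.54, +0.61, 0, 0 | the sign-flip prediction for specialists; generalists attenuated to zero |
| `tau2_study`, `tau2_genus`, `tau2_experiment`, `rho` | 0.5, 0.02, 0.05, 0.5 | study-dominated heterogeneity, tiny genus share, reproducing an I² profile of roughly 73–80% at the study level against the implied typical sampling variances |
| `control_mean`, `control_cv` | 10, 0.3 | a generic positive metric; CV moderate so the Gaussian summary model stays in its valid regime (lnCVR is ill-behaved once CVs approach 1.5) |
| `n_per_group` | 8–40 | replicate-population counts vary across studies; with constant n the SMD standard error would be a near-deterministic function of \|g\| and the funnel degenerate |
| `shared_control_fraction` | 0.3 | enough multi-arm experiments to exercise the shared-control VCV |

Heterogeneity deliberately sits slightly below the highest values reported
for such compilations: on the lnCVR scale a study-level τ near 1 pushes a
non-trivial share of high-diversity groups beyond CV ≈ 1.5, where sample
means of a positive metric go negative and lnCVR's higher-order
small-sample bias dominates — outside the regime the Gaussian-summary
model can represent honestly.

What the generator does *not* emulate: bounded metrics (prevalence is
generated as a generic positive quantity, not a true proportion with
binomial mean–variance coupling), digitisation error, missing or
misreported SDs, selective reporting, phylogenetic correlation beyond the
genus level, and temporal autocorrelation beyond the within-experiment
correlation. Passing tests therefore demonstrate the *estimation
machinery* — calibration of sampling variances, REML recovery, coverage,
the sign-flip detection — under the stated sampling model, not robustness
to those real-data pathologies. One genuine lnCVR property the generator
does reproduce: because the lnCVR sampling variance depends on the CVs
themselves, true variability effects induce a positive effect–SE
association even without any publication bias — a caution for
interpreting funnel diagnostics of variability effects.

`generate_replicates()` emits replicate-level Normal, scaled-binomial or
Poisson observations with a continuous diversity score per population,
feeding the harmonisation path (`summarise_replicates()` →
`dichotomise_continuous()`).

## Test-suite problem sizes

The suite's simulation sizes are chosen to make Monte-Carlo error small
relative to the tolerances while keeping the default run in minutes:
sampling-variance calibration uses 2,000 comparisons at n = 50 with 3σ
bands on the variance ratio; lnCVR consistency uses 1,000 independent
comparisons; parameter recovery fits the 2×2 cell-means model to 500
generated datasets of 100 studies each, requiring per-cell absolute bias
below 0.05 and 95% CI coverage within [0.92, 0.98]; the REML optimiser is
checked against an exhaustive zoomed grid search of the restricted
likelihood on 100 small instances (agreement to 1e−4), and against an
independent reference implementation on fits with the correlation fixed
(free-ρ compound symmetry is a notoriously fragile optimisation in any
implementation, and the reference fails to converge on the toy data).

## Known limitations

* The analysis pipeline fits two univariate models; correlations between
  a comparison's SMD and lnCVR are not modelled.
* Negative within-experiment correlation is not representable.
* lnCVR estimates for records with CVs near or above 1 carry small-sample
  bias that no correction in this family removes; the recovery tests
  quantify the residual (worst observed cell bias ≈ 0.04 at the preset).
* The study/genus variance split is weakly identified when genera rarely
  repeat across studies; report the combined between-study share.
* Leave-one-out averages follow the convention of averaging CI bounds,
  which is descriptive, not inferential.
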