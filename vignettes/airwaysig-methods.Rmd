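---
title: "Methods: signature-score transfer, moderated repeated-measures differential expression, and trial biomarker statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-score transfer and trial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaysig)
```

# What the package computes

`airwaysig` implements the computational backbone of a two-arm, randomized
airway chemoprevention trial with three collection timepoints (baseline,
end-of-treatment, one week post-treatment). The analysis has four arms of
machinery:

1. **Signature-score transfer.** A published gene-expression signature is
   represented by its reference dataset: a two-class (e.g., diseased vs.
   normal) expression matrix plus a signature gene list. Study samples are
   placed on the signature's axis by harmonizing study and reference into
   one batch-free matrix, z-scoring genes, fitting PCA to the reference
   samples over the signature genes, and projecting every sample onto the
   first component. Per-subject score changes are then compared between
   arms.
2. **Moderated differential expression with repeated measures.** Each
   gene is modeled with fixed effects for arm, timepoint, their
   interaction, RNA quality (RIN), and processing batch, with subject as
   a random effect handled through a single consensus within-subject
   correlation. The two interaction contrasts (treated-arm shift at
   end-of-treatment and at one week post) are tested with
   empirical-Bayes moderated t-statistics and gated at p < 0.01.
3. **Enrichment readouts.** Pre-ranked gene-set enrichment of the
   moderated-t ranking (concordance of the two interaction signatures at
   FDR < 0.05; pathway collections at FDR < 0.25), and per-sample
   gene-set scores correlated (Spearman) with urinary analyte changes.
4. **Urinary analyte statistics.** Creatinine-normalized LTE4 and PGEM
   summarized per arm and gender stratum, with two-sample t-tests on
   changes between arms and paired t-tests within arms.

Every stage runs end-to-end on synthetic data produced by the package's
own generators, so the full pipeline is testable without any external
download.

# The synthetic-data model

## Trial expression (`gen_trial`)

For gene $g$, sample $i$ (subject $s(i)$, batch $b(i)$):

$$y_{gi} = \mu_g + u_{s(i)} + \gamma_{g,b(i)} + \beta_g\,(r_i - \bar r)
          + \delta_{gi} + \sigma_{g}\,\lambda_{g,b(i)}\,\varepsilon_{gi}$$

with gene baselines $\mu_g \sim N(7, 1.5^2)$ (log2 intensity scale),
subject intercepts $u_s \sim N(0, \texttt{subject\_sd}^2)$, additive
batch shifts $\gamma_{gb} \sim N(0, \texttt{batch\_shift\_sd}^2)$,
multiplicative batch noise factors $\lambda_{gb} =
\exp(N(0,\texttt{batch\_scale\_sd}^2))$, per-gene RIN slopes $\beta_g
\sim N(0, \texttt{rin\_slope\_sd}^2)$ with RIN drawn uniformly on
`rin_range`, and $\varepsilon \sim N(0,1)$. The additive-plus-
multiplicative batch structure deliberately matches the location/scale
model of the batch-adjustment stage so both parts are exercised. The
treatment-by-time effect $\delta_{gi}$ equals `treatment_effect` (at
end-of-treatment) or `carryover_fraction * treatment_effect` (one week
post) for responsive genes in treated-arm samples, zero otherwise; a
fraction `frac_down` (default 0.5) of responsive genes move down rather
than up, since drug responses are bidirectional and both directions are
needed for a meaningful concordance analysis.

Per-gene noise variances $\sigma^2_g$ follow a scaled inverse-chi-square
around `noise_sd`^2 with `var_df` (default 10) degrees of freedom.
This is the conjugate form assumed by the variance-moderation stage;
homogeneous variances (`var_df = Inf`) would make moderation degenerate
(the prior df estimate diverges), which real array data never shows.

Dropout is monotone: an affected subject keeps a prefix of the timepoint
sequence, mirroring trial attrition rather than random cell deletion.
Sex is Bernoulli(0.5) and a set of "Y-marker" genes is expressed ~4 log2
units higher in male-labeled samples so the sex-verification step has
ground truth. The RIN distribution is a free choice (uniform) — the
design only requires that RIN varies and acts linearly per gene.

## Reference signature data (`gen_reference`)

A two-class matrix in which the signature genes are shifted by
`effect_size` in the case class. Effect sizes on the expression scale are
free parameters: published trials report score-scale summaries only, so
no attempt is made to calibrate the generator to a particular cohort.

## Analytes (`gen_analytes`)

Lognormal values on the creatinine-normalized scale (pg/mg Cr):
log-mean = log(baseline geometric mean) + log(`gender_ratio`) for
females + log(treatment ratio) in treated-arm end samples, with
`(1 - rebound_fraction)` of the log-suppression persisting one week
post. Measurement noise has lognormal coefficient of variation `cv`;
creatinine is uniform on `creatinine_range` and the raw pg/mL value is
reconstructed as normalized x creatinine, so normalization is exactly
invertible. Defaults (LTE4 geometric mean 70 pg/mg Cr, female/male ratio
1.5, treated end/baseline ratio 0.4, cv 0.5) reproduce the qualitative
structure of the urinary readout: clear LTE4 suppression, higher female
baselines, partial rebound, and a weak PGEM response (ratio 0.9).

# Preprocessing

* **PC1 outliers** — QC PCA treats samples as observations with genes
  centered, not scaled; samples beyond `sd_threshold` (default 2) sample
  standard deviations (n-1 denominator) from the mean first-PC score are
  flagged. A zero-variance PC1 flags nothing. Probe-level metrics
  (NUSE/RLE) need raw arrays and are explicitly out of scope, so the
  multi-metric exclusion rule used with raw arrays reduces here to the
  PCA rule alone.
* **Sex verification** — samples are split at the largest gap in sorted
  mean Y-marker expression; the higher cluster is male. If the largest
  gap is under `min_gap` (1 log2 unit) the split is declared degenerate:
  a single label is assigned (chosen by comparing Y-marker level to the
  matrix grand mean, since level alone cannot distinguish an all-male
  from an all-female cohort) and a warning flag is set.
* **Residualization** — gene-wise OLS on [kept design + removed
  covariates]; only the removed terms' fitted contribution is
  subtracted. Continuous covariates are centered and removed factors use
  sum-to-zero coding so gene means do not shift. Rank deficiency is an
  error naming the collinear columns. The operation is idempotent.
* **Z-scoring** — per-gene mean 0, SD 1 (n-1); constant genes map to
  zero rows so matrix shape survives into signature scoring.

# Empirical-Bayes batch adjustment

The location/scale model: standardized data $z_{gi} = (y_{gi} - \alpha_g
- X\beta_g)/\sigma_g$ with batch-size-weighted grand means and pooled
variances; per-batch location $\gamma_{gb}$ (batch mean of $z$) and
scale $\delta^2_{gb}$ (batch variance, n-1). Hyperpriors are fitted
across genes by moments: normal $(\bar\gamma_b, \tau^2_b)$ for location,
inverse-gamma $(\lambda_b, \theta_b)$ for scale (shape/scale solved from
the mean and variance of the $\delta^2_{gb}$). The joint posterior
updates

$$\gamma^*_{gb} = \frac{n_b\tau^2_b\hat\gamma_{gb} +
\delta^{2*}_{gb}\bar\gamma_b}{n_b\tau^2_b + \delta^{2*}_{gb}},\qquad
\delta^{2*}_{gb} = \frac{\theta_b + \tfrac12\sum_i (z_{gi} -
\gamma^*_{gb})^2}{n_b/2 + \lambda_b - 1}$$

are iterated to a maximum relative change below 1e-4 (cap 100; both
recorded in the returned model). Only the parametric variant is
implemented — the standard default, and nothing in the trial design
calls for the nonparametric prior. Study-reference harmonization runs
the same adjustment with dataset-of-origin as the batch and no
covariates: quality covariates are residualized out of the study data
beforehand, though the interface accepts them.

Degenerate inputs are errors: a single batch, a batch with fewer than 2
samples, covariates confounded with batch, or zero pooled variance.

# Signature scoring

PCA is fitted on the **reference samples only** — the axis is a property
of the reference — with genes centered at their reference means;
projecting all samples onto the first loading gives the scores. Centering
at combined means would shift every score equally and change no test, so
it is documented rather than configurable. The sign of a principal axis
is arbitrary; the axis is oriented so the designated class
(disease/exposure, `orientation_class`) scores higher, making a score
decrease the favorable direction. Signature genes missing from either
dataset are dropped with a logged count; fewer than two shared genes is
an error.

Change testing applies the trial's evaluability rule — a subject
contributes only with samples at **all three** timepoints, even for a
two-timepoint contrast — then compares per-subject changes between arms
(pooled-variance two-sample t by default) and within arms (paired t),
overall and per gender stratum. Pooled vs. Welch is a flag: both
reproduce every printed p-value checked in the worked examples at two
decimals, so the choice cannot be identified from published tables.
`ttest_from_summary` computes either test from group means/SDs/sizes
alone, which is what reproducing published tables requires; `fisher2x2`
sums hypergeometric probabilities no larger than the observed table's
(relative tolerance 1e-7 on the comparison), the dominant two-sided
convention.

# Moderated differential expression

**Consensus correlation.** For each gene the within-subject correlation
of the exchangeable model is estimated by REML: for candidate
$\rho$ the data and design are whitened by the inverse square root of
the block correlation matrix (closed form per block: $(I - J/k)/
\sqrt{1-\rho} + (J/k)/\sqrt{1-\rho+k\rho}$), and the REML profile
$-\tfrac12[(n-p)\log \mathrm{RSS}_g(\rho) + \log|V(\rho)| +
\log|X'V^{-1}X|]$ is evaluated. Because the whitening and determinant
terms depend only on $\rho$, one pass over a $\rho$ grid (default step
0.01, range $(-1/(k_{max}-1), 0.99]$) serves all genes simultaneously;
each gene's optimum is refined by quadratic interpolation of its three
top grid points. Per-gene estimates are pooled by a 15%-per-tail trimmed
mean on the atanh scale — the convention of the standard consensus
estimator, which this implementation matches to ~2 decimals on simulated
trials. The 0.99 cap keeps the whitening finite when blocks contain
exact duplicates. All-singleton blocks are an error; a single grid pass
handles mixed block sizes, including size-2 blocks, so no separate
small-block fallback is needed.

**GLS + moderation.** With the consensus $\rho$ fixed, every gene is fit
by whitened OLS (one QR for all genes). Residual variances $s^2_g$ with
$d_g = n - p$ df are shrunk toward a scaled inverse-chi-square prior
$(d_0, s_0^2)$ fitted by matching the mean and variance of $\log s^2_g$
through digamma/trigamma moment equations; the trigamma inverse is
solved by Newton iterations to relative tolerance 1e-8. If the observed
log-variances are *under*dispersed relative to the chi-square sampling
noise the solve has no positive solution; the fit falls back to the
no-moderation limit $d_0 = \infty$ with $s_0^2$ = mean variance and a
warning, rather than aborting. Moderated t uses $\tilde s^2_g = (d_0
s_0^2 + d_g s^2_g)/(d_0 + d_g)$ and $d_g + d_0$ df (capped at the total
residual df pooled over genes). Interaction gene lists gate on the raw
per-contrast p-value (default 0.01) with **no multiple-testing
adjustment** — deliberate: the published analysis gates the same way and
labels all secondary analyses exploratory. The two interaction
contrasts are tested separately (not as a joint F), since the analysis
reports separate end-of-treatment and post-treatment gene counts.

# Enrichment

**Pre-ranked GSEA.** Genes are sorted by the statistic (descending, ties
broken by gene ID so runs are reproducible); the running sum adds
$|t|^w/\sum_{hits}|t|^w$ at members and subtracts $1/(N-N_h)$ elsewhere;
ES is the signed extremum. The null is `n_perm` (default 1000) random
same-size gene sets — gene-set permutation is the only scheme available
to a ranked-list input. NES divides ES by the mean same-sign null ES;
nominal p is the same-sign null tail; FDR follows the positive/negative
pool convention and is forced monotone in |NES| within each sign pool.
Note the null NES mean is *not* exactly zero: the signed extremum lands
positive slightly more often than negative, an inherent property of the
statistic, not a bug. A set covering the whole ranking has no miss step
and is an error; sets with fewer than 2 ranked members are dropped with
a warning.

**Concordance.** The one-week-post up/down lists are scored against the
end-of-treatment ranking; "concordant" requires up-ES > 0, down-ES < 0,
and both FDR q < 0.05.

**Per-sample scores.** Each gene's expression is mapped through a
Gaussian-kernel smoothed cross-sample CDF (bandwidth = gene SD / 4, the
cited method's convention); within each sample genes are ranked by these
values and a weighted KS walk with weight $|N/2 - \mathrm{rank}|$
(exponent 1) over set members yields the maximum-deviation statistic.
The kernel CDF is *not* exactly invariant to monotone per-gene
transforms (no smoothed estimate is); `kernel = "ecdf"` substitutes
average-tie ranks for exact rank invariance when that property matters.
Constant genes carry no rank information and are dropped with a warning.

**Score-analyte correlation.** Spearman (average ranks for ties) of
per-subject score changes against analyte changes, per arm, restricted
to fully-sampled subjects; fewer than 4 pairs flags the result
unreliable rather than failing.

# Analyte statistics

Tests run on the creatinine-normalized scale untransformed, so each
printed change mean equals the difference of the printed level means —
the arithmetic consistency real summary tables show. A `log_scale`
option serves simulation studies of multiplicative effects, where the
log scale is the natural one. Strata with fewer than 2 subjects, or
zero-variance changes, are flagged rather than tested.

# Numerical choices, at a glance

| Quantity | Value | Why |
|---|---|---|
| Batch-EB convergence | 1e-4 relative, cap 100 | posterior updates converge fast; cap recorded per batch |
| Consensus-$\rho$ grid | step 0.01, cap 0.99 | pooled estimate insensitive below grid noise; cap keeps whitening finite |
| Trigamma inverse | Newton, 1e-8 relative | hyperparameter solve to numerical accuracy |
| GSEA ties | stable gene-ID order | bit-reproducible rankings |
| Fisher comparison | relative 1e-7 | guards equality of hypergeometric probabilities against float error |
| z-score / SD | n-1 denominator | sample-statistic convention throughout |

# What the synthetic validation does and does not show

The generators produce Gaussian log-intensities with exchangeable
within-subject correlation, linear RIN effects, and batch effects drawn
from the same family the adjustment assumes. Passing tests therefore
demonstrate that each algorithm does what its definition says under its
own model: batch shifts are removed (and match the reference
implementation to ~1e-5), the consensus correlation recovers a true
intra-class correlation of 0.5 within ±0.08 (30 subjects x 3 timepoints
x 500 genes), the variance-prior solver recovers generating
hyperparameters (d0 within 20%, s02 within 5% at 5000 genes), the
interaction test holds its nominal type-I error at the p < 0.01 gate
(pooled over 10 null trials x 2000 genes), and enrichment scores equal
exhaustive enumeration for lists up to 12 genes. They do not show
robustness to heavy-tailed intensities, nonlinear quality effects,
outlier subjects, or batch effects outside the location/scale family —
properties that only real data can probe. Problem sizes in the test
suite (hundreds of genes, 20-40 subjects) were chosen as the smallest
at which the targeted effects are statistically identifiable.
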