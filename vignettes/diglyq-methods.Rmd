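---
title: "Models and methods behind diglyq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind diglyq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diglyq)
```

# Scope

`diglyq` implements the quantitative core of a diGly (K-&epsilon;-GG)
ubiquitinome study of stimulated synaptosomes: a discovery stage built on
isobaric TMT-6plex reporter ions, a validation stage built on parallel
reaction monitoring (PRM) with heavy peptide standards, a peptidoform
crosstalk model for peptides that carry a phosphosite and a ubiquitination
site on the same tryptic fragment, and cross-method comparisons. A
synthetic-data generator with known ground truth makes every stage testable
without access to raw mass-spectrometry data.

# The TMT discovery stage

## Site-level quality control

A site table row enters quantification only if it is not a potential
contaminant, not a reversed-sequence decoy, has a localization probability
of at least 0.75 (a site at exactly 0.75 is kept — the exclusion rule is
"lower than"), and has at most three zero-intensity channels in its
TMT-6plex. Remaining zeros are treated as left-censored values and imputed
at the minimum nonzero intensity of their own channel, after which all
intensities are log2-transformed. Min-imputation is deliberately simple
and matches practice for reporter-ion data, but it is also the stage's
weakest link: when censoring is condition-dependent (a genuinely
down-regulated site losing its low channels), the imputed floor can
overstate the fold change. The simulation studies below retain this
behaviour on purpose rather than idealizing it away.

## Median-polish normalization

Each labeling batch is normalized independently by Tukey median polish on
the log2 site &times; channel matrix: rows are swept first, then columns,
for at most three full iterations (the iteration cap is the procedure's
stop rule; `stats::medpolish` provides the sweep). The normalized value is

$$\tilde{y}_{ic} = y_{ic} - \hat{\mu} - \hat{\beta}_c,$$

i.e. only the overall level and the column (channel-loading) effects are
removed. Row effects are the biology — site abundance — and are retained.
Because medians drive the decomposition, the estimated channel effects are
insensitive to the sparse minority of truly regulated sites. One numerical
subtlety: with even channel counts the row/column alternation can settle
in a fixed point where the medians of the residuals along the
next-to-be-swept margin are small but not exactly zero; the decomposition
identity `value = overall + row + column + residual` holds exactly
regardless.

## Moderated testing

After the batches are joined on shared sites, each site is fit by ordinary
least squares on condition (Ca²⁺ vs EGTA, reported effect Ca − EGTA) plus
a labeling-batch covariate. The batch term is on by default: the two
6-plexes are normalized independently, so a residual offset between them
is nuisance, not signal (it can be disabled with `batch_term = FALSE`).
Residual variances $s_i^2$ with $d$ degrees of freedom are shrunk toward a
pooled scaled inverse-chi-square prior,

$$s^2_{\text{post},i} = \frac{d_0 s_0^2 + d\, s_i^2}{d_0 + d},$$

with $(d_0, s_0^2)$ estimated by method of moments on $\log s_i^2$
(matching moments of the log chi-square distribution, with a Newton
inversion of the trigamma function). The moderated statistic
$t_i = \hat\beta_i / \sqrt{s^2_{\text{post},i} v}$ is referred to a
$t_{d + d_0}$ distribution. When the moment estimate of $d_0$ is
non-finite — which happens routinely when the true variances are
homogeneous, e.g. in constant-noise simulations — the implementation does
not silently force $d_0 = \infty$; it falls back to ordinary $t$
statistics and records a warning, which `tmt_fit()` surfaces in its
`notes`.

## q-values and calls

Multiple testing is handled by Storey q-values with $\pi_0$ estimated at a
single $\lambda = 0.5$, $\hat\pi_0 = \min\{1, \Pr(p > \lambda)/(1 -
\lambda)\}$. The single-$\lambda$ estimator was chosen over the
spline-over-$\lambda$ variant for determinism at moderate test counts;
$\lambda$ is exposed in `pipeline_config()`. Forcing $\pi_0 = 1$
reproduces Benjamini–Hochberg exactly, which the tests use as an oracle. A
site is called regulated when $|\text{log2FC}| \ge \log_2 1.15$
(inclusive) **and** $q < 0.05$ (strict); the fold-change threshold is
applied symmetrically on the log scale.

# The PRM validation stage

Transition-level QC happens per peptide (sequence + peptidoform +
phosphatase state). The heavy-standard areas of each fragment are summed
across all runs of the peptide, so the surviving transition set is
identical in every run; fragments below 5% of the peptide's maximum are
excluded, and peptides left with fewer than 7 fragments are dropped.
Judging QC on the heavy channel only means the filter cannot bias the
light/heavy ratio. One consequence of a *relative* threshold is worth
knowing: adding a new dominant transition can demote borderline ones, so
the filter is guaranteed monotone only under additions that do not change
the peptide's maximum.

Quantification uses the ratio of sums, $\sum \text{light} / \sum
\text{heavy}$ over surviving transitions per injection — not the mean of
per-transition ratios — which is invariant to common run scaling and
weights strong transitions more. Injection replicates are averaged
arithmetically on the ratio scale (a log-scale geometric mean is available
behind `log_scale = TRUE`). Differential testing models
$\log_2(\text{ratio}) \sim \text{condition} + \text{batch}$ per peptide
with the same empirical-Bayes machinery as the TMT stage; the log scale is
a variance-stabilization choice. Calls require at least a 1.23-fold change
and $q < 0.05$.

# The peptidoform crosstalk model

For a tryptic peptide carrying both a phosphosite and a ubiquitination
site, write $S$ and $D$ for the light/heavy ratios of the singly
ubiquitinated and doubly modified forms. Because each form has its own
heavy standard spiked at the same amount, the ratios act as absolute
abundance proxies, and the total ubiquitinated pool is $S + D$. The model
assumes the double pool changes only by (de)phosphorylation of the single
pool within the observation window; de novo ubiquitination of
already-phosphorylated molecules is folded into the conversion term. The
apparent change of the single form then splits exactly:

$$\underbrace{S_E - S_C}_{\Delta_\text{apparent}} =
  \underbrace{D_C - D_E}_{\Delta_\text{conversion}} +
  \underbrace{(S_E + D_E) - (S_C + D_C)}_{\Delta_\text{net}}.$$

A phosphatase control collapses $D$ back onto $S$, so its predicted
reference/stimulated fold change is $(S_E + D_E)/(S_C + D_C)$ — exactly 1
for pure conversion, even when the single form alone drops by 100%.
Mechanism classification uses an absolute tolerance of 0.02 ratio units
(about half the smallest ratio the model is typically fed) to decide
whether a component is real; both components exceeding it yields
`"both"`. The model's main caveat is the assumption that antibody
enrichment recovers both peptidoforms equally; the co-enriched heavy
standards mitigate but cannot fully remove this.

# Cross-method comparison

The ratio-compression factor of the isobaric stage is estimated by
ordinary least squares **through the origin**, regressing PRM log2 fold
changes (treated as accurate) on TMT log2 fold changes, so the slope reads
directly as the underestimation factor; the orientation is a flag because
the opposite convention also appears in the literature. No intercept is
included: both axes are contrasts that vanish together under the null.
Note that noise in the TMT estimates (the predictor) attenuates this slope
downward — an errors-in-variables effect visible in the simulation
studies, where recovered slopes sit a few percent below the generative
factor.

Cross-dataset site matching replaces a BLAST alignment with direct
windowed comparison: two ±6-residue windows centred on the modified
lysine match when their centres agree and the Hamming distance over
non-padding positions is at most 1 (configurable), absorbing single
cross-species substitutions. Each query window takes its single best
target, ties broken by distance then lexicographic order.

# The synthetic-data generator

The generator emulates, per batch, observed log2 reporter intensities

$$y_{ic} = b_i + \beta_c + x_c \frac{\theta_i}{\kappa} +
\varepsilon_{ic},$$

with site baselines $b_i \sim N(16, 2^2)$ (log2 arbitrary units, spanning
the usual reporter dynamic range), channel loading $\beta_c \sim N(0,
0.3^2)$ centred within batch, $x_c$ the Ca²⁺ indicator, sparse true
effects $\theta_i$ (43 of 5258 sites by default, 60% down / 40% up,
$|\theta| \in [\log_2 1.3, \log_2 3]$), a compression factor $\kappa =
1.43$ applied to the observed isobaric effects, and noise
$\varepsilon \sim N(0, 0.25^2)$. Compression is modeled as a constant
divisor of the true log2 effect — the form a regression slope against an
accurate method measures — rather than as a mechanistic co-isolation
mixture. Missingness is logistic in the latent log2 intensity
(left-censoring), with midpoint 11 and scale 0.5 log2 units: a sharp
detection limit, reflecting that reporter ions several log2 units above
the limit are essentially never absent. Decoy contaminant/reverse rows and
sub-0.75 localization probabilities are injected at configurable rates so
the QC stage has real work to do.

The PRM arm gives each panel peptide 7–12 informative transitions with
heavy areas log-normal around a peptide scale, plus (on average) one weak
transition per ten informative ones generated below 5% of the maximum to
exercise QC; light areas are heavy &times; true ratio &times; log-normal
noise at CV 0.1. The panel (26 peptides, 9 regulated by default) is drawn
from the upper half of the abundance distribution, as a targeted assay
would be designed — low-abundance sites would not yield reliable
transitions. Noise magnitudes (`noise_sd = 0.25`, `prm_cv = 0.1`) are
calibration choices, not measured constants, and are exposed as
parameters.

Each generator stage derives its own RNG stream from the user seed plus a
stage label, so TMT tables, PRM reports and crosstalk observations can be
regenerated independently and reproducibly.

What the generator does **not** emulate: peptide-level interference
structure (co-isolation is summarized by one factor), retention-time or
spectral artefacts, shared-peptide ambiguity, enrichment chemistry, and
protein-level abundance changes. Passing tests therefore demonstrate the
statistical machinery under the stated generative assumptions, not
robustness to every pathology of real data.

# Problem sizes and numerical choices

The simulation checks shipped with the package use: 100 generator seeds of
2000 sites (50 regulated, $|\theta| \in [0.5, 1.5]$, noise 0.25) for the
false-discovery-rate study — run without compression, since compression
rescales effect sizes and therefore power but cannot create false
positives; and 20 seeds of the full TMT + PRM pipeline at default (5258
sites scaled to 2000) for compression-slope recovery. These sizes give
Monte-Carlo standard errors comfortably below the quantities' tolerances.
Other numerical choices: median-polish convergence uses an effectively
zero tolerance so the 3-iteration cap binds; exact zero residual variances
(possible in noise-free simulations) yield p = 0 rather than NaN;
q-values' $\hat\pi_0$ is floored at $1/m$; the trigamma inversion runs
Newton steps to $10^{-10}$ relative precision.

# Known limitations

* Min-imputation biases fold changes of sites with condition-dependent
  censoring (kept by design; see above).
* The compression-slope estimator inherits errors-in-variables
  attenuation from TMT estimation noise.
* The crosstalk model is a steady-state two-timepoint accounting; it
  cannot resolve kinetics, chain topology, or unequal peptidoform
  recovery.
* Storey's single-$\lambda$ $\pi_0$ is slightly conservative when the
  alternative bleeds above $\lambda$.

# A worked example

```{r example}
params <- truth_params(n_sites = 500, n_regulated = 20, rng_seed = 11)
truth <- generate_ground_truth(params)
fit <- tmt_fit(simulate_tmt_experiment(truth))
fit
head(sort(coef(fit)), 3)

obs <- crosstalk_observation(E_single = 0.27, E_double = 0.034,
                             C_single = 0.14, C_double = 0.1)
predict_phosphatase_fold_change(obs)
decompose_apparent_change(obs)
```
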