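---
title: "Encoding and decoding bite force and gape: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding and decoding bite force and gape: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapeforce)
```

# The scientific problem

During incisor biting, the orofacial sensorimotor cortex must control two
behavioral variables with very different dynamics: the **bite force**, which
the subject actively regulates through a trial, and the **gape** (jaw
depression distance), which is set before the trial and held static. The task
emulated here crosses three gapes with three required force levels — nine
trial types — while spiking is recorded simultaneously from neurons labeled
MIo (primary motor), SIo (primary somatosensory), and CMA (cortical
masticatory area). All neural analyses are aligned to **force onset (FO)**,
the time the force trace first rises toward its target, and run on a ±500 ms
window in 4-ms bins.

The package implements two complementary analysis levels plus a generator
that makes both testable by parameter recovery:

1. a **single-neuron encoding model**: a point-process Bernoulli GLM of each
   neuron's 4-ms spike indicator;
2. a **population decomposition**: demixed PCA of the trial-averaged
   population tensor, with time-resolved classification from the leading
   demixed axes;
3. a **synthetic-data module** that simulates the task, the force traces,
   and spike trains from known ground truth.

# The encoding model

For neuron $n$, the probability $p_n(t)$ of a spike in the 4-ms bin at time
$t$ obeys

$$
\mathrm{logit}\, p_n(t) = \beta_0
 + \sum_{j=1}^{3} \beta^H_j H_j(t)
 + \beta^G G
 + \sum_{k=1}^{8} \beta^F_k F(t + \tau_k)
 + \sum_{k=1}^{8} \beta^{GF}_k \tilde G \, F(t + \tau_k),
$$

with

* $H_j(t)$: the neuron's own binarized spike train filtered through
  raised-cosine basis functions with supports ending at 16, 44, and 108 ms
  (`make_basis()`), capturing short/medium/long history effects such as
  refractoriness. Filtering is strictly causal, starts at one bin of lag
  (no instantaneous self-coupling), and never crosses trial boundaries.
* $G$: the trial's gape in mm, constant within a trial.
* $F(t+\tau_k)$: the bite force at eight lags
  $\tau_k = -156, -104, \dots, +208$ ms (`force_lag_grid()`). The sign
  convention is physiological: negative lags read force *before* the spike
  bin (force leads spiking, sensory-like), positive lags read force *after*
  it (force lags spiking, motor-like). With gape, forces, and interactions
  this yields 17 extrinsic covariates.
* $\tilde G = G - \bar G$: gape centered on the session mean of its three
  values, used only in the interaction columns. This is a pure
  reparameterization (the model space is unchanged) chosen for numerical
  conditioning: the raw product $G\,F$ correlates above 0.98 with $F$
  because the gape spread (±3 mm) is small relative to its mean (~14 mm),
  which would inflate the force-coefficient variance roughly six-fold.

Fitting is maximum likelihood via IRLS/Newton with a tiny L2 ridge
($10^{-6}$, for conditioning only) and step halving; a fit is *converged*
when the max-norm of the penalized gradient falls below $10^{-6}$ within 100
iterations. Cross-validation is 10-fold at the **trial** level, stratified
by the nine trial types so every fold sees every condition, and the fold
partition is a function of the trial table and seed only — reduced models
are always scored on exactly the same folds as the full model. Model quality
is the AUROC of predicted per-bin probabilities on held-out trials
(Mann–Whitney formulation, ties counted half), averaged over converged
folds.

The model zoo (`model_zoo_specs()`) contains the full model and its
reductions. A removal drops the named group *and* any interaction whose
parent was removed (a flag restores the interaction if wanted); the
`*_only` models are literal. `no_history` — gape + force + interaction — is
the joint extrinsic model used for the removal comparisons, so "force
removed" compares it with `gape_only` and "gape removed" with `force_only`.

Downstream single-neuron analyses:

* **Classification**: a neuron is force-related (gape-related) when the
  fold AUROCs of its force-only (gape-only) model beat chance (0.5) by a
  one-sided Wilcoxon signed-rank test at $p<0.05$; only neurons converging
  in ≥6 folds are included. For ≤14 non-zero differences the signed-rank
  null is enumerated exactly (ties kept as average ranks), so ten identical
  above-chance folds give $p = 2^{-10}$.
* **Preferred force lag**: from the force-only fit, among lags whose Wald
  statistic ($\beta/\mathrm{SE}$, normal reference) is significant at
  $p<0.05$, the lag of largest $|\beta|$; ties break toward the most
  negative (force-leading) lag; neurons with no significant lag are
  excluded and counted.
* **History timescales**: Kruskal–Wallis across the three $|\beta^H|$
  groups with Bonferroni-corrected pairwise follow-ups.
* **Single-lag control**: six mini-GLMs per neuron — the spike indicator of
  one bin at 60…160 ms after FO regressed on gape, the force at +100 ms,
  and their product — to check that the force-over-gape asymmetry is not an
  artifact of force contributing eight covariates and gape one.

# Population decomposition

`build_condition_tensor()` converts counts to rates, smooths each trial
with a truncated (±3σ, edge-renormalized) 50-ms Gaussian — the same kernel
policy as the PETHs — and averages within each of the nine cells. The
centered tensor $Y[n,g,f,t]$ splits exactly into

$$
Y = X_T + X_G + X_F + X_I,
$$

where $X_T$ is the condition-independent time course, $X_G$ pools the gape
main effect with gape×time, $X_F$ likewise for force, and $X_I$ is the
remainder (gape×force and gape×force×time). On the balanced design these
four parts are mutually orthogonal projections, so their squared norms
partition the centered variance — the variance "pie" is exact and
independent of any fitted model.

`fit_dpca()` then finds, per marginalization $\phi$, encoder/decoder pairs
minimizing $\|X_\phi - F_\phi D_\phi X\|^2 + \lambda\|F_\phi D_\phi\|^2$ in
closed form: the full-rank ridge solution
$A = X_\phi X^\top (XX^\top + \lambda I)^{-1}$ is rank-truncated through the
SVD of $AX$. At $\lambda = 0$ this is exact reduced-rank regression, so the
summed loss can never exceed a PCA-axes baseline of the same rank, and when
all variance lives in a single marginalization the components coincide with
PCA (both identities are tested to $10^{-8}$). $\lambda$ is expressed
relative to the mean per-neuron signal power; `select_lambda()` offers a
cross-validated choice over a logarithmic grid, with $\lambda = 0$ the
default for the balanced, low-noise synthetic regime. Components are
ordered globally by explained variance; per-component variance is split
across marginalizations by projecting each marginalized tensor onto the
component's decoder.

# Decoding and significance

`decode_timecourse()` follows the stratified Monte Carlo leave-group-out
scheme: on each of `n_cv` iterations, one trial per neuron per condition is
held out as a test pseudo-trial (neurons' held-out trials are drawn
independently — the pseudo-population shares only condition identity); the
first demixed axis of the target marginalization is refit on the
training-trial averages (a flag fits it once instead); projections are
classified at each 50-ms bin to the nearest training-class centroid in 1-D,
ties toward the lower class index. Gape and force decoding are 3-class,
trial-type decoding is 9-class.

The null distribution repeats the procedure with condition labels permuted
across whole trials, independently per neuron, preserving per-condition
counts. A bin is significant when the actual mean accuracy **exceeds all**
shuffled accuracies — nominally $p = 1/\text{n}_\text{shuffle}$, i.e. 0.002
at the default 500 shuffles. Because each shuffled curve is itself a mean
over `cv_per_shuffle` iterations (default `n_cv`/10; the paper-style
1000/500 preset and the reduced 200/100 preset are both available), the
null curves are noisier than the actual curve and the rule is conservative
in practice; the measured type-I rate on label-independent populations is
well below nominal.

# The synthetic generator

`generate_trials()` builds the balanced 3×3 session. Defaults: gapes 11,
14, 17 mm; force targets 1, 2, 3 V; randomized gape order (a blocked mode
groups trials by gape); logistic force ramps of ~300 ms reaching the target
and holding through the trial end. Trial-to-trial realism matters here:
ramp durations vary (lognormal, 25% CV), bites overshoot the target before
relaxing (half-normal, 15% of target), and a low-amplitude tremor-like
fluctuation (5% of target, ~20-ms correlation time, i.e. the 8–12 Hz band
of physiological force tremor) rides on the hold, plus white sensor noise
(0.02 V). Without this variability the eight lagged force covariates are
nearly collinear after FO alignment and the multi-lag model is barely
identifiable; with it, coefficient recovery is well-posed. FO is detected
where the trace first crosses 10% of the lowest force target *and stays
there* (the mean of the following 50-ms window must remain at or above
threshold), which rejects isolated noise excursions at baseline; on a
noiseless linear ramp the detected time is exactly $t_0 + \theta/s$.

`simulate_spikes_glm()` runs the encoding model generatively and
sequentially in time, drawing each 4-ms Bernoulli with the neuron's own
just-simulated history filtered through the same basis used in fitting.
`random_glm_truth()` draws cohorts with baseline rates uniform on 5–30
spikes/s, sparse force tuning (weight sd 0.35 per volt), weak gape tuning
(sd 0.04 per mm; zero in the gape-null cohorts), and negative,
short-dominated history weights (means −1.5/−0.6/−0.2).

`simulate_population_latent()` builds rates as baseline (20 Hz) plus
loading-weighted templates per marginalization, scaled so the noiseless
tensor realizes target variance fractions exactly (stored as ground
truth); per-trial rates add Gaussian noise (2 Hz) and spikes are Poisson
per 4-ms bin. Spike history is deliberately absent here: the decomposition
operates on trial-averaged rates, and history would confound the
variance-fraction ground truth.

# Problem sizes and numerical choices

The recovery studies use sizes chosen up front from first principles:

* **GLM recovery**: 50 neurons × 207 trials (23 per condition; the nine
  balanced conditions cannot give exactly 200) × 250 bins. With the
  trace variability above, full-model coefficient SEs are small enough
  that the pooled truth-estimate correlation exceeds 0.9.
* **dPCA recovery**: 40 neurons × 45 trials per condition. The
  trial-averaged Poisson sampling noise floor after 50-ms smoothing is
  roughly $\lambda/\Delta / 44 / n_\text{trials}$ per bin (≈2% of total
  variance at 45 trials), which keeps the recovered variance fractions
  within a couple of points of the realized ground truth.
* **Decoding calibration**: 12-neuron populations, 6 trials per condition,
  at the reduced 200 CV / 100 shuffle preset over 20 seeds for the type-I
  check; the full 1000/500 preset is the default for real runs.

Other numerical decisions: bins are half-open $[l, r)$ left-aligned to
−500 ms (a spike exactly at +500 ms is excluded); binarization clips counts
at 1 and logs the clipped fraction; PETH SEMs are across trials; proportion
SEs are binomial $\sqrt{p(1-p)/n}$; chi-squared tests default to no
continuity correction (a flag enables it); pairwise area comparisons use
Bonferroni-corrected $\alpha = 0.05/3 \approx 0.017$; failed trials are
excluded from neural analyses by default (a flag includes them).

# What the synthetic tests do and do not show

The generator emulates the task structure, force-trace shape and
variability, Bernoulli/Poisson spiking with history, and a low-dimensional
population geometry with known variance splits. It does **not** emulate
correlated noise across neurons, non-stationarity across a session,
electrode artifacts, spike-sorting errors, or the particular tuning
distributions of real MIo/SIo/CMA populations. Passing recovery tests
therefore demonstrates that the estimators are correct and well-calibrated
on data satisfying their assumptions — not that real cortical data meet
those assumptions, and subject- or area-specific quantities (median AUROCs,
variance pies, related-neuron proportions) from real recordings are outside
what synthetic data can reproduce.

# Known limitations

* The dPCA ridge default is $\lambda = 0$; heavily noise-dominated or
  rank-deficient populations need `select_lambda()` or a positive ridge.
* The decoder uses the first demixed axis only, as in the reference
  procedure; multi-axis classifiers would be a straightforward extension.
* Unbalanced trial counts are handled by plain per-cell means; the
  generator always produces balanced designs, and strongly unbalanced real
  data would warrant re-weighting that is not implemented.
* The exceed-all significance rule is a global-maximum test per bin; its
  nominal level assumes exchangeability between the actual and shuffled
  statistics, and the shuffled curves' higher Monte-Carlo variance makes it
  conservative rather than exact.
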