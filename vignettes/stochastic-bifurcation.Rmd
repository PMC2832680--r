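---
title: "Estimating stochastic bifurcation structure from dose-gradient flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating stochastic bifurcation structure from dose-gradient flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochbif)
```

## The problem

A bistable genetic switch — the yeast galactose-utilization network is the
canonical example — responds to an intermediate input dose not with an
intermediate expression level but with two coexisting subpopulations: cells
stochastically commit to a low- or a high-expressing state, and the
population distribution of a fluorescent reporter becomes bimodal. A
classical bifurcation diagram summarizes a *deterministic* model by its
steady states as a function of a control parameter. For a noisy cellular
system measured one cell at a time, the analogous summary — the
*stochastic bifurcation structure* — specifies, as a function of the dose:

1. the number of distinguishable subpopulations,
2. their locations on the measurement scale,
3. the variability within each subpopulation, and
4. the fraction of the population each represents.

This package estimates all four from flow-cytometry channel histograms
collected over a dose gradient, using three mixture-based estimators, and
ships a synthetic-data generator that emulates the galactose experiment so
every estimator can be exercised and validated end to end without access
to the original instrument data.

## Data model

A flow cytometer with a logarithmic amplifier records each event in one of
1024 fluorescence channels spanning four decades of intensity, so channel
$c$ corresponds to relative intensity $10^{4(c-1)/1023}$ and channel 1024
is 10,000 times brighter than channel 1. All fitting happens directly in
channel (log-intensity) coordinates: a Gaussian in channel space is a
lognormal in intensity, the usual working assumption for expression noise
about a steady state. A dataset is a collection of count vectors, one per
(pregrowth condition, replicate, dose), exchanged as a plain TSV table.
Channels are treated as integer bin centers $1,\dots,1024$; densities are
evaluated at bin centers rather than integrated over bins, which is
indistinguishable when component standard deviations (40–80 channels here)
are much wider than one channel, and is documented as a limitation for
hypothetical near-degenerate components.

## The mixture family

Every per-dose model is a $K$-component Gaussian mixture plus one uniform
component over the full channel range:

$$p(c) = \frac{w_u}{1024} + \sum_{i=1}^{K} w_i\,
  \mathcal N(c;\,\mu_i, \sigma_i^2),
  \qquad w_u + \sum_i w_i = 1 .$$

The uniform weight is *fixed* at $w_u = 0.02$ and absorbs outlier events
(contaminating particles, sample carry-over), so the Gaussian weights
share the remaining 0.98. Besides robustness, the uniform floor bounds the
density away from zero, so log-likelihoods are always finite. Subpopulation
fractions are reported renormalized by 0.98 so they sum to one.

### Fitting by EM with restarts (`fit_em_restarts`)

The expectation–maximization updates are the standard ones adapted to
binned counts, with the uniform weight held fixed and the Gaussian weights
renormalized to 0.98 in each M-step. Because the likelihood surface is
multimodal, the fit is repeated from 100 random initializations (component
means uniform between the lowest and highest occupied channel, standard
deviations 50 — the width observed at single-subpopulation doses — and
equal weights), keeping the highest-likelihood run; ties break to the
lowest restart index, and each restart draws from a substream derived from
(seed, restart index) so enlarging the restart budget never reshuffles
earlier runs. A component whose variance falls below 1 channel² is
eliminated and the remaining weights renormalized: such a component has
collapsed onto a single channel and cannot represent a real subpopulation.
The floor value is a package choice on the natural instrument scale (one
channel), exposed as `variance_floor`. Convergence is declared at a
relative log-likelihood change below $10^{-8}$ (500 iteration cap), and
the per-iteration trace is stored so the EM ascent property is testable.

### Choosing the number of components (`select_num_components`)

Starting from $K = 1$, the same ten event-level folds are used to score
$K$ and $K+1$ by held-out mean log-likelihood per event; the step to
$K + 1$ is accepted only when its fold-mean exceeds the $K$ model's
fold-mean by more than $\alpha$ fold-standard-deviations of the $K+1$
scores. Two details were genuinely open and are fixed here as package
choices, both configurable:

* the stringency $\alpha$ defaults to 1.0, which in our synthetic
  calibration is sufficient to keep clearly single subpopulations (e.g. at
  zero dose) from being split while reliably accepting a genuine second
  component;
* the comparator score is the $K$ model's *cross-validation* mean on the
  same folds (symmetric and less biased than comparing against the $K$
  model's training score; `comparator = "train"` switches).

The chosen $K$ is non-increasing in $\alpha$, which the tests assert.

### Mode detection and mode-anchored fitting (`detect_modes`, `fit_me_em`)

The second estimator first finds peaks directly: counts are normalized to
a per-10,000-events scale, smoothed by a width-71 running average
(truncated and renormalized at the edges), and differentiated twice by
centered finite differences of the same 71-channel span. A mode candidate
is a downward zero crossing of the first derivative. The acceptance
threshold of $-0.0002$ is applied, by default, to the second derivative at
the crossing: on the normalized scale genuine subpopulation peaks sit two
orders of magnitude below this threshold while sampling wiggles and very
broad, very small bumps sit two orders of magnitude above it, so the rule
is sharp. A combined first-times-second-derivative criterion is also
available (`criterion = "product"`, with the first derivative taken as its
maximum over the half-window preceding the crossing, i.e. the rising slope
"in the vicinity" of the peak); we do not use it as the default because at
a zero crossing the pointwise first derivative vanishes by construction,
which makes the pointwise product degenerate, and even the vicinity form
passes within a factor of ~1.3 of the threshold for legitimate broad
components (σ ≈ 80) — too close for a detector meant to be robust. The
per-10,000-events normalization makes the threshold sample-size free, and
mode counts are invariant to rescaling total counts. Channels within a
full window of either edge are never eligible.

`fit_me_em` then places one Gaussian per detected mode, pins the means,
and runs a *single* EM pass for weights and variances. Its likelihood can
never exceed the free 100-restart EM optimum at the same $K$ — asserted in
the tests — but it is much faster and more interpretable. When the
density has no detected mode the function refuses and directs the caller
to the restart fitter with $K = 1$.

### The conditional mixture model (`fit_cem`)

The third estimator makes the dose dependence explicit. At dose $g$ the
population is two Gaussians plus the uniform:

* means affine in dose, $\mu_{\text{low}}(g) = a_l + b_l g$ and
  $\mu_{\text{high}}(g) = a_h + b_h g$;
* dose-independent standard deviations $\sigma_l, \sigma_h$;
* low-component weight constant below a threshold dose and exponentially
  decaying above it,
  $$w_{\text{low}}(g) = \begin{cases} 0.98 & g \le g_0\\
    0.98\, e^{-r (g - g_0)} & g > g_0,\end{cases}$$
  with $w_{\text{high}}(g) = 0.98 - w_{\text{low}}(g)$.

The threshold-exponential weight encodes what the per-dose fits show: an
abrupt establishment of the high subpopulation near $g_0$ followed by a
gradual fade-out of the low one. It also prevents a known failure of
dose-independent weights, where the high component "captures" low cells at
low doses and drags its whole mean curve down until the two branches
cross; with this form the fitted mean curves stay separated over the
observed dose range (a tested invariant).

One EM run fits all eight parameters jointly across doses. The M-step
maximizes each block in turn: affine means by responsibility-weighted
least squares of channel on dose; variances by weighted mean squared
residual (floored at 1 channel²); and $(g_0, r)$ by maximizing the
responsibility-weighted weight log-likelihood on a 50×50 grid — linear in
$g_0$ over the observed dose range, log-spaced in $r$ up to $10^4$ per
%-gal plus $r=0$ — followed by golden-section refinement of each
coordinate, accepting only improving steps. Two numerical points deserve
note. First, the weight objective contains $\log(0.98 - w_{\text{low}})$,
which is $-\infty$ wherever $g \le g_0$ and any high-responsibility mass
exists; the search therefore clamps weights to
$[10^{-12}, 0.98 - 10^{-12}]$, while the *data* log-likelihood is always
finite, and an explicit guard reverts any $(g_0, r)$ step that lowers it,
so the EM ascent property holds (tested at $10^{-8}$ relative tolerance).
Second, the stated initialization (means 200 and 700 constant in dose,
standard deviations 50, mixture probabilities 0.49) conflicts with the
weight family, which cannot represent a flat 0.49: we honor both by
running the first E-step with flat 0.49 weights and fitting $(g_0, r)$
for the first time in the first M-step; the flat-weight iteration is
excluded from the ascent trace because its model lies outside the family.
The fit is deterministic, so a single run suffices.

## Assembling and evaluating bifurcation structure

`extract_structure` turns fits into the four-element summary per dose.
For conditional fits the low component formally exists at every dose with
exponentially vanishing size; it is reported only while its coefficient
exceeds 0.01, matching how the per-dose estimators simply stop finding it.

Two evaluations compare estimators and replicates:

* `train_test_nll` scores every model by mean negative log-likelihood per
  event on its own replicate (training) and on the other replicates of
  the same pregrowth arm (testing), conditional fits through their
  predicted snapshot mixtures; 95% intervals come from a seeded
  percentile bootstrap over conditions (1000 resamples by default). With
  replicate-level jitter in the generator, training scores beat testing
  scores essentially always, as expected.
* `variability_decomposition` takes landmark subpopulation locations in a
  method × replicate × landmark array and splits their spread into a
  biological part (SD across replicates of method-averaged locations) and
  a methodological part (SD across methods of replicate-averaged
  locations), both with the $n-1$ denominator. The four default
  landmarks are the low subpopulation at the lowest dose (P1), the low
  and high subpopulations at the 11th dose, where both robustly coexist
  under the default generator (P2, P3 — the intermediate dose index is
  configurable, since any choice inside the coexistence window is
  equally informative), and the high subpopulation at the highest dose
  (P4). On synthetic data with 10-channel replicate jitter the
  replicate component dominates the method component for every landmark,
  reproducing the qualitative conclusion that biological variability
  exceeds method disagreement.

## The synthetic-data generator

`generate_dataset` emulates the acquisition: for each of 17 galactose
concentrations (0 to 0.08 % w/v, densest around the switching threshold),
4 replicates and two pregrowth arms, it draws 60,000 events per condition
from the ground-truth conditional mixture (low/high Gaussian or uniform
outlier, probabilities $(w_{\text{low}}(g),\,0.98-w_{\text{low}}(g),\,
0.02)$), thins events with probability 0.5 independently of fluorescence
(the scatter gate), rounds to integer channels and clips to the rails.
The ground-truth parameters are package choices shaped to produce
realistic trajectories: $a_l = 150$, $b_l = 500$, $a_h = 550$,
$b_h = 4000$ channels per %-gal, $\sigma_l = 40 < \sigma_h = 80$ (the
high state is visibly noisier in real data), $g_0 = 0.003$ %-gal —
matching where the high subpopulation is established in the real network
— and $r = 150$ per %-gal. Replicate identity enters as a Gaussian shift
(SD 10 channels) added to both mean intercepts, and the raffinose
(uninduced-start) arm multiplies $g_0$ by 1.5, emulating the transition
occurring over a slightly higher dose range; no hysteresis dynamics are
simulated. Everything is reproducible from one integer seed.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: autofluorescence structure and non-Gaussian
tails in log-channel space, dose-response curvature beyond affine means,
dose-dependent subpopulation variances, growth-rate differences between
states (a real confounder of the fading low subpopulation),
value-dependent gating, and inter-channel correlations of the instrument.

## The deterministic companion model

For didactic comparison, `steady_states` and `bifurcation_diagram`
analyze the canonical auto-activation ODE
$\dot P = \beta + v\,(sP)^n / (K^n + (sP)^n) - \gamma P$ by a dense
sign-scan plus bisection, classifying stability from the rate derivative
and refining fold points by bisection on the signal. The default
parameters ($\beta = 0.1$, $v = 10$, $K = 1$, $n = 2$, $\gamma = 1$) are
bistable for $s$ roughly in $[0.2, 0.5]$; a basal rate that is not small
relative to $v$ removes the fold entirely and the response becomes
graded. This module reproduces the S-shaped diagram qualitatively; it is
not calibrated to the galactose data.

## Problem sizes and runtimes

The test suite exercises the full acquisition design where it matters:
conditional-mixture recovery runs on a complete replicate (17 doses ×
60,000 events), and the cross-replicate evaluations run the gal-pregrowth
arm (the raffinose arm is statistically identical up to the threshold
scale). Monte-Carlo rates (selection accuracy, train-versus-test,
variability dominance) use 10–50 seeded repetitions with reduced restart
counts (5–10), which the selection rule tolerates well because each fold
fit is itself a multi-restart maximum. A full default `run_pipeline`
(cross-validated EM at 100 restarts for all 136 conditions) is the
faithful replication setting and takes correspondingly long; the
configuration block lets any of these sizes be reduced.

## Known limitations

* Bin-center likelihood (see above); immaterial at $\sigma \gg 1$ channel.
* The affine high-branch mean is a deliberate simplification; on real
  data it overestimates the high location at small doses and
  underestimates it at large ones. Alternative link functions are out of
  scope.
* The mode-detector threshold was recalibrated to the package's
  per-10,000-events normalization; thresholds tuned to raw instrument
  counts are not transferable.
* Dose units are % w/v galactose throughout; nothing constrains the dose
  to be a concentration, but the weight-curve parameterization assumes a
  single switching threshold.
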