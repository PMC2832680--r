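# stochbif

Estimating the **stochastic bifurcation structure** of a bistable genetic
switch from single-cell flow-cytometry histograms collected across a dose
gradient.

## The problem

A deterministic bistable switch is summarized by its bifurcation diagram:
steady states versus a control parameter, with saddle-node (fold) points
bounding the bistable range. Real gene networks are noisy; a population of
genetically identical cells at one dose shows a *distribution* of
expression, which in the bistable regime is bimodal. The stochastic
analogue of the bifurcation diagram specifies, as a function of the dose
$g$: (1) the number of distinguishable subpopulations, (2) their
locations, (3) the variability within each, and (4) the fraction of cells
in each. The motivating system is the galactose-utilization network of
*Saccharomyces cerevisiae*, assayed by a fluorescent reporter in 1024
logarithmic channels over 17 galactose concentrations, two pregrowth
histories, and four biological replicates.

## What the package does

Every per-dose model is a mixture of $K$ Gaussians (in log-intensity
channel space) plus a uniform outlier component with fixed weight 0.02:

$$p(c) = \tfrac{0.02}{1024} + \sum_{i=1}^{K} w_i \,\mathcal N(c; \mu_i, \sigma_i^2),
  \qquad \textstyle\sum_i w_i = 0.98 .$$

Three estimators recover the structure:

* **EM** — `fit_em_restarts()`: maximum-likelihood mixture fit per dose,
  100 random restarts, with `select_num_components()` choosing $K$ by a
  10-fold cross-validation rule (accept $K+1$ only if its held-out mean
  log-likelihood beats $K$'s by more than $\alpha$ fold-SDs).
* **ME+EM** — `detect_modes()` + `fit_me_em()`: smoothed-derivative peak
  detection (width-71 running average, centered differences, threshold
  −0.0002 on the per-10,000-events scale) pins one Gaussian mean per
  density mode; a single EM pass fits weights and variances.
* **CEM** — `fit_cem()`: a conditional mixture across all doses jointly —
  affine component means $\mu(g) = a + b\,g$, dose-independent variances,
  and a low-component weight equal to 0.98 up to a threshold dose $g_0$
  and decaying as $0.98\,e^{-r(g-g_0)}$ above it.

`extract_structure()` assembles the four-element summary,
`train_test_nll()` scores models across replicates, and
`variability_decomposition()` separates replicate-to-replicate from
method-to-method variability in landmark subpopulation locations.
`generate_dataset()` emulates the full acquisition (60,000 events per
condition, ~50% scatter gate, 2% uniform outliers, replicate jitter) from
a ground-truth conditional mixture, and `steady_states()` /
`bifurcation_diagram()` provide the deterministic auto-activator
companion model. See the methods vignette
(`vignettes/stochastic-bifurcation.Rmd`) for the full model account.

## Worked example

Simulate one replicate of the dose gradient, fit all three estimators at
an intermediate dose, and read off the structure:

```r
library(stochbif)
spec <- synthetic_spec(n_replicates = 1, pregrowths = "gal",
                       replicate_jitter_sd = 0, seed = 17)
ds <- generate_dataset(spec)
h  <- ds$histograms[["gal:1:0.0087"]]

select_num_components(h, restarts = 10, seed = 1)
#> cross-validated component selection: chose K = 2 (alpha = 1)
#>  K mean_heldout_ll sd_across_folds
#>  1        -6.95039         0.36622
#>  2        -6.23453         0.01530
#>  3        -6.23464         0.01526

fit_em_restarts(h, 2, n_restarts = 100, seed = 1)
#> EM mixture fit: 2 Gaussian components
#>   loglik -186849.2454, mean NLL 6.234335 nats/event, 21 iterations (converged)
#> Gaussian+uniform mixture: 2 components, uniform weight 0.02
#>    mean    sd weight
#>  154.03 39.92 0.4117
#>  584.81 80.29 0.5683

detect_modes(h)
#> mode detection (window 71, theta -0.0002): 2 modes at channel(s) 153, 589

fit_cem(ds$histograms)
#> conditional mixture fit (CEM): 17 doses, 7 iterations (converged)
#>   loglik -2988365.5107, mean NLL 5.863978 nats/event
#> conditional mixture model (two Gaussians + uniform outlier)
#>   low  mean: 149.8 + 488.9 g   sd 40.07
#>   high mean: 550.1 + 3984 g   sd 79.69
#>   low weight: 0.98 below g0 = 0.003174, decaying at r = 156.2
```

At 0.0087% galactose the population splits into a low subpopulation near
channel 154 (42% of cells) and a high one near channel 585 (58%), with
the high state noticeably noisier — and the conditional fit places the
switching threshold at $g_0 \approx 0.0032$% galactose. The generating
truth was $a_l = 150$, $b_h = 4000$, $\sigma_l = 40$, $\sigma_h = 80$,
$g_0 = 0.003$, $r = 150$: all recovered to within a few percent. The
bifurcation-structure table for any set of doses comes from
`extract_structure(fit_cem(ds$histograms))`.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/stochbif.R` (subcommands `simulate`, `fit-em`, `fit-me-em`,
`fit-cem`, `report`, `ode-diagram`), and `run_pipeline()` drives the whole
simulate–fit–report chain from a YAML configuration.

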