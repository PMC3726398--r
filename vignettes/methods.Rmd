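---
title: "Network inference by Bayesian variable selection over MRA equations"
author: "bvsamra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network inference by Bayesian variable selection over MRA equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bvsamra)
```

## The model

Modular Response Analysis treats a biochemical network as $n$ communicating
modules and relates the measured *global* responses to perturbations to the
*local* (direct) inter-module sensitivities. The global response of node
$i$ to perturbation $k$ is the fractional steady-state change
$R_{ik} = 2(x_i^k - x_i^0)/(x_i^k + x_i^0)$, computed by
`global_response()` / `response_matrix()` against an explicit baseline
column. The local response coefficients $r_{ij}$ obey, for every
perturbation $k$ that does not directly target node $i$,
$\sum_{j\ne i} r_{ij} R_{jk} = R_{ik}$.

Rather than estimating the $r_{ij}$ (which needs a full-rank perturbation
set), the package infers edge *presence*. With binary indicators $A_{ij}$
and a Gaussian error $\epsilon_{ik} \sim N(0, \sigma^2)$ absorbing noise,
each node defines an independent variable-selection problem over its
$n-1$ candidate regulators, using only the $n_{p_i}$ admissible
perturbations (those not targeting the node). Priors:

* $A_{ij} \mid \theta \sim \mathrm{Bernoulli}(\theta)$,
  $\theta \sim \mathrm{Beta}(a, b)$ with $a = 1 < b = 2$: integrating
  $\theta$ gives the proper configuration prior
  $B(a + n_{k_i},\, b + n - 1 - n_{k_i})/B(a, b)$, which penalizes dense
  configurations (`log_prior_config()`).
* Selected coefficients $\rho_i \mid \sigma^2 \sim
  N\!\big(0,\; c\,\sigma^2 (R_{pr} R_{pr}^T + \lambda I)^{-1}\big)$: a
  g-prior slab whose ridge $\lambda = 0.1$ keeps the covariance positive
  definite even with fewer perturbations than selected regulators
  (`prior_precision_kernel()`). The scale $c$ defaults to $n_{p_i}$
  (unit-information prior) and is overridable.
* $\sigma^2 \sim \mathrm{InvGamma}(\alpha = 1, \beta = 1)$, a flat,
  weakly informative choice.

All three are conjugate, so the marginal posterior of a configuration has
the closed form (up to a constant shared by all configurations of one
subnetwork)

$$\log p(\mathbf A_i \mid \mathbf R) =
  \log \pi(n_{k_i})
  - \tfrac12\Big[\,n_{k_i}\log c + \log\lvert K^{-1} + G\rvert
  - \log\lvert G + \lambda I\rvert\Big]
  - \big(\alpha + \tfrac{n_{p_i}}{2}\big)\log b_1,$$

with $G$ the Gram matrix of the selected regulator rows,
$K^{-1} = (G + \lambda I)/c$, and the residual term
$b_1 = \beta + \tfrac12\big(R_i R_i^T - R_i R_{pr}^T (K^{-1} +
G)^{-1} R_{pr} R_i^T\big)$. Closed forms like this are easy to
mistranscribe, so the package treats the derivation itself as the
contract: the test suite checks posterior odds from this expression
against direct numeric integration of the likelihood over
$(\rho, \sigma^2)$ (nested quadrature) to well under 0.5% relative error.

Everything is computed in log space via Cholesky factorizations; $b_1$
exponents would overflow in linear space. The ridge guarantees positive
definiteness, so no fallback jitter is used — a genuinely singular inner
matrix raises an error rather than being papered over.

## Posterior exploration

For each node, either all $2^{n-1}$ configurations are enumerated and
normalized by log-sum-exp (`exhaustive_posterior()`, capped at 20
candidates), or five parallel Gibbs chains sweep the indicators
componentwise (`run_chain()`, compiled). Each update sets bit $j$ to 1
with probability $1/(1 + e^{\log p_0 - \log p_1})$. One sample is
recorded per full sweep; sweeps visit candidates in fixed ascending order
(the sampling literature's "consecutive" scan — a fixed order makes runs
reproducible). Chains start from independent Bernoulli(0.5)
configurations, so the cross-chain log-score overlap
(`convergence_report()`) is a meaningful, though advisory, diagnostic; no
automatic chain extension is attempted. Posterior edge probabilities
average the indicators over all chains after discarding a 20% burn-in.

Sweep counts follow the data regime: 200 sweeps suffice for clean
simulated responses, 500 for noisy data, 2000 for real datasets. These
are defaults in `bvsa_chains()`, not magic numbers — the acceptance tests
verify that 5 chains x 2000 sweeps track exhaustive marginals within 0.05
per entry on problems up to 6 nodes.

Edges are called from the probability matrix by `threshold_edges()`:
`"mean"` (threshold at the average off-diagonal probability — under
collinear data posterior probabilities deflate below 0.5, and the mean
tracks that), `"mpm"` (Median Probability Model, 0.5), or `"fixed"`. Ties
at the threshold are called present.

## Baselines

`mra_tlsr()` solves the orthogonality relations per node by total least
squares (smallest right singular vector of the stacked system), requiring
rank $n-1$ — the restriction the Bayesian treatment removes.
`stochastic_mra()` wraps it in a Monte-Carlo loop over Gaussian response
realizations with symmetric 0.5%-per-tail outlier trimming, a
variance-based unidentifiability flag, Z-tests of the coefficient means
against zero, and Benjamini–Hochberg correction. Two defaults here are
package choices, not canonical constants: the unidentifiability cutoff
(25x the median post-trim variance; scale-free, overridable) and the
desk-scale realization count (10,000; raise it for production use).

## The simulator

`bvsa_model()` equips a signed digraph with saturating kinetics:
$\dot x_i = T_i\,(b_i + \sum_j a_{ij}\, x_j/(K_{ij}+x_j))\,
\prod_j KI_{ij}/(KI_{ij}+x_j) - d_i x_i$, where $T_i$ is the protein
expression level. A knockdown at efficiency $e$ scales $T_i$ to $1-e$ of
baseline — expression, not activity, is what RNAi reduces — so an
isolated constitutive node lands at exactly $(1-e)$ of its baseline, and
$e = 1$ is a knockout. `simulate_knockdowns()` runs the standard design:
every listed node at efficiencies {0.4, 0.6, 0.8}, plus the untouched
baseline column (6 nodes x 3 efficiencies = 18 perturbations + baseline
for the MAPK fixture).

`mapk_network()` is a six-module surrogate of the EGF-driven MAPK
cascade: receptor -> adapter -> initiator -> MAP3K -> MAP2K -> MAPK, with
three negative feedbacks from the terminal kinase (onto the adapter,
MAP3K, and MAP2K). It does not reproduce a detailed mass-action model of
the pathway; the surrogate implements the canonical module topology with
the kinetics above. Its parameters (activation
strength 12, $K = 5$, basal 0.01, $KI = 0.5$, unit decay) are chosen so
each cascade stage transmits perturbations at close to unit log-gain
(local response coefficients 0.8–0.9 forward, about −0.7 for the
feedbacks), as ultrasensitive kinase cascades do. This choice matters: a
weakly coupled parameterization lets knockdown responses decay
geometrically down the cascade, so downstream responses drown in any
realistic measurement noise and the fixture stops posing the inference
problem the cascade actually poses. Results on this fixture speak to the
inference machinery under these surrogate kinetics, nothing more.

Two noise sources mirror real perturbation data:

* **Intrinsic noise**: multiplicative SDE noise
  $dx = f(x)\,dt + \eta\, x\, dW$ integrated with the Milstein update;
  the stochastic steady state is the post-transient time average
  (`milstein_steady_state()`, horizon 30, dt 0.01, second half averaged).
  The Itô reading is the default; a Stratonovich-equivalent
  (drift-corrected) form sits behind the `interpretation` flag, since
  either convention is defensible for phenomenological noise. The
  intensity for the noisy studies is fixed at $\eta = 0.05$ — a modest
  intracellular fluctuation level.
* **Measurement error**: the log-linear model of high-throughput assays,
  $\sigma_e^2 = \alpha_b + \beta_s e^{-Y}$ with $Y$ the log-intensity
  (`add_measurement_error()`), with $\alpha_b < 0.1$, $\beta_s < 1$ the
  realistic proteomics range. This model presumes intensity-scale
  readouts; `simulate_knockdowns()` therefore reports measurements at
  `signal_scale = 1000` intensity units per activity unit, placing
  baseline signals in the 1e2–1e3 range where that parameter regime
  applies. Response coefficients are ratios and do not see the scale.

What the simulator does *not* emulate: cell-to-cell variability,
time-course dynamics, transcriptional feedback on expression levels, or
realistic mass-action detail. Passing tests on these fixtures demonstrate
correctness of the inference machinery under the modeled noise structure,
not performance on any particular experimental platform.

## Evaluation

`evaluate_network()` sweeps the calling threshold (0 to 1 in 0.01 steps
for probabilities; every unique absolute value plus sentinels for
coefficient matrices) and integrates ROC and PR curves by the trapezoidal
rule. With the unique-value grid the swept AUROC equals the midrank
Mann–Whitney statistic exactly, ties contributing 1/2 — the suite asserts
this to 1e-9. Precision at zero predictions is defined as 1 (standard
PR closure). Self-edges are excluded everywhere, since the model does not
define them. `summarize_runs()` reports the mean and standard deviation
of AUROC/AUPR over repeated runs.

## Numerical and design notes

* **Standardization** divides each response row by its *population*
  standard deviation before inference; the convention is recorded in run
  metadata. Sample-vs-population is immaterial to the configuration
  ranking (a common rescaling after standardization preserves it — tested),
  but a fixed convention keeps runs byte-reproducible. Standardization is
  applied to the full matrix before the per-node column exclusion.
* **Degenerate inputs**: constant response rows (uninformative nodes),
  nodes targeted by every perturbation ($n_{p_i} = 0$), and non-positive
  baselines are errors naming the offending node, never silent fixes.
* **Determinism**: all stochastic stages draw from R's RNG — a single
  `set.seed()` (or the `seed` arguments) reproduces chains, simulations,
  and the full pipeline bit-for-bit.
* **Scale of the shipped studies**: the acceptance script runs 100
  repeated fits on the clean MAPK dataset, 50 noisy replicates per
  error-grid corner, and 50 incomplete-design replicates — sizes at which
  the Monte-Carlo error of the summary statistics is comfortably below
  the effects being measured, while a full run stays in the minutes
  range on a single core.
* **Known limitations**: the method infers binary topology only (no
  signs or strengths — the stochastic MRA baseline reports signs);
  strongly collinear responses deflate posterior probabilities, which the
  mean-probability threshold partially compensates; and the enumeration
  engine is exponential in the candidate count, hence the cap.
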