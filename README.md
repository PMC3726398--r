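# bvsamra

Bayesian variable selection for Modular Response Analysis: inferring the
directed topology of a biochemical network from steady-state responses to
perturbation experiments.

## The problem

Modular Response Analysis (MRA) relates the *global* steady-state response
of a network to the *local* (direct) interactions between its modules.
After perturbing a parameter $p_k$, the global response coefficient of
node $i$ is

$$R_{ik} \approx 2\,\frac{x_i^k - x_i^0}{x_i^k + x_i^0},$$

where $x_i^0$ and $x_i^k$ are the node's steady-state activities before
and after the perturbation. The local response (connection) coefficients
$r_{ij}$ satisfy the orthogonality relations

$$\sum_{j \ne i} r_{ij} R_{jk} = R_{ik}, \qquad i \ne k,$$

over the perturbations that do not directly target node $i$. Solving these
relations directly (e.g. by total least squares) needs a full-rank
perturbation set and is fragile under noise. This package instead infers
only the *presence* of each edge: binary indicators $A_{ij}$ are
introduced,

$$\sum_{j \ne i} A_{ij}\, r_{ij} R_{jk} + \epsilon_{ik} = R_{ik},$$

and the coefficients $r_{ij}$, noise variance $\sigma^2$, and network
sparsity are integrated out analytically under spike-and-slab priors (a
ridge-stabilized g-prior slab, an inverse-gamma variance prior, and a
Beta–Bernoulli edge prior). The resulting marginal posterior over edge
configurations is explored per node by componentwise Gibbs sampling (or
exhaustively enumerated for small networks), yielding a posterior edge
probability matrix $P$ with $P_{ij} = P(A_{ij}=1 \mid \mathbf R)$; edges
are called by thresholding (mean-probability scheme, Median Probability
Model, or a fixed cutoff). This works for *any* number of perturbations —
including fewer perturbations than nodes, where classical MRA fails.

The package also provides the deterministic TLSR and Monte-Carlo
stochastic MRA baselines, a kinetic perturbation simulator (knockdowns,
intrinsic SDE noise via Milstein integration, log-linear measurement
error), and ROC/PR evaluation utilities.

## Worked example

```r
library(bvsamra)

model <- mapk_network()                 # 6-module MAPK cascade, 8 edges
sim <- simulate_knockdowns(model, seed = 1)   # 18 knockdowns + baseline
R <- response_matrix(sim$states, "baseline", sim$design)

fit <- bvsa(R, sim$design, settings = bvsa_chains(n_sweeps = 200), seed = 2)
round(coef(fit), 2)
#>           receptor adapter initiator map3k map2k mapk
#> receptor        NA    0.06      0.07  0.06  0.05 0.05
#> adapter       1.00      NA      0.18  0.20  0.20 0.98
#> initiator     0.14    1.00        NA  0.13  0.12 0.12
#> map3k         0.20    0.18      1.00    NA  0.19 0.90
#> map2k         0.18    0.18      0.17  1.00    NA 0.92
#> mapk          0.14    0.12      0.13  0.12  1.00   NA

summary(fit)   # calls the 8 true edges at the mean threshold (p_th = 0.36)
evaluate_network(coef(fit), sim$truth)
#> Network evaluation: AUROC = 1.0000, AUPR = 1.0000 (102 thresholds)
```

`coef(fit)[i, j]` is the posterior probability that node `j` directly
influences node `i`: the cascade edges and all three negative feedbacks
from `mapk` carry probabilities near 1, everything else sits near the
prior. On this noise-free dataset the ranking separates true from absent
edges perfectly (AUROC = AUPR = 1).

A command-line wrapper with `simulate`, `infer`, `baseline`, and
`evaluate` subcommands is provided in `inst/cli/bvsa`.

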