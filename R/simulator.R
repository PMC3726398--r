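#' Kinetic network model for perturbation simulation
#'
#' A signed directed network equipped with saturating (Michaelis-Menten
#' type) activation/inhibition kinetics. The activity `x_i` of node `i`
#' evolves as
#'
#' \deqn{dx_i/dt = T_i \left(b_i + \sum_{j: +} a_{ij}
#'   \frac{x_j}{K_{ij}+x_j}\right) \prod_{j: -}
#'   \frac{KI_{ij}}{KI_{ij}+x_j} - d_i x_i}
#'
#' where `T_i` is the expression level (production capacity) of the node's
#' protein — the quantity scaled down by a knockdown — `b_i` a basal
#' activation rate, and the sums/products run over the node's activating
#' (+1) and inhibiting (-1) regulators.
#'
#' @param adjacency Signed n x n adjacency: `adjacency[i, j]` is +1 / -1 /
#'   0 for `j` activating / inhibiting / not directly affecting `i`;
#'   zero diagonal. Needs row/column names.
#' @param basal Basal activation rate per node.
#' @param strength Activation strength matrix `a` (used where
#'   `adjacency == 1`).
#' @param K Activation saturation constant matrix.
#' @param KI Inhibition constant matrix (used where `adjacency == -1`).
#' @param decay First-order decay rate per node.
#' @param total Expression level per node at baseline. Default 1.
#' @return An object of class `"bvsa_model"`.
#' @export
bvsa_model <- function(adjacency, basal, strength = 1, K = 0.3, KI = 0.5,
                       decay = 1, total = 1) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (is.null(rownames(adjacency)))
    dimnames(adjacency) <- list(paste0("n", 1:n), paste0("n", 1:n))
  if (any(diag(adjacency) != 0)) stop("self-edges are not modeled")
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, n, n)
  nodes <- rownames(adjacency)
  structure(list(adjacency = adjacency, nodes = nodes,
                 basal = rep_len(basal, n),
                 strength = as_mat(strength), K = as_mat(K),
                 KI = as_mat(KI),
                 decay = rep_len(decay, n),
                 total = rep_len(total, n)),
            class = "bvsa_model")
}

#' @export
print.bvsa_model <- function(x, ...) {
  cat(sprintf("Kinetic network model: %d nodes, %d edges (%d inhibitory)\n",
              length(x$nodes), sum(x$adjacency != 0),
              sum(x$adjacency == -1)))
  invisible(x)
}

# time derivative of node activities; total overrides model$total (knockdowns)
model_rates <- function(model, x, total = model$total) {
  n <- length(x)
  xr <- matrix(x, n, n, byrow = TRUE)
  act <- model$adjacency == 1
  inh <- model$adjacency == -1
  drive <- model$basal +
    rowSums(act * model$strength * xr / (model$K + xr))
  inhf <- exp(rowSums(log(ifelse(inh, model$KI / (model$KI + xr), 1))))
  total * drive * inhf - model$decay * x
}

#' Deterministic steady state of a kinetic model
#'
#' Integrates the model ODEs until the relative rates fall below `tol`
#' (`max |dx/dt| / max(|x|, eps)` over nodes), extending the horizon as
#' needed.
#'
#' @param model A [bvsa_model()].
#' @param total Optional expression-level vector overriding the baseline
#'   (used to impose knockdowns).
#' @param init Initial activities. Default: basal production balance.
#' @param tol Steady-state criterion on relative rates. Default 1e-9.
#' @param max_time Abort if not converged by this time. Default 1e4.
#' @return Named vector of steady-state activities (non-negative).
#' @export
ode_steady_state <- function(model, total = model$total, init = NULL,
                             tol = 1e-9, max_time = 1e4) {
  n <- length(model$nodes)
  if (is.null(init)) init <- pmax(total * model$basal / model$decay, 1e-3)
  deriv <- function(t, x, p) list(model_rates(model, pmax(x, 0), total))
  t_end <- 50
  x <- init
  repeat {
    sol <- deSolve::lsoda(y = x, times = c(0, t_end), func = deriv,
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    x <- pmax(sol[nrow(sol), -1], 0)
    rel <- max(abs(model_rates(model, x, total)) / pmax(abs(x), 1e-8))
    if (rel < tol) break
    t_end <- t_end * 2
    if (t_end > max_time)
      stop("failed to reach a steady state (relative rate ",
           format(rel), ")")
  }
  setNames(as.numeric(x), model$nodes)
}

#' Stochastic steady state by Milstein integration
#'
#' Integrates the model as a stochastic differential equation with
#' multiplicative intrinsic noise of intensity `sde_scale` on each node
#' (`dx = f(x) dt + sde_scale * x dW`), using the Milstein update, and
#' returns the time average over the post-transient window as the
#' stochastic steady state. The Ito interpretation is the default; the
#' Stratonovich reading is available via `interpretation`.
#'
#' @param model A [bvsa_model()].
#' @param sde_scale Noise intensity; 0 reduces to the deterministic path.
#' @param total Optional expression-level override (knockdowns).
#' @param horizon Integration time. Default 30 (about 30 relaxation
#'   times at unit decay).
#' @param dt Time step. Default 0.01.
#' @param init Initial state. Default: the deterministic steady state.
#' @param burn_frac Fraction of the trajectory discarded before
#'   averaging. Default 0.5.
#' @param interpretation `"ito"` (default) or `"stratonovich"`.
#' @return Named vector: time-averaged activities.
#' @export
milstein_steady_state <- function(model, sde_scale, total = model$total,
                                  horizon = 30, dt = 0.01, init = NULL,
                                  burn_frac = 0.5,
                                  interpretation = c("ito",
                                                     "stratonovich")) {
  interpretation <- match.arg(interpretation)
  if (dt <= 0) stop("dt must be positive")
  if (is.null(init)) init <- ode_steady_state(model, total)
  if (sde_scale == 0) return(setNames(as.numeric(init), model$nodes))
  steps <- ceiling(horizon / dt)
  burn <- floor(burn_frac * steps)
  n <- length(init)
  x <- as.numeric(init)
  acc <- numeric(n)
  kept <- 0
  s2 <- sde_scale^2
  sqdt <- sqrt(dt)
  for (t in seq_len(steps)) {
    dw <- rnorm(n, 0, sqdt)
    f <- model_rates(model, x, total)
    milstein <- if (interpretation == "ito")
      0.5 * s2 * x * (dw^2 - dt) else 0.5 * s2 * x * dw^2
    x <- pmax(x + f * dt + sde_scale * x * dw + milstein, 0)
    if (any(!is.finite(x)) || max(x) > 1e6)
      stop("stochastic trajectory diverged")
    if (t > burn) { acc <- acc + x; kept <- kept + 1 }
  }
  setNames(acc / kept, model$nodes)
}

#' Noise specification for simulated measurements
#'
#' @param alpha_b Background (signal-independent) measurement-error
#'   variance on the log scale. Default 0.
#' @param beta_s Signal-dependent measurement-error coefficient.
#'   Default 0.
#' @param sde_scale Intrinsic (SDE) noise intensity; 0 disables
#'   stochastic simulation. Default 0.
#' @return An object of class `"bvsa_noise"`.
#' @export
noise_spec <- function(alpha_b = 0, beta_s = 0, sde_scale = 0) {
  stopifnot(alpha_b >= 0, beta_s >= 0, sde_scale >= 0)
  structure(list(alpha_b = alpha_b, beta_s = beta_s,
                 sde_scale = sde_scale), class = "bvsa_noise")
}

#' Add log-linear measurement error
#'
#' Corrupts positive measurements with the standard log-linear error model
#' of high-throughput assays: for a value with log-intensity `Y`, zero-mean
#' Gaussian noise of variance `sigma_e^2 = alpha_b + beta_s * exp(-Y)` is
#' added in log space and the result exponentiated back. High-intensity
#' signals approach the background noise floor `alpha_b`; weak signals are
#' dominated by the signal-dependent term.
#'
#' @param values Positive measurements.
#' @param alpha_b Background variance (log scale).
#' @param beta_s Signal-dependent noise coefficient.
#' @return Noisy values, same shape as `values`.
#' @export
add_measurement_error <- function(values, alpha_b, beta_s) {
  if (any(values <= 0)) stop("measurement-error model needs positive values")
  y <- log(values)
  s <- sqrt(alpha_b + beta_s * exp(-y))
  out <- exp(y + rnorm(length(values), 0, s))
  attributes(out) <- attributes(values)
  out
}

#' Simulate knockdown perturbation responses
#'
#' Reproduces the standard perturbation protocol: each listed node is
#' knocked down at each listed efficiency by scaling its expression level
#' to `1 - efficiency` of baseline (efficiency 1 is a knockout), the
#' system is re-solved to steady state (deterministically, or by Milstein
#' SDE time-averaging when `noise$sde_scale > 0`), and log-linear
#' measurement error is applied. The returned table contains the
#' unperturbed baseline column plus one column per (node, efficiency)
#' pair, with a matching design table.
#'
#' Measurements are reported in assay-intensity units: model activities
#' are multiplied by `signal_scale` before the error model is applied.
#' Global response coefficients are ratios and do not depend on this
#' scale, but the signal-dependent error term `beta_s * exp(-Y)` does —
#' the log-linear error model with `alpha_b < 0.1`, `beta_s < 1`
#' describes intensity readouts in the 1e2-1e4 range, so the default
#' places baseline signals there.
#'
#' @param model A [bvsa_model()].
#' @param efficiencies Knockdown efficiencies in (0, 1].
#'   Default `c(0.4, 0.6, 0.8)`, the three-replicate knockdown protocol.
#' @param targets Nodes to perturb. Default: all.
#' @param noise A [noise_spec()].
#' @param signal_scale Intensity units per model activity unit.
#'   Default 1000.
#' @param seed Optional integer seed.
#' @return List with `states` (node x experiment matrix including the
#'   `"baseline"` column), `design` (a [bvsa_design()]), and `truth`
#'   (the model's signed adjacency).
#' @export
simulate_knockdowns <- function(model, efficiencies = c(0.4, 0.6, 0.8),
                                targets = model$nodes,
                                noise = noise_spec(), signal_scale = 1000,
                                seed = NULL) {
  if (any(efficiencies <= 0 | efficiencies > 1))
    stop("efficiencies must lie in (0, 1]")
  if (!all(targets %in% model$nodes)) stop("unknown perturbation target")
  if (!is.null(seed)) set.seed(seed)

  solve_state <- function(total) {
    if (noise$sde_scale > 0)
      milstein_steady_state(model, noise$sde_scale, total)
    else ode_steady_state(model, total)
  }

  cols <- list(baseline = solve_state(model$total))
  exp_id <- character(0); exp_target <- character(0); exp_eff <- numeric(0)
  for (tg in targets) {
    for (e in efficiencies) {
      id <- sprintf("%s_kd%02d", tg, round(100 * e))
      total <- model$total
      total[match(tg, model$nodes)] <- model$total[match(tg, model$nodes)] *
        (1 - e)
      cols[[id]] <- tryCatch(solve_state(total), error = function(err)
        stop("perturbation '", id, "': ", conditionMessage(err)))
      exp_id <- c(exp_id, id); exp_target <- c(exp_target, tg)
      exp_eff <- c(exp_eff, e)
    }
  }
  states <- do.call(cbind, cols) * signal_scale
  rownames(states) <- model$nodes
  if (noise$alpha_b > 0 || noise$beta_s > 0) {
    pos <- states > 0
    states[pos] <- add_measurement_error(states[pos], noise$alpha_b,
                                         noise$beta_s)
  }
  list(states = states,
       design = bvsa_design(exp_id, exp_target, exp_eff),
       truth = model$adjacency)
}

#' The six-module MAPK cascade fixture
#'
#' A six-node kinetic model of the EGF-driven MAPK signaling cascade at
#' module resolution: receptor -> adapter -> initiator -> MAP3K -> MAP2K
#' -> MAPK (five activating edges), with three inhibitory feedbacks from
#' the terminal kinase — MAPK inhibits the adapter (ERK-mediated SOS
#' inactivation), MAP3K activation (ERK-mediated inhibition of Raf), and
#' MAP2K (ERK-driven activation of MEK phosphatases). The kinetics are a
#' surrogate parameterization of this topology using saturating
#' activation/inhibition terms; it stands in for a full mass-action
#' pathway model. Parameters are chosen so that each cascade stage
#' transmits perturbations with close to unit log-gain (local response
#' coefficients around 0.8-0.9 forward, about -0.7 for the feedbacks), as
#' kinase cascades built from covalent-modification cycles do; a
#' weak-coupling parameterization would let knockdown responses die out
#' after two stages and would not pose the intended inference problem.
#'
#' @return A [bvsa_model()] with 8 edges (3 inhibitory) and a stable
#'   positive baseline steady state.
#' @examples
#' m <- mapk_network()
#' sum(m$adjacency != 0)   # 8
#' @export
mapk_network <- function() {
  nodes <- c("receptor", "adapter", "initiator", "map3k", "map2k", "mapk")
  A <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  A["adapter", "receptor"] <- 1
  A["initiator", "adapter"] <- 1
  A["map3k", "initiator"] <- 1
  A["map2k", "map3k"] <- 1
  A["mapk", "map2k"] <- 1
  A["adapter", "mapk"] <- -1   # ERK -| SOS
  A["map3k", "mapk"] <- -1     # ERK -| Raf activation
  A["map2k", "mapk"] <- -1     # ERK -> MEK phosphatases
  basal <- c(1, rep(0.01, 5))  # receptor constitutively driven by ligand
  bvsa_model(A, basal = basal, strength = 12, K = 5, KI = 0.5)
}

#' Generate a random sparse signed network model
#'
#' Draws a directed signed adjacency with the requested edge density
#' (independent Bernoulli off-diagonal entries; about 25% of edges
#' inhibitory), then rejection-samples kinetic parameterizations until the
#' baseline steady state is positive and locally stable (all Jacobian
#' eigenvalues with negative real part).
#'
#' @param n Number of nodes (>= 2).
#' @param density Edge density in (0, 1).
#' @param seed Optional integer seed.
#' @param max_tries Parameterization retry budget. Default 50.
#' @return A [bvsa_model()].
#' @export
random_network <- function(n, density, seed = NULL, max_tries = 50) {
  if (n < 2) stop("need at least two nodes")
  if (density <= 0 || density >= 1) stop("density must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("n", seq_len(n))
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  off <- which(!diag(n))
  edges <- off[runif(length(off)) < density]
  A[edges] <- ifelse(runif(length(edges)) < 0.25, -1, 1)

  for (try in seq_len(max_tries)) {
    model <- bvsa_model(A,
                        basal = runif(n, 0.3, 0.7),
                        strength = matrix(runif(n * n, 0.5, 1.5), n),
                        K = matrix(runif(n * n, 0.3, 1), n),
                        KI = matrix(runif(n * n, 0.3, 1), n))
    ok <- tryCatch({
      ss <- ode_steady_state(model)
      all(ss > 1e-6) && stable_at(model, ss)
    }, error = function(e) FALSE)
    if (ok) return(model)
  }
  stop("no stable parameterization found within the retry budget")
}

# local stability: finite-difference Jacobian eigenvalues at the steady state
stable_at <- function(model, ss, h = 1e-6) {
  n <- length(ss)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    up <- dn <- ss
    up[j] <- up[j] + h; dn[j] <- max(dn[j] - h, 0)
    J[, j] <- (model_rates(model, up) - model_rates(model, dn)) /
      (up[j] - dn[j])
  }
  all(Re(eigen(J, only.values = TRUE)$values) < 0)
}

#' Local response coefficients of a kinetic model
#'
#' Computes the model's true local (direct) response coefficients at its
#' baseline steady state from the finite-difference Jacobian of the rate
#' function: `r_ij = -(x_j J_ij) / (x_i J_ii)` for `j != i`, with the MRA
#' normalization `r_ii = -1`. Nonzero off-diagonal entries correspond
#' exactly to the model's direct edges.
#'
#' @param model A [bvsa_model()].
#' @return The n x n local response coefficient matrix.
#' @export
local_response_matrix <- function(model) {
  ss <- ode_steady_state(model)
  n <- length(ss)
  h <- 1e-6
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    up <- dn <- ss
    up[j] <- up[j] + h; dn[j] <- max(dn[j] - h, 0)
    J[, j] <- (model_rates(model, up) - model_rates(model, dn)) /
      (up[j] - dn[j])
  }
  r <- -(J * matrix(ss, n, n, byrow = TRUE)) / (diag(J) * ss)
  diag(r) <- -1
  dimnames(r) <- list(model$nodes, model$nodes)
  r
}
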