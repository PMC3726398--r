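# Shared fixtures and independent oracles, built in code at test time.

# A subnetwork problem with random Gaussian responses (no design needed:
# the scorer and samplers consume the subproblem structure directly).
random_subproblem <- function(n, n_pi) {
  nodes <- paste0("n", seq_len(n))
  R <- matrix(rnorm(n * n_pi), n, n_pi,
              dimnames = list(nodes, paste0("e", seq_len(n_pi))))
  structure(list(node = nodes[1], candidates = nodes[-1],
                 R_i = R[1, ], R_pr = R[-1, , drop = FALSE],
                 n_pi = n_pi, experiments = colnames(R)),
            class = "bvsa_subproblem")
}

# Forward-constructed MRA system: given a connection-coefficient matrix r
# (diagonal -1), returns a response matrix satisfying the orthogonality
# relations exactly, with one perturbation per node (R = r^{-1} D).
forward_mra_system <- function(r, strengths = NULL) {
  n <- nrow(r)
  nodes <- rownames(r)
  if (is.null(strengths)) strengths <- runif(n, 0.5, 1.5)
  D <- diag(strengths, n)
  R <- solve(r, D)
  dimnames(R) <- list(nodes, paste0("e", seq_len(n)))
  list(R = R, design = bvsa_design(colnames(R), nodes))
}

# A sparse random connection-coefficient matrix with diagonal -1.
random_r_matrix <- function(n, n_edges) {
  nodes <- paste0("n", seq_len(n))
  r <- matrix(0, n, n, dimnames = list(nodes, nodes))
  diag(r) <- -1
  off <- which(!diag(n))
  picks <- sample(off, n_edges)
  r[picks] <- runif(n_edges, 0.4, 1.2) * sample(c(-1, 1), n_edges, TRUE)
  r
}

# Independent numeric-integration oracle for the marginal likelihood of a
# configuration with <= 2 selected regulators: integrates the Normal
# likelihood against the Normal slab and inverse-gamma variance priors
# directly (nested stats::integrate; pracma::integral2 for the 2-D slab).
# Returns the marginal WITHOUT the Beta-Bernoulli prior factor and without
# the constants the closed form also drops ((2*pi)^(-m/2), IG normalizer).
quad_marginal <- function(prob, bits, hyper = bvsa_hyper()) {
  bits <- as.integer(bits)
  k <- sum(bits)
  stopifnot(k <= 2)
  y <- prob$R_i
  m <- prob$n_pi
  cc <- if (is.na(hyper$c)) m else hyper$c
  ig <- function(v) v^(-(hyper$alpha + 1)) * exp(-hyper$beta / v)
  if (k == 0) {
    f <- function(v) vapply(v, function(vv)
      exp(sum(dnorm(y, 0, sqrt(vv), log = TRUE))) * ig(vv), numeric(1))
    return(integrate(f, 0, Inf, rel.tol = 1e-10)$value)
  }
  X <- prob$R_pr[bits == 1, , drop = FALSE]
  G <- tcrossprod(X)
  V0 <- cc * solve(G + hyper$lambda * diag(k))   # slab covariance / sigma^2
  if (k == 1) {
    x <- drop(X)
    s0 <- sqrt(V0[1, 1])
    inner <- function(v) integrate(function(rho)
      vapply(rho, function(p)
        exp(sum(dnorm(y, p * x, sqrt(v), log = TRUE)) +
              dnorm(p, 0, s0 * sqrt(v), log = TRUE)), numeric(1)),
      -Inf, Inf, rel.tol = 1e-9)$value
    f <- function(v) vapply(v, function(vv) inner(vv) * ig(vv), numeric(1))
    return(integrate(f, 0, Inf, rel.tol = 1e-8)$value)
  }
  # k == 2: box wide enough for both the slab and the likelihood peak;
  # integrate the variance on the log scale for numerical stability
  V0i <- solve(V0)
  ols <- qr.solve(t(X), y)
  inner <- function(v) {
    w <- 8 * sqrt(max(diag(V0)) * v) + max(abs(ols)) + 1
    q <- tryCatch(pracma::integral2(function(p1, p2) {
      out <- p1
      for (i in seq_along(p1)) {
        rho <- c(p1[i], p2[i])
        q0 <- drop(rho %*% V0i %*% rho) / v
        out[i] <- exp(sum(dnorm(y, drop(rho %*% X), sqrt(v), log = TRUE)) -
                        0.5 * q0) /
          (2 * pi * v * sqrt(det(V0)))
      }
      out[!is.finite(out)] <- 0
      out
    }, -w, w, -w, w, reltol = 1e-8, vectorized = TRUE)$Q,
    # regions where the integrand underflows to zero contribute nothing
    error = function(e) 0)
    if (!is.finite(q)) 0 else q
  }
  f <- function(w) vapply(w, function(ww) {
    vv <- exp(ww)
    val <- inner(vv) * ig(vv) * vv
    if (is.finite(val)) val else 0
  }, numeric(1))
  integrate(f, -12, 10, rel.tol = 1e-6)$value
}

# Posterior odds of configuration `bits` against the empty configuration,
# by the quadrature oracle (prior factors included).
quad_odds <- function(prob, bits, hyper = bvsa_hyper()) {
  n <- length(prob$candidates) + 1
  m1 <- quad_marginal(prob, bits, hyper)
  m0 <- quad_marginal(prob, rep(0, n - 1), hyper)
  (m1 / m0) * exp(log_prior_config(sum(bits), n, hyper) -
                    log_prior_config(0, n, hyper))
}

# Midrank Mann-Whitney AUC on off-diagonal scores: the independent
# cross-check for the threshold-sweep AUROC.
rank_auc <- function(scores, truth) {
  off <- !diag(nrow(scores))
  s <- abs(scores[off])
  y <- truth[off] != 0
  r <- rank(s)
  (sum(r[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
}

# Total-variation distance between an empirical configuration frequency
# table and the enumerated posterior.
config_tv <- function(samples, ex) {
  key <- apply(ex$configurations, 1, paste, collapse = "")
  emp <- table(factor(apply(samples, 1, paste, collapse = ""),
                      levels = key)) / nrow(samples)
  0.5 * sum(abs(as.numeric(emp) - ex$probabilities))
}
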