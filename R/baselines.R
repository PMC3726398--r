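#' Deterministic MRA connection coefficients by total least squares
#'
#' Point-estimate Modular Response Analysis baseline: for each node `i` it
#' solves the orthogonality relations `sum_j r_ij R_jk = R_ik` over the
#' perturbations not targeting `i`, by total least squares (smallest right
#' singular vector of the stacked system). Requires the admissible system
#' of each node to have rank `n - 1`; rank deficiency (fewer informative
#' perturbations than candidate regulators) is an error — this is exactly
#' the limitation the Bayesian formulation removes.
#'
#' @param R Node x experiment global response matrix.
#' @param design A [bvsa_design()] covering the columns of `R`.
#' @param rank_tol Relative singular value cut declaring rank deficiency.
#'   Default 1e-10.
#' @return An n x n connection coefficient matrix `r` (`r[i, j]` = direct
#'   effect of `j` on `i`), with the MRA normalization `r[i, i] = -1`.
#' @export
mra_tlsr <- function(R, design, rank_tol = 1e-10) {
  R <- as.matrix(R)
  nodes <- rownames(R)
  n <- length(nodes)
  r <- matrix(0, n, n, dimnames = list(nodes, nodes))
  diag(r) <- -1
  for (node in nodes) {
    prob <- subproblem(R, design, node)
    # stacked system [X | y] with X = t(R_pr), y = t(R_i); TLS solution from
    # the right singular vector of the smallest singular value
    M <- cbind(t(prob$R_pr), prob$R_i)
    sv <- svd(M, nu = 0, nv = ncol(M))
    p <- length(prob$candidates)
    if (nrow(M) < p || sv$d[p] <= rank_tol * sv$d[1])
      stop("rank-deficient perturbation system for node '", node,
           "': total least squares needs rank n-1")
    v <- sv$v[, p + 1]
    if (abs(v[p + 1]) < .Machine$double.eps)
      stop("degenerate total least squares solution for node '", node, "'")
    r[node, prob$candidates] <- -v[seq_len(p)] / v[p + 1]
  }
  r
}

#' Monte-Carlo stochastic MRA with hypothesis testing
#'
#' Stochastic Modular Response Analysis baseline: draws Gaussian
#' realizations of the response matrix (elementwise mean `R_mean`, sd
#' `R_sd`), solves each by [mra_tlsr()], trims the extreme tail values of
#' each coefficient, flags coefficients whose post-trim variance stays
#' large as unidentifiable, Z-tests the remaining coefficient means against
#' zero, and applies Benjamini-Hochberg multiple-testing correction. The
#' interaction sign is the majority sign of the retained realizations.
#'
#' @param R_mean Node x experiment matrix of response means.
#' @param R_sd Matching matrix of elementwise standard deviations
#'   (all `>= 0`).
#' @param design A [bvsa_design()].
#' @param n_realizations Number of Monte-Carlo draws. Default 10000
#'   (reduce for quick runs).
#' @param outlier_frac Total fraction of extreme values trimmed per
#'   coefficient, split equally between the tails. Default 0.01.
#' @param var_cutoff Post-trim variance above which a coefficient is
#'   declared unidentifiable. `NULL` (default) uses 25x the median
#'   post-trim variance across coefficients — a scale-free heuristic, not a
#'   canonical constant.
#' @param fdr Benjamini-Hochberg false discovery rate. Default 0.05.
#' @return A `data.frame` with one row per ordered off-diagonal pair:
#'   `node`, `regulator`, `mean`, `sd`, `n_retained`, `p`, `p_adj`,
#'   `identifiable`, `sign`, `called`; attributes `n_failed` and
#'   `var_cutoff`.
#' @export
stochastic_mra <- function(R_mean, R_sd, design, n_realizations = 10000,
                           outlier_frac = 0.01, var_cutoff = NULL,
                           fdr = 0.05) {
  R_mean <- as.matrix(R_mean); R_sd <- as.matrix(R_sd)
  if (any(R_sd < 0)) stop("response standard deviations must be >= 0")
  if (n_realizations < 100) stop("need at least 100 realizations")
  nodes <- rownames(R_mean)
  n <- length(nodes)

  draws <- array(NA_real_, c(n, n, n_realizations))
  n_failed <- 0
  for (k in seq_len(n_realizations)) {
    Rk <- R_mean + R_sd * matrix(rnorm(length(R_mean)), nrow(R_mean))
    dimnames(Rk) <- dimnames(R_mean)
    rk <- tryCatch(mra_tlsr(Rk, design), error = function(e) NULL)
    if (is.null(rk)) n_failed <- n_failed + 1 else draws[, , k] <- rk
  }
  if (n_failed > n_realizations / 2)
    stop("total least squares failed for more than half of the realizations")

  per_tail <- round(n_realizations * outlier_frac / 2)
  pairs <- which(!diag(n), arr.ind = TRUE)
  trim <- function(x) {
    x <- sort(x[!is.na(x)])
    if (per_tail > 0 && length(x) > 2 * per_tail)
      x <- x[seq.int(per_tail + 1, length(x) - per_tail)]
    x
  }
  retained <- apply(pairs, 1, function(ij) trim(draws[ij[1], ij[2], ]),
                    simplify = FALSE)

  vars <- vapply(retained, stats::var, numeric(1))
  if (is.null(var_cutoff)) var_cutoff <- 25 * stats::median(vars)
  identifiable <- vars <= var_cutoff

  stat <- t(vapply(retained, function(x) {
    m <- mean(x); s <- sd(x)
    # degenerate Monte Carlo (zero spread): call by the point estimate,
    # treating values at numerical-noise level as zero
    z <- if (s == 0) { if (abs(m) < 1e-10) 0 else Inf } else m / s
    c(mean = m, sd = s, n = length(x), p = 2 * pnorm(-abs(z)),
      sign = if (mean(x < 0) > mean(x > 0)) -1 else 1)
  }, numeric(5)))

  p_adj <- rep(NA_real_, nrow(pairs))
  p_adj[identifiable] <- p.adjust(stat[identifiable, "p"], method = "BH")
  out <- data.frame(node = nodes[pairs[, 1]],
                    regulator = nodes[pairs[, 2]],
                    mean = stat[, "mean"], sd = stat[, "sd"],
                    n_retained = as.integer(stat[, "n"]),
                    p = stat[, "p"], p_adj = p_adj,
                    identifiable = identifiable,
                    sign = ifelse(stat[, "sign"] < 0, "inhibitory",
                                  "activating"),
                    called = identifiable & !is.na(p_adj) & p_adj < fdr,
                    stringsAsFactors = FALSE)
  attr(out, "n_failed") <- n_failed
  attr(out, "var_cutoff") <- var_cutoff
  out
}
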