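#' Log marginal prior of an edge configuration
#'
#' Marginal prior probability (log scale) of one specific configuration
#' with `n_ki` present edges among the `n - 1` candidate regulators of a
#' node, after integrating the network sparsity parameter out of its
#' Beta(a, b) prior: `B(a + n_ki, b + (n-1) - n_ki) / B(a, b)`. Summed over
#' all `2^(n-1)` configurations this is a proper distribution.
#'
#' @param n_ki Number of selected regulators (0 .. n-1).
#' @param n Number of nodes in the network (candidates + 1).
#' @param hyper A [bvsa_hyper()].
#' @return Log prior probability of the configuration.
#' @examples
#' exp(log_prior_config(0, 3, bvsa_hyper()))  # 1/2
#' exp(log_prior_config(1, 3, bvsa_hyper()))  # 1/6
#' @export
log_prior_config <- function(n_ki, n, hyper = bvsa_hyper()) {
  if (n_ki < 0 || n_ki > n - 1)
    stop("n_ki must lie in 0 .. n-1")
  lbeta(hyper$a + n_ki, hyper$b + (n - 1) - n_ki) -
    lbeta(hyper$a, hyper$b)
}

#' Prior precision kernel of the selected regulators
#'
#' The sigma^2-free precision kernel of the g-prior slab on the connection
#' coefficients of the selected regulators:
#' `K^{-1} = (1/c) (R_pr_sel R_pr_sel^T + lambda I)`. The ridge `lambda > 0`
#' keeps the kernel positive definite even when the selected block is rank
#' deficient (fewer perturbations than selected regulators, or duplicated
#' response rows).
#'
#' @param R_pr_sel Selected-regulator block (`n_ki` x `n_pi`), `n_ki >= 1`.
#' @param hyper A [bvsa_hyper()]. `c = NA` resolves to `ncol(R_pr_sel)`.
#' @return The `n_ki` x `n_ki` positive-definite kernel matrix.
#' @export
prior_precision_kernel <- function(R_pr_sel, hyper = bvsa_hyper()) {
  R_pr_sel <- as.matrix(R_pr_sel)
  if (any(!is.finite(R_pr_sel))) stop("non-finite entries in regulator block")
  cc <- resolve_c(hyper, ncol(R_pr_sel))
  G <- tcrossprod(R_pr_sel)
  (G + hyper$lambda * diag(nrow(G))) / cc
}

#' Residual term of the marginal configuration score
#'
#' The data-dependent scale `b1` of the integrated-out noise variance:
#' `beta + 0.5 * (R_i R_i^T - R_i R_pr^T (K^{-1} + R_pr R_pr^T)^{-1} R_pr R_i^T)`
#' with `R_pr` restricted to the selected regulators. For the empty
#' configuration `b1 = beta + 0.5 * R_i R_i^T`. Always `>= beta`, since the
#' subtracted quadratic form is a (shrunken) projection.
#'
#' @param prob A [subproblem()].
#' @param bits Binary vector over the candidates (0/1).
#' @param hyper A [bvsa_hyper()].
#' @return The scalar residual term `b1`.
#' @export
residual_b1 <- function(prob, bits, hyper = bvsa_hyper()) {
  bits <- check_bits(bits, prob)
  rr <- sum(prob$R_i^2)
  if (sum(bits) == 0) return(hyper$beta + 0.5 * rr)
  X <- prob$R_pr[bits == 1, , drop = FALSE]
  cc <- resolve_c(hyper, prob$n_pi)
  G <- tcrossprod(X)
  M1 <- (G + hyper$lambda * diag(nrow(G))) / cc + G
  cM <- tryCatch(chol(M1), error = function(e)
    stop("inner matrix numerically singular despite ridge; condition number ",
         format(kappa(M1)), call. = FALSE))
  u <- drop(X %*% prob$R_i)
  q <- sum(backsolve(cM, u, transpose = TRUE)^2)
  max(hyper$beta, hyper$beta + 0.5 * (rr - q))
}

#' Log marginal posterior score of an edge configuration
#'
#' Unnormalized log posterior of one regulator configuration for a
#' subnetwork, after analytic marginalization of the connection
#' coefficients (Gaussian slab with ridge-stabilized g-prior covariance),
#' the noise variance (inverse-gamma), and the sparsity parameter
#' (Beta-Bernoulli). Up to an additive constant shared by all
#' configurations of the same subproblem:
#'
#' \deqn{\log p = \log\pi(n_{ki}) - \tfrac12\left[n_{ki}\log c +
#'   \log|K^{-1}+G| - \log|G+\lambda I|\right] -
#'   (\alpha + n_{pi}/2)\log b_1}
#'
#' with `G` the Gram matrix of the selected regulators. Computed in log
#' space via Cholesky factorizations.
#'
#' @param prob A [subproblem()].
#' @param bits Binary vector over the candidates (0/1).
#' @param hyper A [bvsa_hyper()].
#' @param compiled Use the compiled scorer (identical result; the R path is
#'   the readable reference). Default `FALSE`.
#' @return A list of class `"bvsa_score"`: `log_score`, `b1`, `n_ki`,
#'   `n_pi`.
#' @export
log_marginal_posterior <- function(prob, bits, hyper = bvsa_hyper(),
                                   compiled = FALSE) {
  bits <- check_bits(bits, prob)
  n <- length(prob$candidates) + 1
  n_ki <- sum(bits)
  cc <- resolve_c(hyper, prob$n_pi)
  b1 <- residual_b1(prob, bits, hyper)
  if (compiled) {
    ls <- cpp_log_marginal(prob$R_i, prob$R_pr, as.integer(bits),
                           hyper$a, hyper$b, hyper$alpha, hyper$beta,
                           cc, hyper$lambda)
  } else {
    lp <- log_prior_config(n_ki, n, hyper)
    if (n_ki == 0) {
      ldet <- 0
    } else {
      X <- prob$R_pr[bits == 1, , drop = FALSE]
      G <- tcrossprod(X)
      Gl <- G + hyper$lambda * diag(n_ki)
      M1 <- Gl / cc + G
      ldet <- -0.5 * (n_ki * log(cc) +
                        2 * sum(log(diag(chol(M1)))) -
                        2 * sum(log(diag(chol(Gl)))))
    }
    ls <- lp + ldet - (hyper$alpha + prob$n_pi / 2) * log(b1)
  }
  structure(list(log_score = ls, b1 = b1, n_ki = n_ki, n_pi = prob$n_pi),
            class = "bvsa_score")
}

check_bits <- function(bits, prob) {
  bits <- as.integer(bits)
  if (length(bits) != length(prob$candidates))
    stop("configuration length must equal the number of candidate regulators")
  if (any(!bits %in% c(0L, 1L))) stop("configuration must be binary")
  bits
}
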