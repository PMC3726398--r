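#' One componentwise Gibbs update
#'
#' Resamples a single edge indicator conditional on all others: bit `j` is
#' set to 1 with probability `p1 / (p1 + p0)`, where `p1` and `p0` are the
#' marginal posterior scores of the configuration with bit `j` set and
#' unset. Evaluated in the log-sum-exp stabilized form
#' `1 / (1 + exp(log p0 - log p1))`.
#'
#' @param bits Current binary configuration.
#' @param j Candidate index to update.
#' @param prob A [subproblem()].
#' @param hyper A [bvsa_hyper()].
#' @return The updated configuration (integer 0/1 vector).
#' @export
gibbs_update <- function(bits, j, prob, hyper = bvsa_hyper()) {
  bits <- check_bits(bits, prob)
  if (j < 1 || j > length(bits)) stop("candidate index out of range")
  b1 <- b0 <- bits
  b1[j] <- 1L; b0[j] <- 0L
  lp1 <- log_marginal_posterior(prob, b1, hyper)$log_score
  lp0 <- log_marginal_posterior(prob, b0, hyper)$log_score
  p1 <- 1 / (1 + exp(lp0 - lp1))
  bits[j] <- if (runif(1) < p1) 1L else 0L
  bits
}

#' Run one Gibbs chain over edge configurations
#'
#' Performs `n_sweeps` full sweeps over the candidate regulators of one
#' subnetwork, visiting candidates in fixed ascending index order and
#' recording the configuration and its log marginal score after every
#' sweep. The initial configuration is drawn with independent fair coin
#' flips unless supplied. Uses R's RNG stream, so results are reproducible
#' under `set.seed()`.
#'
#' @param prob A [subproblem()].
#' @param hyper A [bvsa_hyper()].
#' @param settings A [bvsa_chains()]; only `n_sweeps` is used here.
#' @param init Optional initial configuration.
#' @return An object of class `"bvsa_trace"`: list with `samples`
#'   (`n_sweeps` x candidates binary matrix), `log_scores`, `init`.
#' @export
run_chain <- function(prob, hyper = bvsa_hyper(),
                      settings = bvsa_chains(), init = NULL) {
  p <- length(prob$candidates)
  if (settings$n_sweeps < 1) stop("at least one sweep is required")
  if (is.null(init)) {
    init <- as.integer(runif(p) < 0.5)
  } else {
    init <- check_bits(init, prob)
  }
  cc <- resolve_c(hyper, prob$n_pi)
  res <- cpp_run_chain(prob$R_i, prob$R_pr, init, settings$n_sweeps,
                       hyper$a, hyper$b, hyper$alpha, hyper$beta,
                       cc, hyper$lambda)
  colnames(res$samples) <- prob$candidates
  structure(list(samples = res$samples,
                 log_scores = drop(res$log_scores),
                 init = init),
            class = "bvsa_trace")
}

#' Posterior edge probabilities from Gibbs traces
#'
#' Averages each edge indicator over the post-burn-in samples of all
#' chains: `P_ij = sum over chains and retained sweeps of A_ij / (N_c *
#' (NTs - NTb))`.
#'
#' @param traces List of [run_chain()] traces over the same subproblem.
#' @param settings A [bvsa_chains()] supplying the burn-in.
#' @return Named numeric vector of posterior edge probabilities.
#' @export
posterior_edge_probabilities <- function(traces, settings = bvsa_chains()) {
  if (!length(traces)) stop("at least one trace is required")
  nts <- nrow(traces[[1]]$samples)
  nburn <- as.integer(floor(settings$burn_in * nts))
  if (nburn >= nts) stop("burn-in leaves no retained samples")
  keep <- seq.int(nburn + 1, nts)
  acc <- Reduce(`+`, lapply(traces, function(tr)
    colSums(tr$samples[keep, , drop = FALSE])))
  acc / (length(traces) * length(keep))
}

#' Exact posterior by exhaustive configuration enumeration
#'
#' Scores all `2^(n-1)` regulator configurations of a subnetwork,
#' normalizes by log-sum-exp, and returns the exact marginal posterior
#' probability of each candidate edge. Practical for small candidate
#' counts; above `max_candidates` the Gibbs sampler should be used instead.
#'
#' @param prob A [subproblem()].
#' @param hyper A [bvsa_hyper()].
#' @param max_candidates Hard cap on the candidate count. Default 20.
#' @return List with `marginals` (named probability vector),
#'   `configurations` (binary matrix), `probabilities` (normalized
#'   configuration posterior), `log_scores`.
#' @export
exhaustive_posterior <- function(prob, hyper = bvsa_hyper(),
                                 max_candidates = 20) {
  p <- length(prob$candidates)
  if (p > max_candidates)
    stop("candidate count ", p, " above the enumeration cap; ",
         "use the Gibbs sampler")
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))
  dimnames(configs) <- list(NULL, prob$candidates)
  cc <- resolve_c(hyper, prob$n_pi)
  ls <- apply(configs, 1, function(bits)
    cpp_log_marginal(prob$R_i, prob$R_pr, as.integer(bits),
                     hyper$a, hyper$b, hyper$alpha, hyper$beta,
                     cc, hyper$lambda))
  w <- exp(ls - max(ls))
  pr <- w / sum(w)
  list(marginals = setNames(drop(pr %*% configs), prob$candidates),
       configurations = configs,
       probabilities = pr,
       log_scores = ls)
}

#' Cross-chain convergence report
#'
#' Aligns the per-sweep log-score series of parallel chains and summarizes
#' their post-burn-in agreement by the maximum absolute difference of
#' cross-chain mean log scores. Disagreement beyond `tol` raises a warning
#' (advisory only): parallel chains started from overdispersed random
#' configurations are expected to converge on each other.
#'
#' @param traces List of at least two [run_chain()] traces.
#' @param settings A [bvsa_chains()] supplying the burn-in.
#' @param tol Warn when cross-chain mean log scores differ by more.
#'   Default 1.
#' @return List with `log_scores` (sweeps x chains matrix), `chain_means`,
#'   `max_mean_difference`, `flagged`.
#' @export
convergence_report <- function(traces, settings = bvsa_chains(), tol = 1) {
  if (length(traces) < 2) stop("need at least two chains to compare")
  ls <- vapply(traces, function(tr) tr$log_scores,
               numeric(length(traces[[1]]$log_scores)))
  nts <- nrow(ls)
  nburn <- as.integer(floor(settings$burn_in * nts))
  means <- colMeans(ls[seq.int(nburn + 1, nts), , drop = FALSE])
  gap <- max(dist(means))
  flagged <- gap > tol
  if (flagged)
    warning(sprintf(
      "chains disagree: post-burn-in mean log scores differ by %.3g", gap))
  list(log_scores = ls, chain_means = means,
       max_mean_difference = gap, flagged = flagged)
}
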