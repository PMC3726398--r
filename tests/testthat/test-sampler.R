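test_that("componentwise update draws bits with the Bernoulli posterior odds", {
  set.seed(6)
  prob <- random_subproblem(2, 4)
  h <- bvsa_hyper()
  lp1 <- log_marginal_posterior(prob, 1, h)$log_score
  lp0 <- log_marginal_posterior(prob, 0, h)$log_score
  p1 <- 1 / (1 + exp(lp0 - lp1))
  draws <- replicate(10000, gibbs_update(0L, 1, prob, h))
  se <- sqrt(p1 * (1 - p1) / 10000)
  expect_lt(abs(mean(draws) - p1), 3 * se)
  expect_error(gibbs_update(0L, 3, prob, h), "index")
})

test_that("log-sum-exp stabilization keeps extreme odds finite", {
  # direct check of the stabilized form used by the samplers
  expect_equal(1 / (1 + exp(0)), 0.5)
  expect_equal(1 / (1 + exp(-50)), 1, tolerance = 1e-15)
  expect_equal(1 / (1 + exp(1500)), 0)   # no overflow to NaN
})

test_that("chains are deterministic under a seed and record one sample per sweep", {
  set.seed(7)
  prob <- random_subproblem(5, 6)
  one <- run_chain(prob, settings = bvsa_chains(n_sweeps = 1))
  expect_equal(nrow(one$samples), 1)
  expect_length(one$log_scores, 1)

  set.seed(42); tr1 <- run_chain(prob, settings = bvsa_chains(n_sweeps = 50))
  set.seed(42); tr2 <- run_chain(prob, settings = bvsa_chains(n_sweeps = 50))
  expect_identical(tr1$samples, tr2$samples)
  expect_identical(tr1$log_scores, tr2$log_scores)
  expect_error(bvsa_chains(n_sweeps = 0), "n_sweeps")
})

test_that("empirical configuration frequencies approach the enumerated posterior", {
  set.seed(8)
  r <- random_r_matrix(5, 5)
  sys <- forward_mra_system(r)
  prob <- subproblem(standardize_rows(sys$R), sys$design, "n1")
  ex <- exhaustive_posterior(prob)
  tv <- vapply(c(100, 1000, 10000), function(nts) {
    tr <- run_chain(prob, settings = bvsa_chains(n_sweeps = nts))
    config_tv(tr$samples, ex)
  }, numeric(1))
  expect_lt(tv[3], tv[1])
  expect_lt(tv[3], 0.05)
})

test_that("posterior edge probabilities average post-burn-in samples across chains", {
  # hand-built traces: bit sums 30/80 and 50/80 after burn-in -> 0.5
  mk <- function(ones) {
    s <- matrix(0L, 100, 1)
    s[20 + seq_len(ones), 1] <- 1L   # all ones after the 20-sample burn-in
    structure(list(samples = s, log_scores = numeric(100)),
              class = "bvsa_trace")
  }
  p <- posterior_edge_probabilities(list(mk(30), mk(50)),
                                    bvsa_chains(n_sweeps = 100,
                                                burn_in = 0.2))
  expect_equal(unname(p), 0.5)
  p1 <- posterior_edge_probabilities(list(mk(80)),
                                     bvsa_chains(n_sweeps = 100,
                                                 burn_in = 0.2))
  expect_equal(unname(p1), 1)
  expect_error(posterior_edge_probabilities(list(), bvsa_chains()), "trace")
})

test_that("exhaustive enumeration is normalized and capped", {
  set.seed(9)
  prob <- random_subproblem(3, 4)
  ex <- exhaustive_posterior(prob)
  expect_equal(nrow(ex$configurations), 4)   # 2^(n-1)
  expect_equal(sum(ex$probabilities), 1, tolerance = 1e-12)
  expect_true(all(ex$marginals >= 0 & ex$marginals <= 1))
  expect_error(exhaustive_posterior(random_subproblem(7, 4),
                                    max_candidates = 5), "Gibbs")
})

test_that("Gibbs sweep kernel has the enumerated posterior as stationary law", {
  # 2-candidate problem: build the exact 4x4 sweep transition matrix from
  # the conditional odds and compare its stationary vector to enumeration
  set.seed(10)
  prob <- random_subproblem(3, 5)
  h <- bvsa_hyper()
  ex <- exhaustive_posterior(prob, h)
  configs <- ex$configurations
  score <- function(b) log_marginal_posterior(prob, b, h)$log_score
  cond_p1 <- function(b, j) {
    b1 <- b; b1[j] <- 1; b0 <- b; b0[j] <- 0
    1 / (1 + exp(score(b0) - score(b1)))
  }
  step_mat <- function(j) {
    P <- matrix(0, 4, 4)
    for (s in 1:4) {
      b <- configs[s, ]
      p1 <- cond_p1(b, j)
      to1 <- b; to1[j] <- 1
      to0 <- b; to0[j] <- 0
      idx <- function(x) which(apply(configs, 1, function(cc)
        all(cc == x)))
      P[s, idx(to1)] <- P[s, idx(to1)] + p1
      P[s, idx(to0)] <- P[s, idx(to0)] + (1 - p1)
    }
    P
  }
  Psweep <- step_mat(1) %*% step_mat(2)
  ev <- eigen(t(Psweep))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  expect_equal(stat, as.numeric(ex$probabilities), tolerance = 1e-10)
})

test_that("convergence report compares post-burn-in chain means", {
  set.seed(11)
  prob <- random_subproblem(4, 6)
  tr <- run_chain(prob, settings = bvsa_chains(n_sweeps = 80))
  rep1 <- convergence_report(list(tr, tr), bvsa_chains(n_sweeps = 80))
  expect_equal(rep1$max_mean_difference, 0)
  expect_equal(nrow(rep1$log_scores), 80)
  expect_false(rep1$flagged)

  tr2 <- run_chain(prob, settings = bvsa_chains(n_sweeps = 80))
  expect_no_warning(convergence_report(list(tr, tr2),
                                       bvsa_chains(n_sweeps = 80)))
  expect_warning(convergence_report(list(tr, tr2),
                                    bvsa_chains(n_sweeps = 80),
                                    tol = -1), "disagree")
  expect_error(convergence_report(list(tr)), "two chains")
})
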