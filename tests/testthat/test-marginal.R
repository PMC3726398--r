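test_that("marginalized Beta-Bernoulli configuration prior is exact and proper", {
  h <- bvsa_hyper()   # a = 1, b = 2
  expect_equal(exp(log_prior_config(0, 3, h)), 1 / 2)
  expect_equal(exp(log_prior_config(1, 3, h)), 1 / 6)
  # sums to one over all 2^(n-1) configurations
  for (n in c(3, 5, 8)) {
    k <- 0:(n - 1)
    total <- sum(choose(n - 1, k) * exp(vapply(k, log_prior_config,
                                               numeric(1), n = n,
                                               hyper = h)))
    expect_equal(total, 1, tolerance = 1e-14)
  }
  expect_error(log_prior_config(3, 3), "n_ki")
})

test_that("prior precision kernel is the ridged Gram matrix over c", {
  h <- bvsa_hyper(c = 10)
  expect_equal(prior_precision_kernel(matrix(2, 1, 1), h),
               matrix(0.41, 1, 1))   # (4 + 0.1) / 10
  # duplicated regulator rows: ridge keeps the kernel positive definite
  X <- rbind(c(1, 2, 3), c(1, 2, 3))
  K <- prior_precision_kernel(X, bvsa_hyper())
  ev <- eigen(K, only.values = TRUE)$values
  expect_true(min(ev) >= 0.1 / 3 - 1e-12)   # lambda / c with c = n_pi = 3
  # vanishing ridge recovers the plain g-prior kernel on full-rank blocks
  h0 <- bvsa_hyper(c = 5, lambda = 1e-12)
  Xf <- rbind(c(1, 0, 2), c(0, 3, 1))
  expect_equal(prior_precision_kernel(Xf, h0), tcrossprod(Xf) / 5,
               tolerance = 1e-9)
})

test_that("residual term b1 reduces correctly and shrinks under selection", {
  set.seed(2)
  prob <- random_subproblem(4, 5)
  h <- bvsa_hyper()
  zero <- prob; zero$R_i[] <- 0
  expect_equal(residual_b1(zero, c(0, 1, 1), h), 1)    # beta with no data
  # empty configuration: beta + 0.5 * R_i R_i^T
  prob2 <- prob; prob2$R_i <- sqrt(6 / 5) * rep(1, 5)  # sum of squares 6
  expect_equal(residual_b1(prob2, c(0, 0, 0), h), 4)
  # selecting a regulator can only reduce the residual quadratic form
  b_empty <- residual_b1(prob, c(0, 0, 0), h)
  for (j in 1:3) {
    bits <- rep(0, 3); bits[j] <- 1
    expect_lte(residual_b1(prob, bits, h), b_empty)
  }
})

test_that("marginal score: symbolic reductions, symmetry, R/C++ agreement", {
  h <- bvsa_hyper()
  set.seed(3)
  zero <- random_subproblem(4, 6); zero$R_i[] <- 0
  s <- log_marginal_posterior(zero, c(0, 0, 0), h)
  expect_equal(s$log_score,
               log_prior_config(0, 4, h) - (1 + 6 / 2) * log(1))
  # with no data the sparsity prior dominates: empty configuration wins
  scores <- apply(expand.grid(0:1, 0:1, 0:1), 1, function(b)
    log_marginal_posterior(zero, b, h)$log_score)
  expect_equal(which.max(scores), 1L)

  # permuting candidates together with the bits leaves the score unchanged
  prob <- random_subproblem(5, 6)
  bits <- c(1, 0, 1, 0)
  perm <- c(3, 1, 4, 2)
  pprob <- prob
  pprob$candidates <- prob$candidates[perm]
  pprob$R_pr <- prob$R_pr[perm, ]
  expect_equal(log_marginal_posterior(pprob, bits[perm], h)$log_score,
               log_marginal_posterior(prob, bits, h)$log_score)

  # compiled scorer matches the R reference on random configurations
  for (i in 1:25) {
    p <- random_subproblem(sample(3:6, 1), sample(3:8, 1))
    b <- as.integer(runif(length(p$candidates)) < 0.5)
    expect_equal(log_marginal_posterior(p, b, h, compiled = TRUE)$log_score,
                 log_marginal_posterior(p, b, h)$log_score,
                 tolerance = 1e-10)
  }
})

test_that("common rescaling of standardized data preserves configuration ranking", {
  set.seed(4)
  h <- bvsa_hyper()
  for (i in 1:10) {
    prob <- random_subproblem(4, 6)
    # standardization first, as in the inference protocol
    R <- standardize_rows(rbind(prob$R_i, prob$R_pr))
    prob$R_i <- R[1, ]; prob$R_pr <- R[-1, , drop = FALSE]
    configs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
    sc1 <- apply(configs, 1, function(b)
      log_marginal_posterior(prob, b, h)$log_score)
    scaled <- prob
    Rs <- standardize_rows(rbind(prob$R_i, prob$R_pr) * 7.3)
    scaled$R_i <- Rs[1, ]; scaled$R_pr <- Rs[-1, , drop = FALSE]
    sc2 <- apply(configs, 1, function(b)
      log_marginal_posterior(scaled, b, h)$log_score)
    expect_equal(order(sc1), order(sc2))
  }
})

test_that("posterior odds match direct numeric integration of the priors", {
  set.seed(5)
  h <- bvsa_hyper()
  # single selected regulator, several problem shapes
  for (i in 1:4) {
    prob <- random_subproblem(2, sample(3:6, 1))
    ours <- exp(log_marginal_posterior(prob, 1, h)$log_score -
                  log_marginal_posterior(prob, 0, h)$log_score)
    expect_equal(ours, quad_odds(prob, 1, h), tolerance = 5e-3)
  }
  # two selected regulators
  prob <- random_subproblem(3, 5)
  ours <- exp(log_marginal_posterior(prob, c(1, 1), h)$log_score -
                log_marginal_posterior(prob, c(0, 0), h)$log_score)
  expect_equal(ours, quad_odds(prob, c(1, 1), h), tolerance = 5e-3)
})
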