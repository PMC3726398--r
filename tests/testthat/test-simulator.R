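test_that("MAPK fixture has the cascade-plus-feedback topology and a live baseline", {
  m <- mapk_network()
  expect_equal(sum(m$adjacency != 0), 8)
  expect_equal(sum(m$adjacency == -1), 3)
  # the three feedbacks all come from the terminal kinase
  expect_equal(sort(rownames(which(m$adjacency == -1, arr.ind = TRUE))),
               sort(c("adapter", "map3k", "map2k")))
  expect_true(all(m$adjacency[, "mapk"][c("adapter", "map3k", "map2k")]
                  == -1))
  ss <- ode_steady_state(m)
  expect_true(all(ss > 0))
  # steady state satisfies the rate criterion
  expect_lt(max(abs(bvsamra:::model_rates(m, ss)) / ss), 1e-8)
})

test_that("knockdowns scale expression and the design counts match the protocol", {
  m <- mapk_network()
  sim <- simulate_knockdowns(m, seed = 21)
  expect_equal(ncol(sim$states), 19)   # 18 perturbations + baseline
  expect_equal(nrow(sim$design), 18)
  expect_equal(as.vector(table(sim$design$target)), rep(3L, 6))
  expect_identical(sim$truth, m$adjacency)

  # isolated constitutive node: 80% knockdown leaves exactly 20% of baseline
  iso <- bvsa_model(matrix(0, 2, 2,
                           dimnames = list(c("a", "b"), c("a", "b"))),
                    basal = c(1, 1))
  s <- simulate_knockdowns(iso, efficiencies = 0.8, targets = "a")
  expect_equal(s$states["a", "a_kd80"] / s$states["a", "baseline"], 0.2,
               tolerance = 1e-6)
  # knockout: level zero
  s2 <- simulate_knockdowns(iso, efficiencies = 1, targets = "a")
  expect_equal(unname(s2$states["a", "a_kd100"]), 0, tolerance = 1e-9)
  expect_error(simulate_knockdowns(iso, efficiencies = 1.2), "efficiencies")
})

test_that("measurement error follows the log-linear variance model", {
  expect_equal(add_measurement_error(c(1, 5, 10), 0, 0), c(1, 5, 10))
  expect_error(add_measurement_error(c(1, -1), 0.1, 0.1), "positive")
  set.seed(22)
  # Y = 0, alpha_b = 0.1, beta_s = 1 -> variance 1.1
  v <- var(log(add_measurement_error(rep(1, 4000), 0.1, 1)))
  se <- 1.1 * sqrt(2 / 3999)
  expect_lt(abs(v - 1.1), 3 * se)
  # high intensity: variance collapses to the background floor
  vhi <- var(log(add_measurement_error(rep(exp(12), 4000), 0.1, 1)))
  expect_lt(abs(vhi - 0.1), 3 * 0.1 * sqrt(2 / 3999))
})

test_that("Milstein integration degenerates to the ODE and is seed-stable", {
  m <- mapk_network()
  ss <- ode_steady_state(m)
  expect_equal(milstein_steady_state(m, 0), ss)
  set.seed(23); s1 <- milstein_steady_state(m, 0.05)
  set.seed(23); s2 <- milstein_steady_state(m, 0.05)
  expect_identical(s1, s2)
  expect_lt(max(abs(s1 - ss) / ss), 0.25)   # fluctuates around the ODE state
})

test_that("halving the Milstein step changes the estimate within seed noise", {
  m <- mapk_network()
  ss <- ode_steady_state(m)
  est <- function(dt, seed) {
    set.seed(seed)
    milstein_steady_state(m, 0.05, dt = dt, init = ss)["mapk"]
  }
  seeds <- 1:12
  coarse <- vapply(seeds, function(s) est(0.02, s), numeric(1))
  fine <- vapply(seeds, function(s) est(0.01, s + 100), numeric(1))
  se <- sqrt(var(coarse) / length(seeds) + var(fine) / length(seeds))
  expect_lt(abs(mean(coarse) - mean(fine)), 3 * se + 1e-8)
})

test_that("random networks hit the requested density and are stable by construction", {
  set.seed(24)
  dens <- vapply(1:60, function(s) {
    m <- random_network(6, 0.25, seed = s)
    mean(m$adjacency[!diag(6)] != 0)
  }, numeric(1))
  # realized edge count is Binomial(30, 0.25) per network
  se <- sqrt(0.25 * 0.75 / (30 * 60))
  expect_lt(abs(mean(dens) - 0.25), 3 * se)
  # seeded reproducibility
  expect_identical(random_network(5, 0.3, seed = 3)$adjacency,
                   random_network(5, 0.3, seed = 3)$adjacency)
  expect_error(random_network(1, 0.5), "two nodes")
  expect_error(random_network(5, 0), "density")
})

test_that("noise-free responses satisfy the MRA relations in the small-perturbation limit", {
  m <- mapk_network()
  r <- local_response_matrix(m)
  # direct edges of the model appear exactly as nonzero local coefficients
  expect_identical(unname(abs(r) > 1e-6 & row(r) != col(r)),
                   unname(m$adjacency != 0))
  resid <- function(eff) {
    sim <- simulate_knockdowns(m, efficiencies = eff)
    R <- response_matrix(sim$states, "baseline", sim$design)
    worst <- 0
    for (i in seq_len(6)) {
      keep <- sim$design$target != m$nodes[i]
      lhs <- drop(r[i, -i, drop = FALSE] %*% R[-i, keep])
      worst <- max(worst, max(abs(lhs - R[i, keep])))
    }
    worst
  }
  r_small <- resid(0.05)
  r_large <- resid(0.4)
  expect_lt(r_small, r_large)   # first-order relation tightens as eff -> 0
  expect_lt(r_small, 0.02)
})
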