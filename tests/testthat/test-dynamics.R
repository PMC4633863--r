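test_that("mean activity is the weighted sum of mean inputs", {
  sys <- toy_system(3)
  st <- sys$state
  ## by-hand computation for locus 1: phi[1,2] xb_2 + phi[1,3] xb_3
  xb <- 2 * st$rho - 1
  expect_equal(mean_activity(st, 1),
               st$phi[1, 2] * xb[2] + st$phi[1, 3] * xb[3])
  expect_equal(mean_activity(st), as.vector(st$phi %*% xb))
  ## zero weights or rho = 1/2 give zero activity
  topo <- make_complete(3)
  z <- ensemble_state(c(0.2, 0.8, 0.5), matrix(0, 3, 3), topo)
  expect_equal(mean_activity(z), rep(0, 3))
  half <- ensemble_state(rep(0.5, 3), st$phi, topo)
  expect_equal(mean_activity(half), rep(0, 3))
})

test_that("activity rule: M is 1/2 when naive and decays with |activity|", {
  expect_equal(switching_probability(0), 0.5)
  expect_lt(switching_probability(50), 1e-12)
  Y <- seq(0, 6, by = 0.05)
  M <- switching_probability(Y)
  expect_true(all(diff(M) <= 0))          # monotone non-increasing in |Y|
  expect_true(all(M > 0 & M <= 0.5))
  expect_equal(switching_probability(-2), switching_probability(2))
})

test_that("firing-probability rate satisfies the switching contracts", {
  topo <- make_complete(3)
  ls <- landscape_directional(2)
  ## M = 0 and rho in {0, 1}: absorbing under pure selection
  st <- ensemble_state(c(0, 1, 0.5), matrix(0, 3, 3), topo)
  r0 <- rho_rate(st, ls, M = rep(0, 3))
  expect_equal(r0[1:2], c(0, 0))
  ## switching term vanishes at rho = 1/2 and pulls toward 1/2 at rate M
  ls0 <- landscape_directional(0)        # W_on = W_off
  st2 <- ensemble_state(c(0.5, 0.1, 0.9), matrix(0, 3, 3), topo)
  r2 <- rho_rate(st2, ls0, M = rep(0.3, 3))
  expect_equal(r2[1], 0)
  expect_equal(r2[2], 0.3 * (1 - 0.2))
  expect_lt(r2[3], 0)
  expect_equal(rho_rate(st2, ls0, M = rep(0, 3)), rep(0, 3))
})

test_that("no-learning equilibrium matches the independent balance root", {
  ## constant gradient, constant switching: integration must land on the
  ## root found by bisection
  topo <- make_complete(3)
  ls <- landscape_directional(5)
  st <- init_state(topo, seed = 11)
  tr <- integrate_dynamics(st, ls,
                           dynamics_params(lambda = 0, t_max = 2000,
                                           fixed_M = 0.5))
  root <- exact_balance_root(5, 0.5)
  expect_lt(max(abs(tr$final_state$rho - root)), 1e-6)
})

test_that("Oja rule: zero rate cases and unit incoming norm at the fixed point", {
  sys <- toy_system(3)
  expect_equal(phi_rate(sys$state, lambda = 0), matrix(0, 3, 3))
  topo <- make_complete(3)
  half <- ensemble_state(rep(0.5, 3), sys$state$phi, topo)
  expect_equal(phi_rate(half, lambda = 0.1), matrix(0, 3, 3))
  ## all-on 3-neuron system, firing probabilities frozen: incoming norms -> 1
  on <- init_state(topo, seed = 12)
  on$rho <- rep(1, 3)
  tr <- integrate_dynamics(on, landscape_directional(1),
                           dynamics_params(lambda = 0.05, t_max = 5000),
                           freeze_rho = TRUE)
  norms <- sqrt(rowSums(tr$final_state$phi^2))
  expect_equal(norms, rep(1, 3), tolerance = 1e-6)
})

test_that("adaptive solver agrees with the independent Euler oracle", {
  topo <- make_complete(3)
  ls <- landscape_directional(3)
  st <- init_state(topo, seed = 13)
  eo <- euler_oracle(st, ls, t_max = 50, dt = 1e-3, lambda = 0.01)
  tr <- integrate_dynamics(st, ls, dynamics_params(lambda = 0.01, t_max = 50))
  expect_lt(max(abs(eo$rho - tr$final_state$rho)), 1e-4)
  ## the compiled and plain-R right-hand sides integrate identically
  trR <- integrate_dynamics(st, ls, dynamics_params(lambda = 0.01, t_max = 50),
                            compiled = FALSE)
  expect_lt(max(abs(trR$final_state$rho - tr$final_state$rho)), 1e-8)
})

test_that("trajectories stay in bounds and preserve sparsity", {
  topo <- make_er(8, 0.4, seed = 14)
  ls <- landscape_stabilizing(beta_from_gradient(5, 5), 5)
  st <- init_state(topo, seed = 14)
  tr <- integrate_dynamics(st, ls, dynamics_params(lambda = 0.01,
                                                   t_max = 3000))
  expect_true(all(tr$rho >= 0 & tr$rho <= 1))
  off <- as.vector(adjacency_matrix(topo)) == 0
  expect_true(all(tr$phi[, off] == 0))
})

test_that("symmetric problems give permutation-invariant trajectories", {
  topo <- make_complete(6)
  ls <- landscape_stabilizing(beta_from_gradient(5, 4), 4)
  st <- ensemble_state(rep(0.005, 6),
                       0.005 * adjacency_matrix(topo), topo)
  tr <- integrate_dynamics(st, ls, dynamics_params(lambda = 0.01,
                                                   t_max = 1000))
  expect_lt(diff(range(tr$final_state$rho)), 1e-8)
})

test_that("pure switching relaxes firing probabilities to one half", {
  topo <- make_complete(4)
  st <- init_state(topo, seed = 15)
  tr <- integrate_dynamics(st, landscape_directional(0),
                           dynamics_params(lambda = 0, t_max = 500))
  expect_equal(tr$final_state$rho, rep(0.5, 4), tolerance = 1e-6)
})

test_that("the learnt equilibrium is independent of the learning rate", {
  topo <- make_complete(6)
  ls <- landscape_directional(5)
  fin <- lapply(c(1e-3, 1e-2), function(l) {
    st <- init_state(topo, seed = 16)
    integrate_dynamics(st, ls, dynamics_params(lambda = l,
                                               t_max = 1e4))$final_state$rho
  })
  expect_lt(max(abs(fin[[1]] - fin[[2]])), 1e-3)
})

test_that("convergence time is the first crossing of the smoothed fitness", {
  topo <- make_complete(3)
  ls <- landscape_directional(5)
  ## start at the no-switching optimum: already converged at t = 0
  st <- ensemble_state(rep(1, 3), matrix(0, 3, 3), topo)
  tr <- integrate_dynamics(st, ls, dynamics_params(lambda = 0, t_max = 100,
                                                   fixed_M = 0))
  expect_equal(convergence_time(tr), 0)
})

test_that("trajectory writer emits the long CSV and summary", {
  topo <- make_complete(3)
  st <- init_state(topo, seed = 17)
  tr <- integrate_dynamics(st, landscape_directional(2),
                           dynamics_params(lambda = 0.01, t_max = 100))
  d <- tempfile()
  write_trajectory(tr, d)
  long <- read.csv(file.path(d, "trajectory.csv"))
  expect_setequal(unique(long$variable), c("rho", "M"))
  expect_equal(nrow(long), 2 * 3 * length(tr$times))
  expect_match(readLines(file.path(d, "summary.json")),
               "final_mean_fitness")
  unlink(d, recursive = TRUE)
})
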