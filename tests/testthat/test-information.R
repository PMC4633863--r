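test_that("a zero-weight synapse carries exactly zero information", {
  eqp <- equilibrated_pair_state(n = 3, w = 0.1)
  st <- eqp$state; ls <- eqp$landscape
  st$phi[1, 2] <- 0; st$phi[2, 1] <- 0
  expect_lt(abs(mutual_information_exact(st, ls, 1, 2)), 1e-12)
  M1 <- switching_probability(mean_activity(st, 1))
  expect_lt(abs(mutual_information_approx(0, M1, st$rho[1], st$rho[2])),
            1e-12)
  ## conditional equals marginal under independence
  p_on <- conditional_firing(st, ls, 1, 2, "on")
  p_off <- conditional_firing(st, ls, 1, 2, "off")
  expect_equal(p_on, p_off, tolerance = 1e-12)
})

test_that("a perfectly coupled pair at rho_j = 1/2 carries one bit", {
  expect_equal(mutual_information_from_conditionals(1, 0, 0.5), 1)
  expect_equal(mutual_information_from_conditionals(1, 0, 0.5, unit = "nats"),
               log(2))
})

test_that("assembled mutual information matches the enumerated joint table", {
  p_on <- 0.83; p_off <- 0.41; rho_j <- 0.64
  joint <- rbind(off = (1 - rho_j) * c(1 - p_off, p_off),
                 on  = rho_j * c(1 - p_on, p_on))
  expect_equal(mutual_information_from_conditionals(p_on, p_off, rho_j),
               brute_mi_bits(joint), tolerance = 1e-12)
})

test_that("conditioning on the neighbour brackets the marginal equilibrium", {
  eqp <- equilibrated_pair_state(n = 3, w = 0.15)
  st <- eqp$state; ls <- eqp$landscape
  p_on <- conditional_firing(st, ls, 1, 2, "on")
  p_off <- conditional_firing(st, ls, 1, 2, "off")
  expect_gte(p_on, p_off)      # positive weight: firing neighbour excites
  expect_gte(st$rho[1], min(p_on, p_off) - 1e-9)
  expect_lte(st$rho[1], max(p_on, p_off) + 1e-9)
})

test_that("exact information increases with the weight magnitude", {
  eqp <- equilibrated_pair_state(n = 3, w = 0.1)
  ls <- eqp$landscape
  H <- vapply(c(0.05, 0.1, 0.2, 0.4), function(w) {
    st <- eqp$state
    st$phi[1, 2] <- w
    mutual_information_exact(st, ls, 1, 2)
  }, numeric(1))
  expect_true(all(diff(H) > 0))
})

test_that("the closed-form approximation is quadratic and tracks the exact MI", {
  eqp <- equilibrated_pair_state(n = 3, w = 0.45, S = 2)
  st <- eqp$state
  M1 <- switching_probability(mean_activity(st, 1))
  ## quadratic dominance: H(2 phi) / H(phi) ~ 4
  r4 <- mutual_information_approx(0.02, M1, st$rho[1], st$rho[2]) /
    mutual_information_approx(0.01, M1, st$rho[1], st$rho[2])
  expect_equal(r4, 4, tolerance = 0.05)
  ## within 20% of the conditional-dynamics value for small weights
  ## (the state is re-equilibrated with each probe weight in place)
  for (w in c(0.05, 0.1, 0.2)) {
    eqw <- equilibrated_pair_state(n = 3, w = 0.45, S = 2, phi12 = w)
    stw <- eqw$state
    Mw <- switching_probability(mean_activity(stw, 1))
    He <- mutual_information_exact(stw, eqw$landscape, 1, 2)
    Ha <- mutual_information_approx(w, Mw, stw$rho[1], stw$rho[2])
    expect_lt(abs(Ha - He) / He, 0.2)
  }
})

test_that("per-synapse weights and information are larger in sparse circuits", {
  ## star vs complete circuit at n = 6 under the same directional problem
  n <- 6
  star <- topology(n, cbind(1, 2:n))
  comp <- make_complete(n)
  ls <- landscape_directional(5)
  run <- function(topo) {
    st <- init_state(topo, seed = 21)
    integrate_dynamics(st, ls, dynamics_params(lambda = 0.01,
                                               t_max = 3000))$final_state
  }
  f_star <- run(star); f_comp <- run(comp)
  w_star <- abs(f_star$phi[adjacency_matrix(star) == 1])
  w_comp <- abs(f_comp$phi[adjacency_matrix(comp) == 1])
  expect_gt(mean(w_star), mean(w_comp))
  ## at equal switching probability, the larger weights carry more
  ## information; H is monotone in |phi| on the approximation's domain
  H_grid <- mutual_information_approx(seq(0, 1, by = 0.05), 0.1, 0.75, 0.6)
  expect_true(all(diff(H_grid) > 0))
  H_star <- mean(mutual_information_approx(w_star, 0.1, 0.75, 0.6))
  H_comp <- mean(mutual_information_approx(w_comp, 0.1, 0.75, 0.6))
  expect_gt(H_star, H_comp)
})

test_that("synapse_information tabulates both directions of every edge", {
  eqp <- equilibrated_pair_state(n = 3, w = 0.1)
  tab <- synapse_information(eqp$state, eqp$landscape)
  expect_equal(nrow(tab), 2 * n_edges(eqp$state$topology))
  expect_true(all(tab$H_ij >= 0))
  empty <- ensemble_state(c(0.4, 0.6), matrix(0, 2, 2), topology(2))
  expect_equal(nrow(synapse_information(empty, eqp$landscape)), 0)
})
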