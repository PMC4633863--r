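test_that("synaptogenesis samples unconnected pairs by co-firing weight", {
  topo <- topology(4, rbind(c(1, 2)))      # 5 vacant pairs
  ## all rho equal: uniform over vacant pairs
  st <- ensemble_state(rep(0.5, 4), matrix(0, 4, 4) * 0, topo)
  st$phi <- matrix(0, 4, 4)
  set.seed(31)
  draws <- replicate(10000, paste(propose_synaptogenesis(st, topo),
                                  collapse = "-"))
  ct <- table(draws)
  expect_equal(length(ct), 5)
  expect_gt(chisq.test(ct)$p.value, 0.001)
  ## a single hot pair is chosen almost surely
  st2 <- ensemble_state(c(1, 0, 0, 1), matrix(0, 4, 4), topo)
  set.seed(32)
  d2 <- replicate(200, paste(propose_synaptogenesis(st2, topo),
                             collapse = "-"))
  expect_true(all(d2 == "1-4"))
  ## complete graph: no-op
  stc <- init_state(make_complete(4), seed = 33)
  expect_null(propose_synaptogenesis(stc, make_complete(4)))
})

test_that("synaptogenesis frequencies match the rho_i rho_j weights", {
  topo <- topology(5)                      # empty: all 10 pairs vacant
  rho <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  st <- ensemble_state(rho, matrix(0, 5, 5), topo)
  pairs <- t(combn(5, 2))
  w <- rho[pairs[, 1]] * rho[pairs[, 2]]
  set.seed(34)
  draws <- replicate(50000, paste(propose_synaptogenesis(st, topo),
                                  collapse = "-"))
  key <- paste(pairs[, 1], pairs[, 2], sep = "-")
  ct <- table(factor(draws, levels = key))
  expect_gt(chisq.test(ct, p = w / sum(w))$p.value, 0.001)
})

test_that("disbanding probability is maximal at zero information, decreasing", {
  expect_equal(disband_probability(0), 0.1)
  expect_equal(disband_probability(0, r_max = 0.25), 0.25)
  H <- seq(0, 2, by = 0.05)
  R <- disband_probability(H)
  expect_true(all(diff(R) < 0))
  expect_error(disband_probability(-1), "non-negative")
})

test_that("informative synapses survive disbanding sweeps longer", {
  ## 3-node path: edge 1-2 strong and informative, edge 2-3 zero weight
  topo <- topology(3, rbind(c(1, 2), c(2, 3)))
  phi <- matrix(0, 3, 3)
  phi[1, 2] <- phi[2, 1] <- 0.6
  st <- ensemble_state(c(0.85, 0.85, 0.85), phi, topo)
  ls <- landscape_directional(1)
  set.seed(35)
  surv <- replicate(1000, {
    tp <- topo
    alive <- c(TRUE, TRUE); t_dead <- c(NA, NA)
    for (step in 1:200) {
      rem <- propose_disbanding(st, ls, tp)
      if (!is.null(rem) && nrow(rem)) {
        for (r in seq_len(nrow(rem))) {
          k <- if (all(rem[r, ] == c(1, 2))) 1 else 2
          if (alive[k]) { alive[k] <- FALSE; t_dead[k] <- step }
        }
        keep <- !apply(tp$edges, 1, function(e)
          any(apply(rem, 1, function(q) all(q == e))))
        tp <- topology(3, tp$edges[keep, , drop = FALSE])
      }
      if (!any(alive)) break
    }
    t_dead[is.na(t_dead)] <- 201
    t_dead
  })
  expect_gt(mean(surv[1, ]), mean(surv[2, ]))   # informative edge lives longer
})

test_that("random rewiring conserves the synapse count and triggers at rate u", {
  topo <- make_er(8, 0.4, seed = 36)
  set.seed(36)
  hits <- 0
  for (k in 1:2000) {
    mv <- propose_random_rewire(topo, u = 0.1)
    if (!is.null(mv)) {
      hits <- hits + 1
      t2 <- apply_moves_for_test(topo, mv)
      expect_equal(n_edges(t2), n_edges(topo))
    }
  }
  p_hat <- hits / 2000
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / 2000))
  set.seed(37)
  expect_true(all(vapply(1:200, function(i)
    is.null(propose_random_rewire(topo, u = 0)), logical(1))))
})

test_that("Metropolis acceptance follows min(1, exp(dW))", {
  set.seed(38)
  expect_true(metropolis_accept(2, 1))
  expect_true(metropolis_accept(1, 1))       # exp(0) = 1
  acc <- mean(replicate(10000, metropolis_accept(0, 1)))
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 10000)
  expect_lt(abs(acc - exp(-1)), 3 * se)
})

test_that("the acceptance rule induces the implied stationary distribution", {
  ## frozen 3-node system: 8 topologies indexed by edge bitmask, fixed
  ## fitness table, symmetric single-edge-toggle proposals; the chain must
  ## match pi propto exp(W) in total variation
  W <- c(0.0, 0.9, 0.3, 1.4, 0.6, 0.2, 1.1, 0.5)
  target <- exp(W) / sum(exp(W))
  set.seed(39)
  state <- 1L
  counts <- numeric(8)
  for (it in 1:200000) {
    cand <- bitwXor(state - 1L, bitwShiftL(1L, sample(0:2, 1))) + 1L
    if (metropolis_accept(W[cand], W[state])) state <- cand
    counts[state] <- counts[state] + 1
  }
  emp <- counts / sum(counts)
  expect_lt(0.5 * sum(abs(emp - target)), 0.05)
})

test_that("a full SSP run keeps the simple-graph constraint and its records coherent", {
  rec <- run_ssp_experiment(n = 8, target = 5, S = 10, lambda = 0.01,
                            n_steps = 60, seed = 41)
  r <- rec$record
  expect_equal(nrow(r), 60)
  expect_true(all(r$d >= 0 & r$d <= choose(8, 2)))
  ## the final topology passes the constructor audit by construction
  expect_s3_class(topology(8, rec$topology$edges), "topology")
  ## rejected steps leave the running value unchanged
  expect_true(all(diff(r$W_penalized)[!r$accepted[-1]] == 0))
  ## the running best fitness is attained: accepted moves raised it overall
  expect_gte(tail(r$rel_fitness, 1), r$rel_fitness[1] - 1e-9)
})

test_that("SSP with no synapse cost climbs toward the fitness optimum", {
  rec <- run_ssp_experiment(n = 10, target = 7, S = 10, lambda = 0.01,
                            k_cost = 0, n_steps = 250, seed = 42)
  r <- rec$record
  expect_gt(max(r$rel_fitness, na.rm = TRUE), 0.7)
  expect_gt(tail(cummax(r$rel_fitness), 1), r$rel_fitness[1])
  ## evolved circuits connect the active loci into one component
  act <- which(rec$state$rho > 0.5)
  A <- adjacency_matrix(rec$topology)[act, act]
  sub <- topology(length(act), which(upper.tri(A) & A == 1, arr.ind = TRUE))
  expect_equal(n_components(sub), 1)
})
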