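## Config-driven experiment drivers reproducing the model's main regimes at
## desk scale.  Every driver returns its full configuration in a `manifest`
## element so that summary outputs can be re-created bit-for-bit from the
## returned object and the seed(s).

manifest <- function(...) {
  c(list(...), package_version = as.character(utils::packageVersion("evoneuro")))
}

#' Directional-landscape comparison: learning vs no learning vs learnt weights
#'
#' Three runs on a fully connected circuit under a symmetric directional
#' landscape: (1) coupled selection + learning; (2) the no-learning baseline
#' with naive switching probabilities (`lambda = 0`, zero weights, so
#' `M = 1/2` throughout), which settles at the mutation--selection balance;
#' (3) a re-run with the learnt weights and fresh random firing
#' probabilities, which converges much faster.
#'
#' @param n number of loci.
#' @param S selection gradient.
#' @param lambda learning rate.
#' @param t_max horizon.
#' @param seed integer seed.
#' @param conv_fraction fraction of final fitness defining convergence time.
#' @return List with trajectories `learning`, `no_learning`, `relearn`,
#'   convergence times, the `speedup` factor (no-learning-path convergence of
#'   the learnt circuit relative to the learning run), and `manifest`.
#' @export
run_directional_comparison <- function(n = 20, S = 5, lambda = 1e-3,
                                       t_max = 1e4, seed = 1,
                                       conv_fraction = 0.95) {
  topo <- make_complete(n)
  ls <- landscape_directional(S)
  st0 <- init_state(topo, seed = seed)
  learn <- integrate_dynamics(st0, ls,
                              dynamics_params(lambda = lambda, t_max = t_max))
  naive <- ensemble_state(st0$rho, matrix(0, n, n), topo)
  no_learn <- integrate_dynamics(naive, ls,
                                 dynamics_params(lambda = 0, t_max = t_max))
  st_re <- init_state(topo, seed = seed + 1L)
  relearn0 <- ensemble_state(st_re$rho, learn$final_state$phi, topo)
  relearn <- integrate_dynamics(relearn0, ls,
                                dynamics_params(lambda = 0, t_max = t_max))
  ct <- c(learning = convergence_time(learn, conv_fraction),
          no_learning = convergence_time(no_learn, conv_fraction),
          relearn = convergence_time(relearn, conv_fraction))
  list(learning = learn, no_learning = no_learn, relearn = relearn,
       convergence_times = ct,
       speedup = unname(ct["learning"] / ct["relearn"]),
       manifest = manifest(experiment = "directional_comparison", n = n,
                           S = S, lambda = lambda, t_max = t_max,
                           seed = seed, conv_fraction = conv_fraction))
}

#' Stabilizing-landscape census of active loci
#'
#' Integrates the coupled dynamics on a fully connected circuit under a
#' stabilizing landscape with target `target` and counts, per seed, how many
#' loci end with firing probability above 1/2.  At equilibrium exactly
#' `target` loci are on; which ones is contingent on the initial conditions.
#'
#' @param n number of loci.
#' @param target target count `T`.
#' @param S equivalent directional gradient; the stabilizing sharpness is
#'   `beta = S / (2 T)`.
#' @param lambda learning rate.
#' @param t_max horizon.
#' @param seeds integer vector of seeds (one run each).
#' @return List with `census` data frame (seed, census, mean_active_rho,
#'   active locus sets), the last trajectory, and `manifest`.
#' @export
run_stabilizing_census <- function(n = 20, target = 15, S = 5,
                                   lambda = 1e-3, t_max = 1e4,
                                   seeds = 1:20) {
  ls <- landscape_stabilizing(beta_from_gradient(S, target), target)
  topo <- make_complete(n)
  rows <- vector("list", length(seeds))
  active_sets <- vector("list", length(seeds))
  traj <- NULL
  for (k in seq_along(seeds)) {
    st0 <- init_state(topo, seed = seeds[k])
    traj <- integrate_dynamics(st0, ls,
                               dynamics_params(lambda = lambda,
                                               t_max = t_max))
    rho_f <- traj$final_state$rho
    act <- which(rho_f > 0.5)
    active_sets[[k]] <- act
    rows[[k]] <- data.frame(seed = seeds[k], census = length(act),
                            mean_active_rho = mean(rho_f[act]),
                            mean_inactive_rho =
                              if (length(act) < n)
                                mean(rho_f[-act]) else NA_real_)
  }
  list(census = do.call(rbind, rows), active_sets = active_sets,
       last_trajectory = traj,
       manifest = manifest(experiment = "stabilizing_census", n = n,
                           target = target, S = S, lambda = lambda,
                           t_max = t_max, seeds = seeds))
}

#' Learning outcomes on random vs complete circuit topologies
#'
#' Runs the same stabilizing-landscape problem on a fully connected circuit
#' and on Erdos-Renyi, Barabasi-Albert and Watts-Strogatz random topologies,
#' recording final relative fitness and per-node (degree, final switching
#' probability) pairs.  Random, sparse topologies typically converge to
#' suboptimal impasses; poorly connected nodes keep high switching
#' probabilities.
#'
#' @param n number of loci.
#' @param target target count.
#' @param S equivalent gradient (`beta = S / (2 T)`).
#' @param lambda learning rate.
#' @param t_max horizon.
#' @param er_r,ba_k,ws_r,ws_degree random-topology parameters.
#' @param seed integer seed (drives topology draws and initial conditions).
#' @return List with `summary` (topology, d, final relative fitness),
#'   `nodes` (topology, degree, final M, final rho), and `manifest`.
#' @export
run_topology_comparison <- function(n = 12, target = 8, S = 5,
                                    lambda = 0.01, t_max = 2000,
                                    er_r = 0.25, ba_k = 2, ws_r = 0.3,
                                    ws_degree = 4, seed = 1) {
  ls <- landscape_stabilizing(beta_from_gradient(S, target), target)
  set.seed(seed)
  topos <- list(complete = make_complete(n),
                er = make_er(n, er_r),
                ba = make_ba(n, ba_k),
                ws = make_ws(n, ws_r, ws_degree))
  summ <- NULL; nodes <- NULL
  for (nm in names(topos)) {
    st0 <- init_state(topos[[nm]], seed = seed)
    traj <- integrate_dynamics(st0, ls,
                               dynamics_params(lambda = lambda,
                                               t_max = t_max))
    rho_f <- traj$final_state$rho
    M_f <- switching_probability(mean_activity(traj$final_state))
    summ <- rbind(summ, data.frame(
      topology = nm, d = n_edges(topos[[nm]]),
      rel_fitness = utils::tail(traj$relative_fitness, 1)))
    nodes <- rbind(nodes, data.frame(
      topology = nm, node = seq_len(n), degree = degrees(topos[[nm]]),
      final_M = M_f, final_rho = rho_f))
  }
  list(summary = summ, nodes = nodes,
       manifest = manifest(experiment = "topology_comparison", n = n,
                           target = target, S = S, lambda = lambda,
                           t_max = t_max, er_r = er_r, ba_k = ba_k,
                           ws_r = ws_r, ws_degree = ws_degree, seed = seed))
}

#' Single SSP run on a stabilizing problem
#'
#' @param n number of loci.
#' @param target target count.
#' @param S equivalent gradient.
#' @param lambda learning rate.
#' @param k_cost synapse cost.
#' @param n_steps Metropolis--Hastings steps.
#' @param start_r edge probability of the Erdos-Renyi starting topology.
#' @param seed integer seed.
#' @param ... passed on to [ssp_params()].
#' @return The `"ssp_record"`, with the manifest attached as attribute
#'   `"manifest"`.
#' @export
run_ssp_experiment <- function(n = 10, target = 7, S = 10, lambda = 0.01,
                               k_cost = 0, n_steps = 500, start_r = 0.3,
                               seed = 1, ...) {
  ls <- landscape_stabilizing(beta_from_gradient(S, target), target)
  topo0 <- make_er(n, start_r, seed = seed)
  rec <- run_ssp(topo0, ls, dynamics_params(lambda = lambda),
                 ssp_params(n_steps = n_steps, k_cost = k_cost, ...),
                 seed = seed + 1L)
  attr(rec, "manifest") <- manifest(experiment = "ssp", n = n,
                                    target = target, S = S, lambda = lambda,
                                    k_cost = k_cost, n_steps = n_steps,
                                    start_r = start_r, seed = seed)
  rec
}

#' Synapse-cost sweep over SSP runs
#'
#' Replicated SSP runs across a grid of synapse costs, summarized over the
#' stationary segment of each chain.
#'
#' @param k_costs cost grid.
#' @param replicates runs per cost.
#' @param n,target,S,lambda,n_steps,start_r as in [run_ssp_experiment()].
#' @param seed base seed; run `r` of cost index `c` uses
#'   `seed + 1000 * c + r`.
#' @param last stationary segment length for averaging.
#' @param ... passed on to [ssp_params()].
#' @return List with `sweep` (a `"sweep_result"`), `means` (per-cost
#'   averages), `records`, and `manifest`.
#' @export
run_cost_sweep <- function(k_costs = c(0.01, 0.1, 0.5, 1), replicates = 4,
                           n = 10, target = 7, S = 10, lambda = 0.01,
                           n_steps = 150, start_r = 0.3, seed = 1,
                           last = 50, ...) {
  records <- list(); kc <- numeric(0); rep_id <- integer(0)
  for (ci in seq_along(k_costs)) {
    for (r in seq_len(replicates)) {
      records[[length(records) + 1L]] <-
        run_ssp_experiment(n = n, target = target, S = S, lambda = lambda,
                           k_cost = k_costs[ci], n_steps = n_steps,
                           start_r = start_r,
                           seed = seed + 1000L * ci + r, ...)
      kc <- c(kc, k_costs[ci]); rep_id <- c(rep_id, r)
    }
  }
  sweep <- cost_sweep_summary(records, kc, rep_id, last = last)
  list(sweep = sweep, means = sweep_means(sweep), records = records,
       manifest = manifest(experiment = "cost_sweep", k_costs = k_costs,
                           replicates = replicates, n = n, target = target,
                           S = S, lambda = lambda, n_steps = n_steps,
                           start_r = start_r, seed = seed, last = last))
}
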