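## Structural synaptic plasticity: a Metropolis--Hastings search over circuit
## topologies on a time scale much slower than associative learning.
##
## Each step builds one proposal topology by (a) synaptogenesis -- a new
## synapse between an unconnected pair, drawn with probability proportional
## to the co-firing weight rho_i * rho_j; (b) a disbanding sweep -- every
## existing synapse is removed independently with probability R(H) =
## r_max * exp(-h_scale * H), a decreasing function of its information
## content, so informative synapses persist; and (c), with small probability
## u, a random rewire that moves one synapse to a uniformly chosen vacant
## pair.  The inner learning dynamics are then run to equilibrium on the
## proposal, its cost-penalized fitness is compared with the incumbent's, and
## the proposal is accepted with probability min(1, exp(W_new - W_old)).

#' SSP parameters
#'
#' @param n_steps number of Metropolis--Hastings iterations.
#' @param k_cost fitness penalty per synapse (multiplicative `exp(-k d)`).
#' @param u probability of a random rewire per step.
#' @param weight_policy `"reset-all"` (all weights redrawn each proposal; the
#'   more efficient strategy) or `"keep"` (carried over, only new synapses
#'   randomized).
#' @param reset_rho redraw the firing probabilities each proposal instead of
#'   carrying the equilibrium over.
#' @param r_max maximal disbanding probability (at zero information).
#' @param h_scale decay rate of the disbanding probability per bit of
#'   synaptic information.
#' @param log_fitness compare log cost-penalized fitness in the acceptance
#'   rule (default); `FALSE` compares raw fitness values, which loses all
#'   cost sensitivity once `k_cost * d` is large.
#' @param inner_t_max,inner_steady_tol,inner_rtol,inner_atol inner-dynamics
#'   controls: horizon, early-stop rate tolerance, solver tolerances.
#' @param init_low,init_high uniform bounds for (re)drawn weights and firing
#'   probabilities.
#' @param record_every thin the per-step record to every so-many steps (1 =
#'   keep all).
#' @return A list of class `"ssp_params"`.
#' @export
ssp_params <- function(n_steps = 2000, k_cost = 0, u = 0.01,
                       weight_policy = c("reset-all", "keep"),
                       reset_rho = FALSE, r_max = 0.1, h_scale = 10,
                       log_fitness = TRUE, inner_t_max = 1500,
                       inner_steady_tol = 1e-6, inner_rtol = 1e-6,
                       inner_atol = 1e-8, init_low = 0, init_high = 0.01,
                       record_every = 1L) {
  weight_policy <- match.arg(weight_policy)
  if (u < 0 || u > 1) stop("`u` must be a probability")
  if (k_cost < 0) stop("`k_cost` must be non-negative")
  if (n_steps < 1) stop("`n_steps` must be at least 1")
  structure(as.list(environment()), class = "ssp_params")
}

#' Disbanding probability of a synapse
#'
#' `R(H) = r_max * exp(-h_scale * H)`: maximal for an uninformative synapse
#' (`H = 0`), decreasing in the synaptic information, so informative synapses
#' are unlikely to be disconnected.
#'
#' @param H synaptic mutual information (bits).
#' @param r_max maximal removal probability.
#' @param h_scale decay per bit.
#' @return Removal probabilities in `[0, r_max]`.
#' @export
disband_probability <- function(H, r_max = 0.1, h_scale = 10) {
  if (any(H < 0)) stop("`H` must be non-negative")
  r_max * exp(-h_scale * H)
}

#' Propose a new synapse (synaptogenesis)
#'
#' Samples one unconnected pair with probability proportional to the
#' co-firing weight `rho_i * rho_j`, so pairs of neurons that are both likely
#' to spike tend to get connected.
#'
#' @param state an [ensemble_state()].
#' @param topology current [topology()].
#' @return Integer pair `c(i, j)`, or `NULL` when the graph is complete.
#' @export
propose_synaptogenesis <- function(state, topology) {
  A <- adjacency_matrix(topology)
  vac <- which(upper.tri(A) & A == 0)
  if (!length(vac)) return(NULL)
  ij <- arrayInd(vac, dim(A))
  w <- state$rho[ij[, 1]] * state$rho[ij[, 2]]
  if (all(w == 0)) w <- rep(1, length(vac))
  k <- if (length(vac) == 1L) 1L else sample.int(length(vac), 1L, prob = w)
  c(ij[k, 1], ij[k, 2])
}

#' Propose synapse disbandings
#'
#' Flags every existing synapse independently for removal with probability
#' `R(H_ij)` from [disband_probability()], with `H_ij` the (approximate)
#' synaptic information of the synapse at the current state.
#'
#' @param state an [ensemble_state()].
#' @param landscape a landscape object.
#' @param topology current [topology()].
#' @param r_max,h_scale see [disband_probability()].
#' @return Integer matrix of flagged edges (possibly zero rows); `NULL` for
#'   an empty graph.
#' @export
propose_disbanding <- function(state, landscape, topology, r_max = 0.1,
                               h_scale = 10) {
  ed <- topology$edges
  if (!nrow(ed)) return(NULL)
  M <- switching_probability(mean_activity(state))
  ## symmetrized information of the undirected synapse: max over directions
  H <- vapply(seq_len(nrow(ed)), function(k) {
    i <- ed[k, 1]; j <- ed[k, 2]
    max(mutual_information_approx(state$phi[i, j], M[i],
                                  state$rho[i], state$rho[j]),
        mutual_information_approx(state$phi[j, i], M[j],
                                  state$rho[j], state$rho[i]))
  }, numeric(1))
  flag <- stats::runif(nrow(ed)) < disband_probability(H, r_max, h_scale)
  ed[flag, , drop = FALSE]
}

#' Propose a random rewire
#'
#' Removes one uniformly chosen synapse and adds one uniformly chosen vacant
#' pair, conserving the synapse count.
#'
#' @param topology current [topology()].
#' @param u trigger probability; the move happens with probability `u`.
#' @return `NULL` (not triggered or impossible) or
#'   `list(remove = c(i, j), add = c(l, m))`.
#' @export
propose_random_rewire <- function(topology, u = 0.01) {
  if (stats::runif(1) >= u) return(NULL)
  A <- adjacency_matrix(topology)
  pres <- which(upper.tri(A) & A == 1)
  vac <- which(upper.tri(A) & A == 0)
  if (!length(pres) || !length(vac)) return(NULL)
  a <- if (length(pres) == 1L) pres else sample(pres, 1L)
  b <- if (length(vac) == 1L) vac else sample(vac, 1L)
  list(remove = as.integer(arrayInd(a, dim(A))),
       add = as.integer(arrayInd(b, dim(A))))
}

#' Metropolis--Hastings acceptance
#'
#' Accepts with probability `min(1, exp(W_new - W_old))`: a proposal that
#' does not lower the comparison value is always accepted; a worse one is
#' accepted with probability `exp(W_new - W_old)`, which lets the search
#' escape impasses.
#'
#' @param W_new,W_old comparison values (cost-penalized fitness, or its log).
#' @return Logical.
#' @export
metropolis_accept <- function(W_new, W_old) {
  if (W_new >= W_old) return(TRUE)
  stats::runif(1) < exp(W_new - W_old)
}

apply_moves <- function(topology, add_pair, remove_edges, rewire) {
  A <- adjacency_matrix(topology)
  if (!is.null(add_pair)) {
    A[add_pair[1], add_pair[2]] <- 1
    A[add_pair[2], add_pair[1]] <- 1
  }
  if (!is.null(remove_edges) && nrow(remove_edges)) {
    A[remove_edges] <- 0
    A[remove_edges[, c(2, 1), drop = FALSE]] <- 0
  }
  if (!is.null(rewire)) {
    A[rewire$remove[1], rewire$remove[2]] <- 0
    A[rewire$remove[2], rewire$remove[1]] <- 0
    A[rewire$add[1], rewire$add[2]] <- 1
    A[rewire$add[2], rewire$add[1]] <- 1
  }
  topology(topology$n, which(upper.tri(A) & A == 1, arr.ind = TRUE))
}

#' Run the structural-synaptic-plasticity search
#'
#' The full Metropolis--Hastings loop: propose a rewired topology
#' (synaptogenesis + disbanding sweep + occasional random rewire), give new
#' synapses random weights (or reset all weights, per `weight_policy`), run
#' the learning dynamics to equilibrium on the proposal, evaluate the
#' cost-penalized fitness, and accept or reject.
#'
#' @param topology0 starting [topology()].
#' @param landscape a landscape object.
#' @param dyn_params a [dynamics_params()]; its `lambda` drives the inner
#'   learning runs (horizon and tolerances are taken from `ssp_params`).
#' @param params an [ssp_params()].
#' @param seed optional integer seed.
#' @return An object of class `"ssp_record"`: list with `record` (data frame:
#'   step, move, d, W_penalized, rel_fitness, accepted, n_components,
#'   mean_degree, mean_M_connected, edge_connectivity), the final `topology`,
#'   final `state`, and the input parameters.
#' @export
run_ssp <- function(topology0, landscape, dyn_params = dynamics_params(),
                    params = ssp_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- topology0$n
  topo <- topology0
  state <- init_state(topo, init_low = params$init_low,
                      init_high = params$init_high)
  inner_params <- dynamics_params(
    lambda = dyn_params$lambda, t_max = params$inner_t_max,
    rtol = params$inner_rtol, atol = params$inner_atol, n_out = 12,
    allow_negative_weights = dyn_params$allow_negative_weights,
    steady_tol = params$inner_steady_tol)
  W_cur <- -Inf
  rec <- vector("list", params$n_steps)
  relw_cur <- NA_real_
  for (s in seq_len(params$n_steps)) {
    add <- propose_synaptogenesis(state, topo)
    rem <- propose_disbanding(state, landscape, topo,
                              params$r_max, params$h_scale)
    rew <- propose_random_rewire(topo, params$u)
    cand <- apply_moves(topo, add, rem, rew)
    A_new <- adjacency_matrix(cand)
    ## weights for the proposal
    if (params$weight_policy == "reset-all") {
      phi_new <- matrix(stats::runif(n * n, params$init_low,
                                     params$init_high), n, n) * A_new
    } else {
      phi_new <- state$phi * A_new
      fresh <- A_new == 1 & adjacency_matrix(topo) == 0
      phi_new[fresh] <- stats::runif(sum(fresh), params$init_low,
                                     params$init_high)
    }
    rho_new <- if (params$reset_rho)
      stats::runif(n, params$init_low, params$init_high) else state$rho
    traj <- integrate_dynamics(ensemble_state(rho_new, phi_new, cand),
                               landscape, inner_params)
    eq <- traj$final_state
    d_new <- n_edges(cand)
    relw <- relative_fitness(landscape, eq$rho)
    W_new <- if (params$log_fitness)
      log(mean_fitness(landscape, eq$rho)) - params$k_cost * d_new
    else
      apply_synapse_cost(mean_fitness(landscape, eq$rho),
                         params$k_cost, d_new)
    acc <- metropolis_accept(W_new, W_cur)
    if (acc) {
      topo <- cand
      state <- eq
      W_cur <- W_new
      relw_cur <- relw
    }
    if (s %% params$record_every == 0L) {
      conn <- degrees(topo) > 0
      M <- switching_probability(mean_activity(state))
      rec[[s]] <- data.frame(
        step = s,
        move = paste0(if (!is.null(add)) "g" else "",
                      if (!is.null(rem) && nrow(rem)) "d" else "",
                      if (!is.null(rew)) "r" else ""),
        d = n_edges(topo),
        W_penalized = W_cur,
        rel_fitness = relw_cur,
        accepted = acc,
        n_components = n_components(topo),
        mean_degree = mean(degrees(topo)),
        mean_M_connected = if (any(conn)) mean(M[conn]) else NA_real_,
        edge_connectivity = edge_connectivity(topo))
    }
  }
  structure(list(record = do.call(rbind, rec[!vapply(rec, is.null, TRUE)]),
                 topology = topo, state = state, landscape = landscape,
                 params = params, dyn_params = dyn_params),
            class = "ssp_record")
}

#' @export
print.ssp_record <- function(x, ...) {
  r <- x$record
  cat(sprintf(paste0("SSP run: %d recorded steps, final d = %d, final",
                     " relative fitness %.4f, acceptance %.2f\n"),
              nrow(r), utils::tail(r$d, 1), utils::tail(r$rel_fitness, 1),
              mean(r$accepted)))
  invisible(x)
}

#' Write an SSP record to disk
#'
#' Per-step CSV plus the final topology as edge list and GraphML.
#'
#' @param record an `"ssp_record"`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ssp_record <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(record$record, file.path(dir, "ssp_record.csv"),
                   row.names = FALSE)
  write_edgelist(record$topology, file.path(dir, "final_topology.edgelist"))
  write_graphml(record$topology, file.path(dir, "final_topology.graphml"))
  invisible(dir)
}
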