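## Coupled selection--mutation / Oja-learning ODE system on a fixed topology.
##
## State of the infinite circuit ensemble:
##   rho_i  : probability that neuronal locus i fires (allele frequency),
##   phi_ij : directed synaptic weight from input j onto focal neuron i,
##            supported only on topology edges (two directed weights per
##            undirected synapse).
##
## Mean-field activity (variance and correlation terms neglected):
##   Y_i = sum_j phi_ij * Xbar_j,  Xbar_j = 2 rho_j - 1.
## Activity rule (switching probability, the state-dependent mutation rate):
##   M_i = (1/2) exp(-Y_i^2)  -- 1/2 for a naive neuron, -> 0 as the input
##   current grows in magnitude (a strongly inhibited neuron is stably off).
## Firing-probability dynamics (selection + symmetric switching):
##   drho_i/dt = rho_i (1 - rho_i) sigma_i + M_i (1 - 2 rho_i),
## with sigma_i the per-locus selection gradient (see selection_gradient).
## Oja learning on mean activities:
##   dphi_ij/dt = lambda (Y_i Xbar_j - Y_i^2 phi_ij),
## which drives the incoming-weight vector of each neuron to unit Euclidean
## norm while aligning it with the mean input pattern.

PAR_LEN <- 3000L
PAR_OFFSET <- 16L
MAX_COMPILED_N <- 50L

#' Ensemble state
#'
#' @param rho firing probabilities, length `n`, in `[0, 1]`.
#' @param phi `n x n` matrix of directed weights `phi[i, j]` (input `j` onto
#'   focal `i`); entries off the topology must be zero.
#' @param topology a [topology()].
#' @return An object of class `"ensemble_state"`.
#' @export
ensemble_state <- function(rho, phi, topology) {
  n <- topology$n
  if (length(rho) != n) stop("`rho` must have one entry per locus")
  if (any(rho < 0 | rho > 1)) stop("`rho` must lie in [0, 1]")
  phi <- as.matrix(phi)
  if (!all(dim(phi) == c(n, n))) stop("`phi` must be n x n")
  A <- adjacency_matrix(topology)
  if (any(phi[A == 0] != 0))
    stop("`phi` must vanish off the topology (including the diagonal)")
  structure(list(rho = as.numeric(rho), phi = phi, topology = topology),
            class = "ensemble_state")
}

#' @export
print.ensemble_state <- function(x, ...) {
  cat(sprintf("ensemble state: n = %d, mean rho = %.3f, mean |phi| = %.4f\n",
              length(x$rho), mean(x$rho),
              mean(abs(x$phi[adjacency_matrix(x$topology) == 1]))))
  invisible(x)
}

#' Random initial ensemble state
#'
#' Firing probabilities and edge weights drawn independently from
#' `U[init_low, init_high]` (both directions of each synapse drawn
#' independently).
#'
#' @param topology a [topology()].
#' @param seed optional integer seed.
#' @param init_low,init_high bounds of the uniform initial distribution.
#' @return An [ensemble_state()].
#' @export
init_state <- function(topology, seed = NULL, init_low = 0,
                       init_high = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  n <- topology$n
  A <- adjacency_matrix(topology)
  rho <- stats::runif(n, init_low, init_high)
  phi <- matrix(stats::runif(n * n, init_low, init_high), n, n) * A
  ensemble_state(rho, phi, topology)
}

#' Dynamics parameters
#'
#' @param lambda Hebbian learning rate (per time unit).  The intended regime
#'   is learning slower than selection (`lambda < S`); a warning (not an
#'   error) is issued by [integrate_dynamics()] when violated.
#' @param t_max integration horizon in time units.
#' @param rtol,atol solver tolerances.
#' @param n_out number of (log-spaced) output times.
#' @param fixed_M if non-`NULL`, freeze the switching probability at this
#'   value instead of the activity rule (the "naive M" baseline).
#' @param allow_negative_weights if `FALSE`, weights are clamped at zero from
#'   below (the no-inhibition variant).
#' @param steady_tol if non-`NULL`, stop integration early once the
#'   sup-norm of the rates falls below this value.
#' @param maxsteps solver step budget per output interval.
#' @return A list of class `"dynamics_params"`.
#' @export
dynamics_params <- function(lambda = 1e-3, t_max = 1e4, rtol = 1e-8,
                            atol = 1e-10, n_out = 200, fixed_M = NULL,
                            allow_negative_weights = TRUE,
                            steady_tol = NULL, maxsteps = 50000) {
  if (lambda < 0) stop("`lambda` must be non-negative")
  if (t_max <= 0) stop("`t_max` must be positive")
  structure(list(lambda = lambda, t_max = t_max, rtol = rtol, atol = atol,
                 n_out = n_out, fixed_M = fixed_M,
                 allow_negative_weights = allow_negative_weights,
                 steady_tol = steady_tol, maxsteps = maxsteps),
            class = "dynamics_params")
}

#' Mean input activity of each neuron
#'
#' `Y_i = sum_j phi_ij (2 rho_j - 1)`, the mean-field input current.
#'
#' @param state an [ensemble_state()].
#' @param i optional locus index; if missing the full vector is returned.
#' @return Numeric activity value(s).
#' @export
mean_activity <- function(state, i = NULL) {
  Y <- as.vector(state$phi %*% (2 * state$rho - 1))
  if (is.null(i)) Y else Y[i]
}

#' Switching probability (activity rule)
#'
#' `M(Y) = (1/2) exp(-Y^2)`: one half for a naive neuron with no net input,
#' decreasing to zero as the magnitude of the input current grows.  This is
#' the state-dependent analogue of a mutation rate.
#'
#' @param Y activity value(s).
#' @return Switching probabilities in `(0, 1/2]`.
#' @export
switching_probability <- function(Y) 0.5 * exp(-Y^2)

#' Rate of change of the firing probabilities
#'
#' Selection term `rho (1 - rho) sigma` plus the symmetric switching term
#' `M (1 - 2 rho)`, which vanishes at `rho = 1/2`, relaxes `rho` toward 1/2
#' at rate proportional to `M`, and vanishes when `M = 0`.
#'
#' @param state an [ensemble_state()].
#' @param landscape a landscape object.
#' @param M optional switching probabilities (defaults to the activity rule
#'   applied to the current state).
#' @param backend gradient backend, see [selection_gradient()].
#' @return Numeric vector `drho/dt`.
#' @export
rho_rate <- function(state, landscape, M = NULL, backend = "approx") {
  rho <- state$rho
  if (any(rho < 0 | rho > 1)) stop("state has rho outside [0, 1]")
  if (is.null(M)) M <- switching_probability(mean_activity(state))
  sigma <- selection_gradient(landscape, rho, backend = backend)
  rho * (1 - rho) * sigma + M * (1 - 2 * rho)
}

#' Rate of change of the synaptic weights (Oja rule on mean activities)
#'
#' `dphi_ij/dt = lambda (Y_i Xbar_j - Y_i^2 phi_ij)` on topology edges, zero
#' elsewhere.
#'
#' @param state an [ensemble_state()].
#' @param lambda learning rate.
#' @return `n x n` matrix `dphi/dt`.
#' @export
phi_rate <- function(state, lambda) {
  A <- adjacency_matrix(state$topology)
  xb <- 2 * state$rho - 1
  Y <- as.vector(state$phi %*% xb)
  lambda * (outer(Y, xb) - Y^2 * state$phi) * A
}

## parameter vector for the compiled RHS
pack_parms <- function(state, landscape, lambda, fixed_M, allow_neg,
                       freeze_rho, freeze_phi, steady_tol) {
  n <- length(state$rho)
  if (n > MAX_COMPILED_N)
    stop("compiled dynamics support at most ", MAX_COMPILED_N, " loci")
  pv <- numeric(PAR_LEN)
  pv[1] <- n
  pv[2] <- lambda
  if (inherits(landscape, "directional_landscape")) {
    pv[3] <- 0
    pv[PAR_OFFSET + seq_len(n)] <- rep_len(landscape$S, n)
  } else {
    pv[3] <- 1
    pv[4] <- landscape$beta
    pv[5] <- landscape$target
  }
  pv[6] <- if (is.null(fixed_M)) -1 else fixed_M
  pv[7] <- as.numeric(allow_neg)
  pv[8] <- as.numeric(freeze_rho)
  pv[9] <- as.numeric(freeze_phi)
  pv[10] <- if (is.null(steady_tol)) 0 else steady_tol
  pv[PAR_OFFSET + n + seq_len(n * n)] <- as.vector(adjacency_matrix(state$topology))
  pv
}

## plain-R RHS, same algebra as src/evodyn.c (used when compiled = FALSE)
r_rhs_factory <- function(landscape, A, lambda, fixed_M, allow_neg,
                          freeze_rho, freeze_phi) {
  n <- nrow(A)
  function(t, y, parms) {
    rho <- pmin(pmax(y[1:n], 0), 1)
    phi <- matrix(y[-(1:n)], n, n) * A
    xb <- 2 * rho - 1
    Y <- as.vector(phi %*% xb)
    M <- if (is.null(fixed_M)) switching_probability(Y) else rep(fixed_M, n)
    sigma <- selection_gradient(landscape, rho, backend = "approx")
    drho <- if (freeze_rho) numeric(n) else
      rho * (1 - rho) * sigma + M * (1 - 2 * rho)
    dphi <- if (freeze_phi) matrix(0, n, n) else
      lambda * (outer(Y, xb) - Y^2 * phi) * A
    if (!allow_neg) dphi[phi <= 0 & dphi < 0] <- 0
    list(c(drho, as.vector(dphi)))
  }
}

#' Integrate the coupled selection--learning dynamics
#'
#' Solves the `n + n_edges*2` coupled ODEs for the firing probabilities and
#' directed weights with an adaptive solver (`deSolve::lsoda`; compiled
#' right-hand side by default), reporting the state at log-spaced output
#' times.
#'
#' @param state initial [ensemble_state()].
#' @param landscape a landscape object.
#' @param params a [dynamics_params()].
#' @param compiled use the compiled right-hand side (fast path; falls back to
#'   the plain-R rates otherwise).
#' @param freeze_rho,freeze_phi hold the firing probabilities (resp. weights)
#'   fixed; useful for assessing one subsystem in isolation.
#' @return An object of class `"evo_trajectory"`: list with `times`, matrices
#'   `rho`, `M` (times x loci), array-backed `phi` (times x n^2), vectors
#'   `mean_fitness` and `relative_fitness`, the `final_state`, the rate
#'   sup-norm `rate_norm` at the end, and a `converged` flag (rate norm below
#'   `1e-6`; non-convergence is flagged, not fatal).
#' @export
integrate_dynamics <- function(state, landscape, params = dynamics_params(),
                               compiled = TRUE, freeze_rho = FALSE,
                               freeze_phi = FALSE) {
  n <- length(state$rho)
  A <- adjacency_matrix(state$topology)
  if (inherits(landscape, "directional_landscape") && params$lambda > 0 &&
      params$lambda >= min(abs(rep_len(landscape$S, n))))
    warning("learning rate lambda is not slower than selection (lambda >= S)")
  y0 <- c(state$rho, as.vector(state$phi))
  times <- unique(c(0, 10^seq(-2, log10(params$t_max),
                              length.out = params$n_out)))
  use_compiled <- compiled && n <= MAX_COMPILED_N
  steady <- !is.null(params$steady_tol)
  if (use_compiled) {
    pv <- pack_parms(state, landscape, params$lambda, params$fixed_M,
                     params$allow_negative_weights, freeze_rho, freeze_phi,
                     params$steady_tol)
    if (steady) {
      out <- deSolve::lsodar(y0, times, func = "evo_derivs", parms = pv,
                             dllname = "evoneuro", initfunc = "evo_init",
                             rootfunc = "evo_root", nroot = 1L,
                             rtol = params$rtol, atol = params$atol,
                             maxsteps = params$maxsteps)
    } else {
      out <- deSolve::ode(y0, times, func = "evo_derivs", parms = pv,
                          dllname = "evoneuro", initfunc = "evo_init",
                          method = "lsoda", rtol = params$rtol,
                          atol = params$atol, maxsteps = params$maxsteps)
    }
  } else {
    rhs <- r_rhs_factory(landscape, A, params$lambda, params$fixed_M,
                         params$allow_negative_weights, freeze_rho,
                         freeze_phi)
    if (steady) {
      rootf <- function(t, y, p) max(abs(unlist(rhs(t, y, p)))) -
        params$steady_tol
      out <- deSolve::lsodar(y0, times, rhs, NULL, rootfunc = rootf,
                             rtol = params$rtol, atol = params$atol,
                             maxsteps = params$maxsteps)
    } else {
      out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                          rtol = params$rtol, atol = params$atol,
                          maxsteps = params$maxsteps)
    }
  }
  out <- out[stats::complete.cases(out), , drop = FALSE]
  tt <- out[, 1]
  rho_m <- out[, 1 + seq_len(n), drop = FALSE]
  rho_m <- pmin(pmax(rho_m, 0), 1)          # project solver drift to [0, 1]
  phi_m <- out[, 1 + n + seq_len(n * n), drop = FALSE]
  M_m <- t(apply(out, 1, function(row) {
    phi <- matrix(row[1 + n + seq_len(n * n)], n, n)
    Y <- as.vector(phi %*% (2 * pmin(pmax(row[1 + seq_len(n)], 0), 1) - 1))
    if (is.null(params$fixed_M)) switching_probability(Y)
    else rep(params$fixed_M, n)
  }))
  wbar <- apply(rho_m, 1, function(r) mean_fitness(landscape, r))
  relw <- wbar / max_fitness(landscape, n)
  fin <- ensemble_state(rho_m[nrow(rho_m), ],
                        matrix(phi_m[nrow(phi_m), ], n, n) * A,
                        state$topology)
  rate_norm <- max(abs(c(
    rho_rate(fin, landscape,
             M = if (is.null(params$fixed_M)) NULL else
               rep(params$fixed_M, n)),
    phi_rate(fin, params$lambda))))
  structure(list(times = tt, rho = rho_m, phi = phi_m, M = M_m,
                 mean_fitness = wbar, relative_fitness = relw,
                 final_state = fin, rate_norm = rate_norm,
                 converged = rate_norm < 1e-6,
                 landscape = landscape, params = params),
            class = "evo_trajectory")
}

#' @export
print.evo_trajectory <- function(x, ...) {
  cat(sprintf(paste0("trajectory: %d loci, t in [0, %g], final relative",
                     " fitness %.4f, %s\n"),
              ncol(x$rho), max(x$times), utils::tail(x$relative_fitness, 1),
              if (x$converged) "converged" else
                sprintf("rate norm %.2g at t_max", x$rate_norm)))
  invisible(x)
}

#' Time to reach a fraction of the final mean fitness
#'
#' The fitness trace is made monotone by a running maximum before
#' thresholding, so transient dips do not register as convergence.
#'
#' @param trajectory an `"evo_trajectory"`.
#' @param fraction fraction of the final mean fitness to reach.
#' @return First output time at which the smoothed mean fitness is at least
#'   `fraction` times its final value, or `NA_real_` if never attained.
#' @export
convergence_time <- function(trajectory, fraction = 0.95) {
  w <- cummax(trajectory$mean_fitness)
  hit <- which(w >= fraction * w[length(w)])
  if (!length(hit)) return(NA_real_)
  trajectory$times[hit[1]]
}

#' Write a trajectory to disk
#'
#' Long-format CSV (`t`, `variable`, `index`, `value`) for `rho` and `M`, a
#' dense final-weights CSV, and a JSON-like summary (written with base R).
#'
#' @param trajectory an `"evo_trajectory"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(trajectory, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- ncol(trajectory$rho)
  long <- rbind(
    data.frame(t = rep(trajectory$times, n),
               variable = "rho",
               index = rep(seq_len(n), each = length(trajectory$times)),
               value = as.vector(trajectory$rho)),
    data.frame(t = rep(trajectory$times, n),
               variable = "M",
               index = rep(seq_len(n), each = length(trajectory$times)),
               value = as.vector(trajectory$M)))
  utils::write.csv(long, file.path(dir, "trajectory.csv"), row.names = FALSE)
  utils::write.csv(trajectory$final_state$phi,
                   file.path(dir, "final_weights.csv"), row.names = FALSE)
  summ <- c(sprintf('"final_mean_fitness": %.10g',
                    utils::tail(trajectory$mean_fitness, 1)),
            sprintf('"final_relative_fitness": %.10g',
                    utils::tail(trajectory$relative_fitness, 1)),
            sprintf('"rate_norm": %.3g', trajectory$rate_norm),
            sprintf('"converged": %s',
                    if (trajectory$converged) "true" else "false"),
            sprintf('"convergence_time_95": %.6g',
                    convergence_time(trajectory)))
  writeLines(paste0("{", paste(summ, collapse = ", "), "}"),
             file.path(dir, "summary.json"))
  invisible(dir)
}
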