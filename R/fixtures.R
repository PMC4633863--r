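## Tiny deterministic systems and brute-force oracles.  The oracles
## re-implement the model equations independently of the main code paths
## (no shared rate functions), so they can catch transcription errors there.

#' Enumerate the joint configuration distribution of independent loci
#'
#' All `2^n` spin configurations with their product-measure probabilities.
#'
#' @param rho firing probabilities (length at most 12).
#' @return Data frame with columns `x1..xn` (values -1/+1) and `prob`.
#' @export
enumerate_joint <- function(rho) {
  n <- length(rho)
  if (n > 12) stop("refusing to enumerate more than 2^12 configurations")
  if (any(rho < 0 | rho > 1)) stop("`rho` must lie in [0, 1]")
  grid <- expand.grid(rep(list(c(-1, 1)), n))
  names(grid) <- paste0("x", seq_len(n))
  prob <- apply(grid, 1, function(x)
    prod(ifelse(x == 1, rho, 1 - rho)))
  cbind(grid, prob = prob)
}

#' Fixed-step explicit Euler integration of the coupled dynamics
#'
#' Independent re-integration of the selection--switching and Oja equations
#' with a hand-written Euler stepper; used to cross-validate the adaptive
#' solver.  If an instability is detected (`rho` leaving `[0, 1]` by more
#' than `tol`), the step is halved and the integration restarted, up to
#' `max_retries` times.
#'
#' @param state initial [ensemble_state()].
#' @param landscape a landscape object (directional `S` or stabilizing
#'   `(beta, target)`).
#' @param t_max horizon.
#' @param dt step size.
#' @param lambda learning rate.
#' @param fixed_M optional frozen switching probability.
#' @param tol boundary-excursion tolerance triggering a retry.
#' @param max_retries maximum number of dt halvings.
#' @return List with `rho`, `phi` at `t_max` and the `dt` actually used.
#' @export
euler_oracle <- function(state, landscape, t_max, dt, lambda = 0,
                         fixed_M = NULL, tol = 1e-6, max_retries = 8) {
  n <- length(state$rho)
  A <- adjacency_matrix(state$topology)
  directional <- inherits(landscape, "directional_landscape")
  S <- if (directional) rep_len(landscape$S, n) else NULL
  for (attempt in 0:max_retries) {
    rho <- state$rho
    phi <- state$phi
    ok <- TRUE
    nstep <- ceiling(t_max / dt)
    for (s in seq_len(nstep)) {
      xb <- 2 * rho - 1
      Y <- as.vector(phi %*% xb)
      M <- if (is.null(fixed_M)) 0.5 * exp(-Y^2) else rep(fixed_M, n)
      sigma <- if (directional) S else
        2 * landscape$beta *
          (landscape$target - (sum(rho) - rho) - 0.5)
      rho_new <- rho + dt * (rho * (1 - rho) * sigma + M * (1 - 2 * rho))
      phi_new <- phi + dt * lambda * (outer(Y, xb) - Y^2 * phi) * A
      if (any(rho_new < -tol | rho_new > 1 + tol)) { ok <- FALSE; break }
      rho <- pmin(pmax(rho_new, 0), 1)
      phi <- phi_new
    }
    if (ok) return(list(rho = rho, phi = phi, dt = dt))
    dt <- dt / 2
  }
  stop("Euler oracle unstable even after ", max_retries, " dt halvings")
}

#' Mutation--selection balance of a single locus (bisection oracle)
#'
#' Root of `S rho (1 - rho) + M (1 - 2 rho)` in `(1/2, 1]`: the equilibrium
#' firing probability under a constant directional gradient `S` and constant
#' switching probability `M`, found by hand-written bisection.
#'
#' @param S constant selection gradient, non-negative.
#' @param M constant switching probability in `[0, 1/2]`.
#' @param tol bisection tolerance.
#' @return The balance firing probability `rho*`.
#' @export
exact_balance_root <- function(S, M, tol = 1e-12) {
  if (M < 0 || M > 0.5) stop("`M` must lie in [0, 1/2]")
  if (S < 0) stop("`S` must be non-negative")
  if (M == 0) return(1)
  if (S == 0) return(0.5)
  g <- function(r) S * r * (1 - r) + M * (1 - 2 * r)
  lo <- 0.5; hi <- 1
  if (g(lo) < 0 || g(hi) > 0)
    stop("no balance root in (1/2, 1]: inconsistent rate function")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Tiny fully specified system for oracle tests
#'
#' A deterministic toy system (no RNG): `n <= 4` loci on an explicit
#' topology with fixed firing probabilities and weights.
#'
#' @param n number of loci (2--4).
#' @param landscape optional landscape (default: directional `S = 1`).
#' @return List with `state`, `topology`, `landscape`.
#' @export
toy_system <- function(n = 3, landscape = landscape_directional(1)) {
  if (n < 2 || n > 4) stop("toy systems have 2 to 4 loci")
  topo <- make_complete(n)
  rho <- seq(0.3, 0.7, length.out = n)
  A <- adjacency_matrix(topo)
  phi <- (outer(seq_len(n), seq_len(n), function(i, j) 0.05 * i + 0.02 * j) *
            A)
  list(state = ensemble_state(rho, phi, topo), topology = topo,
       landscape = landscape)
}
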