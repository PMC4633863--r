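## Synaptic mutual information.
##
## The information content of synapse {i, j} is the mutual information
## between the binary states X_i and X_j.  The exact route conditions the
## switching probability of the focal neuron i on the state of j (weights
## frozen: only the capacity of this one synapse is assessed), relaxes locus
## i to its conditional equilibrium, and assembles the joint distribution
## P(X_i, X_j) = P(X_i | X_j) P(X_j) with P(X_j = on) = rho_j.  The
## approximate route is the chi-square (small-dependence) expansion of the
## same quantity around the marginal equilibrium of locus i, which is
## proportional to phi_ij^2.

## equilibrium of a single locus under fixed switching probability m:
## root of rho (1 - rho) sigma_i(rho) + m (1 - 2 rho) in [0, 1].
locus_equilibrium <- function(state, landscape, i, m, backend = "approx") {
  g <- function(r) {
    rho <- state$rho
    rho[i] <- r
    sigma <- selection_gradient(landscape, rho, backend = backend)[i]
    r * (1 - r) * sigma + m * (1 - 2 * r)
  }
  if (m <= 0) {
    s0 <- sign(g(0.5))
    return(if (s0 > 0) 1 else if (s0 < 0) 0 else 0.5)
  }
  stats::uniroot(g, c(0, 1), tol = 1e-13)$root
}

#' Conditional firing probability of a neuron given a neighbour's state
#'
#' Fixes neuron `j` to off (`rho_j = 0`) or on (`rho_j = 1`), recomputes the
#' conditioned activity `Y_i|j` and switching probability `M_i|j` of the
#' focal neuron `i` with all weights frozen, and relaxes locus `i` alone to
#' its equilibrium under the conditioned switching rate.  Only the switching
#' probability is conditioned; the fitness terms keep the ensemble `rho`, so
#' a zero-weight (or absent) synapse yields conditional = marginal.
#'
#' @param state an [ensemble_state()], typically near equilibrium.
#' @param landscape a landscape object.
#' @param i focal locus.
#' @param j conditioning locus.
#' @param x_j `"on"` or `"off"`.
#' @param backend selection-gradient backend.
#' @return Conditional firing probability of locus `i`.
#' @export
conditional_firing <- function(state, landscape, i, j,
                               x_j = c("on", "off"), backend = "approx") {
  x_j <- match.arg(x_j)
  xb <- 2 * state$rho - 1
  x_val <- if (x_j == "on") 1 else -1
  Y_cond <- sum(state$phi[i, ] * xb) - state$phi[i, j] * xb[j] +
    state$phi[i, j] * x_val
  M_cond <- switching_probability(Y_cond)
  locus_equilibrium(state, landscape, i, M_cond, backend = backend)
}

#' Mutual information from a pair of conditional probabilities
#'
#' Assembles the joint `P(X_i, X_j) = P(X_i | X_j) P(X_j)` from the two
#' conditional firing probabilities of `i` and the marginal `rho_j`, and
#' returns the mutual information.
#'
#' @param p_on conditional firing probability of `i` given `j` on.
#' @param p_off conditional firing probability of `i` given `j` off.
#' @param rho_j marginal firing probability of `j`.
#' @param unit `"bits"` (default) or `"nats"`.
#' @return Mutual information, non-negative.
#' @export
mutual_information_from_conditionals <- function(p_on, p_off, rho_j,
                                                 unit = c("bits", "nats")) {
  unit <- match.arg(unit)
  if (p_on == p_off) return(0)     # independence, exactly
  pj <- c(off = 1 - rho_j, on = rho_j)
  cond <- rbind(off = c(1 - p_off, p_off), on = c(1 - p_on, p_on))
  J <- cond * pj                   # joint, rows X_j, cols X_i (off, on)
  pi_marg <- colSums(J)
  H <- 0
  for (a in 1:2) for (b in 1:2) {
    if (J[a, b] > 0)
      H <- H + J[a, b] * log(J[a, b] / (pj[a] * pi_marg[b]))
  }
  H <- max(H, 0)
  if (unit == "bits") H / log(2) else H
}

#' Exact synaptic mutual information (conditional-dynamics route)
#'
#' @param state an [ensemble_state()].
#' @param landscape a landscape object.
#' @param i,j the synapse endpoints (focal neuron `i`).
#' @param unit `"bits"` or `"nats"`.
#' @param backend selection-gradient backend.
#' @return `H_ij >= 0`; exactly 0 when `phi_ij = 0`.
#' @export
mutual_information_exact <- function(state, landscape, i, j,
                                     unit = c("bits", "nats"),
                                     backend = "approx") {
  unit <- match.arg(unit)
  p_on <- conditional_firing(state, landscape, i, j, "on", backend)
  p_off <- conditional_firing(state, landscape, i, j, "off", backend)
  mutual_information_from_conditionals(p_on, p_off, state$rho[j], unit)
}

#' Approximate synaptic mutual information (Gaussian-landscape closure)
#'
#' Chi-square expansion of the exact mutual information around the marginal
#' equilibrium of the focal locus.  With the focal neuron at its own
#' equilibrium `rho_i` under switching probability `M_i` (which implies the
#' activity magnitude `Y0 = sqrt(log(1 / (2 M_i)))`), conditioning the
#' neighbour spreads the input current by `+/- phi` around the baseline
#' `Yb = Y0 - phi (2 rho_j - 1)` (the activity without the synapse's own
#' mean contribution), shifting the Gaussian switching probability by
#' `dM = (exp(-(Yb + phi)^2) - exp(-(Yb - phi)^2)) / 2`, the conditional
#' equilibrium by `delta = dM (1 - 2 rho_i) rho_i (1 - rho_i) /
#' (M_i ((1 - 2 rho_i)^2 + 2 rho_i (1 - rho_i)))`, and
#' `H ~ delta^2 rho_j (1 - rho_j) / (2 ln 2 rho_i (1 - rho_i))`.
#' `H` grows quadratically in the weight for small `|phi|` (the quadratic
#' term dominates the switching-rate dependence), increases with `|phi|`,
#' and is exactly 0 at `phi = 0`.  The expansion is accurate for weights
#' small relative to the operating activity (`|phi|` below about `Y0`).
#'
#' @param phi_ij synaptic weight.
#' @param M_i switching probability of the focal neuron at assessment.
#' @param rho_i,rho_j marginal firing probabilities.
#' @param unit `"bits"` or `"nats"`.
#' @return Approximate `H_ij >= 0`.
#' @export
mutual_information_approx <- function(phi_ij, M_i, rho_i = 0.5, rho_j = 0.5,
                                      unit = c("bits", "nats")) {
  unit <- match.arg(unit)
  M_i <- pmin(M_i, 0.5)
  Y0 <- sqrt(pmax(0, log(1 / (2 * M_i))))
  Yb <- Y0 - phi_ij * (2 * rho_j - 1)
  dM <- 0.5 * (exp(-(Yb + phi_ij)^2) - exp(-(Yb - phi_ij)^2))
  denom <- M_i * ((2 * rho_i - 1)^2 + 2 * rho_i * (1 - rho_i))
  delta <- dM * (1 - 2 * rho_i) * rho_i * (1 - rho_i) / denom
  H <- delta^2 * rho_j * (1 - rho_j) /
    (2 * log(2) * rho_i * (1 - rho_i))
  degenerate <- rep_len(rho_i <= 0 | rho_i >= 1 | M_i <= 1e-12, length(H))
  H[degenerate] <- 0
  if (unit == "nats") H <- H * log(2)
  H
}

#' Synaptic information of every synapse in a state
#'
#' @param state an [ensemble_state()].
#' @param landscape a landscape object.
#' @param method `"approx"` (default) or `"exact"`.
#' @param unit `"bits"` or `"nats"`.
#' @return Data frame with one row per directed pair on an edge: `i`, `j`,
#'   `phi_ij`, `H_ij`.
#' @export
synapse_information <- function(state, landscape,
                                method = c("approx", "exact"),
                                unit = c("bits", "nats")) {
  method <- match.arg(method)
  unit <- match.arg(unit)
  ed <- state$topology$edges
  if (!nrow(ed))
    return(data.frame(i = integer(0), j = integer(0),
                      phi_ij = numeric(0), H_ij = numeric(0)))
  pairs <- rbind(ed, ed[, c(2, 1), drop = FALSE])
  M <- switching_probability(mean_activity(state))
  H <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (method == "exact")
      mutual_information_exact(state, landscape, i, j, unit)
    else
      mutual_information_approx(state$phi[i, j], M[i],
                                state$rho[i], state$rho[j], unit)
  }, numeric(1))
  data.frame(i = pairs[, 1], j = pairs[, 2],
             phi_ij = state$phi[pairs], H_ij = H)
}
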