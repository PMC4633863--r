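## Fitness landscapes over circuit configurations x in {-1, +1}^n.
##
## The network output Omega is the COUNT of firing (+1) loci.  Stabilizing
## selection rewards configurations whose output matches a target count T
## through the Gaussian fitness W = exp(-beta * (T - Omega)^2); directional
## selection has a constant per-locus log-fitness gradient S_i,
## W = exp(sum_i S_i * 1[x_i = +1]).
##
## Under the product-measure (Hardy-Weinberg-like) assumption the loci are
## independent across the ensemble, so every expectation over circuit
## configurations factorizes through the Poisson-binomial distribution of the
## on-count.

#' Directional fitness landscape
#'
#' Constant selection gradient per neuronal locus: the log fitness of a
#' configuration is `sum(S[i] * (x[i] == +1))`, i.e. every additional firing
#' neuron multiplies fitness by `exp(S_i)`.
#'
#' @param S selection gradient; a scalar (symmetric landscape) or a vector of
#'   per-locus gradients.
#' @return An object of class `c("directional_landscape", "landscape")`.
#' @export
landscape_directional <- function(S) {
  if (any(!is.finite(S))) stop("`S` must be finite")
  structure(list(S = as.numeric(S)),
            class = c("directional_landscape", "landscape"))
}

#' Stabilizing (Gaussian) fitness landscape
#'
#' `W = exp(-beta * (T - Omega)^2)` where `Omega` is the number of firing
#' neurons and `T` the target count.  Maximal fitness 1 is reached exactly at
#' `Omega = T`.
#'
#' @param beta selection sharpness, positive.
#' @param target target number of spiking neurons, non-negative.
#' @return An object of class `c("stabilizing_landscape", "landscape")`.
#' @export
landscape_stabilizing <- function(beta, target) {
  if (beta <= 0) stop("`beta` must be positive")
  if (target < 0) stop("`target` must be non-negative")
  structure(list(beta = beta, target = target),
            class = c("stabilizing_landscape", "landscape"))
}

#' @export
print.landscape <- function(x, ...) {
  if (inherits(x, "directional_landscape"))
    cat("directional landscape, S =", format(x$S), "\n")
  else
    cat(sprintf("stabilizing landscape, beta = %g, target T = %g\n",
                x$beta, x$target))
  invisible(x)
}

#' Directional gradient equivalent to a distant stabilizing target
#'
#' When the current output is far below the target, the stabilizing landscape
#' acts like a directional one with gradient `S = 2 * beta * T`.
#'
#' @param beta stabilizing sharpness.
#' @param target target count `T`.
#' @return The equivalent gradient `S`.
#' @export
gradient_from_target <- function(beta, target) {
  if (beta <= 0) stop("`beta` must be positive")
  if (target < 0) stop("`target` must be non-negative")
  2 * beta * target
}

#' Stabilizing sharpness implied by a directional gradient
#' @param S directional gradient.
#' @param target target count `T`.
#' @return `beta = S / (2 * T)`.
#' @export
beta_from_gradient <- function(S, target) {
  if (target <= 0) stop("`target` must be positive")
  S / (2 * target)
}

#' Network output of a spin configuration
#'
#' The output evaluation `Omega` is the number of firing (`+1`) neurons.
#'
#' @param x vector with entries in `{-1, +1}`.
#' @return Integer count of `+1` entries.
#' @export
output_of_state <- function(x) {
  if (!all(x %in% c(-1, 1))) stop("states must be -1 or +1")
  sum(x == 1)
}

#' Fitness of a network output
#'
#' @param landscape a [landscape_directional()] (symmetric `S` only) or
#'   [landscape_stabilizing()].
#' @param omega network output (count of firing neurons); vectorized.
#' @return Fitness value(s) `W`.
#' @export
fitness <- function(landscape, omega) UseMethod("fitness")

#' @export
fitness.stabilizing_landscape <- function(landscape, omega) {
  exp(-landscape$beta * (landscape$target - omega)^2)
}

#' @export
fitness.directional_landscape <- function(landscape, omega) {
  if (length(unique(landscape$S)) > 1L)
    stop("per-locus gradients: use fitness_state() on a full configuration")
  exp(landscape$S[1] * omega)
}

#' Fitness of a full spin configuration
#' @param landscape a landscape object.
#' @param x configuration vector in `{-1, +1}^n`.
#' @return Fitness `W`.
#' @export
fitness_state <- function(landscape, x) {
  if (!all(x %in% c(-1, 1))) stop("states must be -1 or +1")
  if (inherits(landscape, "directional_landscape")) {
    S <- rep_len(landscape$S, length(x))
    exp(sum(S[x == 1]))
  } else {
    fitness(landscape, sum(x == 1))
  }
}

## Distribution of the on-count of loci with firing probabilities `rho`:
## Poisson-binomial probabilities by the O(n^2) convolution recursion.
on_count_distribution <- function(rho) {
  p <- 1
  for (r in rho) p <- c(p * (1 - r), 0) + c(0, p * r)
  p  # length(rho) + 1 values for counts 0..n
}

#' Locus-marginal fitness terms
#'
#' Expectations of the configuration fitness conditional on the state of one
#' locus, under independent loci with `P(X_j = +1) = rho_j`:
#' `W_on[i] = E[W | X_i = +1]`, `W_off[i] = E[W | X_i = -1]`, and the mean
#' `W_bar = rho_i W_on + (1 - rho_i) W_off` (identical for every locus).
#'
#' Two backends are available.  `"exact"` computes the conditional
#' expectations through the Poisson-binomial distribution of the on-count of
#' the other `n - 1` loci.  `"approx"` is the first-order (Gaussian) closure
#' that tracks only the mean and variance of the output: it is exact for
#' directional landscapes and agrees with the exact backend to first order in
#' `beta` for stabilizing ones.
#'
#' @param landscape a landscape object.
#' @param rho vector of firing probabilities in `[0, 1]`.
#' @param backend `"exact"` or `"approx"`.
#' @return List with numeric vectors `W_on`, `W_off`, `W_bar`.
#' @export
locus_fitness_terms <- function(landscape, rho,
                                backend = c("exact", "approx")) {
  backend <- match.arg(backend)
  if (any(rho < 0 | rho > 1)) stop("`rho` must lie in [0, 1]")
  n <- length(rho)
  if (inherits(landscape, "directional_landscape")) {
    S <- rep_len(landscape$S, n)
    f <- rho * exp(S) + (1 - rho)     # per-locus fitness factor
    tot <- prod(f)
    W_on <- exp(S) * tot / f
    W_off <- tot / f
  } else if (backend == "exact") {
    beta <- landscape$beta; target <- landscape$target
    W_on <- W_off <- numeric(n)
    for (i in seq_len(n)) {
      pk <- on_count_distribution(rho[-i])     # counts 0..n-1
      k <- 0:(n - 1)
      W_on[i] <- sum(pk * fitness(landscape, k + 1))
      W_off[i] <- sum(pk * fitness(landscape, k))
    }
  } else {
    beta <- landscape$beta; target <- landscape$target
    Kbar <- sum(rho) - rho                    # mean on-count of other loci
    V <- sum(rho * (1 - rho)) - rho * (1 - rho)
    W_on <- exp(-beta * ((target - Kbar - 1)^2 + V))
    W_off <- exp(-beta * ((target - Kbar)^2 + V))
  }
  list(W_on = W_on, W_off = W_off, W_bar = rho * W_on + (1 - rho) * W_off)
}

#' Per-locus selection gradient
#'
#' The selective force entering the firing-probability dynamics.  The
#' `"approx"` backend returns the log-fitness gradient
#' `E[ln W | X_i = +1] - E[ln W | X_i = -1]` under the first-order closure:
#' `S_i` for directional landscapes (the constant-gradient property) and
#' `2 * beta * (T - Kbar_i - 1/2)` for stabilizing ones, where `Kbar_i` is
#' the expected on-count of the other loci.  The `"exact"` backend returns
#' the fitness-ratio differential `(W_on - W_off) / W_bar`; the two agree to
#' first order in the selection strength.
#'
#' @param landscape a landscape object.
#' @param rho firing probabilities.
#' @param backend `"approx"` (default, used by the dynamics) or `"exact"`.
#' @return Numeric vector of per-locus gradients.
#' @export
selection_gradient <- function(landscape, rho,
                               backend = c("approx", "exact")) {
  backend <- match.arg(backend)
  n <- length(rho)
  if (backend == "approx") {
    if (inherits(landscape, "directional_landscape"))
      return(rep_len(landscape$S, n))
    Kbar <- sum(rho) - rho
    return(2 * landscape$beta * (landscape$target - Kbar - 0.5))
  }
  ft <- locus_fitness_terms(landscape, rho, backend = "exact")
  (ft$W_on - ft$W_off) / ft$W_bar
}

#' Mean fitness of the ensemble
#'
#' `E[W]` under independent loci, and the same normalized by the maximal
#' attainable fitness.
#'
#' @param landscape a landscape object.
#' @param rho firing probabilities.
#' @return `mean_fitness` returns `E[W]`; `relative_fitness` returns
#'   `E[W] / max_x W(x)`.
#' @export
mean_fitness <- function(landscape, rho) {
  if (inherits(landscape, "directional_landscape")) {
    S <- rep_len(landscape$S, length(rho))
    prod(rho * exp(S) + (1 - rho))
  } else {
    pk <- on_count_distribution(rho)
    sum(pk * fitness(landscape, 0:length(rho)))
  }
}

#' @rdname mean_fitness
#' @export
relative_fitness <- function(landscape, rho) {
  mean_fitness(landscape, rho) / max_fitness(landscape, length(rho))
}

max_fitness <- function(landscape, n) {
  if (inherits(landscape, "directional_landscape")) {
    S <- rep_len(landscape$S, n)
    exp(sum(S[S > 0]))
  } else {
    if (landscape$target <= n) 1 else fitness(landscape, n)
  }
}

#' Multiplicative synapse cost
#'
#' Penalizes a fitness value by `exp(-k_cost * d)` where `d` is the number of
#' synapses.
#'
#' @param W fitness value(s).
#' @param k_cost cost per synapse, non-negative.
#' @param d synapse count, non-negative.
#' @return Penalized fitness `W * exp(-k_cost * d)`.
#' @export
apply_synapse_cost <- function(W, k_cost, d) {
  if (k_cost < 0) stop("`k_cost` must be non-negative")
  if (any(d < 0)) stop("`d` must be non-negative")
  W * exp(-k_cost * d)
}
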