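## Brute-force oracles, written independently of the package's main paths.

## global minimum edge cut by exhausting all 2^(n-1) bipartitions
brute_min_cut <- function(topo) {
  n <- topo$n
  A <- adjacency_matrix(topo)
  if (igraph::components(as_igraph(topo))$no > 1) return(0L)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    side <- c(as.logical(bitwAnd(mask, 2^(0:(n - 2)))), FALSE)
    cut <- sum(A[side, !side])
    if (cut < best) best <- cut
  }
  as.integer(best)
}

## Spearman correlation as rank-then-Pearson, by hand
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## locus fitness terms by full 2^n enumeration with product weights
brute_locus_terms <- function(landscape, rho) {
  n <- length(rho)
  tab <- enumerate_joint(rho)
  X <- as.matrix(tab[, seq_len(n)])
  W <- apply(X, 1, function(x) fitness_state(landscape, x))
  W_on <- W_off <- numeric(n)
  for (i in seq_len(n)) {
    on <- X[, i] == 1
    W_on[i] <- sum(tab$prob[on] * W[on]) / sum(tab$prob[on])
    W_off[i] <- sum(tab$prob[!on] * W[!on]) / sum(tab$prob[!on])
  }
  list(W_on = W_on, W_off = W_off, W_bar = sum(tab$prob * W))
}

## mean fitness by full enumeration
brute_mean_fitness <- function(landscape, rho) {
  tab <- enumerate_joint(rho)
  X <- as.matrix(tab[, seq_len(length(rho))])
  sum(tab$prob * apply(X, 1, function(x) fitness_state(landscape, x)))
}

## mutual information from an explicit 2x2 joint table
brute_mi_bits <- function(joint) {
  pi_ <- rowSums(joint); pj <- colSums(joint)
  H <- 0
  for (a in 1:2) for (b in 1:2)
    if (joint[a, b] > 0)
      H <- H + joint[a, b] * log2(joint[a, b] / (pi_[a] * pj[b]))
  unname(H)
}

## apply a rewire move to a topology (test-side re-implementation)
apply_moves_for_test <- function(topo, mv) {
  A <- adjacency_matrix(topo)
  A[mv$remove[1], mv$remove[2]] <- A[mv$remove[2], mv$remove[1]] <- 0
  A[mv$add[1], mv$add[2]] <- A[mv$add[2], mv$add[1]] <- 1
  topology(topo$n, which(upper.tri(A) & A == 1, arr.ind = TRUE))
}

## an ensemble state at the marginal equilibrium of every locus, for
## information tests: complete graph, uniform weights w except the probe
## weight phi12 on edge 1->2, all loci relaxed under frozen weights
equilibrated_pair_state <- function(n = 3, w = 0.1, S = 1, phi12 = w,
                                    rho_start = 0.7, iters = 300) {
  topo <- make_complete(n)
  A <- adjacency_matrix(topo)
  phi <- w * A
  phi[1, 2] <- phi12
  ls <- landscape_directional(S)
  rho <- rep(rho_start, n)
  g <- function(r, m) r * (1 - r) * S + m * (1 - 2 * r)
  for (k in seq_len(iters)) {
    Y <- as.vector(phi %*% (2 * rho - 1))
    M <- switching_probability(Y)
    rho <- vapply(seq_len(n), function(i)
      stats::uniroot(g, c(0, 1), m = M[i], tol = 1e-13)$root, numeric(1))
  }
  list(state = ensemble_state(rho, phi, topo), landscape = ls)
}
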