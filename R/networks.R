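## Circuit topologies: undirected simple graphs on n neuronal loci.
## An edge is a synapse; weights live in the dynamics module, not here.

#' Circuit topology
#'
#' An undirected simple graph on `n` neuronal loci.  Self-loops and multiple
#' edges are rejected at construction, mirroring the model's constraint that
#' a pair of neurons carries at most one synapse.
#'
#' @param n number of neuronal loci (nodes).
#' @param edges two-column integer matrix of 1-based node pairs, one row per
#'   synapse; order within a row is irrelevant.  May have zero rows.
#' @return An object of class `"topology"`: a list with elements `n` and
#'   `edges` (canonicalized so that `edges[, 1] < edges[, 2]`, rows sorted).
#' @export
topology <- function(n, edges = matrix(integer(0), 0, 2)) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("`n` must be a single positive integer")
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(is.na(edges)) || any(edges < 1L) || any(edges > n))
      stop("edge endpoints must be in 1..n")
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(paste(edges[, 1], edges[, 2])))
      stop("multiple edges between the same pair are not allowed")
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(n = n, edges = edges), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d neuronal loci, %d synapses\n", x$n, n_edges(x)))
  invisible(x)
}

#' Number of synapses (edges) in a topology
#' @param topo a [topology()].
#' @return Integer edge count `d`.
#' @export
n_edges <- function(topo) nrow(topo$edges)

#' Node degrees of a topology
#' @param topo a [topology()].
#' @return Integer vector of length `n`.
#' @export
degrees <- function(topo) {
  tabulate(c(topo$edges[, 1], topo$edges[, 2]), nbins = topo$n)
}

#' Symmetric 0/1 adjacency matrix of a topology
#' @param topo a [topology()].
#' @return `n x n` numeric matrix with zero diagonal.
#' @export
adjacency_matrix <- function(topo) {
  A <- matrix(0, topo$n, topo$n)
  if (nrow(topo$edges)) {
    A[topo$edges] <- 1
    A[topo$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

#' Convert a topology to an igraph graph
#' @param topo a [topology()].
#' @return An undirected `igraph` graph on `topo$n` vertices.
#' @export
as_igraph <- function(topo) {
  g <- igraph::make_empty_graph(topo$n, directed = FALSE)
  if (nrow(topo$edges)) g <- igraph::add_edges(g, t(topo$edges))
  g
}

from_igraph <- function(g, n = igraph::vcount(g)) {
  topology(n, igraph::as_edgelist(g, names = FALSE))
}

#' Fully connected circuit
#'
#' @param n number of neuronal loci, at least 2.
#' @return A [topology()] with all `n(n-1)/2` synapses present.
#' @export
make_complete <- function(n) {
  if (n < 2) stop("a complete circuit needs n >= 2 loci")
  idx <- utils::combn(n, 2)
  topology(n, t(idx))
}

#' Erdos-Renyi random circuit
#'
#' Each of the `n(n-1)/2` possible synapses is present independently with
#' probability `r`.
#'
#' @param n number of neuronal loci.
#' @param r connection probability in `[0, 1]`.
#' @param seed optional integer seed (sets R's RNG).
#' @return A [topology()].
#' @export
make_er <- function(n, r, seed = NULL) {
  if (r < 0 || r > 1) stop("`r` must be a probability in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  from_igraph(igraph::sample_gnp(n, r), n)
}

#' Barabasi-Albert preferential-attachment circuit
#'
#' Nodes are added one at a time; each new node attaches to
#' `min(k_attach, existing nodes)` distinct earlier nodes with probability
#' proportional to their degree.  Under this convention the edge count is
#' `choose(k_attach, 2) + k_attach * (n - k_attach)`.
#'
#' @param n number of neuronal loci.
#' @param k_attach number of synapses attached per incoming node,
#'   `1 <= k_attach < n`.
#' @param seed optional integer seed.
#' @return A connected [topology()].
#' @export
make_ba <- function(n, k_attach, seed = NULL) {
  if (k_attach < 1 || k_attach >= n)
    stop("`k_attach` must satisfy 1 <= k_attach < n")
  if (!is.null(seed)) set.seed(seed)
  from_igraph(igraph::sample_pa(n, power = 1, m = k_attach, directed = FALSE), n)
}

#' Watts-Strogatz small-world circuit
#'
#' Starts from a ring lattice in which every node is connected to its
#' `base_degree / 2` nearest neighbours on each side, then rewires the far
#' endpoint of each edge with probability `r` to a uniformly chosen node,
#' avoiding self-loops and multiple edges (a rewire that cannot be placed is
#' kept in place).  The edge count `n * base_degree / 2` is preserved.
#'
#' @param n number of neuronal loci.
#' @param r rewiring probability in `[0, 1]`.
#' @param base_degree even ring-lattice degree, less than `n`.  The model
#'   description leaves this free; 4 is the package default.
#' @param seed optional integer seed.
#' @return A [topology()].
#' @export
make_ws <- function(n, r, base_degree = 4, seed = NULL) {
  if (base_degree %% 2 != 0) stop("`base_degree` must be even")
  if (base_degree >= n) stop("`base_degree` must be smaller than n")
  if (r < 0 || r > 1) stop("`r` must be a probability in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0L, n, n)
  for (k in seq_len(base_degree / 2)) {
    j <- (seq_len(n) + k - 1L) %% n + 1L
    A[cbind(seq_len(n), j)] <- 1L
    A[cbind(j, seq_len(n))] <- 1L
  }
  ed <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  for (e in seq_len(nrow(ed))) {
    if (stats::runif(1) >= r) next
    i <- ed[e, 1]
    cand <- which(A[i, ] == 0L)
    cand <- setdiff(cand, i)
    if (!length(cand)) next
    j_new <- if (length(cand) == 1L) cand else sample(cand, 1L)
    j_old <- ed[e, 2]
    A[i, j_old] <- A[j_old, i] <- 0L
    A[i, j_new] <- A[j_new, i] <- 1L
  }
  topology(n, which(upper.tri(A) & A == 1L, arr.ind = TRUE))
}

#' Global minimum edge cut of a circuit
#'
#' The number of synapses that must be removed to separate the circuit into
#' two disconnected parts; 0 if and only if the circuit is already
#' disconnected.
#'
#' @param topo a [topology()].
#' @return Non-negative integer.
#' @export
edge_connectivity <- function(topo) {
  if (topo$n < 2L) return(0L)
  as.integer(igraph::edge_connectivity(as_igraph(topo)))
}

#' Number of connected components
#' @param topo a [topology()].
#' @return Positive integer.
#' @export
n_components <- function(topo) {
  igraph::components(as_igraph(topo))$no
}

#' Read/write a topology as a whitespace-delimited edge list
#'
#' The on-disk format uses 0-based node indices, one edge per line.
#'
#' @param topo a [topology()].
#' @param file path.
#' @param n number of loci (needed on read because isolated nodes leave no
#'   trace in an edge list).
#' @return `write_edgelist` returns `file` invisibly; `read_edgelist` a
#'   [topology()].
#' @export
write_edgelist <- function(topo, file) {
  utils::write.table(topo$edges - 1L, file,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(file, n) {
  raw <- utils::read.table(file)
  topology(n, as.matrix(raw) + 1L)
}

#' Read/write a topology as GraphML
#' @param topo a [topology()].
#' @param file path.
#' @return `write_graphml` returns `file` invisibly; `read_graphml` a
#'   [topology()].
#' @export
write_graphml <- function(topo, file) {
  igraph::write_graph(as_igraph(topo), file, format = "graphml")
  invisible(file)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(file) {
  g <- igraph::read_graph(file, format = "graphml")
  from_igraph(g)
}
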