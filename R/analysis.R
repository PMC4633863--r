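## Statistical post-processing of simulation output.

#' Spearman rank dependence between a condition and an outcome
#'
#' Used to quantify how equilibrium weights depend on the selection gradient:
#' rank correlation is appropriate because the dependence is nonlinear.
#'
#' @param x condition values (e.g. selection gradients).
#' @param y outcomes (e.g. equilibrium weight magnitudes).
#' @return List with `rho_s` (Spearman correlation) and `p` (two-sided
#'   p-value).  Constant input yields `NA` values with a warning.
#' @export
spearman_dependence <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 5) stop("need at least 5 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined")
    return(list(rho_s = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho_s = unname(ct$estimate), p = ct$p.value)
}

#' Chi-square test of node degrees against the binomial null
#'
#' Takes an ensemble of circuit topologies on `n` nodes and tests the pooled
#' per-node degree distribution against `Binomial(n - 1, p_hat)`, the
#' Erdos-Renyi null, with `p_hat` estimated from the empirical mean degree.
#' Bins with expected count below 5 are pooled; degrees of freedom are
#' `bins - 2` (one constraint for the total, one for the estimated `p_hat`).
#' Evolved circuit ensembles typically reject this null: their degree
#' variance is larger than binomial.
#'
#' @param topologies list of [topology()] objects on a common `n`, at least
#'   30 recommended (a warning is issued below that).
#' @return List with `p_hat`, `chi2`, `df`, `p_value`.
#' @export
degree_null_test <- function(topologies) {
  if (length(topologies) < 30)
    warning("fewer than 30 topologies: the test may have little power")
  n <- topologies[[1]]$n
  deg <- unlist(lapply(topologies, degrees))
  p_hat <- mean(deg) / (n - 1)
  obs <- tabulate(deg + 1L, nbins = n)       # degrees 0..n-1
  expd <- length(deg) * stats::dbinom(0:(n - 1), n - 1, p_hat)
  ## pool adjacent bins until every expected count is at least 5
  bins_o <- numeric(0); bins_e <- numeric(0)
  acc_o <- 0; acc_e <- 0
  for (k in seq_along(expd)) {
    acc_o <- acc_o + obs[k]; acc_e <- acc_e + expd[k]
    if (acc_e >= 5) {
      bins_o <- c(bins_o, acc_o); bins_e <- c(bins_e, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0 && length(bins_e)) {
    bins_o[length(bins_o)] <- bins_o[length(bins_o)] + acc_o
    bins_e[length(bins_e)] <- bins_e[length(bins_e)] + acc_e
  }
  if (length(bins_e) < 2)
    return(list(p_hat = p_hat, chi2 = NA_real_, df = NA_integer_,
                p_value = NA_real_))
  chi2 <- sum((bins_o - bins_e)^2 / bins_e)
  df <- max(1L, length(bins_e) - 2L)
  list(p_hat = p_hat, chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Summarize SSP runs across a synapse-cost sweep
#'
#' Averages each run over its stationary segment (by default the last 50
#' recorded points) and returns one row per (cost, replicate).
#'
#' @param records list of `"ssp_record"` objects.
#' @param k_costs numeric vector, the cost condition of each record.
#' @param replicate integer vector, the replicate index of each record
#'   (defaults to sequence within cost).
#' @param last number of trailing recorded points to average over.
#' @return Data frame of class `"sweep_result"` with columns `k_cost`,
#'   `replicate`, `rel_fitness`, `mean_degree`, `d`, `mean_M_connected`,
#'   `edge_connectivity`, `n_components`.  Empty input gives an empty table.
#' @export
cost_sweep_summary <- function(records, k_costs,
                               replicate = NULL, last = 50) {
  if (!length(records)) {
    out <- data.frame(k_cost = numeric(0), replicate = integer(0),
                      rel_fitness = numeric(0), mean_degree = numeric(0),
                      d = numeric(0), mean_M_connected = numeric(0),
                      edge_connectivity = numeric(0),
                      n_components = numeric(0))
    class(out) <- c("sweep_result", "data.frame")
    return(out)
  }
  if (length(k_costs) != length(records))
    stop("`k_costs` must have one entry per record")
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(k_costs), k_costs, FUN = seq_along)
  rows <- lapply(seq_along(records), function(m) {
    r <- records[[m]]$record
    seg <- utils::tail(r, last)
    if (any(!is.finite(utils::tail(seg$rel_fitness, 1))))
      warning("run ", m, " has non-finite stationary fitness; ",
              "consider a longer chain")
    data.frame(k_cost = k_costs[m], replicate = replicate[m],
               rel_fitness = mean(seg$rel_fitness, na.rm = TRUE),
               mean_degree = mean(seg$mean_degree),
               d = mean(seg$d),
               mean_M_connected = mean(seg$mean_M_connected, na.rm = TRUE),
               edge_connectivity = mean(seg$edge_connectivity),
               n_components = mean(seg$n_components))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Per-cost averages of a sweep result
#' @param sweep a `"sweep_result"` from [cost_sweep_summary()].
#' @return Data frame with one row per `k_cost`, averaging over replicates.
#' @export
sweep_means <- function(sweep) {
  agg <- stats::aggregate(
    sweep[, c("rel_fitness", "mean_degree", "d", "mean_M_connected",
              "edge_connectivity", "n_components")],
    by = list(k_cost = sweep$k_cost), FUN = mean, na.rm = TRUE)
  agg[order(agg$k_cost), ]
}

#' Plot a cost sweep (fitness, degree and switching vs cost)
#' @param x a `"sweep_result"`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.sweep_result <- function(x, ...) {
  m <- sweep_means(x)
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  graphics::plot(m$k_cost, m$rel_fitness, log = "x", type = "b",
                 xlab = "cost per synapse k", ylab = "relative fitness")
  graphics::plot(m$k_cost, m$mean_degree, log = "x", type = "b",
                 xlab = "cost per synapse k", ylab = "mean degree")
  graphics::plot(m$k_cost, m$mean_M_connected, log = "x", type = "b",
                 xlab = "cost per synapse k",
                 ylab = "mean M (connected nodes)")
  invisible(x)
}
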