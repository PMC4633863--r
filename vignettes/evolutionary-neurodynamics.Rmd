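---
title: "Evolutionary neurodynamics: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary neurodynamics: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoneuro)
```

## The model

`evoneuro` simulates an effectively infinite ensemble of neuronal circuits
that compete, in parallel, to solve a target-output problem.  Each circuit
contains `n` *neuronal loci*; the on/off state of a locus is the analogue of
a biallelic gene, coded as `X = +1` (firing) or `X = -1` (silent).  The
ensemble is summarized by the *firing probability* `rho_i`, the fraction of
circuits in which locus `i` fires -- the analogue of an allele frequency.
Circuits whose output scores a higher fitness overwrite lower-scoring
circuits, and because the copying is assumed free-recombining across loci,
the ensemble stays in product form (a Hardy--Weinberg-like assumption):
every expectation over circuit configurations factorizes through the
Poisson-binomial distribution of the on-count.

Three processes act on this ensemble:

1. **Selection.**  The network output is the *count* of firing neurons,
   `Omega`.  A *stabilizing* landscape scores `W = exp(-beta (T - Omega)^2)`
   around a target count `T`; a *directional* landscape has a constant
   per-locus log-fitness gradient `S` (the limit of a distant target, with
   `S = 2 beta T`).
2. **Switching (state-dependent mutation).**  Each neuron flips on/off with
   the switching probability given by the activity rule `M(Y) =
   exp(-Y^2) / 2`, where `Y_i = sum_j phi_ij (2 rho_j - 1)` is the
   mean-field input current.  A naive neuron (no net input) switches at
   `M = 1/2`; strong input of either sign stabilizes the neuron's state and
   drives `M` toward zero.
3. **Hebbian learning.**  The directed weights evolve by Oja's rule on mean
   activities, `dphi_ij/dt = lambda (Y_i Xbar_j - Y_i^2 phi_ij)`, which
   keeps the incoming-weight vector of each neuron bounded (its Euclidean
   norm converges to 1) while aligning it with the mean input pattern.

The firing probabilities follow the continuous-time selection--mutation
equation

```
drho_i/dt = rho_i (1 - rho_i) sigma_i + M_i (1 - 2 rho_i),
```

with `sigma_i` the per-locus selection gradient.  The package integrates
the first-order (mean-and-variance) closure of that gradient:
`sigma_i = S_i` for directional landscapes -- exactly the constant-gradient
property -- and `sigma_i = 2 beta (T - Kbar_i - 1/2)` for stabilizing ones,
where `Kbar_i` is the expected on-count of the other loci.  The exact
conditional-expectation gradient `(W_on - W_off) / W_bar`, computed by an
`O(n^2)` Poisson-binomial convolution, is available as a backend of
`locus_fitness_terms()` / `selection_gradient()` and serves as the oracle
for the closure (the two agree to first order in `beta`; the variance term
of the squared deviation appears in both conditional expectations and
cancels from the gradient, so only the level of the mean fitness feels it).

On a slower time scale, **structural synaptic plasticity** (SSP) rewires
the topology itself: synaptogenesis proposes new synapses between
unconnected pairs with probability proportional to the co-firing weight
`rho_i rho_j`; existing synapses are disbanded independently with
probability `R(H) = r_max exp(-a H)`, decreasing in the synaptic mutual
information `H`; and, with small probability `u`, one synapse is moved to a
random vacant pair.  The inner learning dynamics are run to equilibrium on
each proposal, and a Metropolis--Hastings rule accepts it with probability
`min(1, exp(W_new - W_old))`.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `lambda` | learning rate (per time unit) | `1e-3` | the intended regime is learning slower than selection (`lambda < S`); the learnt equilibrium itself is independent of `lambda` |
| `t_max` | integration horizon (time units) | `1e4` | long enough for convergence at the default rates; one time unit is on the order of one evaluation round |
| `S` | directional gradient (dimensionless) | `5` | reference configuration for the 20-locus directional runs |
| `beta`, `T` | stabilizing sharpness and target count | `S/(2T)`, problem-specific | `beta = S/(2T)` keeps stabilizing runs commensurate with directional ones |
| `init_low`, `init_high` | uniform initial bounds for `rho` and `phi` | `0`, `0.01` | naive circuits: near-silent loci, near-zero weights |
| `u` | random-rewire probability per SSP step | `0.01` | rare undirected structural noise |
| `r_max`, `h_scale` | disbanding rate at `H = 0` and its decay per bit | `0.1`, `10` | an uninformative synapse survives ~10 SSP steps; one that stores a few tenths of a bit is effectively protected.  The model statement fixes only the *shape* (decreasing in `H`, maximal at 0); these scales were chosen once so that disbanding turnover and synaptogenesis balance at moderate degree |
| `k_cost` | fitness cost per synapse | `0` | sweep variable of the cost experiments |

## Numerical choices

* **Solver.**  `deSolve::lsoda` (adaptive, stiff-capable) with `rtol =
  1e-8`, `atol = 1e-10` and log-spaced output times; the right-hand side is
  compiled C (the standard `deSolve` compiled-model pattern), with an
  identical plain-R implementation used for cross-checking
  (`compiled = FALSE`).
* **Boundary handling.**  The switching term points inward at `rho = 0, 1`,
  so the simplex is invariant; reported trajectories are additionally
  projected to `[0, 1]` to absorb floating-point drift.  Weights stay
  exactly zero off the topology by construction.
* **Equilibrium detection.**  SSP inner runs stop early when the rate
  sup-norm falls below `inner_steady_tol` (`1e-6`), via the solver's root
  finding; a run that reaches `t_max` with a larger rate norm is flagged,
  not fatal, and its end state is used.
* **Conditional information.**  `mutual_information_exact()` conditions
  *only* the switching probability of the focal neuron on its neighbour's
  state (weights and all other loci frozen, fitness terms kept at ensemble
  values) and relaxes the focal locus to equilibrium by root finding.
  Conditioning only through `M` is what makes a zero-weight synapse carry
  exactly zero information.  The state at which information is assessed is
  an explicit argument; no canonical assessment time is imposed.
* **Information units.**  Bits by default, switchable to nats.
* **Approximate information.**  `mutual_information_approx()` is the
  chi-square (small-dependence) expansion of the exact route around the
  focal locus's marginal equilibrium; it is proportional to `phi^2` at
  small weights and accurate (couple of percent at `|phi| ~ 0.05`, ~15% at
  `|phi| ~ 0.3`) while `|phi|` stays below the operating activity
  magnitude implied by `M_i`.  Outside that domain it saturates, because a
  switching probability confined to `(0, 1/2]` cannot change by more than
  one half.
* **Chi-square degree test.**  Expected bins below 5 are pooled; degrees of
  freedom are `bins - 2` (total plus the estimated `p_hat`).

## Design choices where the design was open

* **Output measure.**  `Omega` counts firing neurons rather than summing
  the `+1/-1` states; the stabilizing problems are stated as "a target
  number of spiking neurons", which forces the count convention.
* **The activity rule is even in `Y`.**  `M = exp(-Y^2)/2` decreases with
  the *magnitude* of the input current.  This is forced by the stabilizing
  results: the loci that must stay silent are held off through negative
  input (inhibition emerges from the learning rule itself, since co-silent
  neurons strengthen their mutual weights), and a stably-off neuron must
  also stop switching.  A rule monotone in signed `Y` with range
  `(0, 1/2]` would pin every silenced neuron at `M = 1/2` and destroy the
  exact-count equilibrium.
* **Acceptance on log fitness.**  The SSP comparison value is
  `log(mean fitness) - k_cost * d`.  Comparing raw fitness values in
  `exp(W_new - W_old)` collapses all cost-penalized fitnesses to ~0 once
  `k_cost * d` exceeds a few units, making the chain blind to costs
  precisely in the regime the cost experiments probe; the log form keeps
  the acceptance sensitive across the whole sweep (`log_fitness = FALSE`
  restores the raw rule).
* **Weight directionality.**  The topology is undirected but each synapse
  carries two independently evolving directed weights.
* **Disbanding is an independent per-edge sweep** per SSP step (not
  normalized to at most one removal), matching "any, including all, events
  may happen in a step".
* **Barabasi--Albert convention.**  Each incoming node attaches
  `min(k, existing)` edges, so `d = choose(k, 2) + k (n - k)`.
  **Watts--Strogatz** is implemented directly (ring lattice plus
  simple-graph-preserving rewires) so that the edge count is conserved at
  any rewiring probability; the base ring degree is exposed
  (`base_degree`, default 4).

## What the simulations do and do not show

The dynamics regime matters for two documented phenomena:

* **Symmetry breaking needs strong equilibrium activity.**  On a complete
  circuit the exactly-`T`-active equilibrium forms only if the active-state
  input current `x sqrt(n - 1)` is large enough to quench switching.  The
  reference 20-locus, `T = 15`, `S = 5` configuration is comfortably in
  that regime (the census is exactly 15 across seeds, with active loci at
  `rho ~ 1`); small circuits with mild gradients (e.g. 12 loci, `T = 8`,
  `S = 5`) stall on the symmetric manifold.  Desk-scale tests therefore use
  `n = 12, T = 9, S = 8`, which breaks cleanly.
* **Weight--gradient dependence is a learning-epoch property.**  At the
  fully converged Oja fixed point the incoming-weight norm is 1 for *every*
  gradient -- normalization pins the magnitude -- so the increase of weight
  magnitudes with the selection gradient is assessed at a fixed horizon
  inside the learning epoch (`lambda = 1e-4`, `t = 2000` in the tests),
  where it is strong and monotone.  Relatedly, under the
  activity-normalized Oja rule the learning epoch lasts about
  `1/(2 lambda ||Xbar||^2)` rather than `1/lambda`: the incubation plateau
  between the fast selective stage (`~1/S`) and convergence scales as
  `1/lambda` but with a topology- and state-dependent prefactor below 1.

The synthetic experiments emulate idealized conditions real neural tissue
does not satisfy: infinitely many circuits (no drift), free recombination
during copying, a mean-field activity with variance and correlation terms
neglected, and a separation of time scales between spiking, learning and
rewiring.  Passing tests validate the model's internal regularities --
mutation--selection balance, learning acceleration, exact-count equilibria,
information-guided rewiring, cost--sparsity trade-offs -- not any claim
about real brains.

## Problem sizes used by the test suite

Unit and property tests run on 2--12 locus systems; the census and
learning-acceleration checks use the full 20-locus reference configuration
(20 seeds, `t = 1e4`); the SSP cost sweep uses 10-locus circuits, costs
`{0.01, 0.1, 0.5, 1}`, 10 replicates of 150 Metropolis--Hastings steps with
stationary averages over the last 50 recorded points; the frozen-system
acceptance chain runs 200,000 steps.  These sizes were chosen as the
smallest at which each regularity is unambiguous.

## Known limitations

* The compiled right-hand side supports up to 50 loci (the plain-R backend
  has no such limit, only speed).
* `mutual_information_approx()` is quantitative only on its small-weight
  domain; use the exact route for strong synapses.
* Metropolis--Hastings step counts do not correspond to physiological
  time; only orderings and stationary summaries are meaningful.
* With `log_fitness = TRUE`, a proposal whose equilibrium mean fitness
  underflows to zero is effectively always rejected; at the problem sizes
  here mean fitness stays well above the underflow threshold.

## A worked example

```{r example, eval = FALSE}
library(evoneuro)

## stabilizing problem: 20 loci, target 15 firing
cen <- run_stabilizing_census(n = 20, target = 15, S = 5, lambda = 1e-3,
                              t_max = 1e4, seeds = 1:20)
table(cen$census$census)     # how many loci end active, per seed
mean(cen$census$mean_active_rho)

## learning vs mutation-selection balance
cmp <- run_directional_comparison(n = 20, S = 5, lambda = 1e-3, seed = 1)
cmp$convergence_times
cmp$speedup

## structural plasticity under synapse costs
sw <- run_cost_sweep(k_costs = c(0.01, 0.1, 0.5, 1), replicates = 4,
                     n = 10, target = 7, S = 10, lambda = 0.01,
                     n_steps = 150, seed = 1)
sw$means
```
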