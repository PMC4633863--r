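Package: evoneuro
Title: Evolutionary Neurodynamics of Learning Neuronal Circuit Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulator for evolutionary neurodynamics: an infinite ensemble of
    neuronal circuits in which the firing probability of each neuronal locus
    evolves under selection on a fitness landscape while Oja-rule Hebbian
    learning tunes the switching probabilities that generate spiking
    variability.  Includes directional and stabilizing (Gaussian) fitness
    landscapes, random circuit topologies (Erdos-Renyi, Barabasi-Albert,
    Watts-Strogatz), synaptic mutual information measures, and a
    Metropolis-Hastings structural-synaptic-plasticity search over topologies
    with synapse costs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
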