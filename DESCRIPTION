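Package: selfherd
Title: Selfish-Herd Dynamics via Multi-Agent Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Agent-based simulation of Hamilton's selfish herd. Disk-shaped
    agents on an unbounded plane learn, by centralized-training
    decentralized-execution policy-gradient reinforcement learning, to
    minimize their Voronoi domain of danger bounded by a cutoff radius.
    Provides exact cutoff-Voronoi geometry, a five-sector vision-cone
    observable with sight blocking, the combined risk and proximity reward,
    an advantage actor-critic trainer returning a fitted policy object,
    frozen-policy rollouts, and trajectory statistics (mean squared
    displacement, rotational order and its spatial map, cumulative
    domain-of-danger averages, autocorrelation, neighbor persistence)
    that quantify the emergent strongly and weakly rotating group states
    and the long-time equalization of predation risk.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
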