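Package: coevonet
Title: Adaptive Co-Evolution of Health Behaviour and Social Network Structure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of a binary health behaviour (smoking)
    co-evolving with a two-layer social network under exogenous normative
    forcing. A slow contact network of reciprocal, degree-bounded ties is
    rewired by homophily on a proximity matrix that mixes a static
    small-world background with behavioural similarity, while a fast
    interaction network sampled from distance-dependent probabilities
    carries Ising-type peer influence on the behaviour. Includes the four
    model variants (coupled, network, interaction, mean-field), a parabolic
    disposition-forcing schedule driven by a Kolmogorov-Smirnov matching
    criterion, network observables (prevalence, eigenvector centrality by
    behavioural group, conditional probability of smoking by social
    distance), and seeded ensemble runners with bootstrap confidence bands.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
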