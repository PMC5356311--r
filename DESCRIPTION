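Package: peroxasr
Title: Ancestral Sequence Reconstruction and Catalytic Typing of Fungal
    Class-II Peroxidases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline from a protein multiple alignment and a rooted
    phylogeny to resurrected-ancestor candidates for fungal class-II
    (ligninolytic) peroxidases. Implements empirical amino-acid substitution
    models (WAG, LG, Dayhoff) with discrete-gamma rate heterogeneity,
    Felsenstein pruning likelihoods with branch-length and shape optimization,
    empirical-Bayes marginal ancestral reconstruction with per-site posterior
    matrices, threshold-gated Monte-Carlo sampling of alternative ancestors,
    catalytic-site typing (MnP/VP/LiP/GP) from the manganese-binding acidic
    triad and the exposed catalytic tryptophan, a sequence-evolution simulator
    with known internal-node truths, and steady-state kinetics (single-site and
    biphasic two-site Michaelis-Menten) plus pH/thermal stability summaries
    (residual activity, T50, melting midpoint Tm).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    minpack.lm,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
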