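Package: aaconv
Title: Detection of Convergent and Parallel Amino Acid Substitutions on
    Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-scale detection of convergent and parallel amino acid
    substitutions on focal branches of a species tree. Provides reversible
    empirical amino acid substitution models (JTT, WAG, LG), Felsenstein
    pruning likelihoods with per-gene maximum likelihood branch length
    estimation, marginal (empirical Bayes) ancestral sequence
    reconstruction, counting of convergent and parallel substitutions on
    configured branch sets, a model-based expected-count null with exact
    Poisson tests in both directions (excess on focal branches, deficit on
    control branches), a seeded phylogenetic protein sequence simulator
    with ground-truth substitution histories and injectable convergent
    sites, and a batch pipeline over directories of single-copy ortholog
    alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    phangorn,
    Matrix,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
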