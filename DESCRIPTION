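Package: triexnet
Title: Co-Expression Networks from Ternary-Discretized Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene co-expression networks by ternary-coding a
    gene-by-sample expression matrix (-1 down, 0 unchanged, +1 up relative to
    each gene's own mean), counting per-pair co-occurrences with indicator
    inner products, and retaining pairs whose support exceeds a
    density-conditional permutation null (exact hypergeometric or Monte
    Carlo). Networks come in three relation classes: up-together (pp),
    down-together (mm) and directed up-down (pm). Includes Pearson
    correlation networks with a t-test cutoff as a cross-validating filter,
    prediction of transitive co-expression pairs from a signed
    activator/repressor regulatory network, randomization tests of network
    size, spectral reordering of adjacency matrices, sample stratification by
    clique scores, and a simulator producing expression data from a known
    signed regulatory network plus pure-noise background genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
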