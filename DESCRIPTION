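Package: mitopop
Title: Mitochondrial Haplotype and Population Structure Analysis for
    Island Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mitochondrial DNA population analysis from
    hypervariable-region or whole-mitogenome data: variant motif calling
    against a reference segment, haplogroup assignment against a reduced
    phylotree, Nei gene diversity with sampling error, exact two-tailed
    Fisher tests for geographically asymmetric haplogroup distributions,
    AMOVA-based pairwise Phi-ST with Slatkin linearization, metric
    multidimensional scaling by stress majorization (SMACOF),
    weighted-least-squares admixture estimation from haplogroup
    frequencies, median-joining haplotype networks, and rho-statistic
    coalescence dating under a fixed substitution clock. Includes a
    seed-deterministic synthetic-data generator emulating small island
    populations so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
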