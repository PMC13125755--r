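Package: gmisnet
Title: Genetic Minimal Intervention Sets in Integrated Metabolic and
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes genetic Minimal Intervention Sets (gMISs): minimal
    combinations of gene knockouts and knock-ins that abolish a target
    metabolic function in a genome-scale metabolic model whose
    gene-protein-reaction (GPR) rules have been extended with a signed,
    possibly cyclic, transcriptional regulatory network.  Per reaction,
    a layered Boolean-network expansion builds an extended GPR; minimal
    trap spaces (attractors) of that network yield the minimal gene
    intervention rows that inactivate the reaction; a linear-programming
    feasibility check inside an enumeration loop then lifts these rows
    to intervention sets that block the target flux.  Includes an
    attractor-based adaptation post-check, expression-conditioned
    essentiality prediction scored against CRISPR dependency screens
    with the Matthews correlation coefficient, exhaustive brute-force
    oracles for every stage, and self-contained toy fixtures with
    brute-forceable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    parallel,
    stats,
    utils,
    xml2
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
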