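Package: rotastoich
Title: Soil Enzyme Stoichiometry, Microbial Community and Path-Model
    Analysis for Mushroom-Crop Rotation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing soil remediation experiments that combine
    spent mushroom substrate amendment with crop rotation. Implements
    treatment statistics (one-way ANOVA with Fisher's LSD compact letter
    displays, percent changes, Pearson correlation matrices), extracellular
    enzyme C:N:P stoichiometry and vector analysis with nutrient-limitation
    classification, alpha diversity and Bray-Curtis ordination with
    PERMANOVA, SparCC compositional co-occurrence networks with permutation
    significance and topology metrics, and partial least squares path
    modelling with bootstrap validation and goodness-of-fit. A synthetic
    data module simulates treatment-structured soil tables, compositional
    count matrices with known basis correlations, and latent-variable
    datasets with known path coefficients, so every stage is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vegan,
    ape,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
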