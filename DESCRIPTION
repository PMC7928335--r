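Package: spcnet
Title: Condition-Stratified Network Analysis of Spectral-Count Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction and topological analysis of protein networks from
    label-free (spectral count) proteomic profiles measured under crossed
    nutritional conditions. Provides spectral-count normalization, prevalence
    filtering and F-ratio feature selection; homology-transferred (interolog)
    protein-protein interaction networks filtered on evidence-channel scores;
    signed Spearman co-expression networks per condition grouping; exact
    betweenness and centroid centralities with above-average hub calling,
    condition-specific hub set algebra and differential-correlation detection;
    and a synthetic spectral-count data generator with planted co-expression
    modules, hubs and differentially expressed proteins for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
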