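Package: haplodelim
Title: Integrative Molecular Species Delimitation for Cryptic Species Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delimiting cryptic species from multi-marker sequence
    data, built around the workflow used for North East Atlantic Terebellides
    (Annelida): specimen/site registry with biogeographic, bathymetric and
    rarefaction accounting; haplotype collapsing with flank pruning;
    uncorrected p-distance summaries and barcode-gap assessment; statistical
    parsimony (TCS-style) haplotype networks under a 95% connection limit;
    single-threshold GMYC fitting on ultrametric trees with model-ensemble
    node support; posterior species-partition summaries; and a rule-based
    multi-marker consensus with an audit trail and species-count bounds. A
    multispecies-coalescent synthesizer generates Yule species trees, embedded
    gene trees and simulated mitochondrial- and nuclear-like alignments so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    phangorn,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
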