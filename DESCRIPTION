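Package: mutstab
Title: Mutational Stability Effects and Selection on Protein Folding and Binding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how amino-acid substitutions accessible
    through single nucleotide mutations alter protein folding stability
    (ddG fold) and protein-protein binding stability (ddG bind), and how
    substitutions fixed by natural or laboratory selection differ from the
    accessible pool. Implements mutational-neighborhood enumeration under
    the standard genetic code, validated ddG substitution tables, zone
    membership statistics, a Monte-Carlo randomization test, a truncated
    bivariate-normal selection-surface grid fit, cumulative stability
    trajectories for (possibly branching) adaptation experiments, and a
    synthetic-data generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, StructuralPrediction, Phylogenetics
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'ddg-table.R'
    'genetic-code.R'
    'mutational-neighborhood.R'
    'mutstab-package.R'
    'observed-data.R'
    'pipeline.R'
    'randomization-test.R'
    'selection-surface.R'
    'stability-stats.R'
    'synthetic-data.R'
    'utils.R'
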