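Package: coassembly
Title: Contact-Based Cluster Analysis of Peptide-Drug-Ion Co-Assembly Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects multicomponent clusters of cyclic dipeptides, small-molecule
    drugs and ions (Zn2+, NO3-, Cl-) in periodic molecular trajectories using an
    any-atom contact criterion with the minimum-image convention, and computes
    per-cluster statistics: composition percentages, drug encapsulation,
    drug/peptide and Zn/peptide ratios, radius of gyration, Shrake-Rupley solvent
    accessible surface area burial, ion- and molecule-mediated triplet interaction
    motifs, and chemical-group contact profiles. Includes a synthetic-configuration
    generator (planted clusters with exact ground truth and a coarse-grained
    Metropolis Monte Carlo co-assembly process), multi-model PDB trajectory I/O,
    a one-vs-one multiclass support vector machine over per-cluster feature
    vectors, and a single-config pipeline driver with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'RcppExports.R'
    'cluster_detection.R'
    'cluster_metrics.R'
    'interaction_analysis.R'
    'features_classifier.R'
    'pipeline.R'
    'synthetic_data.R'
    'topology.R'
    'trajectory_io.R'
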