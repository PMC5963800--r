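Package: MirrorSort
Title: Separating Native from Mirror-Image Protein Backbone Models by
    Energy-Term Clustering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect and separate mirror-image backbone models from
    natively oriented ones within per-domain model ensembles, as arise when
    structures are reconstructed from residue-residue Calpha contact maps
    (a representation that is blind to chirality). Provides proper-rotation
    Kabsch superposition and RMSD-based orientation assignment against a
    reference and its reflection, backbone dihedral analysis and the
    positive-phi ratio, Ramachandran density-grid classification into
    favored/allowed/outlier regions, contact-map generation and a normalized
    map-difference statistic, simplified physical and knowledge-based energy
    terms (Coulomb electrostatics with distance-dependent dielectric,
    split Lennard-Jones attractive/repulsive, Ramachandran preference and
    amino-acid-conditional torsion probability), per-domain statistical
    comparison of energy terms between orientation groups, and unsupervised
    two-cluster k-means partitioning with an energy-based cluster-labeling
    rule and confusion-matrix evaluation. Includes a deterministic
    synthetic-ensemble generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, bio3d, jsonlite
Suggests: testthat (>= 3.0.0), igraph, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'clustering.R'
    'domain-stats.R'
    'ramachandran.R'
    'energy.R'
    'structure-io.R'
    'pipeline.R'
    'cli.R'
    'contact-map.R'
    'geometry.R'
    'synthetic.R'
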