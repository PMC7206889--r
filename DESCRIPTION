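Package: aroclust
Title: Aromatic Ring Clusters in Protein-Drug and Protein-Protein Complexes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects aromatic rings in protein residues and drug-like
    ligands from PDB coordinate files, measures pairwise ring-ring
    interaction geometry (centroid distance, planar angle, orientational
    angle), enumerates aromatic clusters as connected components of the
    interaction graph under context-specific edge rules for protein-drug
    and protein-protein complexes, and computes structural and statistical
    summaries: Shrake-Rupley solvent accessibility and exposure ratios,
    secondary-structure preference log-odds, radial distribution
    functions, Boltzmann-inverted free-energy maps, and binding-affinity
    stratification. Includes a synthetic-fixture generator that writes
    toy PDB complexes with exactly controlled ring geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: StructuralBioinformatics, Proteomics
RoxygenNote: 7.3.3
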