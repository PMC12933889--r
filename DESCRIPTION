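Package: fragspace
Title: Chemical Space, 3D Shape and Crystal-Contact Analysis of Kinase Fragment Hits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the cheminformatic and structural characterization of
    natural-product-like fragment hits against protein kinases. Provides
    molecule standardization and activity-based curation, a 2D descriptor
    panel (saturation, stereogenicity, spatial score, natural-product
    likeness, rule-of-three compliance), 3D shape analysis via the
    plane-of-best-fit descriptor on generated and protein-bound
    conformations, shape-abstracted RMSD between conformers, kinase
    binding-pocket occupancy classification from pseudo-atom proximity,
    crystallographic symmetry-mate expansion with ligand surface
    partitioning and polar-contact counting, Bemis-Murcko scaffold and
    cyclic-skeleton novelty analysis, Morgan fingerprint similarity
    ranking, growth-vector mining against parent molecules, and
    nonparametric group-comparison statistics with effect sizes. Ships a
    synthetic-data generator producing molecule libraries with controlled
    descriptor structure and toy crystals with known ground truth, so the
    whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: OpenBabel (obabel on PATH); Python 3 with RDKit for
    conformer embedding (python on PATH)
Config/testthat/edition: 3
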