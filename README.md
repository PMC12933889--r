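# fragspace

Cheminformatic and structural analysis of natural-product-like fragment
hits against protein kinases, in R.

Fragment-based drug discovery screens very small molecules (roughly under
300 Da) and grows the confirmed binders into leads. Whether a fragment
library leaves "flat land" — the over-represented chemical space of planar,
heteroaromatic compounds — is quantified with saturation and shape
descriptors, and whether a crystallographically observed binding event is
trustworthy depends on where in the kinase the fragment sits and how much
the crystal lattice, rather than the protein, holds it in place. This
package implements that whole analysis chain for people characterizing
fragment screens against kinases:

* **Standardization & curation** — metal disconnection, desalting,
  neutralization, canonicalization, deduplication; activity filtering with
  pChEMBL >= 5 and/or ligand efficiency LE = 1.37 x pChEMBL / HAC >= 0.3 at
  assay confidence 9.
* **2D descriptor panel** — MW, HBA/HBD, logP, rotatable bonds, TPSA,
  aromatic ring count, Fsp³ (fraction of sp³ carbons), FC_stereo (fraction
  of stereogenic carbons), the spatial score SPS = Σ h·s·r·n² over heavy
  atoms with its size-normalized form nSPS, natural-product likeness from
  circular-fragment contributions, and rule-of-three compliance.
* **3D shape** — knowledge-based distance-geometry conformers (RDKit
  ETKDGv3 via the bundled Python helper), the plane-of-best-fit descriptor
  PBF (mean distance of all atoms to the least-squares plane, in Å) and
  nPBF = PBF / heavy atoms, binding-induced flattening ΔnPBF =
  nPBF(protein-bound) − nPBF(in silico), and shape-abstracted RMSD (all
  heavy atoms to carbon, all bonds to single, minimized over graph
  automorphisms after Kabsch superposition).
* **Pocket assignment** — Cα-based superposition onto a reference
  structure, pocket pseudo-atoms at reference-ligand centers of mass, and
  the 5 Å any-atom occupancy rule for the orthosteric ATP pocket "A" and
  peripheral sites "B".."L", with binder classification
  (orthosteric-only / peripheral-only / both / unassigned).
* **Crystal contacts** — symmetry-mate generation within 6 Å of each
  ligand copy from the unit cell and space-group operators, the
  lattice-proximal flag (any ligand atom closer to a mate than to the
  asymmetric unit), Shrake–Rupley partition of the ligand surface between
  protein entities, and distance-based polar-contact counts.
* **Scaffolds & similarity** — Bemis–Murcko scaffolds, cyclic skeletons
  (chemotype proxy), novelty reports against reference sets, Morgan
  fingerprint (radius 2, 4096 bits) Tanimoto ranking, stereospecific
  natural-product parent search, growth-vector mining, and sociability
  counts.
* **Statistics** — Kruskal–Wallis, Dunn's post-hoc test with Bonferroni
  correction, Cohen's d, Spearman trend.
* **Synthetic fixtures** — generators for "flat" vs "three_d" molecule
  libraries with controlled descriptor structure, toy crystals with exact
  pocket/lattice ground truth, and activity tables, so everything above
  runs end-to-end without downloads.

## Worked example

The classic plane-of-best-fit contrast: globular amantadine versus planar
salicylic acid.

```r
library(fragspace)

wk <- pbf_worked_examples(seed = 42)
wk
#>               id n_heavy   pbf   npbf
#> 1     amantadine      11 1.021 0.0928
#> 2 salicylic_acid      10 0.133 0.0133
```

Amantadine's cage keeps every atom about 1 Å away from any plane you fit
through it (PBF ≈ 1.02 Å), while salicylic acid is almost flat
(PBF ≈ 0.13 Å, driven by the hydroxyl hydrogens leaving the ring plane).
Dividing by heavy-atom count gives the size-independent nPBF (0.093 vs
0.013).

The 2D panel on the same molecules:

```r
fx <- reference_fixtures()
descriptor_table(fx[c("amantadine", "salicylic_acid", "toluene")])[,
  c("id", "mw", "fsp3", "fc_stereo", "nsps", "nar", "ro3_compliant")]
#>               id    mw  fsp3 fc_stereo  nsps nar ro3_compliant
#> 1     amantadine 151.3 1.000         0 36.82   0          TRUE
#> 2 salicylic_acid 138.1 0.000         0  9.20   1          TRUE
#> 3        toluene  92.1 0.143         0  8.71   1          TRUE
```

And the statistics layer separating a flat from a three-dimensional
library:

```r
flat   <- generate_library("flat",    25, seed = 1)
threed <- generate_library("three_d", 25, seed = 1)
v <- function(rs) vapply(rs, function(r) suppressWarnings(fsp3(r$graph)), numeric(1))
cohens_d(v(threed), v(flat))
#> [1] 15.63
dunn_bonferroni(list(flat = v(flat), three_d = v(threed)))$p_adj["flat", "three_d"]
#> [1] 1.2e-10
```

A saturated, stereocenter-rich library separates from flat-land aromatics
by many pooled standard deviations in Fsp³ — the qualitative pattern the
descriptor panel is built to expose.

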