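---
title: "Methods: descriptors, pockets, crystal contacts and their design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors, pockets, crystal contacts and their design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what each quantity means, which parameters matter, where the design was
genuinely open and what was decided, and what the synthetic fixtures do
and do not demonstrate.

## The analysis problem

Fragment screens against kinases produce a small set of confirmed binders
that must be characterized along three axes: *where* they bind (the
orthosteric ATP pocket versus peripheral sites), *whether the crystal
lattice rather than the protein stabilizes them* (a peripheral "hit" held
in place by a symmetry mate is a crystallographic artifact candidate), and
*what part of chemical space they occupy* (saturation, stereogenicity and
three-dimensional shape relative to reference collections of kinase
ligands and drugs). The package implements one module per question plus
the statistics and fixtures needed to exercise them.

## Molecular graphs

All 2D analysis runs on a light molecular graph built from SMILES.
OpenBabel provides canonicalization and the kekulized connection table;
aromaticity is read from the lowercase atoms of the canonical SMILES
itself so that perception always matches the canonicalizer. Implicit
hydrogen counts come from standard valences adjusted for formal charge;
rings from a smallest-set-of-smallest-rings perception (shortest cycle
through each non-bridge bond, greedily selected up to the cyclomatic
number). Atom symmetry classes use Morgan-style iterative refinement of an
invariant (element, charge, hydrogen count, degree, aromaticity, ring
membership); refinement stops when the partition stabilizes.

**Stereocenter perception.** A carbon is a potential tetrahedral
stereocenter when it is sp3, carries at most one hydrogen, has four
substituents and all heavy neighbors fall in pairwise distinct symmetry
classes. This counts both configured and unconfigured centers — the
package default for the stereogenic-carbon fraction, switchable to
assigned-only. The rule is deliberately conservative on polycyclic ring
systems: it does not flag para-substituted-ring cis/trans centers
(symmetry-equivalent branch pairs) and does not flag bridgeheads of
symmetric cages, where some toolkits report "possible" stereocenters that
admit no actual stereoisomer. Consequences: spatial-score values on fused
saturated ring systems can sit below those of implementations using the
more liberal perception; on acyclic and singly-ring-substituted molecules
the implementations agree (the test suite pins 22 such values against a
published implementation).

## Descriptor panel

* `Fsp3`: sp3 carbons / all carbons. sp3 means only single bonds and not
  aromatic.
* `FC_stereo`: stereogenic carbons / all carbons, with the perception
  above. Both are 0 by convention (with a warning) for carbon-free input.
* `SPS` and `nSPS`: per heavy atom, the product of a hybridization term
  (sp 1, sp2 2, sp3 3, other 4), a stereo term (2 for stereogenic
  tetrahedral carbons and atoms of stereogenic double bonds, else 1), a
  non-aromatic-ring term (2 in a non-aromatic ring) and the squared
  heavy-neighbor count; summed, and for nSPS divided by the heavy-atom
  count. Two perception details matter and were calibrated against the
  published implementation before freezing: lone-pair nitrogen and oxygen
  adjacent to a multiple bond or aromatic system count as sp2
  (amide/ester/phenol conjugation), while divalent and hypervalent sulfur
  stays sp3 unless aromatic.
* `HBA`/`HBD`: nitrogen and oxygen *atom* counts (donors additionally
  carry at least one hydrogen). This is the atom-feature reading, not the
  Lipinski pharmacophore count; the alternative was genuinely open and
  the choice is recorded here because it changes absolute counts for
  molecules with many heteroatoms.
* `NRB`: single acyclic bonds whose two atoms each have another heavy
  neighbor; no amide exclusion. The definition is stated so that hand
  counts in the tests use the same rule.
* `logP`, `TPSA`: OpenBabel's atom-contribution estimators; the parameter
  set is OpenBabel's and is recorded in output metadata by virtue of the
  estimator's name.
* `NAR`: aromatic rings in the smallest ring basis; fused aromatics count
  per ring.
* Rule-of-three: MW <= 300, HBD <= 3, HBA <= 3, logP <= 3, NRB <= 3,
  TPSA <= 60 A^2, all inclusive, all configurable. The saturation
  threshold used in compliance summaries is Fsp3 >= 0.42, boundary
  inclusive.
* NP-likeness: each atom's radius-2 circular environment is looked up in
  a contribution table; the score is the mean contribution over atoms,
  clipped to the table's contribution range, which makes it independent
  of molecular size. A table is the log10 ratio of smoothed environment
  frequencies between a natural-product and a synthetic exemplar set.
  The packaged table is trained on the two ~30-molecule exemplar files
  under `inst/extdata/`; it supports *ordering* statements (sugar above
  biphenyl), not absolute score reproduction against tables trained on
  large corpora — user tables can be loaded with `train_np_table()`.

## 3D shape

Conformers are embedded with RDKit's ETKDGv3 (torsion-knowledge distance
geometry, random starting coordinates, fixed seed, one conformer per
molecule, explicit hydrogens kept), called through a bundled Python
helper; this is the standard knowledge-based generator for reproducing
bioactive-like conformations, and the generated geometry — not the
generator — is what the package analyzes.

**PBF.** The plane of best fit is the least-squares plane of all atoms
carrying coordinates (singular value decomposition of centered
coordinates; distances are absolute perpendicular distances). The
descriptor is the *mean* distance in Angstrom. Two conventions required a
decision:

1. *Mean versus sum.* The descriptor is sometimes described as a sum of
   distances, but the worked values this package reproduces (amantadine
   about 1.0 A at 11 heavy atoms, salicylic acid about 0.13 A at 10) are
   only consistent with the mean; the mean is implemented.
2. *Hydrogens.* Generated conformers carry explicit hydrogens and the
   plane fit includes them — for salicylic acid most of the deviation
   *is* the hydroxyl hydrogens leaving the ring plane. Crystal-derived
   conformers normally contain heavy atoms only, and then the fit uses
   the resolved heavy atoms; partially resolved copies use resolved atoms
   only.

`nPBF = PBF / resolved heavy atoms` (note: heavy atoms, even when the fit
included hydrogens — this keeps the normalization comparable between
generated and crystal conformations). `delta_npbf` is protein-bound minus
in-silico, so flattening upon binding is negative.

Because the embedding is stochastic, the worked-example helper
(`pbf_worked_examples()`) and the acceptance script report the median over
a 7-conformer seed-derived ensemble. Each conformer follows the
single-conformer protocol; the median is a reporting choice that reduces
seed-to-seed variance of a quantity whose per-seed spread (roughly
+/- 0.04 A for amantadine) is comparable to the agreement tolerance.

**Abstracted RMSD.** Conformations of the same molecule are compared on an
abstracted graph (all heavy atoms carbon, all bonds single) so that shape,
not chemistry, is compared; the heavy-atom RMSD after Kabsch superposition
is minimized over the automorphisms of that graph (enumeration capped at
10,000 matchings with a deterministic identity fallback). Superposition is
applied because generated and crystal frames are unrelated; a pose-frame
RMSD would be meaningless. Only mutually resolved atoms enter. Per-ligand
values over crystallographic copies: all fully resolved copies are kept,
otherwise the single best-resolved copy (ties broken by structure id, then
copy id); descriptor values are averaged per ligand.

## Pockets

Structures of the same protein are superposed on C-alpha atoms matched by
chain and residue number (Kabsch; at least 3 pairs), and the transform is
applied to all atoms including ligands. Pocket pseudo-atoms are the
mass-weighted centers (standard atomic masses; plain centroid available)
of reference-ligand atoms — for the ATP pocket, conventionally the adenine
substructure of bound ATP. A ligand copy occupies a pocket when *any*
resolved heavy atom lies within the 5 A radius, boundary inclusive; the
stricter centroid reading is available behind a flag because the phrase
"located in a 5 A radius" does not disambiguate. Binder classes aggregate
copies: orthosteric-only (all labels "A"), peripheral-only, both,
unassigned.

No cross-family sequence alignment is attempted; matching by residue
number assumes same-protein structures, which is the intended use.

## Crystal contacts

The unit cell is read from `CRYST1`; space-group operators come from a
packaged table (P1, P2, P21, C2, P21212, P212121, P43212) whose group
closure is verified in the tests, and operators can be supplied directly
for other groups. Fractional/Cartesian conversion uses the standard
orthogonalization with *a* along x and *b* in the xy-plane. Symmetry
mates are protein images (operator x lattice translation, identity-zero
excluded) with any atom within 6 A of any ligand atom; translations are
searched over -2..2 per axis with bounding-box pruning, which covers any
ligand placed within or near the cell. A copy is lattice-proximal when
any of its atoms is *strictly* closer to a mate than to the asymmetric
unit — ties resolve to the asymmetric unit, a documented tie-break.

Ligand surface partition uses Shrake-Rupley sampling: 960 deterministic
golden-spiral points per atom on the solvent-accessible sphere (van der
Waals radius + 1.4 A probe), points buried by other ligand atoms removed,
each exposed point attributed to the entity owning the nearest protein
atom if that atom is within a 6 A proximity cap, else unassigned. The cap
is why entity percentages need not sum to 100: solvent-facing surface
belongs to nobody. A single cap serves both the partition and the
surface-share summaries.

Polar contacts are distance-only on heavy atoms because inputs may lack
hydrogens: N/O/S pairs within 3.5 A count as hydrogen-bond contacts;
opposite formal charges (ligand charges from its graph, protein charges
from the Arg/Lys/Asp/Glu sidechain-atom convention) within 4.0 A count as
salt bridges. Waters are reported separately as water-mediated contacts.
No angle terms, no pi-stacking, no interface energies.

## Statistics

Kruskal-Wallis (tie-corrected, chi-squared approximation) is the omnibus
test; Dunn's z on pooled ranks with tie correction provides the pairwise
follow-up, Bonferroni-adjusted over all group pairs within one descriptor
(the correction family had to be fixed somewhere; per-descriptor pairs is
the choice and it is stated here). Cohen's d uses the pooled standard
deviation and means — medians are reported descriptively alongside, but d
is mean-based by definition. Significance language uses p < 0.05.

## Synthetic fixtures

`generate_library()` assembles molecules from a small, auditable grammar
(about ten scaffold templates x ten substituents per profile), then keeps
only products satisfying the profile: "flat" molecules have >= 2 aromatic
rings and Fsp3 <= 0.2; "three_d" molecules have Fsp3 >= 0.42, at most one
aromatic ring and >= 1 stereocenter. The 0.42 boundary is the customary
saturation threshold for molecular three-dimensionality, so the two
profiles sit on opposite sides of it by construction. The generator
emulates the *descriptor contrast* between flat-land screening compounds
and saturated natural-product-like fragments; it does not emulate
realistic size distributions, synthesizability or activity, so passing
discrimination tests shows the pipeline resolves a designed contrast, not
that any real library separates equally well.

`generate_toy_crystal()` writes a P1 cell (40 A cube) containing a
spherical C-alpha blob, one "arm" atom near a cell face, two pocket
pseudo-atoms outside the blob, and rigid 5-atom ligand crosses placed at
stated nearest-atom distances (4.0/4.5 in-pocket, 4.9/5.1 boundary cases,
one lattice-interface ligand reachable only by a translated image).
Ground truth is exact by construction with >= 0.5 A margin everywhere;
placements are checked for clashes. The fixture is geometric, not
physical: no real kinase geometry, no electron density, no B-factors.

## Problem sizes and runtimes

The shipped tests and the acceptance script run at deliberately small
sizes chosen as sufficient for their statistical purpose: descriptor
oracles on 50 enumerated molecules, libraries of 25-50 molecules per
profile, 7-conformer ensembles for the worked examples, 1000 replicates
for the null calibration of the Dunn test at n = 50 per group, and 20
fixtures for the RMSD-oracle comparison.

## Known limitations

* Stereo perception misses para-type ring cis/trans centers and, by
  design, does not flag cage bridgeheads; spatial scores on such systems
  differ from liberal-perception implementations.
* The Morgan fingerprint is this package's dialect of the
  extended-connectivity family (own invariants and hash); Tanimoto values
  agree with other toolkits only approximately, and bit collisions from
  4096-bit folding are part of the method.
* The packaged NP-likeness table is exemplar-trained and supports ordering
  statements only.
* Space groups outside the packaged table require explicit operators.
* Substructure matching is graph-based (element, charge, bond class);
  there is no SMARTS query language and no maximum-common-substructure
  search.
* Tetrahedral parity in stereospecific matching is evaluated on generated
  3D coordinates; molecules whose stereocenters the rule-based generator
  cannot realize would be matched permissively.
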