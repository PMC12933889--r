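#' @title 2D molecular descriptor panel
#' @description Saturation (Fsp3), stereogenicity (FC_stereo), the spatial
#'   score (SPS/nSPS), natural-product likeness, the fundamental
#'   physicochemical properties (MW, HBA, HBD, logP, NRB, TPSA, NAR) and
#'   rule-of-three compliance.
#' @name descriptors
NULL

as_molgraph <- function(mol) {
  if (inherits(mol, "molgraph")) return(mol)
  if (inherits(mol, "mol_record")) return(mol$graph)
  if (is.character(mol) && length(mol) == 1L) return(molgraph(mol))
  stop("Expected a molgraph, mol_record or SMILES string", call. = FALSE)
}

#' Fraction of sp3-hybridized carbons
#'
#' Number of sp3 carbons divided by the number of all carbons. Molecules
#' without carbon return 0 with a warning (convention).
#'
#' @param mol a molgraph, mol_record or SMILES string.
#' @return value in \[0, 1\].
#' @examples
#' \dontrun{
#' fsp3("CC")        # 1
#' fsp3("c1ccccc1")  # 0
#' }
#' @export
fsp3 <- function(mol) {
  mg <- as_molgraph(mol)
  is_c <- mg$element == "C"
  if (!any(is_c)) {
    warning("Molecule has no carbon atoms; Fsp3 set to 0 by convention")
    return(0)
  }
  sum(is_c & mg$hybridization$hyb == "sp3") / sum(is_c)
}

#' Fraction of stereogenic carbons
#'
#' Number of stereogenic carbons divided by the number of all carbons.
#' `mode = "potential"` (default) uses symmetry-aware perception of
#' tetrahedral centers whether or not a configuration is assigned;
#' `mode = "assigned"` counts only carbons carrying an explicit tetrahedral
#' mark in the canonical SMILES.
#'
#' @param mol a molgraph, mol_record or SMILES string.
#' @param mode `"potential"` or `"assigned"`.
#' @return value in \[0, 1\].
#' @export
fc_stereo <- function(mol, mode = c("potential", "assigned")) {
  mode <- match.arg(mode)
  mg <- as_molgraph(mol)
  is_c <- mg$element == "C"
  if (!any(is_c)) {
    warning("Molecule has no carbon atoms; FC_stereo set to 0 by convention")
    return(0)
  }
  stereo <- if (mode == "potential") mg$stereocenter
            else nzchar(mg$stereo_mark)
  sum(is_c & stereo) / sum(is_c)
}

# Stereogenic double bonds: acyclic C=C where each end carries at least one
# heavy substituent besides the partner, and where two such substituents are
# never symmetry-equivalent. Both configured and unconfigured bonds count,
# mirroring the potential-stereocenter convention.
stereo_double_bond_atoms <- function(mg) {
  out <- rep(FALSE, mg$n_atoms)
  b <- mg$bonds
  if (!nrow(b)) return(out)
  cls <- mg$sym_class
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 2L || b$in_ring[k]) next
    a1 <- b$a1[k]; a2 <- b$a2[k]
    if (mg$element[a1] != "C" || mg$element[a2] != "C") next
    ok <- TRUE
    for (a in c(a1, a2)) {
      nb <- setdiff(mg$adj[[a]], c(a1, a2))
      if (length(nb) == 0L) { ok <- FALSE; break }
      if (length(nb) == 2L && cls[nb[1L]] == cls[nb[2L]]) { ok <- FALSE; break }
    }
    if (ok) out[c(a1, a2)] <- TRUE
  }
  out
}

#' Spatial score (SPS) and its size-normalized form (nSPS)
#'
#' For every heavy atom the product of four terms is accumulated: a
#' hybridization term (sp 1, sp2 2, sp3 3, other 4; lone-pair N/O adjacent
#' to multiple bonds or aromatics count as sp2, non-aromatic sulfur as sp3),
#' a stereoisomeric term (2 for stereogenic tetrahedral carbons and atoms of
#' stereogenic double bonds, else 1), a non-aromatic ring term (2 in a
#' non-aromatic ring, else 1) and the squared heavy-neighbor count. nSPS
#' divides the sum by the heavy-atom count.
#'
#' Stereo perception here is the package's symmetry-class rule; on fused and
#' bridged ring systems it is more conservative than perceptions that flag
#' potential cis/trans ring stereocenters, so absolute SPS values on such
#' systems can differ between toolkits.
#'
#' @param mol a molgraph, mol_record or SMILES string.
#' @return list with elements `sps` and `nsps`.
#' @examples
#' \dontrun{
#' spatial_score("c1ccccc1")$nsps  # 8
#' }
#' @export
spatial_score <- function(mol) {
  mg <- as_molgraph(mol)
  if (mg$n_atoms == 0L) stop("Empty molecule", call. = FALSE)
  hyb <- mg$hybridization$conj
  h <- ifelse(hyb == "sp", 1L, ifelse(hyb == "sp2", 2L,
       ifelse(hyb == "sp3", 3L, 4L)))
  # divalent/hypervalent sulfur scores as sp3 unless aromatic
  s_fix <- mg$element == "S" & !mg$aromatic &
    !(mg$degree == 1L & mg$hybridization$n_double > 0L)
  h[s_fix] <- 3L
  s <- ifelse(mg$stereocenter | stereo_double_bond_atoms(mg), 2L, 1L)
  arom_ring_atom <- rep(FALSE, mg$n_atoms)
  for (r in mg$aromatic_rings) arom_ring_atom[r] <- TRUE
  r <- ifelse(mg$ring_atom & !arom_ring_atom, 2L, 1L)
  sps <- sum(h * s * r * mg$degree^2)
  list(sps = sps, nsps = sps / mg$n_atoms)
}

#' Count rotatable bonds
#'
#' Single acyclic bonds between two heavy atoms that each carry at least one
#' further heavy neighbor. No amide exclusion is applied; the definition is
#' recorded here so hand counts in the test suite use the same rule.
#'
#' @param mol a molgraph, mol_record or SMILES string.
#' @return integer count.
#' @export
n_rotatable_bonds <- function(mol) {
  mg <- as_molgraph(mol)
  b <- mg$bonds
  if (!nrow(b)) return(0L)
  sum(b$order == 1L & !b$in_ring &
      mg$degree[b$a1] >= 2L & mg$degree[b$a2] >= 2L)
}

#' Fundamental physicochemical properties
#'
#' Molecular weight (standard atomic masses, hydrogens included), hydrogen
#' bond acceptor and donor atom counts (N/O atoms; donors additionally carry
#' at least one hydrogen), OpenBabel's atom-contribution logP and topological
#' polar surface area, rotatable bonds and the number of aromatic rings in
#' the smallest ring basis.
#'
#' @param mol a molgraph, mol_record or SMILES string.
#' @return data.frame with columns `mw`, `hba`, `hbd`, `logp`, `nrb`,
#'   `tpsa`, `nar`.
#' @export
physchem_panel <- function(mol) {
  mg <- as_molgraph(mol)
  pt <- ob_logp_tpsa(mg$smiles)
  no <- mg$element %in% c("N", "O")
  data.frame(
    mw = molgraph_mw(mg),
    hba = sum(no),
    hbd = sum(no & mg$nH >= 1L),
    logp = pt$logp,
    nrb = n_rotatable_bonds(mg),
    tpsa = pt$tpsa,
    nar = length(mg$aromatic_rings)
  )
}

#' Rule-of-three compliance
#'
#' All bounds inclusive: MW <= 300, HBD <= 3, HBA <= 3, logP <= 3, and the
#' customary extensions NRB <= 3 and TPSA <= 60.
#'
#' @param v one-row data.frame (or list) with fields `mw`, `hbd`, `hba`,
#'   `logp`, `nrb`, `tpsa`, e.g. from [physchem_panel()].
#' @param bounds named list overriding individual bounds.
#' @return logical.
#' @export
ro3_compliance <- function(v, bounds = list()) {
  b <- utils::modifyList(
    list(mw = 300, hbd = 3, hba = 3, logp = 3, nrb = 3, tpsa = 60), bounds)
  isTRUE(v$mw <= b$mw && v$hbd <= b$hbd && v$hba <= b$hba &&
         v$logp <= b$logp && v$nrb <= b$nrb && v$tpsa <= b$tpsa)
}

#' Fraction of values meeting a threshold
#'
#' @param values numeric vector (e.g. Fsp3 values of a library).
#' @param cutoff threshold; values `>= cutoff` count (boundary inclusive).
#' @return fraction in \[0, 1\].
#' @examples
#' compliance_fraction(c(0.5, 0.3, 0.42), 0.42)  # 2/3
#' @export
compliance_fraction <- function(values, cutoff) {
  if (!length(values)) stop("Empty value vector", call. = FALSE)
  mean(values >= cutoff)
}

#' Full 2D descriptor table for a molecule collection
#'
#' One row per record with the complete descriptor panel. logP and TPSA are
#' computed in a single OpenBabel batch call.
#'
#' @param records list of `mol_record` (or character vector of SMILES).
#' @param np_table natural-product likeness contribution table
#'   (default: the packaged table, see [np_contribution_table()]); pass
#'   `NULL` to skip the NP score.
#' @return data.frame with columns `id`, `source_tag`, the
#'   descriptor-vector fields and `ro3_compliant`.
#' @export
descriptor_table <- function(records, np_table = np_contribution_table()) {
  if (is.character(records)) {
    records <- lapply(seq_along(records), function(i) {
      molecule_record(ob_canonical(records[i]), id = sprintf("mol%04d", i))
    })
  }
  if (!length(records)) stop("No records supplied", call. = FALSE)
  smis <- vapply(records, function(r) r$smiles_canonical, character(1))
  pt <- ob_logp_tpsa(smis)
  rows <- lapply(seq_along(records), function(i) {
    mg <- records[[i]]$graph
    no <- mg$element %in% c("N", "O")
    sc <- spatial_score(mg)
    d <- data.frame(
      id = records[[i]]$id,
      source_tag = records[[i]]$source_tag,
      mw = molgraph_mw(mg),
      hba = sum(no),
      hbd = sum(no & mg$nH >= 1L),
      logp = pt$logp[i],
      nrb = n_rotatable_bonds(mg),
      tpsa = pt$tpsa[i],
      nar = length(mg$aromatic_rings),
      fsp3 = suppressWarnings(fsp3(mg)),
      fc_stereo = suppressWarnings(fc_stereo(mg)),
      sps = sc$sps,
      nsps = sc$nsps,
      stringsAsFactors = FALSE
    )
    d$np_likeness <- if (!is.null(np_table)) np_likeness(mg, np_table) else NA_real_
    d$ro3_compliant <- ro3_compliance(d)
    d
  })
  do.call(rbind, rows)
}
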