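#' @title Scaffolds, substructure search, growth vectors and sociability
#' @description Bemis-Murcko scaffolds (ring systems plus linkers, exocyclic
#'   double-bonded atoms retained), cyclic skeletons (the scaffold with every
#'   heavy atom carbon and every bond single — a shape-only chemotype proxy),
#'   substructure matching with optional stereochemistry, growth-vector
#'   mining of fragments against parent molecules, library sociability
#'   counts and scaffold novelty reports.
#' @name scaffolds
NULL

#' Bemis-Murcko scaffold
#'
#' Non-ring atoms are pruned iteratively from the leaves inward, leaving ring
#' systems and the linkers between them; atoms attached to the kept core by a
#' double or triple bond (e.g. exocyclic carbonyl oxygens) are restored.
#' Acyclic molecules yield the empty-scaffold marker `""`.
#'
#' @param mol a molgraph, mol_record or SMILES string.
#' @return canonical SMILES of the scaffold, or `""` for acyclic input.
#' @examples
#' \dontrun{
#' bemis_murcko("Cc1ccccc1")  # "c1ccccc1"
#' }
#' @export
bemis_murcko <- function(mol) {
  mg <- as_molgraph(mol)
  atoms <- bm_scaffold_atoms(mg)
  if (!length(atoms)) return("")
  parts_to_smiles(molgraph_parts(mg, sort(atoms)))
}

# Atom indices of the Bemis-Murcko scaffold.
bm_scaffold_atoms <- function(mg) {
  if (!any(mg$ring_atom)) return(integer())
  keep <- rep(TRUE, mg$n_atoms)
  repeat {
    deg <- vapply(seq_len(mg$n_atoms), function(i) {
      if (!keep[i]) return(0L)
      sum(keep[mg$adj[[i]]])
    }, integer(1))
    drop <- which(keep & !mg$ring_atom & deg <= 1L)
    if (!length(drop)) break
    keep[drop] <- FALSE
  }
  # restore atoms multiply bonded to the retained core
  b <- mg$bonds
  for (k in seq_len(nrow(b))) {
    if (b$order[k] >= 2L) {
      if (keep[b$a1[k]] && !keep[b$a2[k]]) keep[b$a2[k]] <- TRUE
      else if (keep[b$a2[k]] && !keep[b$a1[k]]) keep[b$a1[k]] <- TRUE
    }
  }
  which(keep)
}

#' Cyclic skeleton (generic framework)
#'
#' The Bemis-Murcko scaffold with every heavy atom replaced by carbon and
#' every bond by a single bond, canonicalized. Molecules sharing a skeleton
#' are treated as one chemotype by this package (a documented, pluggable
#' proxy for the loosely defined term).
#'
#' @param mol a molgraph, mol_record or SMILES string.
#' @return canonical SMILES of the skeleton, or `""` for acyclic input.
#' @examples
#' \dontrun{
#' cyclic_skeleton("c1ccncc1") == cyclic_skeleton("C1CCCCC1")  # TRUE
#' }
#' @export
cyclic_skeleton <- function(mol) {
  mg <- as_molgraph(mol)
  atoms <- bm_scaffold_atoms(mg)
  if (!length(atoms)) return("")
  parts <- molgraph_parts(mg, sort(atoms))
  parts$element <- rep("C", length(parts$element))
  parts$charge <- rep(0L, length(parts$charge))
  parts$bonds$order <- rep(1L, nrow(parts$bonds))
  parts_to_smiles(parts)
}

#' Scaffold records for a molecule collection
#'
#' @param records list of `mol_record`.
#' @return data.frame `molecule_id`, `bm_scaffold`, `cyclic_skeleton`.
#' @export
scaffold_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(molecule_id = r$id, bm_scaffold = bemis_murcko(r$graph),
               cyclic_skeleton = cyclic_skeleton(r$graph),
               stringsAsFactors = FALSE)
  }))
}

.gen3d_cache <- new.env(parent = emptyenv())

# 3D coordinates for stereo-parity checks (rule-based generator; respects
# tetrahedral marks in the SMILES). Cached per canonical SMILES.
gen3d_coords <- function(smiles) {
  key <- smiles
  if (!is.null(.gen3d_cache[[key]])) return(.gen3d_cache[[key]])
  sdf <- ob_to_sdf(smiles, gen3d = TRUE)
  ct <- parse_ctab(sdf)
  hv <- ct$element != "H"
  out <- ct$coords[hv, , drop = FALSE]
  .gen3d_cache[[key]] <- out
  out
}

# Sign of the chiral volume at atom `center` given up to three/four
# neighbor positions (in a fixed neighbor order).
chirality_sign <- function(coords, center, nbrs) {
  if (length(nbrs) == 4L) {
    v <- rbind(coords[nbrs[2L], ] - coords[nbrs[1L], ],
               coords[nbrs[3L], ] - coords[nbrs[1L], ],
               coords[nbrs[4L], ] - coords[nbrs[1L], ])
  } else {
    v <- rbind(coords[nbrs[1L], ] - coords[center, ],
               coords[nbrs[2L], ] - coords[center, ],
               coords[nbrs[3L], ] - coords[center, ])
  }
  sign(det(v))
}

#' Substructure search
#'
#' Finds embeddings of `pattern` in `target`: element and formal charge must
#' match per atom, bond classes (single/double/triple/aromatic) per bond.
#' With `stereo = TRUE`, configured tetrahedral centers of the pattern must
#' map onto target centers of matching handedness (parity is compared
#' geometrically on generated 3D coordinates, using the mapped neighbor
#' ordering); pattern centers without an assigned configuration, and target
#' atoms that are not stereogenic, match freely.
#'
#' @param pattern,target molgraphs, mol_records or SMILES strings.
#' @param stereo respect assigned tetrahedral configuration (default FALSE).
#' @param max_maps cap on returned embeddings (default 10000).
#' @return list of integer vectors mapping pattern atoms to target atoms
#'   (empty list when there is no match).
#' @export
match_substructure <- function(pattern, target, stereo = FALSE,
                               max_maps = 10000L) {
  pg <- as_molgraph(pattern); tg <- as_molgraph(target)
  if (pg$n_atoms == 0L || pg$n_atoms > tg$n_atoms) return(list())
  # vertex domains: element + charge compatibility
  domains <- lapply(seq_len(pg$n_atoms), function(i) {
    which(tg$element == pg$element[i] & tg$charge == pg$charge[i] &
          tg$degree >= pg$degree[i])
  })
  if (any(lengths(domains) == 0L)) return(list())
  gp <- pg$igraph; gt <- tg$igraph
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(gp, gt, method = "lad", induced = FALSE,
                                  domains = domains),
    error = function(e) list())
  if (!length(maps)) return(list())
  tcode <- new.env(parent = emptyenv())
  tb <- tg$bonds
  tbc <- bond_code(tb$order, tb$aromatic)
  for (k in seq_len(nrow(tb))) {
    tcode[[paste(min(tb$a1[k], tb$a2[k]), max(tb$a1[k], tb$a2[k]))]] <- tbc[k]
  }
  pb <- pg$bonds
  pbc <- bond_code(pb$order, pb$aromatic)
  ok_bonds <- function(mp) {
    for (k in seq_len(nrow(pb))) {
      a <- mp[pb$a1[k]]; b <- mp[pb$a2[k]]
      cd <- tcode[[paste(min(a, b), max(a, b))]]
      if (is.null(cd) || cd != pbc[k]) return(FALSE)
    }
    TRUE
  }
  maps <- Filter(ok_bonds, lapply(maps, as.integer))
  if (length(maps) > max_maps) maps <- maps[seq_len(max_maps)]
  if (!stereo || !length(maps)) return(maps)
  centers <- which(nzchar(pg$stereo_mark) & pg$stereocenter)
  if (!length(centers)) return(maps)
  pc <- gen3d_coords(pg$smiles)
  tc <- gen3d_coords(tg$smiles)
  ok_stereo <- function(mp) {
    for (a in centers) {
      ta <- mp[a]
      if (!tg$stereocenter[ta]) next  # target center not stereogenic
      nb <- mg_sorted_neighbors(pg, a)
      if (length(nb) < 3L) next
      sp <- chirality_sign(pc, a, nb)
      st <- chirality_sign(tc, ta, mp[nb])
      if (sp != 0 && st != 0 && sp != st) return(FALSE)
    }
    TRUE
  }
  Filter(ok_stereo, maps)
}

mg_sorted_neighbors <- function(mg, atom) {
  nb <- sort(mg$adj[[atom]])
  if (length(nb) > 4L) nb <- nb[1:4]
  nb
}

#' Does the target contain the pattern as a substructure?
#'
#' @inheritParams match_substructure
#' @return logical.
#' @export
has_substructure <- function(pattern, target, stereo = FALSE) {
  length(match_substructure(pattern, target, stereo = stereo,
                            max_maps = 1L)) > 0L
}

#' Find natural-product parents of a fragment
#'
#' Stereospecific substructure search of the fragment in a natural-product
#' collection: a parent embedding the fragment with opposite configuration
#' at an assigned stereocenter is not a parent.
#'
#' @param fragment a `mol_record` (or SMILES).
#' @param np_set list of `mol_record`.
#' @param stereo respect stereochemistry (default TRUE).
#' @return character vector of parent ids.
#' @export
find_np_parents <- function(fragment, np_set, stereo = TRUE) {
  hit <- vapply(np_set, function(p) {
    has_substructure(fragment, p, stereo = stereo)
  }, logical(1))
  vapply(np_set[hit], function(p) p$id, character(1))
}

#' Growth vectors of a fragment from its parent molecules
#'
#' Each parent is searched for the fragment (stereochemistry ignored by
#' default: derivatization analysis); a fragment atom that is bonded, in the
#' parent, to an atom outside the matched image is a growth vector. Vector
#' atoms are merged across symmetry-equivalent fragment positions (canonical
#' symmetry classes), each parent contributing at most one count per
#' position.
#'
#' @param fragment a `mol_record` (or SMILES).
#' @param parents list of `mol_record`.
#' @param stereo respect stereochemistry in the matching (default FALSE).
#' @return data.frame of class `growth_vector_map`: one row per symmetry
#'   class of fragment atoms (`atom` = representative index, `atoms` = all
#'   members, `element`, `count`); parents without a match are reported via
#'   the `unmatched_parents` attribute and skipped.
#' @export
growth_vectors <- function(fragment, parents, stereo = FALSE) {
  fg <- as_molgraph(fragment)
  cls <- fg$sym_class
  counts <- stats::setNames(integer(length(unique(cls))), sort(unique(cls)))
  unmatched <- character()
  for (p in parents) {
    pg <- as_molgraph(p)
    maps <- match_substructure(fg, pg, stereo = stereo)
    if (!length(maps)) {
      unmatched <- c(unmatched, if (inherits(p, "mol_record")) p$id else "?")
      next
    }
    vec_atoms <- logical(fg$n_atoms)
    for (mp in maps) {
      inside <- rep(FALSE, pg$n_atoms)
      inside[mp] <- TRUE
      for (a in seq_len(fg$n_atoms)) {
        ta <- mp[a]
        if (any(!inside[pg$adj[[ta]]])) vec_atoms[a] <- TRUE
      }
    }
    hit_classes <- unique(cls[vec_atoms])
    for (h in hit_classes) {
      key <- as.character(h)
      counts[key] <- counts[key] + 1L
    }
  }
  reps <- vapply(sort(unique(cls)), function(cc) min(which(cls == cc)),
                 integer(1))
  out <- data.frame(
    atom = reps,
    atoms = vapply(sort(unique(cls)), function(cc) {
      paste(which(cls == cc), collapse = ",")
    }, character(1)),
    element = fg$element[reps],
    count = as.integer(counts[as.character(sort(unique(cls)))]),
    stringsAsFactors = FALSE)
  out <- out[order(out$atom), ]
  rownames(out) <- NULL
  attr(out, "unmatched_parents") <- unmatched
  class(out) <- c("growth_vector_map", class(out))
  out
}

#' Sociability of a fragment within a compound library
#'
#' Counts library members sharing the fragment's cyclic skeleton (same
#' chemotype), sharing its Bemis-Murcko scaffold, and containing the
#' fragment as a (stereospecific) substructure.
#'
#' @param fragment a `mol_record` (or SMILES).
#' @param library list of `mol_record` (standardized).
#' @param stereo stereospecific substructure matching (default TRUE).
#' @return named integer vector `c(n_chemotype, n_scaffold, n_substructure)`.
#' @export
sociability_counts <- function(fragment, library, stereo = TRUE) {
  if (!length(library)) {
    return(c(n_chemotype = 0L, n_scaffold = 0L, n_substructure = 0L))
  }
  f_sc <- bemis_murcko(fragment)
  f_sk <- cyclic_skeleton(fragment)
  n_ch <- 0L; n_sc <- 0L; n_su <- 0L
  for (m in library) {
    if (cyclic_skeleton(m) == f_sk) n_ch <- n_ch + 1L
    if (bemis_murcko(m) == f_sc) n_sc <- n_sc + 1L
    if (has_substructure(fragment, m, stereo = stereo)) n_su <- n_su + 1L
  }
  c(n_chemotype = n_ch, n_scaffold = n_sc, n_substructure = n_su)
}

#' Scaffold novelty report
#'
#' For each query molecule, whether its Bemis-Murcko scaffold and its cyclic
#' skeleton occur in each reference set.
#'
#' @param queries list of `mol_record`.
#' @param reference_sets named list; each element a list of `mol_record`.
#' @return data.frame `query_id`, `reference_set`, `scaffold_seen`,
#'   `skeleton_seen`.
#' @export
novelty_report <- function(queries, reference_sets) {
  ref_scaf <- lapply(reference_sets, function(rs) {
    unique(vapply(rs, function(r) bemis_murcko(r$graph), character(1)))
  })
  ref_skel <- lapply(reference_sets, function(rs) {
    unique(vapply(rs, function(r) cyclic_skeleton(r$graph), character(1)))
  })
  rows <- list()
  for (q in queries) {
    qs <- bemis_murcko(q$graph); qk <- cyclic_skeleton(q$graph)
    for (nm in names(reference_sets)) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = q$id, reference_set = nm,
        scaffold_seen = qs %in% ref_scaf[[nm]],
        skeleton_seen = qk %in% ref_skel[[nm]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(), reference_set = character(),
                      scaffold_seen = logical(), skeleton_seen = logical()))
  }
  do.call(rbind, rows)
}
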