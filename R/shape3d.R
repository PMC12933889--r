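#' @title 3D conformations and the plane-of-best-fit descriptor
#' @description Conformer objects (in-silico or crystal-derived), the
#'   plane-of-best-fit (PBF) descriptor and its size-normalized form (nPBF),
#'   shape-abstracted RMSD between conformations of the same molecule, and
#'   per-ligand aggregation over crystallographic copies.
#'
#'   PBF fits a least-squares plane to all atoms carrying coordinates
#'   (hydrogens included when present, as in generated conformers; crystal
#'   conformers usually carry heavy atoms only) and reports the mean
#'   absolute distance to that plane in Angstrom. nPBF divides PBF by the
#'   number of resolved heavy atoms.
#' @name shape3d
NULL

#' Construct a conformer
#'
#' @param coords numeric matrix (n x 3), one row per atom with coordinates;
#'   unresolved atoms are not included.
#' @param element character vector of element symbols, same length.
#' @param molecule_id identifier of the parent molecule.
#' @param provenance `"in_silico"` or `"crystal"`.
#' @param resolved_mask logical vector over the molecule's heavy atoms
#'   (crystal conformers); default all resolved.
#' @param seed embedding seed (in-silico conformers).
#' @param graph optional [molgraph()] of the parent molecule (heavy atoms in
#'   graph order must correspond to the heavy-atom rows of `coords`).
#' @param copy_id,structure_id identifiers of the crystallographic copy.
#' @return object of class `conformer`.
#' @export
conformer <- function(coords, element, molecule_id = NA_character_,
                      provenance = c("in_silico", "crystal"),
                      resolved_mask = NULL, seed = NA_integer_, graph = NULL,
                      copy_id = NA_character_, structure_id = NA_character_) {
  provenance <- match.arg(provenance)
  coords <- as.matrix(coords)
  if (nrow(coords) != length(element)) {
    stop("coords and element length mismatch", call. = FALSE)
  }
  if (any(!is.finite(coords))) stop("Non-finite coordinates", call. = FALSE)
  heavy <- element != "H"
  if (is.null(resolved_mask)) resolved_mask <- rep(TRUE, sum(heavy))
  structure(list(
    molecule_id = molecule_id, provenance = provenance, coords = coords,
    element = element, heavy = heavy, resolved_mask = resolved_mask,
    seed = seed, graph = graph, copy_id = copy_id,
    structure_id = structure_id
  ), class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer %s> %s, %d atoms (%d heavy), %s\n",
              x$provenance, x$molecule_id, nrow(x$coords), sum(x$heavy),
              if (x$provenance == "in_silico") paste("seed", x$seed)
              else paste0(sum(x$resolved_mask), "/", length(x$resolved_mask),
                          " heavy atoms resolved")))
  invisible(x)
}

python_binary <- function() {
  bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) {
    stop("No python interpreter on PATH; conformer embedding requires ",
         "Python with RDKit.", call. = FALSE)
  }
  bin
}

#' Embed one 3D conformer per molecule
#'
#' Knowledge-based distance geometry (torsion-angle and ring-geometry
#' preferences, random starting coordinates, fixed seed) via RDKit's ETKDGv3,
#' run through the bundled Python helper. One conformer per molecule;
#' explicit hydrogens are kept so that the plane-of-best-fit sees the full
#' molecule.
#'
#' @param records list of `mol_record` (or character vector of SMILES).
#' @param seed integer seed; molecule `i` uses `seed + i - 1`.
#' @return list of `conformer` objects (provenance `"in_silico"`).
#' @export
embed_conformers <- function(records, seed = 42L) {
  if (is.character(records)) {
    records <- lapply(seq_along(records), function(i) {
      molecule_record(ob_canonical(records[i]), id = sprintf("mol%04d", i))
    })
  }
  if (!length(records)) return(list())
  script <- system.file("python", "embed_etkdg.py", package = "fragspace")
  if (!nzchar(script)) stop("Bundled embedding helper not found", call. = FALSE)
  fin <- tempfile(fileext = ".tsv"); fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  ids <- vapply(records, function(r) r$id, character(1))
  smis <- vapply(records, function(r) r$smiles_canonical, character(1))
  writeLines(sprintf("%s\t%s\t%d", ids, smis, seed + seq_along(records) - 1L),
             fin)
  out <- suppressWarnings(system2(python_binary(), c(shQuote(script),
                                  shQuote(fin), shQuote(fout)),
                                  stdout = TRUE, stderr = TRUE))
  fails <- sub("^FAIL ", "", grep("^FAIL ", out, value = TRUE))
  if (length(fails)) {
    stop("Conformer embedding failed for: ", paste(fails, collapse = ", "),
         call. = FALSE)
  }
  if (!file.exists(fout) || !any(out == "OK")) {
    stop("Conformer embedding helper failed: ", paste(out, collapse = "\n"),
         call. = FALSE)
  }
  sdf_lines <- readLines(fout, warn = FALSE)
  recs <- split(sdf_lines, cumsum(c(TRUE, utils::head(sdf_lines, -1) == "$$$$")))
  confs <- list()
  for (blk in recs) {
    if (length(blk) < 5L) next
    ct <- parse_ctab(blk)
    id <- trimws(blk[1L])
    i <- match(id, ids)
    sd <- grep("^>  <seed>", blk)
    sv <- if (length(sd)) as.integer(blk[sd[1L] + 1L]) else NA_integer_
    confs[[length(confs) + 1L]] <- conformer(
      ct$coords, ct$element, molecule_id = id, provenance = "in_silico",
      seed = sv, graph = if (!is.na(i)) records[[i]]$graph else NULL)
  }
  if (length(confs) != length(records)) {
    stop("Embedding returned ", length(confs), " conformers for ",
         length(records), " molecules", call. = FALSE)
  }
  confs
}

#' Embed a single molecule
#'
#' @param mol a `mol_record` or SMILES string.
#' @param seed integer seed.
#' @return a `conformer`.
#' @export
embed_conformer <- function(mol, seed = 42L) {
  rec <- if (inherits(mol, "mol_record")) mol else {
    molecule_record(ob_canonical(mol), id = "mol0001")
  }
  embed_conformers(list(rec), seed = seed)[[1L]]
}

#' Plane of best fit (PBF)
#'
#' Least-squares plane through all atoms carrying coordinates (singular
#' value decomposition of the centered coordinates); returns the mean
#' absolute perpendicular distance in Angstrom.
#'
#' @param conf a `conformer`, or a bare n x 3 coordinate matrix.
#' @return PBF in Angstrom.
#' @export
pbf <- function(conf) {
  x <- if (inherits(conf, "conformer")) conf$coords else as.matrix(conf)
  if (nrow(x) < 3L) {
    stop("PBF needs at least 3 atoms with coordinates", call. = FALSE)
  }
  xc <- sweep(x, 2L, colMeans(x))
  sv <- svd(xc)
  if (sv$d[2L] < 1e-9) {
    stop("Degenerate geometry: atoms are collinear", call. = FALSE)
  }
  normal <- sv$v[, 3L]
  mean(abs(xc %*% normal))
}

#' Size-normalized plane of best fit (nPBF)
#'
#' PBF divided by the number of resolved heavy atoms.
#'
#' @param conf a `conformer`.
#' @return dimensionless nPBF.
#' @export
npbf <- function(conf) {
  stopifnot(inherits(conf, "conformer"))
  n_heavy <- sum(conf$heavy)
  if (n_heavy == 0L) stop("No heavy atoms", call. = FALSE)
  pbf(conf) / n_heavy
}

#' Conformational flattening/puckering upon binding
#'
#' Signed difference `nPBF(protein-bound) - nPBF(in silico)`: negative when
#' the protein-bound conformation is flatter than the generated one.
#'
#' @param crystal protein-bound `conformer`.
#' @param insilico generated `conformer` of the same molecule.
#' @return signed difference.
#' @export
delta_npbf <- function(crystal, insilico) {
  npbf(crystal) - npbf(insilico)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' @param moving,target n x 3 matrices of paired coordinates.
#' @return list `rotation` (3 x 3, proper), `translation` (length 3; the
#'   transform is `x %*% rotation + translation`), `rmsd`.
#' @export
kabsch <- function(moving, target) {
  moving <- as.matrix(moving); target <- as.matrix(target)
  stopifnot(nrow(moving) == nrow(target), ncol(moving) == 3L)
  mu_m <- colMeans(moving); mu_t <- colMeans(target)
  A <- sweep(moving, 2L, mu_m); B <- sweep(target, 2L, mu_t)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  t_vec <- unname(mu_t) - as.numeric(mu_m %*% R)
  fitted <- sweep(moving %*% R, 2L, t_vec, `+`)
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((fitted - target)^2))))
}

# Abstracted graph of a conformer restricted to given heavy-atom indices:
# all atoms carbon, all bonds single.
abstract_subgraph <- function(graph, atoms) {
  b <- graph$bonds
  keep <- b$a1 %in% atoms & b$a2 %in% atoms
  idx <- match(seq_len(graph$n_atoms), atoms)
  g <- igraph::make_empty_graph(length(atoms), directed = FALSE)
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(idx[b$a1[keep]], idx[b$a2[keep]]))
  }
  g
}

#' Shape-abstracted RMSD between two conformations
#'
#' Both conformations are reduced to an abstracted representation (every
#' heavy atom carbon, every bond single); the heavy-atom RMSD after optimal
#' rigid superposition is minimized over the automorphisms of that
#' abstracted graph, so chemically equivalent and shape-equivalent atom
#' orderings cannot inflate the deviation. Only mutually resolved heavy
#' atoms are compared.
#'
#' @param a,b `conformer` objects of the same molecular graph (same
#'   heavy-atom ordering); at least one must carry the graph.
#' @param max_matchings automorphism cap; beyond it, the identity matching
#'   is used (deterministic fallback).
#' @return RMSD in Angstrom.
#' @export
abstracted_rmsd <- function(a, b, max_matchings = 10000L) {
  stopifnot(inherits(a, "conformer"), inherits(b, "conformer"))
  graph <- if (!is.null(a$graph)) a$graph else b$graph
  if (is.null(graph)) {
    stop("Neither conformer carries a molecular graph", call. = FALSE)
  }
  n_heavy <- graph$n_atoms
  ra <- conformer_resolved(a, n_heavy)
  rb <- conformer_resolved(b, n_heavy)
  mutual <- which(ra$mask & rb$mask)
  if (length(mutual) < 3L) {
    stop("Fewer than 3 mutually resolved atoms", call. = FALSE)
  }
  g <- abstract_subgraph(graph, mutual)
  maps <- tryCatch(igraph::subgraph_isomorphisms(g, g, method = "vf2"),
                   error = function(e) NULL)
  if (is.null(maps) || length(maps) == 0L || length(maps) > max_matchings) {
    maps <- list(seq_along(mutual))
  }
  A <- ra$coords[match(mutual, which(ra$mask)), , drop = FALSE]
  B <- rb$coords[match(mutual, which(rb$mask)), , drop = FALSE]
  best <- Inf
  for (mp in maps) {
    perm <- as.integer(mp)
    fit <- kabsch(B[perm, , drop = FALSE], A)
    if (fit$rmsd < best) best <- fit$rmsd
  }
  best
}

# Heavy-atom coordinates + resolved mask of a conformer, aligned to the
# molecule's heavy-atom ordering (length n_heavy).
conformer_resolved <- function(conf, n_heavy) {
  hv <- which(conf$heavy)
  mask <- rep(FALSE, n_heavy)
  present <- which(conf$resolved_mask)
  if (length(hv) == length(present)) {
    mask[present] <- TRUE
    coords <- conf$coords[hv, , drop = FALSE]
  } else {
    stop("Conformer heavy atoms do not match its resolved mask", call. = FALSE)
  }
  list(coords = coords, mask = mask)
}

#' Bundle crystallographic copies of one ligand
#'
#' @param molecule_id ligand identifier.
#' @param copies list of crystal `conformer`s.
#' @return object of class `ligand_copy_set`.
#' @export
ligand_copy_set <- function(molecule_id, copies) {
  if (!length(copies)) stop("Empty copy set", call. = FALSE)
  structure(list(molecule_id = molecule_id, copies = copies),
            class = "ligand_copy_set")
}

#' Select which crystallographic copies to keep
#'
#' All fully resolved copies are retained; when none is fully resolved, the
#' single copy with the most resolved heavy atoms is kept (ties broken
#' deterministically by structure id, then copy id).
#'
#' @param copyset a `ligand_copy_set`.
#' @return a `ligand_copy_set` with the retained copies.
#' @export
select_copies <- function(copyset) {
  stopifnot(inherits(copyset, "ligand_copy_set"))
  copies <- copyset$copies
  nres <- vapply(copies, function(cf) sum(cf$resolved_mask), integer(1))
  ntot <- vapply(copies, function(cf) length(cf$resolved_mask), integer(1))
  full <- nres == ntot
  keep <- if (any(full)) which(full) else {
    o <- order(-nres,
               vapply(copies, function(cf) paste(cf$structure_id, cf$copy_id),
                      character(1)))
    o[1L]
  }
  ligand_copy_set(copyset$molecule_id, copies[keep])
}

#' Average a per-copy descriptor into a per-ligand value
#'
#' @param values numeric vector, one value per retained copy.
#' @return arithmetic mean.
#' @export
aggregate_per_ligand <- function(values) {
  if (!length(values)) stop("No copy values to aggregate", call. = FALSE)
  mean(values)
}

#' Per-ligand 3D shape table
#'
#' For each ligand: the generated conformer's PBF/nPBF, the per-ligand
#' average over retained crystallographic copies, the binding-induced
#' nPBF change and the abstracted RMSD (averaged over retained copies).
#'
#' @param records list of `mol_record`.
#' @param copysets named list of `ligand_copy_set` keyed by molecule id
#'   (ligands without an entry get `NA` crystal columns).
#' @param seed embedding seed.
#' @return data.frame, one row per ligand.
#' @export
shape_table <- function(records, copysets = list(), seed = 42L) {
  confs <- embed_conformers(records, seed = seed)
  rows <- lapply(seq_along(records), function(i) {
    id <- records[[i]]$id
    ci <- confs[[i]]
    row <- data.frame(id = id, pbf_insilico = pbf(ci), npbf_insilico = npbf(ci),
                      pbf_crystal = NA_real_, npbf_crystal = NA_real_,
                      delta_npbf = NA_real_, rmsd = NA_real_, n_copies = 0L,
                      seed = ci$seed, stringsAsFactors = FALSE)
    cs <- copysets[[id]]
    if (!is.null(cs)) {
      kept <- select_copies(cs)
      row$n_copies <- length(kept$copies)
      row$pbf_crystal <- aggregate_per_ligand(vapply(kept$copies, pbf, numeric(1)))
      row$npbf_crystal <- aggregate_per_ligand(vapply(kept$copies, npbf, numeric(1)))
      row$delta_npbf <- row$npbf_crystal - row$npbf_insilico
      row$rmsd <- aggregate_per_ligand(
        vapply(kept$copies, abstracted_rmsd, numeric(1), b = ci))
    }
    row
  })
  do.call(rbind, rows)
}

#' Plane-of-best-fit worked examples
#'
#' Computes PBF and nPBF for the two canonical worked-example molecules,
#' globular amantadine (11 heavy atoms) and planar salicylic acid (10 heavy
#' atoms). Because the descriptor depends on the stochastic embedding, the
#' reported value is the median over a small ensemble of conformers whose
#' seeds derive from `seed` (each conformer still follows the
#' single-conformer embedding protocol); the per-conformer values are
#' returned alongside.
#'
#' @param seed base integer seed.
#' @param n_conformers ensemble size for the median (default 7).
#' @return data.frame with one row per molecule: `id`, `n_heavy`, `pbf`
#'   (median, Angstrom), `npbf` (= pbf / heavy atoms); attribute
#'   `"per_conformer"` holds the individual values.
#' @export
pbf_worked_examples <- function(seed = 42L, n_conformers = 7L) {
  fx <- reference_fixtures()
  mols <- fx[c("amantadine", "salicylic_acid")]
  per <- list()
  for (nm in names(mols)) {
    recs <- rep(list(mols[[nm]]), n_conformers)
    confs <- embed_conformers(recs, seed = seed)
    per[[nm]] <- vapply(confs, pbf, numeric(1))
  }
  out <- data.frame(
    id = names(mols),
    n_heavy = vapply(mols, function(r) r$heavy_atom_count, integer(1)),
    pbf = vapply(per, stats::median, numeric(1)),
    stringsAsFactors = FALSE)
  out$npbf <- out$pbf / out$n_heavy
  rownames(out) <- NULL
  attr(out, "per_conformer") <- per
  out
}

#' Write in-silico conformers to an SDF file
#'
#' @param confs list of `conformer`s.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_conformer_sdf <- function(confs, path) {
  lines <- character()
  for (cf in confs) {
    parts <- list(element = cf$element,
                  charge = rep(0L, length(cf$element)),
                  bonds = data.frame(a1 = integer(), a2 = integer(),
                                     order = integer()),
                  coords = cf$coords)
    if (!is.null(cf$graph)) {
      b <- cf$graph$bonds
      parts$bonds <- data.frame(a1 = b$a1, a2 = b$a2, order = b$order)
      parts$charge <- c(cf$graph$charge,
                        rep(0L, length(cf$element) - cf$graph$n_atoms))
    }
    blk <- write_ctab(parts, title = cf$molecule_id)
    # insert the seed as an SD property before the record terminator
    blk <- c(blk[-length(blk)], ">  <seed>", as.character(cf$seed), "", "$$$$")
    lines <- c(lines, blk)
  }
  writeLines(lines, path)
  invisible(path)
}
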