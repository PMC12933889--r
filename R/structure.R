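#' @title Structure models, superposition and pocket assignment
#' @description Reading protein-ligand crystal structures, least-squares
#'   superposition onto a reference structure via matched C-alpha atoms,
#'   pseudo-atom pocket definitions and the classification of ligand copies
#'   into kinase pockets (orthosteric ATP pocket "A" and peripheral sites
#'   "B".."L") by pseudo-atom proximity.
#' @name structure
NULL

#' Read a protein-ligand structure from a PDB file
#'
#' Protein `ATOM` records and non-water `HETATM` ligand copies are separated;
#' each ligand copy (unique residue) becomes a crystal [conformer()]. The
#' unit cell, when present, is parsed from the `CRYST1` record.
#'
#' @param path PDB file.
#' @param structure_id identifier (default: file name).
#' @param n_expected optional named integer vector giving the expected
#'   heavy-atom count per ligand residue name, used to mark partially
#'   resolved copies.
#' @return object of class `structure_model` with elements `structure_id`,
#'   `protein` (data.frame), `ligands` (list of `conformer`), `waters`
#'   (data.frame), `lattice` (a [crystal_lattice()] or `NULL`).
#' @export
read_structure_pdb <- function(path, structure_id = NULL, n_expected = NULL) {
  if (is.null(structure_id)) {
    structure_id <- sub("\\.pdb$", "", basename(path))
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- trimws(at$elesy)
  elem[!nzchar(elem)] <- substr(trimws(at$elety[!nzchar(elem)]), 1L, 1L)
  prot <- at$type == "ATOM"
  wat <- at$type == "HETATM" & at$resid %in% c("HOH", "WAT")
  lig <- at$type == "HETATM" & !wat
  protein <- data.frame(
    element = elem[prot], chain = at$chain[prot], resno = at$resno[prot],
    resid = at$resid[prot], atom_name = trimws(at$elety[prot]),
    x = at$x[prot], y = at$y[prot], z = at$z[prot], stringsAsFactors = FALSE)
  waters <- data.frame(
    element = elem[wat], chain = at$chain[wat], resno = at$resno[wat],
    x = at$x[wat], y = at$y[wat], z = at$z[wat], stringsAsFactors = FALSE)
  ligands <- list()
  if (any(lig)) {
    key <- paste(at$resid[lig], at$chain[lig], at$resno[lig])
    for (k in unique(key)) {
      rows <- which(lig)[key == k]
      heavy <- elem[rows] != "H"
      rows <- rows[heavy]
      resid <- at$resid[rows[1L]]
      nexp <- if (!is.null(n_expected) && resid %in% names(n_expected)) {
        n_expected[[resid]]
      } else length(rows)
      mask <- c(rep(TRUE, length(rows)), rep(FALSE, max(0L, nexp - length(rows))))
      ligands[[length(ligands) + 1L]] <- conformer(
        cbind(at$x[rows], at$y[rows], at$z[rows]), elem[rows],
        molecule_id = resid, provenance = "crystal", resolved_mask = mask,
        copy_id = paste0(at$chain[rows[1L]], at$resno[rows[1L]]),
        structure_id = structure_id)
    }
  }
  lattice <- NULL
  cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cl)) {
    lattice <- tryCatch(lattice_from_cryst1(cl[1L]), error = function(e) NULL)
  }
  structure(list(structure_id = structure_id, protein = protein,
                 ligands = ligands, waters = waters, lattice = lattice),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model %s> %d protein atoms, %d ligand copies, %d waters%s\n",
              x$structure_id, nrow(x$protein), length(x$ligands),
              nrow(x$waters),
              if (!is.null(x$lattice)) paste0(", space group ", x$lattice$spacegroup)
              else ""))
  invisible(x)
}

protein_coords <- function(model) {
  as.matrix(model$protein[, c("x", "y", "z")])
}

#' Superpose a structure onto a reference
#'
#' C-alpha atoms are matched by chain identifier and residue number (the
#' structures are assumed to be the same protein); the least-squares rigid
#' transform over the matched pairs is applied to every atom of the model,
#' ligands included.
#'
#' @param model,reference `structure_model` objects.
#' @return list with `model` (transformed copy) and `result` (class
#'   `superposition_result`: `rotation`, `translation`, `rmsd`, `n_matched`).
#' @export
superpose_to_reference <- function(model, reference) {
  ca_m <- model$protein[model$protein$atom_name == "CA", ]
  ca_r <- reference$protein[reference$protein$atom_name == "CA", ]
  key_m <- paste(ca_m$chain, ca_m$resno)
  key_r <- paste(ca_r$chain, ca_r$resno)
  common <- intersect(key_m, key_r)
  if (length(common) < 3L) {
    stop("Superposition needs at least 3 matched C-alpha pairs; found ",
         length(common), call. = FALSE)
  }
  P <- as.matrix(ca_m[match(common, key_m), c("x", "y", "z")])
  Q <- as.matrix(ca_r[match(common, key_r), c("x", "y", "z")])
  fit <- kabsch(P, Q)
  tx <- function(m) sweep(m %*% fit$rotation, 2L, fit$translation, `+`)
  out <- model
  pm <- tx(protein_coords(model))
  out$protein$x <- pm[, 1L]; out$protein$y <- pm[, 2L]; out$protein$z <- pm[, 3L]
  out$ligands <- lapply(model$ligands, function(cf) {
    cf$coords <- tx(cf$coords)
    cf
  })
  if (nrow(model$waters)) {
    wm <- tx(as.matrix(model$waters[, c("x", "y", "z")]))
    out$waters$x <- wm[, 1L]; out$waters$y <- wm[, 2L]; out$waters$z <- wm[, 3L]
  }
  res <- structure(list(rotation = fit$rotation, translation = fit$translation,
                        rmsd = fit$rmsd, n_matched = length(common)),
                   class = "superposition_result")
  list(model = out, result = res)
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> %d C-alpha pairs, rmsd %.3f A\n",
              x$n_matched, x$rmsd))
  invisible(x)
}

#' Pseudo-atom position from reference ligand atoms
#'
#' Center of mass (standard atomic masses) or plain centroid of the atoms of
#' the reference ligand(s) known to occupy a pocket; for the ATP pocket the
#' convention is the center of mass of the adenine substructure of bound ATP.
#'
#' @param coords n x 3 coordinate matrix.
#' @param elements element symbols (required for `mode = "mass"`).
#' @param mode `"mass"` (default) or `"centroid"`.
#' @return length-3 coordinate.
#' @export
pocket_center <- function(coords, elements = NULL,
                          mode = c("mass", "centroid")) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3L)
  if (nrow(coords) == 0L) stop("No atoms supplied", call. = FALSE)
  if (mode == "centroid") return(colMeans(coords))
  if (is.null(elements)) stop("mode='mass' needs element symbols", call. = FALSE)
  w <- ATOMIC_MASSES[elements]
  if (anyNA(w)) stop("Unknown element in pocket ligand atoms", call. = FALSE)
  as.numeric(t(coords) %*% w / sum(w))
}

#' Define a set of labeled pockets
#'
#' @param labels character vector (conventionally `"A"` for the orthosteric
#'   ATP pocket, `"B".."L"` for peripheral sites).
#' @param centers n x 3 matrix of pseudo-atom coordinates.
#' @param radius pocket radius in Angstrom (default 5), recycled.
#' @return data.frame of class `pocket_set` with columns `label`, `x`, `y`,
#'   `z`, `radius`.
#' @export
pocket_set <- function(labels, centers, radius = 5) {
  centers <- as.matrix(centers)
  stopifnot(length(labels) == nrow(centers))
  if (anyDuplicated(labels)) stop("Pocket labels must be unique", call. = FALSE)
  if (any(radius <= 0)) stop("Pocket radius must be positive", call. = FALSE)
  out <- data.frame(label = labels, x = centers[, 1L], y = centers[, 2L],
                    z = centers[, 3L], radius = radius,
                    stringsAsFactors = FALSE)
  class(out) <- c("pocket_set", class(out))
  out
}

#' Assign a ligand copy to pockets
#'
#' A pocket label is assigned when any resolved heavy atom of the copy lies
#' within the pocket radius of its pseudo-atom (boundary inclusive). The
#' alternative `mode = "centroid"` tests only the copy's centroid, for the
#' stricter reading of "located in a 5 A radius".
#'
#' @param copy a crystal `conformer`, superposed into the reference frame.
#' @param pockets a [pocket_set()].
#' @param mode `"any_atom"` (default) or `"centroid"`.
#' @return character vector of assigned labels (possibly empty).
#' @export
assign_pockets <- function(copy, pockets, mode = c("any_atom", "centroid")) {
  mode <- match.arg(mode)
  coords <- copy$coords[copy$element != "H", , drop = FALSE]
  if (mode == "centroid") coords <- matrix(colMeans(coords), 1L, 3L)
  hits <- vapply(seq_len(nrow(pockets)), function(i) {
    ctr <- c(pockets$x[i], pockets$y[i], pockets$z[i])
    d2 <- rowSums(sweep(coords, 2L, ctr)^2)
    any(d2 <= pockets$radius[i]^2)
  }, logical(1))
  pockets$label[hits]
}

#' Classify a fragment's binding from its per-copy pocket assignments
#'
#' @param assignments list of character vectors, one per crystallographic
#'   copy, as returned by [assign_pockets()].
#' @param orthosteric label of the orthosteric pocket (default `"A"`).
#' @return one of `"orthosteric_only"`, `"peripheral_only"`, `"both"`,
#'   `"unassigned"`.
#' @export
classify_binder <- function(assignments, orthosteric = "A") {
  if (!length(assignments)) stop("No copies supplied", call. = FALSE)
  labels <- unique(unlist(assignments))
  if (!length(labels)) return("unassigned")
  has_orth <- orthosteric %in% labels
  has_peri <- length(setdiff(labels, orthosteric)) > 0L
  if (has_orth && has_peri) "both"
  else if (has_orth) "orthosteric_only"
  else "peripheral_only"
}

#' Write / read pocket definitions as CSV
#'
#' @param pockets a [pocket_set()].
#' @param path CSV path.
#' @return (`read_pocket_csv`) a `pocket_set`.
#' @export
write_pocket_csv <- function(pockets, path) {
  utils::write.csv(as.data.frame(pockets), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pocket_csv
#' @export
read_pocket_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pocket_set(df$label, as.matrix(df[, c("x", "y", "z")]), df$radius)
}
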