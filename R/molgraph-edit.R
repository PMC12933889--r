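#' @title Molecular graph editing and serialization
#' @description Helpers to take induced subgraphs of a molecule, write them
#'   back out as V2000 connection tables, and round-trip them through the
#'   canonicalizer. Used by the standardizer (metal removal, desalting) and
#'   the scaffold machinery (substituent pruning, skeleton abstraction).
#' @name molgraph-edit
#' @keywords internal
NULL

#' Induced subgraph of a molgraph as raw parts
#'
#' @param mg a molgraph.
#' @param atoms integer vector of atom indices to keep.
#' @return list(element, charge, bonds) with bonds reindexed to the kept
#'   atoms (in the order given).
#' @keywords internal
molgraph_parts <- function(mg, atoms) {
  idx <- match(seq_len(mg$n_atoms), atoms)
  b <- mg$bonds
  keep <- b$a1 %in% atoms & b$a2 %in% atoms
  b <- b[keep, , drop = FALSE]
  list(
    element = mg$element[atoms],
    charge = mg$charge[atoms],
    bonds = data.frame(a1 = idx[b$a1], a2 = idx[b$a2], order = b$order)
  )
}

#' Write raw molecule parts as a V2000 SDF record
#'
#' Coordinates default to zero (connection-table-only record); formal charges
#' are emitted as `M  CHG` lines.
#'
#' @param parts list(element, charge, bonds[, coords]).
#' @param title record title.
#' @return character vector of SDF lines (terminated by `$$$$`).
#' @keywords internal
write_ctab <- function(parts, title = "mol") {
  n <- length(parts$element)
  nb <- nrow(parts$bonds)
  coords <- parts$coords
  if (is.null(coords)) coords <- matrix(0, n, 3L)
  lines <- c(title, "  fragspace", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              coords[i, 1], coords[i, 2], coords[i, 3],
                              parts$element[i]))
  }
  if (nb) for (k in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              parts$bonds$a1[k], parts$bonds$a2[k],
                              parts$bonds$order[k]))
  }
  chg <- which(parts$charge != 0L)
  for (i in chg) {
    lines <- c(lines, sprintf("M  CHG%3d%4d%4d", 1L, i, parts$charge[i]))
  }
  c(lines, "M  END", "$$$$")
}

#' Canonical SMILES of raw molecule parts (via the connection table)
#' @keywords internal
parts_to_smiles <- function(parts) {
  sdf <- write_ctab(parts)
  out <- ob_run(sdf, "sdf", "can")
  out <- out[nzchar(trimws(out))]
  if (!length(out)) stop("Canonicalization of edited structure failed")
  strsplit(out[1L], "[ \t]+")[[1L]][1L]
}
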