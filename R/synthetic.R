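#' @title Synthetic fixtures: molecule libraries, toy crystals, reference
#'   molecules
#' @description Generators for everything the pipeline needs without
#'   downloads: molecule libraries with controlled saturation/aromaticity
#'   structure ("flat" heteroaromatic vs "three_d" saturated stereocenter-rich
#'   profiles), toy crystals with a known unit cell, protein point cloud and
#'   ligand copies placed at known pocket centers and lattice interfaces
#'   (ground truth recoverable by construction), activity tables, and the
#'   small reference molecules with documented descriptor values.
#' @name synthetic
NULL

# Building-block grammar: sprintf templates with one substitution site.
# Products are filtered against the profile constraints after generation,
# so every emitted molecule satisfies its profile by construction.
FLAT_TEMPLATES <- c(
  "c1cc(%s)c2ccccc2c1",      # naphthalene
  "c1cc(%s)c2ncccc2c1",      # quinoline
  "c1cc(%s)c2cnccc2c1",      # isoquinoline
  "c1cc(%s)cc2c1cc[nH]2",    # indole
  "c1cc(%s)c2occc2c1",       # benzofuran
  "c1cc(%s)c2sccc2c1",       # benzothiophene
  "c1cc(%s)ccc1-c1ccccc1",   # biphenyl
  "c1cc(%s)ccc1-c1ccncc1",   # phenylpyridine
  "c1cc(%s)c2ncncc2c1",      # quinazoline
  "c1cc(%s)ccc1-c1cccs1"     # phenylthiophene
)
FLAT_SUBSTITUENTS <- c("", "F", "Cl", "Br", "C#N", "O", "N", "OC",
                       "C(F)(F)F", "C(N)=O")

THREED_TEMPLATES <- c(
  "C[C@H]1CC[C@@H](%s)C(=O)C1",   # 2-methylcyclohexanone
  "C[C@H]1O[C@@H](%s)CC[C@@H]1O", # trisubstituted oxane
  "O[C@@H]1C[C@H](%s)CN1",        # pyrrolidinol
  "C[C@H](O)C[C@@H](%s)C(=O)O",   # hydroxy acid chain
  "N[C@@H]1C[C@H](%s)C[C@@H](O)C1", # aminocyclohexanol
  "CC1(C)C[C@@H](%s)CC[C@H]1O",   # gem-dimethyl cyclohexanol
  "C[C@@H]1CC[C@H](%s)CN1",       # methylpiperidine
  "O[C@H]1CO[C@@H](%s)C1",        # oxolanol
  "C[C@H]1C[C@@H](%s)C[C@H](C)O1", # dimethyl oxane
  "N[C@@H](C%s)C(=O)O"            # amino acid chain
)
THREED_SUBSTITUENTS <- c("", "C", "O", "N", "CO", "CC", "C(C)C", "CN",
                         "CCO", "C(C)O")

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

expand_grammar <- function(templates, substituents) {
  out <- character()
  for (tp in templates) for (su in substituents) {
    smi <- if (nzchar(su)) sprintf(tp, su) else gsub("(%s)", "", tp, fixed = TRUE)
    out <- c(out, smi)
  }
  unique(out)
}

#' Generate a synthetic molecule library
#'
#' Deterministic per seed. Profiles:
#' \describe{
#'   \item{flat}{fused/linked heteroaromatic products; every molecule has
#'     at least 2 aromatic rings and Fsp3 <= 0.2.}
#'   \item{three_d}{saturated ring/chain products with stereocenters; every
#'     molecule has Fsp3 >= 0.42, at most 1 aromatic ring and at least one
#'     stereocenter.}
#'   \item{mixed}{half flat, half three_d (flat gets the extra molecule for
#'     odd `n`).}
#' }
#'
#' @param profile `"flat"`, `"three_d"` or `"mixed"`.
#' @param n number of molecules (must not exceed the grammar's pool of
#'   distinct conforming products).
#' @param seed integer seed.
#' @return list of `mol_record` with `source_tag` set to the profile.
#' @export
generate_library <- function(profile = c("flat", "three_d", "mixed"), n = 50L,
                             seed = 7L) {
  profile <- match.arg(profile)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (profile == "mixed") {
    n_flat <- ceiling(n / 2); n_3d <- n - n_flat
    out <- generate_library("flat", n_flat, seed)
    if (n_3d > 0L) out <- c(out, generate_library("three_d", n_3d, seed + 1L))
    return(out)
  }
  smis <- if (profile == "flat") {
    expand_grammar(FLAT_TEMPLATES, FLAT_SUBSTITUENTS)
  } else {
    expand_grammar(THREED_TEMPLATES, THREED_SUBSTITUENTS)
  }
  cans <- ob_canonical(smis)
  cans <- unique(cans[!is.na(cans)])
  recs <- lapply(cans, function(s) molecule_record(s, source_tag = profile))
  ok <- vapply(recs, function(r) {
    f <- suppressWarnings(fsp3(r$graph))
    nar <- length(r$graph$aromatic_rings)
    if (profile == "flat") nar >= 2L && f <= 0.2
    else f >= 0.42 && nar <= 1L && sum(r$graph$stereocenter) >= 1L
  }, logical(1))
  pool <- recs[ok]
  if (n > length(pool)) {
    stop("Unsatisfiable profile: ", n, " molecules requested but the grammar",
         " yields only ", length(pool), " conforming products", call. = FALSE)
  }
  sel <- with_local_seed(seed, sample.int(length(pool), n))
  out <- pool[sel]
  for (i in seq_along(out)) out[[i]]$id <- sprintf("%s%03d", toupper(substr(profile, 1, 1)), i)
  out
}

#' Generate a synthetic activity table
#'
#' Draws molecules from the mixed grammar and attaches pChEMBL values
#' (normal around 6, truncated at 0) and assay confidence scores (8 or 9).
#'
#' @param n number of rows.
#' @param seed integer seed.
#' @param path optional CSV path to write.
#' @return data.frame `id`, `smiles`, `pchembl`, `confidence`, `source_tag`.
#' @export
generate_activity_table <- function(n = 20L, seed = 11L, path = NULL) {
  recs <- generate_library("mixed", n, seed)
  df <- with_local_seed(seed + 1L, {
    data.frame(
      id = sprintf("ACT%03d", seq_len(n)),
      smiles = vapply(recs, function(r) r$smiles_canonical, character(1)),
      pchembl = round(pmax(0, stats::rnorm(n, mean = 6, sd = 1.2)), 2),
      confidence = sample(c(8L, 9L), n, replace = TRUE, prob = c(0.3, 0.7)),
      source_tag = "chembl_kinase",
      stringsAsFactors = FALSE)
  })
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

orthonormal_basis <- function(u) {
  u <- u / sqrt(sum(u^2))
  a <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2L] * v[3L] - u[3L] * v[2L],
         u[3L] * v[1L] - u[1L] * v[3L],
         u[1L] * v[2L] - u[2L] * v[1L])
  list(u = u, v = v, w = w)
}

# Rigid 5-atom carbon cross in the plane perpendicular to `dir`, centered at
# `pocket_center + dist * dir`: the central atom is the nearest ligand atom
# to the pseudo-atom, so the constructed nearest-atom distance is exact.
place_cross <- function(pocket_center, dir, dist, arm = 1.3) {
  b <- orthonormal_basis(dir)
  ctr <- pocket_center + dist * b$u
  rbind(ctr,
        ctr + arm * b$v, ctr - arm * b$v,
        ctr + arm * b$w, ctr - arm * b$w)
}

#' Default toy-crystal layout
#'
#' Six ligands exercising the pocket and lattice machinery: an
#' orthosteric-only binder with two copies in pocket A, a peripheral-only
#' binder in pocket G, a dual binder with one copy in each, a
#' lattice-interface ligand near the cell edge (no pocket), and the two
#' boundary cases with nearest atoms at 4.9 and 5.1 Angstrom of pocket A.
#'
#' @return data.frame understood by [generate_toy_crystal()].
#' @export
toy_crystal_default_layout <- function() {
  data.frame(
    ligand_id = c("L01", "L01", "L02", "L03", "L03", "L04", "L05", "L06"),
    pocket = c("A", "A", "G", "A", "G", NA, "A", "A"),
    dist = c(4.0, 4.0, 4.0, 4.5, 4.5, NA, 4.9, 5.1),
    dir = c("z+", "x+", "z+", "x-", "y+", NA, "y+", "y-"),
    interface = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    expected = c("A", "A", "G", "A", "G", "", "A", ""),
    stringsAsFactors = FALSE)
}

DIR_VECTORS <- list(`x+` = c(1, 0, 0), `x-` = c(-1, 0, 0),
                    `y+` = c(0, 1, 0), `y-` = c(0, -1, 0),
                    `z+` = c(0, 0, 1), `z-` = c(0, 0, -1))

#' Generate a toy crystal with known ground truth
#'
#' Writes a PDB file with a `CRYST1` record, a protein C-alpha point cloud
#' (a spherical blob plus one "arm" atom near the cell edge) and rigid
#' 5-atom ligand copies placed at the distances and directions given by the
#' layout, plus a ground-truth CSV. Pocket pseudo-atoms A and G sit outside
#' the blob; the interface ligand sits near the cell boundary so that a
#' lattice translate of the arm approaches it closer than the asymmetric
#' unit does (margin >= 0.5 Angstrom everywhere by construction).
#'
#' @param layout data.frame as from [toy_crystal_default_layout()].
#' @param cell unit cell (default 40 Angstrom cube, P1).
#' @param spacegroup space-group symbol (default `"P1"`; the default layout's
#'   ground truth assumes P1).
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return list `pdb_path`, `truth_path`, `model` (the structure read back),
#'   `pockets` (a [pocket_set()]), `truth` (data.frame with per-copy labels,
#'   per-ligand binder class and lattice flags), `lattice`.
#' @export
generate_toy_crystal <- function(layout = toy_crystal_default_layout(),
                                 cell = c(40, 40, 40, 90, 90, 90),
                                 spacegroup = "P1", dir = tempdir(),
                                 prefix = "toycrystal") {
  stopifnot(nrow(layout) >= 1L)
  lattice <- crystal_lattice(cell, spacegroup)
  blob_center <- c(20, 20, 20)
  pts <- sphere_points(96L) * 7
  protein <- rbind(sweep(pts, 2L, blob_center, `+`),
                   blob_center,
                   c(38, 20, 20))  # arm atom near the +x cell face
  pockets <- pocket_set(c("A", "G"),
                        rbind(c(20, 20, 31), c(20, 31, 20)), radius = 5)
  lig_coords <- list(); lig_meta <- list()
  for (i in seq_len(nrow(layout))) {
    if (isTRUE(layout$interface[i])) {
      coords <- place_cross(c(2, 20, 20), c(1, 0, 0), 0)
    } else {
      pk <- pockets[pockets$label == layout$pocket[i], ]
      dirv <- DIR_VECTORS[[layout$dir[i]]]
      coords <- place_cross(c(pk$x, pk$y, pk$z), dirv, layout$dist[i])
    }
    lig_coords[[i]] <- coords
    lig_meta[[i]] <- data.frame(ligand_id = layout$ligand_id[i],
                                copy = i, stringsAsFactors = FALSE)
  }
  # overlap guard: ligand copies must not clash with the protein or each other
  for (i in seq_along(lig_coords)) {
    if (sqrt(min(min_dist2(lig_coords[[i]], protein))) < 2) {
      stop("Overlapping placement: ligand ", layout$ligand_id[i],
           " clashes with the protein", call. = FALSE)
    }
    for (j in seq_along(lig_coords)) {
      if (j <= i) next
      if (sqrt(min(min_dist2(lig_coords[[i]], lig_coords[[j]]))) < 2) {
        stop("Overlapping placement: ligands ", layout$ligand_id[i], " and ",
             layout$ligand_id[j], call. = FALSE)
      }
    }
  }
  pdb_path <- file.path(dir, paste0(prefix, ".pdb"))
  lines <- sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
    cell[1], cell[2], cell[3], cell[4], cell[5], cell[6], spacegroup, 1L)
  serial <- 0L
  for (i in seq_len(nrow(protein))) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, i, protein[i, 1], protein[i, 2], protein[i, 3]))
  }
  for (i in seq_along(lig_coords)) {
    for (k in seq_len(nrow(lig_coords[[i]]))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d  C%d  %-3s X%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, k, layout$ligand_id[i], i,
        lig_coords[[i]][k, 1], lig_coords[[i]][k, 2], lig_coords[[i]][k, 3]))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, pdb_path)
  model <- read_structure_pdb(pdb_path, structure_id = prefix)
  truth <- layout
  truth$copy_id <- paste0("X", seq_len(nrow(layout)))
  truth$lattice_proximal <- isTRUE(spacegroup == "P1") & layout$interface
  cls <- vapply(unique(layout$ligand_id), function(lid) {
    labs <- layout$expected[layout$ligand_id == lid]
    classify_binder(strsplit(labs, ",", fixed = TRUE))
  }, character(1))
  truth$binder_class <- cls[truth$ligand_id]
  truth_path <- file.path(dir, paste0(prefix, "_truth.csv"))
  utils::write.csv(truth, truth_path, row.names = FALSE)
  list(pdb_path = pdb_path, truth_path = truth_path, model = model,
       pockets = pockets, truth = truth, lattice = lattice)
}

#' Reference molecules with documented descriptor values
#'
#' The small worked-example molecules used throughout the package
#' documentation and tests: amantadine (11 heavy atoms, the globular
#' plane-of-best-fit example), salicylic acid (10 heavy atoms, the planar
#' example), benzene, cyclohexane, toluene and (S)-alanine.
#'
#' @return named list of `mol_record`.
#' @export
reference_fixtures <- function() {
  smis <- c(
    amantadine = "NC12CC3CC(C2)CC(C1)C3",
    salicylic_acid = "OC(=O)c1ccccc1O",
    benzene = "c1ccccc1",
    cyclohexane = "C1CCCCC1",
    toluene = "Cc1ccccc1",
    s_alanine = "C[C@H](N)C(=O)O")
  out <- lapply(names(smis), function(nm) {
    molecule_record(ob_canonical(smis[[nm]]), id = nm,
                    smiles_raw = smis[[nm]], source_tag = "reference")
  })
  names(out) <- names(smis)
  out
}
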