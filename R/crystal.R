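#' @title Crystallographic symmetry expansion and contact analysis
#' @description Unit-cell handling, generation of the symmetry mates of the
#'   protein within a cutoff of a ligand copy, detection of lattice-proximal
#'   ligands (any atom closer to a symmetry mate than to the asymmetric
#'   unit), partition of the ligand's solvent-accessible surface between
#'   protein entities, and distance-based polar-contact counting.
#' @name crystal
NULL

#' Construct a crystal lattice
#'
#' @param cell numeric vector `c(a, b, c, alpha, beta, gamma)` (Angstrom,
#'   degrees).
#' @param spacegroup Hermann-Mauguin symbol (spaces ignored), looked up in
#'   the packaged operator table; alternatively supply `operators`.
#' @param operators optional list of `list(R = 3x3, t = length-3)` fractional
#'   operators (identity first).
#' @return object of class `crystal_lattice`.
#' @export
crystal_lattice <- function(cell, spacegroup = "P1", operators = NULL) {
  stopifnot(length(cell) == 6L)
  if (any(cell[1:3] <= 0)) stop("Cell lengths must be positive", call. = FALSE)
  if (any(cell[4:6] <= 0 | cell[4:6] >= 180)) {
    stop("Cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  if (is.null(operators)) operators <- spacegroup_operators(spacegroup)
  id <- operators[[1L]]
  if (!isTRUE(all.equal(id$R, diag(3))) || !isTRUE(all.equal(id$t, c(0, 0, 0)))) {
    stop("First operator must be the identity", call. = FALSE)
  }
  ab <- cell[4:6] * pi / 180
  ca <- cos(ab[1]); cb <- cos(ab[2]); cg <- cos(ab[3]); sg <- sin(ab[3])
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  # orthogonalization: a along x, b in the xy-plane
  M <- matrix(c(cell[1], cell[2] * cg, cell[3] * cb,
                0,       cell[2] * sg, cell[3] * (ca - cb * cg) / sg,
                0,       0,            cell[3] * v / sg),
              nrow = 3L, byrow = TRUE)
  structure(list(cell = cell, spacegroup = toupper(gsub(" ", "", spacegroup)),
                 operators = operators, orth = M, frac = solve(M)),
            class = "crystal_lattice")
}

#' @export
print.crystal_lattice <- function(x, ...) {
  cat(sprintf("<crystal_lattice %s> a=%.2f b=%.2f c=%.2f alpha=%.1f beta=%.1f gamma=%.1f, %d operators\n",
              x$spacegroup, x$cell[1], x$cell[2], x$cell[3], x$cell[4],
              x$cell[5], x$cell[6], length(x$operators)))
  invisible(x)
}

#' Look up space-group operators from the packaged table
#'
#' @param symbol Hermann-Mauguin symbol; spaces and case are ignored.
#' @return list of `list(R, t)` operators, identity first.
#' @export
spacegroup_operators <- function(symbol) {
  key <- toupper(gsub(" ", "", symbol))
  path <- system.file("extdata", "spacegroups.csv", package = "fragspace")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  rows <- tab[toupper(tab$symbol) == key, ]
  if (!nrow(rows)) {
    stop("Space group '", symbol, "' not in the packaged operator table; ",
         "supply operators explicitly.", call. = FALSE)
  }
  rows <- rows[order(rows$op), ]
  lapply(seq_len(nrow(rows)), function(i) {
    list(R = matrix(as.numeric(rows[i, c("r11", "r12", "r13",
                                         "r21", "r22", "r23",
                                         "r31", "r32", "r33")]),
                    3L, 3L, byrow = TRUE),
         t = as.numeric(rows[i, c("t1", "t2", "t3")]))
  })
}

#' Parse a PDB CRYST1 record into a lattice
#'
#' @param line the CRYST1 line.
#' @return a [crystal_lattice()].
#' @export
lattice_from_cryst1 <- function(line) {
  cell <- as.numeric(c(substr(line, 7, 15), substr(line, 16, 24),
                       substr(line, 25, 33), substr(line, 34, 40),
                       substr(line, 41, 47), substr(line, 48, 54)))
  sg <- trimws(substr(line, 56, 66))
  crystal_lattice(cell, spacegroup = sg)
}

frac_to_cart <- function(lattice, frac) t(lattice$orth %*% t(frac))
cart_to_frac <- function(lattice, cart) t(lattice$frac %*% t(cart))

min_dist2 <- function(A, B) {
  # squared distance from each row of A to the nearest row of B
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, `+`) - 2 * (A %*% t(B))
  pmax(apply(d2, 1L, min), 0)
}

#' Generate symmetry mates near a ligand copy
#'
#' All symmetry/lattice images of the protein with at least one atom within
#' `cutoff` of at least one ligand atom. The identity operator with zero
#' lattice translation (the asymmetric unit itself) is never a mate.
#'
#' @param protein_coords n x 3 Cartesian protein coordinates (asymmetric
#'   unit).
#' @param lattice a [crystal_lattice()].
#' @param ligand_coords m x 3 Cartesian ligand coordinates (same frame).
#' @param cutoff contact distance in Angstrom (default 6).
#' @return list of `symmetry_mate` objects: `op` (operator index),
#'   `shift` (integer lattice translation), `coords` (transformed protein),
#'   `min_dist` (closest approach to the ligand).
#' @export
expand_symmetry <- function(protein_coords, lattice, ligand_coords,
                            cutoff = 6) {
  stopifnot(inherits(lattice, "crystal_lattice"))
  protein_coords <- as.matrix(protein_coords)
  ligand_coords <- as.matrix(ligand_coords)
  if (cutoff <= 0) return(list())
  pf <- cart_to_frac(lattice, protein_coords)
  lf <- cart_to_frac(lattice, ligand_coords)
  # candidate lattice shifts: enough to cover the distance between the
  # ligand's and the transformed protein's fractional bounding boxes
  mates <- list()
  shifts <- expand.grid(s1 = -2:2, s2 = -2:2, s3 = -2:2)
  for (oi in seq_along(lattice$operators)) {
    op <- lattice$operators[[oi]]
    pfo <- t(op$R %*% t(pf)) + matrix(op$t, nrow(pf), 3L, byrow = TRUE)
    for (si in seq_len(nrow(shifts))) {
      sh <- as.numeric(shifts[si, ])
      if (oi == 1L && all(sh == 0)) next
      cand <- sweep(pfo, 2L, sh, `+`)
      cart <- frac_to_cart(lattice, cand)
      # cheap bounding-box rejection before the full distance computation
      if (any(apply(cart, 2L, min) > apply(ligand_coords, 2L, max) + cutoff) ||
          any(apply(cart, 2L, max) < apply(ligand_coords, 2L, min) - cutoff)) {
        next
      }
      dmin <- sqrt(min(min_dist2(ligand_coords, cart)))
      if (dmin <= cutoff) {
        mates[[length(mates) + 1L]] <- structure(
          list(op = oi, shift = as.integer(sh), coords = cart,
               min_dist = dmin), class = "symmetry_mate")
      }
    }
  }
  mates
}

#' Is a ligand copy lattice-proximal?
#'
#' `TRUE` when any ligand atom is strictly closer to a symmetry-mate protein
#' atom than to the asymmetric unit (ties resolve to the asymmetric unit).
#'
#' @param ligand_coords m x 3 ligand coordinates.
#' @param asym_coords asymmetric-unit protein coordinates.
#' @param mates list of symmetry mates from [expand_symmetry()].
#' @return logical.
#' @export
flag_lattice_proximal <- function(ligand_coords, asym_coords, mates) {
  if (!length(mates)) return(FALSE)
  ligand_coords <- as.matrix(ligand_coords)
  d_asym <- min_dist2(ligand_coords, as.matrix(asym_coords))
  for (m in mates) {
    d_mate <- min_dist2(ligand_coords, m$coords)
    if (any(d_mate < d_asym)) return(TRUE)
  }
  FALSE
}

VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
               S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

# Deterministic golden-section spiral on the unit sphere.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Partition a ligand's solvent-accessible surface between protein entities
#'
#' Shrake-Rupley point sampling: each ligand atom's solvent-accessible
#' sphere (van der Waals radius + probe) is sampled with a deterministic
#' spiral; points buried by other ligand atoms are discarded. Every exposed
#' point is attributed to the entity owning the nearest protein heavy atom,
#' provided that atom lies within `proximity_cap`; otherwise the point stays
#' unassigned. Percentages are areas relative to the total accessible
#' surface.
#'
#' @param ligand_coords m x 3 ligand heavy-atom coordinates.
#' @param ligand_elements element symbols.
#' @param entities named list of k x 3 coordinate matrices (e.g. asymmetric
#'   unit and each symmetry mate).
#' @param probe probe radius in Angstrom (default 1.4).
#' @param proximity_cap maximum point-to-protein-atom distance for
#'   attribution (default 6).
#' @param n_points sampling points per atom (default 960).
#' @return object of class `surface_partition`: data.frame with `entity`,
#'   `area` (A^2), `percent`; attribute `total_area`; the `"unassigned"` row
#'   absorbs the remainder.
#' @export
surface_partition <- function(ligand_coords, ligand_elements, entities,
                              probe = 1.4, proximity_cap = 6,
                              n_points = 960L) {
  ligand_coords <- as.matrix(ligand_coords)
  m <- nrow(ligand_coords)
  if (m == 0L) stop("Zero-area ligand", call. = FALSE)
  if (!length(entities)) stop("At least one entity required", call. = FALSE)
  if (is.null(names(entities)) || any(!nzchar(names(entities)))) {
    names(entities) <- paste0("entity", seq_along(entities))
  }
  radii <- vdw_radius(ligand_elements) + probe
  pts <- sphere_points(n_points)
  ent_names <- names(entities)
  areas <- stats::setNames(numeric(length(entities) + 1L),
                           c(ent_names, "unassigned"))
  total <- 0
  for (i in seq_len(m)) {
    p <- sweep(pts * radii[i], 2L, ligand_coords[i, ], `+`)
    # exposed = outside every other ligand atom's accessible sphere
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(m)) {
      if (j == i) next
      d2 <- rowSums(sweep(p, 2L, ligand_coords[j, ])^2)
      exposed <- exposed & d2 > radii[j]^2
      if (!any(exposed)) break
    }
    if (!any(exposed)) next
    pe <- p[exposed, , drop = FALSE]
    a_point <- 4 * pi * radii[i]^2 / n_points
    total <- total + nrow(pe) * a_point
    best_d2 <- rep(Inf, nrow(pe)); best_e <- rep(NA_integer_, nrow(pe))
    for (ei in seq_along(entities)) {
      d2 <- min_dist2(pe, as.matrix(entities[[ei]]))
      upd <- d2 < best_d2
      best_d2[upd] <- d2[upd]; best_e[upd] <- ei
    }
    ok <- best_d2 <= proximity_cap^2
    for (ei in seq_along(entities)) {
      areas[ei] <- areas[ei] + sum(ok & best_e == ei) * a_point
    }
    areas["unassigned"] <- areas["unassigned"] + sum(!ok) * a_point
  }
  if (total <= 0) stop("Zero-area ligand", call. = FALSE)
  out <- data.frame(entity = names(areas), area = as.numeric(areas),
                    percent = 100 * as.numeric(areas) / total,
                    stringsAsFactors = FALSE)
  attr(out, "total_area") <- total
  class(out) <- c("surface_partition", class(out))
  out
}

# Protein atoms carrying a formal charge at physiological pH, typed by
# residue and atom name (sidechain termini of Arg/Lys positive, Asp/Glu
# negative).
PROTEIN_CHARGED <- data.frame(
  resid = c("ARG", "ARG", "ARG", "LYS", "ASP", "ASP", "GLU", "GLU"),
  atom_name = c("NH1", "NH2", "NE", "NZ", "OD1", "OD2", "OE1", "OE2"),
  charge = c(1, 1, 1, 1, -1, -1, -1, -1),
  stringsAsFactors = FALSE)

#' Count polar contacts between a ligand copy and a protein entity
#'
#' Distance-only criteria on heavy atoms (inputs may lack hydrogens):
#' a hydrogen-bond contact is any ligand N/O/S within `hbond_cutoff` of an
#' entity N/O/S; a salt bridge additionally requires opposite formal charges
#' (ligand charges from its molecular graph when available; protein charges
#' from the Arg/Lys/Asp/Glu sidechain-atom convention) within `salt_cutoff`.
#'
#' @param copy a crystal `conformer` (its graph, when present, provides
#'   ligand formal charges).
#' @param entity data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `resid`, `atom_name` (as in `structure_model$protein`).
#' @param hbond_cutoff heavy-atom distance cutoff in Angstrom (default 3.5).
#' @param salt_cutoff salt-bridge cutoff (default 4.0).
#' @return list `n_hbonds`, `n_saltbridges`, `contacts` (data.frame of
#'   ligand atom, partner atom, distance, type).
#' @export
polar_contacts <- function(copy, entity, hbond_cutoff = 3.5,
                           salt_cutoff = 4.0) {
  le <- copy$element
  lc <- copy$coords
  lig_polar <- which(le %in% c("N", "O", "S"))
  lig_charge <- rep(0, length(le))
  if (!is.null(copy$graph)) {
    hv <- which(le != "H")
    res <- which(copy$resolved_mask)
    if (length(hv) == length(res)) lig_charge[hv] <- copy$graph$charge[res]
  }
  ent_polar <- which(entity$element %in% c("N", "O", "S"))
  ec <- as.matrix(entity[, c("x", "y", "z")])
  ent_charge <- rep(0, nrow(entity))
  if (all(c("resid", "atom_name") %in% names(entity))) {
    key <- paste(entity$resid, entity$atom_name)
    mk <- match(key, paste(PROTEIN_CHARGED$resid, PROTEIN_CHARGED$atom_name))
    ent_charge[!is.na(mk)] <- PROTEIN_CHARGED$charge[mk[!is.na(mk)]]
  }
  rows <- list()
  for (i in lig_polar) {
    d <- sqrt(rowSums(sweep(ec[ent_polar, , drop = FALSE], 2L, lc[i, ])^2))
    hb <- which(d <= hbond_cutoff)
    for (k in hb) {
      rows[[length(rows) + 1L]] <- data.frame(
        ligand_atom = i, partner_atom = ent_polar[k], distance = d[k],
        type = "hbond", stringsAsFactors = FALSE)
    }
    if (lig_charge[i] != 0) {
      sb <- which(d <= salt_cutoff &
                  ent_charge[ent_polar] * lig_charge[i] < 0)
      for (k in sb) {
        rows[[length(rows) + 1L]] <- data.frame(
          ligand_atom = i, partner_atom = ent_polar[k], distance = d[k],
          type = "saltbridge", stringsAsFactors = FALSE)
      }
    }
  }
  contacts <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(ligand_atom = integer(), partner_atom = integer(),
               distance = numeric(), type = character())
  }
  list(n_hbonds = sum(contacts$type == "hbond"),
       n_saltbridges = sum(contacts$type == "saltbridge"),
       contacts = contacts)
}

#' Crystal-contact report for every ligand copy of a structure
#'
#' For each ligand copy: symmetry mates within the cutoff, the
#' lattice-proximal flag, the surface partition between the asymmetric unit
#' and each mate, and polar-contact counts per entity (waters, when present,
#' are counted separately as water-mediated contacts).
#'
#' @param model a `structure_model` with a lattice.
#' @param cutoff symmetry-mate search cutoff (default 6).
#' @param probe,proximity_cap,n_points see [surface_partition()].
#' @param hbond_cutoff,salt_cutoff see [polar_contacts()].
#' @return data.frame, one row per (ligand copy, entity).
#' @export
crystal_contact_report <- function(model, cutoff = 6, probe = 1.4,
                                   proximity_cap = 6, n_points = 960L,
                                   hbond_cutoff = 3.5, salt_cutoff = 4.0) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(model$lattice)) stop("Structure has no unit cell", call. = FALSE)
  prot <- protein_coords(model)
  rows <- list()
  for (cf in model$ligands) {
    lig_hv <- cf$element != "H"
    lc <- cf$coords[lig_hv, , drop = FALSE]
    mates <- expand_symmetry(prot, model$lattice, lc, cutoff = cutoff)
    prox <- flag_lattice_proximal(lc, prot, mates)
    entities <- c(list(asym = prot), lapply(mates, `[[`, "coords"))
    if (length(mates)) {
      names(entities)[-1L] <- vapply(mates, function(m) {
        sprintf("mate_op%d_%d_%d_%d", m$op, m$shift[1], m$shift[2], m$shift[3])
      }, character(1))
    }
    sp <- surface_partition(lc, cf$element[lig_hv], entities, probe = probe,
                            proximity_cap = proximity_cap,
                            n_points = n_points)
    ent_dfs <- c(list(asym = model$protein),
                 lapply(mates, function(m) {
                   df <- model$protein
                   df$x <- m$coords[, 1L]; df$y <- m$coords[, 2L]
                   df$z <- m$coords[, 3L]
                   df
                 }))
    names(ent_dfs) <- names(entities)
    n_water <- 0L
    if (nrow(model$waters)) {
      wd <- polar_contacts(cf, data.frame(element = model$waters$element,
                                          x = model$waters$x,
                                          y = model$waters$y,
                                          z = model$waters$z),
                           hbond_cutoff = hbond_cutoff)
      n_water <- wd$n_hbonds
    }
    for (en in names(ent_dfs)) {
      pc <- polar_contacts(cf, ent_dfs[[en]], hbond_cutoff = hbond_cutoff,
                           salt_cutoff = salt_cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = model$structure_id, ligand = cf$molecule_id,
        copy_id = cf$copy_id, entity = en,
        surface_percent = sp$percent[match(en, sp$entity)],
        n_hbonds = pc$n_hbonds, n_saltbridges = pc$n_saltbridges,
        n_water_mediated = n_water, lattice_proximal = prox,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
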