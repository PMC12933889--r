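#' @title Molecular graph construction
#' @description A `molgraph` is the package's light-weight molecular graph:
#'   atoms with element, formal charge, aromaticity, attached-hydrogen count
#'   and optional 3D coordinates, plus a kekulized bond list. Graphs are built
#'   from SMILES through OpenBabel (canonicalization + connection table), with
#'   aromaticity taken from the aromatic (lowercase) atoms of the SMILES
#'   itself so that perception matches the canonicalizer's.
#' @name molgraph
NULL

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# Standard atomic masses for the elements this package expects to see.
ATOMIC_MASSES <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Co = 58.933,
  Ni = 58.693, Cu = 63.546, Zn = 65.38, As = 74.922, Se = 78.971,
  Br = 79.904, Ag = 107.87, I = 126.904, Pt = 195.084, Au = 196.967,
  Hg = 200.592
)

METALS <- c("Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba",
            "Al", "Ga", "In", "Tl", "Sn", "Pb", "Bi", "Sc", "Ti", "V",
            "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Y", "Zr", "Nb",
            "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "La", "Hf", "Ta",
            "W", "Re", "Os", "Ir", "Pt", "Au", "Hg")

#' Tokenize the atoms of a SMILES string
#'
#' Returns, in order of appearance, each atom's element symbol, aromatic flag
#' (lowercase notation), tetrahedral stereo mark and bracket hydrogen count.
#'
#' @param smiles a single SMILES string.
#' @return data.frame with columns `element`, `aromatic`, `stereo`
#'   (`""`, `"@"`, `"@@"`), `bracket_h` (`NA` outside brackets).
#' @keywords internal
smiles_atoms <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  el <- character(); ar <- logical(); st <- character(); bh <- integer()
  i <- 1L
  two_letter <- c("Cl", "Br")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      # strip isotope
      body2 <- sub("^[0-9]+", "", body)
      m <- regmatches(body2, regexpr("^([A-Z][a-z]?|as|se|b|c|n|o|p|s)", body2))
      if (length(m) == 0L) stop("Cannot parse bracket atom in SMILES: ", smiles)
      sym <- m
      rest <- substring(body2, nchar(sym) + 1L)
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "as", "se")
      sym_el <- if (aromatic) {
        paste0(toupper(substring(sym, 1, 1)), substring(sym, 2))
      } else sym
      stereo <- if (grepl("@@", rest, fixed = TRUE)) "@@"
        else if (grepl("@", rest, fixed = TRUE)) "@" else ""
      hm <- regmatches(rest, regexpr("H[0-9]*", rest))
      hcount <- if (length(hm) == 0L) 0L
        else if (hm == "H") 1L else as.integer(substring(hm, 2))
      el <- c(el, sym_el); ar <- c(ar, aromatic)
      st <- c(st, stereo); bh <- c(bh, hcount)
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% two_letter) {
      el <- c(el, paste0(ch, chars[i + 1L])); ar <- c(ar, FALSE)
      st <- c(st, ""); bh <- c(bh, NA_integer_)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      el <- c(el, ch); ar <- c(ar, FALSE); st <- c(st, ""); bh <- c(bh, NA_integer_)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      el <- c(el, toupper(ch)); ar <- c(ar, TRUE); st <- c(st, ""); bh <- c(bh, NA_integer_)
      i <- i + 1L
    } else if (ch == "%") {
      i <- i + 3L
    } else {
      i <- i + 1L
    }
  }
  data.frame(element = el, aromatic = ar, stereo = st, bracket_h = bh,
             stringsAsFactors = FALSE)
}

#' Parse a V2000 connection table
#'
#' @param lines character vector holding one SDF record (through `M  END`).
#' @return list with `element`, `coords` (n x 3), `charge`, `bonds`
#'   (data.frame a1, a2, order).
#' @keywords internal
parse_ctab <- function(lines) {
  counts <- lines[4L]
  natoms <- as.integer(substr(counts, 1L, 3L))
  nbonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(natoms)) stop("Malformed connection table")
  el <- character(natoms); xyz <- matrix(NA_real_, natoms, 3L)
  chg <- integer(natoms)
  chg_col_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  for (k in seq_len(natoms)) {
    ln <- lines[4L + k]
    xyz[k, ] <- c(as.numeric(substr(ln, 1, 10)), as.numeric(substr(ln, 11, 20)),
                  as.numeric(substr(ln, 21, 30)))
    el[k] <- trimws(substr(ln, 32, 34))
    cc <- trimws(substr(ln, 37, 39))
    if (nzchar(cc) && cc %in% names(chg_col_map)) chg[k] <- chg_col_map[[cc]]
  }
  a1 <- integer(nbonds); a2 <- integer(nbonds); ord <- integer(nbonds)
  for (k in seq_len(nbonds)) {
    ln <- lines[4L + natoms + k]
    a1[k] <- as.integer(substr(ln, 1, 3))
    a2[k] <- as.integer(substr(ln, 4, 6))
    ord[k] <- as.integer(substr(ln, 7, 9))
  }
  # M CHG lines override the (deprecated) atom-block charge column
  mchg <- grep("^M  CHG", lines, value = TRUE)
  if (length(mchg)) {
    chg <- integer(natoms)
    for (ln in mchg) {
      f <- as.integer(strsplit(trimws(substring(ln, 7)), "[ ]+")[[1]])
      nn <- f[1L]
      for (q in seq_len(nn)) chg[f[2L * q]] <- f[2L * q + 1L]
    }
  }
  list(element = el, coords = xyz, charge = chg,
       bonds = data.frame(a1 = a1, a2 = a2, order = ord))
}

default_valence <- function(element, charge, bondsum) {
  v <- switch(element,
    C = 4L + ifelse(charge < 0, charge, -charge),
    N = 3L + charge,
    O = 2L + charge,
    P = if (bondsum > 3L) 5L else 3L,
    S = if (bondsum > 4L) 6L else if (bondsum > 2L) 4L else 2L,
    B = 3L,
    F = 1L, Cl = 1L, Br = 1L, I = 1L,
    Se = if (bondsum > 2L) bondsum else 2L,
    Si = 4L,
    As = 3L,
    0L)
  max(v, 0L)
}

#' Build a molecular graph from a SMILES string
#'
#' The SMILES is canonicalized with OpenBabel; aromaticity comes from the
#' canonical aromatic SMILES, the kekulized bond list from the corresponding
#' connection table, implicit hydrogen counts from standard valences, and
#' rings from a smallest-set-of-smallest-rings perception.
#'
#' @param smiles a single SMILES string.
#' @param canonicalize canonicalize first (default); set `FALSE` when
#'   `smiles` is already an OpenBabel canonical SMILES.
#' @return an object of class `molgraph`.
#' @examples
#' \dontrun{
#' mg <- molgraph("c1ccccc1C")  # toluene
#' mg$n_heavy
#' }
#' @export
molgraph <- function(smiles, canonicalize = TRUE) {
  stopifnot(length(smiles) == 1L)
  can <- if (canonicalize) ob_canonical(smiles) else smiles
  if (is.na(can) || !nzchar(can)) {
    stop("Unparseable structure: ", smiles, call. = FALSE)
  }
  sdf <- ob_to_sdf(can)
  ct <- parse_ctab(sdf)
  tok <- smiles_atoms(can)
  if (nrow(tok) != length(ct$element) ||
      !all(toupper(tok$element) == toupper(ct$element))) {
    stop("Internal atom-order mismatch between SMILES and connection table for: ",
         can, call. = FALSE)
  }
  build_molgraph(element = ct$element, charge = ct$charge, bonds = ct$bonds,
                 aromatic_atom = tok$aromatic, stereo_mark = tok$stereo,
                 smiles = can)
}

#' Assemble a molgraph from parsed components
#' @keywords internal
build_molgraph <- function(element, charge, bonds, aromatic_atom,
                           stereo_mark = NULL, smiles = NA_character_,
                           coords = NULL) {
  n <- length(element)
  if (is.null(stereo_mark)) stereo_mark <- rep("", n)
  adj <- vector("list", n)
  bond_order_sum <- numeric(n)
  degree <- integer(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds$a1[k]; b <- bonds$a2[k]; o <- bonds$order[k]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
      bond_order_sum[a] <- bond_order_sum[a] + o
      bond_order_sum[b] <- bond_order_sum[b] + o
      degree[a] <- degree[a] + 1L; degree[b] <- degree[b] + 1L
    }
  }
  nH <- integer(n)
  for (i in seq_len(n)) {
    v <- default_valence(element[i], charge[i], bond_order_sum[i])
    nH[i] <- max(0L, as.integer(v - bond_order_sum[i]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(bonds)) {
    g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  }
  in_ring_bond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds)) {
    br <- igraph::bridges(g)
    in_ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  ring_atom <- rep(FALSE, n)
  if (any(in_ring_bond)) {
    ring_atom[unique(c(bonds$a1[in_ring_bond], bonds$a2[in_ring_bond]))] <- TRUE
  }
  sssr <- perceive_sssr(g, bonds, in_ring_bond)
  # aromatic ring: every member atom flagged aromatic
  arom_ring <- vapply(sssr, function(r) all(aromatic_atom[r]), logical(1))
  bonds$aromatic <- in_ring_bond & aromatic_atom[bonds$a1] & aromatic_atom[bonds$a2]
  bonds$in_ring <- in_ring_bond
  mg <- structure(list(
    n_atoms = n,
    element = element,
    charge = charge,
    aromatic = aromatic_atom,
    stereo_mark = stereo_mark,
    nH = nH,
    degree = degree,
    bonds = bonds,
    adj = adj,
    ring_atom = ring_atom,
    sssr = sssr,
    aromatic_rings = if (length(sssr)) sssr[arom_ring] else list(),
    smiles = smiles,
    coords = coords,
    n_heavy = n,
    igraph = g
  ), class = "molgraph")
  mg$hybridization <- perceive_hybridization(mg)
  mg$sym_class <- symmetry_classes(mg)
  mg$stereocenter <- potential_stereocenters(mg)
  mg
}

#' @export
print.molgraph <- function(x, ...) {
  cat("molgraph:", x$smiles, "\n")
  cat(" atoms:", x$n_atoms, " bonds:", nrow(x$bonds),
      " rings:", length(x$sssr),
      " aromatic rings:", length(x$aromatic_rings), "\n")
  invisible(x)
}

# Note: the conjugation promotion above applies to N and O only; divalent
# and hypervalent sulfur is treated as sp3 by the spatial score regardless
# of neighboring multiple bonds (matching the published implementation).

# Smallest set of smallest rings: for each ring bond, the shortest cycle
# through it; greedily select independent cycles up to the cyclomatic number.
perceive_sssr <- function(g, bonds, in_ring_bond) {
  n <- igraph::vcount(g); m <- nrow(bonds)
  ncomp <- igraph::components(g)$no
  rank <- m - n + ncomp
  if (rank <= 0L) return(list())
  cand <- list()
  for (k in which(in_ring_bond)) {
    g2 <- igraph::delete_edges(g, k)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = bonds$a1[k], to = bonds$a2[k], output = "vpath"))
    vp <- as.integer(sp$vpath[[1]])
    if (length(vp) >= 3L) cand[[length(cand) + 1L]] <- vp
  }
  if (!length(cand)) return(list())
  cand <- cand[order(lengths(cand))]
  eid <- function(a, b) paste(pmin(a, b), pmax(a, b))
  covered <- character()
  sel <- list()
  for (r in cand) {
    a <- r; b <- c(r[-1L], r[1L])
    ids <- eid(a, b)
    if (any(!(ids %in% covered))) {
      sel[[length(sel) + 1L]] <- sort(r)
      covered <- union(covered, ids)
      if (length(sel) >= rank) break
    }
  }
  sel
}

#' Atom hybridization from the kekulized graph
#'
#' `sp3` = only single bonds and not aromatic; `sp2` = aromatic or exactly one
#' double bond; `sp` = a triple bond or two double bonds. A conjugation-aware
#' variant used by the spatial score additionally treats single-bonded N, O
#' and S adjacent to an aromatic atom or to a multiple bond as `sp2`
#' (matching common toolkit perception of amide, ester and phenolic centers).
#'
#' @keywords internal
perceive_hybridization <- function(mg) {
  n <- mg$n_atoms
  ndouble <- integer(n); ntriple <- integer(n)
  b <- mg$bonds
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    if (b$order[k] == 2L) {
      ndouble[b$a1[k]] <- ndouble[b$a1[k]] + 1L
      ndouble[b$a2[k]] <- ndouble[b$a2[k]] + 1L
    } else if (b$order[k] == 3L) {
      ntriple[b$a1[k]] <- ntriple[b$a1[k]] + 1L
      ntriple[b$a2[k]] <- ntriple[b$a2[k]] + 1L
    }
  }
  hyb <- ifelse(ntriple > 0L | ndouble >= 2L, "sp",
         ifelse(mg$aromatic | ndouble == 1L, "sp2", "sp3"))
  has_multiple <- mg$aromatic | ndouble > 0L | ntriple > 0L
  conj <- hyb
  for (i in seq_len(n)) {
    if (hyb[i] == "sp3" && mg$element[i] %in% c("N", "O") &&
        any(has_multiple[mg$adj[[i]]])) {
      conj[i] <- "sp2"
    }
  }
  data.frame(hyb = hyb, conj = conj, n_double = ndouble, n_triple = ntriple,
             stringsAsFactors = FALSE)
}

# -- 32-bit-ish stable hashing -------------------------------------------------

HASH_MOD <- 2147483647  # Mersenne prime 2^31 - 1: no lattice structure
HASH_MUL <- 65599       # against the power-of-two folding of fingerprints

#' Stable hash of an integer vector (order-sensitive)
#' @keywords internal
hash_ints <- function(v) {
  h <- 17
  for (x in v) {
    x <- as.numeric(x) %% HASH_MOD
    lo <- x %% 65536
    hi <- (x - lo) / 65536
    h <- ((h * HASH_MUL) + lo + 1) %% HASH_MOD
    h <- ((h * HASH_MUL) + hi + 3) %% HASH_MOD
  }
  h
}

bond_code <- function(order, aromatic) ifelse(aromatic, 4L, as.integer(order))

#' Symmetry (equivalence) classes of heavy atoms
#'
#' Morgan-style iterative refinement: atoms start from an invariant of
#' element, charge, attached hydrogens, degree, aromaticity and ring
#' membership, and are refined by the sorted multiset of
#' (bond class, neighbor class) pairs until the partition stabilizes. Atoms
#' sharing a final class are graph-symmetric for the purposes of this package
#' (stereocenter perception, growth-vector merging).
#'
#' @param mg a molgraph.
#' @return integer vector of class ids (1-based, dense).
#' @export
symmetry_classes <- function(mg) {
  n <- mg$n_atoms
  if (n == 0L) return(integer())
  elem_code <- match(mg$element, unique(sort(mg$element)))
  inv <- mapply(function(e, q, h, d, a, r) {
    hash_ints(c(e, q + 10L, h, d, as.integer(a), as.integer(r)))
  }, elem_code, mg$charge, mg$nH, mg$degree, mg$aromatic, mg$ring_atom)
  cls <- match(inv, sort(unique(inv)))
  bmat <- mg$bonds
  bcode <- if (nrow(bmat)) bond_code(bmat$order, bmat$aromatic) else integer()
  nb_bond <- vector("list", n)
  if (nrow(bmat)) for (k in seq_len(nrow(bmat))) {
    nb_bond[[bmat$a1[k]]] <- rbind(nb_bond[[bmat$a1[k]]], c(bcode[k], bmat$a2[k]))
    nb_bond[[bmat$a2[k]]] <- rbind(nb_bond[[bmat$a2[k]]], c(bcode[k], bmat$a1[k]))
  }
  repeat {
    newinv <- vapply(seq_len(n), function(i) {
      nb <- nb_bond[[i]]
      if (is.null(nb)) return(hash_ints(c(cls[i])))
      pairs <- cbind(nb[, 1L], cls[nb[, 2L]])
      pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
      hash_ints(c(cls[i], t(pairs)))
    }, numeric(1))
    newcls <- match(newinv, sort(unique(newinv)))
    if (max(newcls) == max(cls)) {
      # partition stable (refinement can only split classes)
      return(newcls)
    }
    cls <- newcls
  }
}

#' Potential tetrahedral stereocenters
#'
#' A carbon qualifies when it is sp3, carries at most one hydrogen, has four
#' substituents in total (heavy + H) and all its heavy-atom neighbors belong
#' to pairwise different symmetry classes. Both configured and unconfigured
#' centers are reported; this symmetry-aware "potential stereocenter"
#' perception is the package default for the stereogenic-carbon fraction.
#'
#' @param mg a molgraph.
#' @return logical vector over atoms.
#' @export
potential_stereocenters <- function(mg) {
  n <- mg$n_atoms
  out <- rep(FALSE, n)
  if (n == 0L) return(out)
  cls <- mg$sym_class
  if (is.null(cls)) cls <- symmetry_classes(mg)
  for (i in seq_len(n)) {
    if (mg$element[i] != "C") next
    if (mg$hybridization$hyb[i] != "sp3") next
    if (mg$nH[i] > 1L) next
    if (mg$degree[i] + mg$nH[i] != 4L) next
    ncls <- cls[mg$adj[[i]]]
    if (anyDuplicated(ncls) == 0L) out[i] <- TRUE
  }
  out
}

#' Molecular weight from standard atomic masses (hydrogens included)
#' @param mg a molgraph.
#' @return mass in Da.
#' @export
molgraph_mw <- function(mg) {
  m <- ATOMIC_MASSES[mg$element]
  if (anyNA(m)) {
    stop("No atomic mass tabulated for element(s): ",
         paste(unique(mg$element[is.na(m)]), collapse = ", "))
  }
  sum(m) + sum(mg$nH) * ATOMIC_MASSES[["H"]]
}
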