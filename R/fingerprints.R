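#' @title Circular (Morgan) fingerprints and Tanimoto similarity
#' @description An extended-connectivity fingerprint: atoms start from an
#'   invariant of (atomic number, heavy degree, attached hydrogens, formal
#'   charge, ring membership) and are iteratively updated with the sorted
#'   (bond class, neighbor code) pairs of their neighborhood. Environments
#'   with identical bond sets are deduplicated (smallest radius, then
#'   smallest code, wins) and the surviving codes are folded to a fixed bit
#'   length. Bit collisions from folding are an accepted part of the method.
#' @name fingerprints
NULL

#' Per-atom circular environment codes
#'
#' @param mg a molgraph.
#' @param radius maximum environment radius (bonds).
#' @return data.frame with columns `atom`, `radius`, `code`, `bondset`
#'   (canonical key of the environment's bond set).
#' @keywords internal
morgan_environments <- function(mg, radius = 2L) {
  n <- mg$n_atoms
  if (n == 0L) return(data.frame(atom = integer(), radius = integer(),
                                 code = numeric(), bondset = character()))
  elem_num <- match(mg$element, names(ATOMIC_MASSES))
  elem_num[is.na(elem_num)] <- 99L
  codes <- vapply(seq_len(n), function(i) {
    hash_ints(c(elem_num[i], mg$degree[i], mg$nH[i], mg$charge[i] + 16L,
                as.integer(mg$ring_atom[i])))
  }, numeric(1))
  b <- mg$bonds
  bcode <- if (nrow(b)) bond_code(b$order, b$aromatic) else integer()
  # neighbor bond lookup: per atom, matrix of (bond index, bond code, nbr)
  nb <- vector("list", n)
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    nb[[b$a1[k]]] <- rbind(nb[[b$a1[k]]], c(k, bcode[k], b$a2[k]))
    nb[[b$a2[k]]] <- rbind(nb[[b$a2[k]]], c(k, bcode[k], b$a1[k]))
  }
  envs <- data.frame(atom = seq_len(n), radius = 0L, code = codes,
                     bondset = "", stringsAsFactors = FALSE)
  bondsets <- rep(list(integer()), n)
  for (r in seq_len(radius)) {
    newcodes <- numeric(n)
    newsets <- vector("list", n)
    for (i in seq_len(n)) {
      m <- nb[[i]]
      if (is.null(m)) {
        # isolated atom: the environment stops growing
        newcodes[i] <- codes[i]
        newsets[i] <- list(integer())
        next
      }
      pairs <- cbind(m[, 2L], codes[m[, 3L]])
      o <- order(pairs[, 1L], pairs[, 2L])
      pairs <- pairs[o, , drop = FALSE]
      newcodes[i] <- hash_ints(c(r, codes[i], t(pairs)))
      newsets[[i]] <- sort(unique(c(m[, 1L],
                                    unlist(bondsets[m[, 3L]]))))
    }
    codes <- newcodes
    bondsets <- newsets
    envs <- rbind(envs, data.frame(
      atom = seq_len(n), radius = r, code = codes,
      bondset = vapply(bondsets, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE))
  }
  envs
}

#' Morgan fingerprint as a set of folded bits
#'
#' @param mol a molgraph, mol_record or SMILES string.
#' @param radius environment radius (default 2).
#' @param nbits folded length (default 4096).
#' @return sorted integer vector of set bit positions (0-based).
#' @export
morgan_fingerprint <- function(mol, radius = 2L, nbits = 4096L) {
  mg <- as_molgraph(mol)
  envs <- morgan_environments(mg, radius)
  if (!nrow(envs)) return(integer())
  r0 <- envs[envs$radius == 0L, ]
  rn <- envs[envs$radius > 0L, ]
  if (nrow(rn)) {
    # nonempty duplicate bond sets collapse to one environment
    rn <- rn[order(rn$radius, rn$code), ]
    dup <- rn$bondset != "" & duplicated(rn$bondset)
    rn <- rn[!dup, ]
    # environments identical to a smaller-radius environment contribute once
  }
  codes <- unique(c(r0$code, rn$code))
  sort(unique(as.integer(codes %% nbits)))
}

#' Tanimoto coefficient of two Morgan fingerprints
#'
#' @param a,b molgraphs, mol_records or SMILES strings.
#' @param radius,nbits fingerprint parameters (defaults 2 and 4096).
#' @return similarity in \[0, 1\].
#' @examples
#' \dontrun{
#' morgan_tanimoto("c1ccccc1", "c1ccccc1")  # 1
#' }
#' @export
morgan_tanimoto <- function(a, b, radius = 2L, nbits = 4096L) {
  fa <- morgan_fingerprint(a, radius, nbits)
  fb <- morgan_fingerprint(b, radius, nbits)
  if (!length(fa) && !length(fb)) return(1)
  length(intersect(fa, fb)) / length(union(fa, fb))
}

#' Rank the most similar reference molecules for a query
#'
#' @param query a molgraph, mol_record or SMILES string.
#' @param references list of `mol_record`.
#' @param k number of hits (default 3).
#' @param radius,nbits fingerprint parameters.
#' @return data.frame `query_id`, `rank`, `reference_id`,
#'   `reference_dataset`, `tanimoto`, sorted by descending similarity with
#'   deterministic tie-break on reference id.
#' @export
top_k_similar <- function(query, references, k = 3L, radius = 2L,
                          nbits = 4096L) {
  if (!length(references)) stop("Empty reference set", call. = FALSE)
  if (k > length(references)) {
    warning("k exceeds the number of references; returning all")
    k <- length(references)
  }
  qid <- if (inherits(query, "mol_record")) query$id else NA_character_
  fq <- morgan_fingerprint(query, radius, nbits)
  tc <- vapply(references, function(r) {
    fr <- morgan_fingerprint(r, radius, nbits)
    if (!length(fq) && !length(fr)) return(1)
    length(intersect(fq, fr)) / length(union(fq, fr))
  }, numeric(1))
  rid <- vapply(references, function(r) r$id, character(1))
  rtag <- vapply(references, function(r) r$source_tag, character(1))
  o <- order(-tc, rid)
  sel <- utils::head(o, k)
  if (!length(sel)) {
    return(data.frame(query_id = character(), rank = integer(),
                      reference_id = character(),
                      reference_dataset = character(), tanimoto = numeric()))
  }
  data.frame(query_id = qid, rank = seq_along(sel), reference_id = rid[sel],
             reference_dataset = rtag[sel], tanimoto = tc[sel],
             stringsAsFactors = FALSE)
}
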