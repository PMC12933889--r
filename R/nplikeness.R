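#' @title Natural-product likeness score
#' @description A fragment-contribution score of how similar a molecule is to
#'   natural-product chemical space. Circular atom environments (radius 2)
#'   are tallied in a natural-product exemplar collection and a
#'   synthetic-compound exemplar collection; each environment's contribution
#'   is the log10 ratio of its (smoothed) relative frequencies. A molecule
#'   scores the mean contribution of its atom environments, clipped to the
#'   contribution range of the table, so that the score is independent of
#'   molecular size.
#'
#'   The packaged default table is trained on the small exemplar sets shipped
#'   with the package; it supports ordering comparisons (sugar-like above
#'   biphenyl-like) rather than absolute score reproduction, and can be
#'   replaced by a user-trained table from larger corpora.
#' @name nplikeness
NULL

.np_cache <- new.env(parent = emptyenv())

#' Train a natural-product likeness contribution table
#'
#' @param np_smiles character vector of natural-product-like SMILES.
#' @param synthetic_smiles character vector of synthetic-like SMILES.
#' @param radius environment radius (default 2).
#' @return object of class `np_table`: data.frame `code`, `contribution`,
#'   with the training radius as attribute.
#' @export
train_np_table <- function(np_smiles, synthetic_smiles, radius = 2L) {
  if (!length(np_smiles) || !length(synthetic_smiles)) {
    stop("Both exemplar sets must be non-empty", call. = FALSE)
  }
  count_envs <- function(smis) {
    tab <- new.env(parent = emptyenv())
    for (s in smis) {
      mg <- molgraph(s)
      envs <- morgan_environments(mg, radius)
      codes <- unique(envs$code[envs$radius == radius])
      for (cd in codes) {
        key <- sprintf("%.0f", cd)
        tab[[key]] <- (if (is.null(tab[[key]])) 0L else tab[[key]]) + 1L
      }
    }
    tab
  }
  np <- count_envs(np_smiles)
  syn <- count_envs(synthetic_smiles)
  keys <- union(ls(np), ls(syn))
  n_np <- length(np_smiles); n_syn <- length(synthetic_smiles)
  contribution <- vapply(keys, function(k) {
    c_np <- if (is.null(np[[k]])) 0L else np[[k]]
    c_syn <- if (is.null(syn[[k]])) 0L else syn[[k]]
    log10(((c_np + 1) / (n_np + 1)) / ((c_syn + 1) / (n_syn + 1)))
  }, numeric(1))
  out <- data.frame(code = as.numeric(keys), contribution = contribution,
                    row.names = NULL)
  attr(out, "radius") <- radius
  class(out) <- c("np_table", class(out))
  out
}

#' The packaged default contribution table
#'
#' Trained once per session on the exemplar sets shipped under
#' `inst/extdata` (`np_exemplars.smi`, `synthetic_exemplars.smi`).
#'
#' @return an `np_table`.
#' @export
np_contribution_table <- function() {
  if (is.null(.np_cache$table)) {
    npf <- system.file("extdata", "np_exemplars.smi", package = "fragspace")
    syf <- system.file("extdata", "synthetic_exemplars.smi", package = "fragspace")
    if (!nzchar(npf) || !nzchar(syf)) {
      stop("Packaged exemplar sets not found", call. = FALSE)
    }
    read1 <- function(p) {
      x <- trimws(readLines(p, warn = FALSE))
      x <- x[nzchar(x) & !startsWith(x, "#")]
      vapply(strsplit(x, "[ \t]+"), `[`, character(1), 1L)
    }
    .np_cache$table <- train_np_table(read1(npf), read1(syf))
  }
  .np_cache$table
}

#' Natural-product likeness of a molecule
#'
#' @param mol a molgraph, mol_record or SMILES string.
#' @param table an `np_table` (default: packaged table).
#' @return unitless score; positive values lean natural-product-like,
#'   negative synthetic-like, 0 when no environment is known to the table.
#' @export
np_likeness <- function(mol, table = np_contribution_table()) {
  if (is.null(table) || !nrow(table)) {
    stop("Empty NP contribution table", call. = FALSE)
  }
  mg <- as_molgraph(mol)
  radius <- attr(table, "radius")
  envs <- morgan_environments(mg, radius)
  codes <- envs$code[envs$radius == radius]
  contrib <- table$contribution[match(codes, table$code)]
  contrib[is.na(contrib)] <- 0
  score <- sum(contrib) / mg$n_atoms
  lo <- min(table$contribution); hi <- max(table$contribution)
  min(max(score, lo), hi)
}
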