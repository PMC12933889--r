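# Shared fixtures and independent oracle helpers for the test suite.

# Build a molecule record from a SMILES without standardization.
make_record <- function(smiles, id = "m1", source_tag = "user",
                        pchembl = NA_real_, confidence = NA_integer_) {
  molecule_record(fragspace:::ob_canonical(smiles), id = id,
                  smiles_raw = smiles, source_tag = source_tag,
                  pchembl = pchembl, assay_confidence = confidence)
}

# Reference molecules, built once per test run.
ref_fixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- reference_fixtures()
    cache
  }
})

# Independent brute-force automorphism enumeration of an abstracted
# (element-free, bond-order-free) graph, by recursive backtracking on the
# adjacency matrix. Used as the oracle for abstracted_rmsd.
brute_force_automorphisms <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  res <- list()
  assign_next <- function(mapping, used) {
    i <- length(mapping) + 1L
    if (i > n) {
      res[[length(res) + 1L]] <<- mapping
      return(invisible())
    }
    for (cand in seq_len(n)) {
      if (used[cand] || deg[cand] != deg[i]) next
      ok <- TRUE
      for (j in seq_along(mapping)) {
        if (adj[i, j] != adj[cand, mapping[j]]) { ok <- FALSE; break }
      }
      if (ok) assign_next(c(mapping, cand), `[<-`(used, cand, TRUE))
    }
  }
  assign_next(integer(), rep(FALSE, n))
  res
}

# Oracle RMSD: minimum over all brute-force automorphism matchings of the
# Kabsch-fitted RMSD.
oracle_abstracted_rmsd <- function(conf_a, conf_b, graph) {
  hv_a <- which(conf_a$heavy); hv_b <- which(conf_b$heavy)
  A <- conf_a$coords[hv_a, , drop = FALSE]
  B <- conf_b$coords[hv_b, , drop = FALSE]
  n <- graph$n_atoms
  adj <- matrix(0L, n, n)
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$a1[k]; b <- graph$bonds$a2[k]
    adj[a, b] <- 1L; adj[b, a] <- 1L
  }
  perms <- brute_force_automorphisms(adj)
  best <- Inf
  for (p in perms) {
    fit <- kabsch(B[p, , drop = FALSE], A)
    best <- min(best, fit$rmsd)
  }
  best
}

# Deterministic rigid transform for invariance tests.
rigid_transform <- function(coords, angle = 0.73, axis = c(1, 2, 2),
                            shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(as.matrix(coords) %*% t(R), 2L, shift, `+`)
}

# Toy crystal built once per test run.
toy_crystal <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_toy_crystal(dir = tempdir())
    cache
  }
})
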