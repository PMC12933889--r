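test_that("PBF is zero for planar geometry and errors on degenerate input", {
  # idealized planar hexagon
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  hexagon <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  expect_equal(pbf(hexagon), 0, tolerance = 1e-12)
  expect_error(pbf(hexagon[1:2, ]), "at least 3")
  collinear <- cbind(1:5, 1:5 * 2, 1:5 * 3)
  expect_error(pbf(collinear), "collinear")
})

test_that("PBF is invariant under rigid motion", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  v0 <- pbf(x)
  for (ang in c(0.3, 1.2, 2.9)) {
    expect_equal(pbf(rigid_transform(x, angle = ang)), v0, tolerance = 1e-9)
  }
})

test_that("nPBF equals PBF over resolved heavy atoms and decreases with size", {
  set.seed(2)
  x <- matrix(rnorm(24), 8, 3)
  cf <- conformer(x, rep("C", 8), "m", "crystal")
  expect_equal(npbf(cf), pbf(cf) / 8)
  cf12 <- conformer(rbind(x, matrix(rnorm(12), 4, 3)), rep("C", 12), "m", "crystal")
  # same pbf value scaled over more atoms gives smaller npbf
  expect_lt(pbf(cf12) / 12, pbf(cf12) / 8)
})

test_that("Kabsch recovers a constructed transform and matches bio3d", {
  set.seed(3)
  P <- matrix(rnorm(30), 10, 3)
  Q <- rigid_transform(P, angle = 1.1)
  fit <- kabsch(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  moved <- sweep(P %*% fit$rotation, 2, fit$translation, `+`)
  expect_equal(moved, Q, tolerance = 1e-9)
  # independent oracle: bio3d's least-squares fit on noisy pairs
  Qn <- Q + matrix(rnorm(30, sd = 0.3), 10, 3)
  fit2 <- kabsch(P, Qn)
  xyz_fit <- bio3d::fit.xyz(fixed = as.numeric(t(Qn)), mobile = as.numeric(t(P)),
                            fixed.inds = 1:30, mobile.inds = 1:30)
  rmsd_bio3d <- sqrt(mean(rowSums((matrix(xyz_fit, ncol = 3, byrow = TRUE) - Qn)^2)))
  expect_equal(fit2$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("conformer embedding is deterministic per seed", {
  fx <- ref_fixtures()
  c1 <- embed_conformer(fx$salicylic_acid, seed = 11L)
  c2 <- embed_conformer(fx$salicylic_acid, seed = 11L)
  expect_identical(c1$coords, c2$coords)
  expect_equal(c1$provenance, "in_silico")
  expect_equal(sum(c1$heavy), 10L)
  c3 <- embed_conformer(fx$salicylic_acid, seed = 12L)
  expect_false(isTRUE(all.equal(c1$coords, c3$coords)))
})

test_that("abstracted RMSD: identity, rigid invariance, symmetry", {
  fx <- ref_fixtures()
  cf <- embed_conformer(fx$amantadine, seed = 5L)
  hv <- which(cf$heavy)
  a <- conformer(cf$coords[hv, ], cf$element[hv], "amantadine", "crystal",
                 graph = cf$graph)
  expect_equal(abstracted_rmsd(a, a), 0, tolerance = 1e-9)
  b <- conformer(rigid_transform(cf$coords[hv, ]), cf$element[hv],
                 "amantadine", "crystal", graph = cf$graph)
  expect_equal(abstracted_rmsd(a, b), 0, tolerance = 1e-9)
  # symmetry of the measure
  set.seed(4)
  bb <- conformer(cf$coords[hv, ] + matrix(rnorm(length(hv) * 3, sd = 0.2),
                                           length(hv), 3),
                  cf$element[hv], "amantadine", "crystal", graph = cf$graph)
  expect_equal(abstracted_rmsd(a, bb), abstracted_rmsd(bb, a),
               tolerance = 1e-9)
})

test_that("abstracted RMSD equals the brute-force automorphism oracle", {
  smis <- c("c1ccccc1", "Cc1ccccc1", "c1ccncc1", "C1CCCCC1", "CC(C)CC",
            "c1ccc2ccccc2c1", "CC1CCCO1", "C1CC2CCC1C2")
  recs <- lapply(seq_along(smis), function(i) {
    molecule_record(fragspace:::ob_canonical(smis[i]), id = paste0("m", i))
  })
  confs <- embed_conformers(recs, seed = 21L)
  set.seed(5)
  for (cf in confs) {
    hv <- which(cf$heavy)
    a <- conformer(cf$coords[hv, ], cf$element[hv], cf$molecule_id, "crystal",
                   graph = cf$graph)
    # displace one atom and apply a rigid motion
    pert <- cf$coords[hv, ]
    pert[1L, ] <- pert[1L, ] + c(1, 0, 0)
    b <- conformer(rigid_transform(pert), cf$element[hv], cf$molecule_id,
                   "crystal", graph = cf$graph)
    expect_equal(abstracted_rmsd(a, b), oracle_abstracted_rmsd(a, b, cf$graph),
                 tolerance = 1e-6, info = cf$molecule_id)
  }
})

test_that("copy selection prefers fully resolved copies, then best coverage", {
  g <- molgraph("CCCCC")
  mk <- function(n_res, sid, cid) {
    conformer(matrix(rnorm(n_res * 3), n_res, 3), rep("C", n_res), "lig",
              "crystal", resolved_mask = c(rep(TRUE, n_res), rep(FALSE, 5 - n_res)),
              graph = g, structure_id = sid, copy_id = cid)
  }
  cs <- ligand_copy_set("lig", list(mk(5, "s1", "a"), mk(3, "s1", "b"),
                                    mk(5, "s2", "a")))
  kept <- select_copies(cs)
  expect_length(kept$copies, 2L)
  expect_true(all(vapply(kept$copies, function(x) sum(x$resolved_mask), integer(1)) == 5L))
  # none fully resolved: single best, tie broken by structure then copy id
  cs2 <- ligand_copy_set("lig", list(mk(3, "s2", "a"), mk(4, "s1", "b"),
                                     mk(4, "s1", "a")))
  kept2 <- select_copies(cs2)
  expect_length(kept2$copies, 1L)
  expect_equal(kept2$copies[[1]]$copy_id, "a")
  expect_equal(kept2$copies[[1]]$structure_id, "s1")
  expect_error(ligand_copy_set("lig", list()), "Empty")
})

test_that("per-ligand aggregation is the arithmetic mean", {
  expect_equal(aggregate_per_ligand(c(0.03, 0.05)), 0.04)
  expect_equal(aggregate_per_ligand(0.7), 0.7)
  expect_equal(aggregate_per_ligand(rep(0.25, 6)), 0.25)
  expect_error(aggregate_per_ligand(numeric()), "No copy values")
})

test_that("delta nPBF is signed crystal minus in-silico", {
  fx <- ref_fixtures()
  cf <- embed_conformer(fx$salicylic_acid, seed = 31L)
  hv <- which(cf$heavy)
  crystal_same <- conformer(cf$coords, cf$element, "sal", "crystal",
                            resolved_mask = rep(TRUE, length(hv)),
                            graph = cf$graph)
  expect_equal(delta_npbf(crystal_same, cf), 0, tolerance = 1e-12)
  # flatten the crystal copy: negative sign by the formula
  flat <- cf$coords; flat[, 3] <- 0
  crystal_flat <- conformer(flat, cf$element, "sal", "crystal",
                            resolved_mask = rep(TRUE, length(hv)),
                            graph = cf$graph)
  expect_lt(delta_npbf(crystal_flat, cf), 0)
})

test_that("conformer SDF round trip preserves coordinates and seed", {
  fx <- ref_fixtures()
  cf <- embed_conformer(fx$benzene, seed = 9L)
  path <- tempfile(fileext = ".sdf")
  write_conformer_sdf(list(cf), path)
  lines <- readLines(path)
  ct <- fragspace:::parse_ctab(lines)
  expect_equal(ct$coords, unname(cf$coords), tolerance = 1e-4)
  expect_true(any(grepl("^>  <seed>", lines)))
  expect_equal(lines[grep("^>  <seed>", lines) + 1L], "9")
})
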