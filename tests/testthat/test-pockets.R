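make_model <- function(coords, chain = "A", resno = seq_len(nrow(coords)),
                       id = "model") {
  structure(list(
    structure_id = id,
    protein = data.frame(element = "C", chain = chain, resno = resno,
                         resid = "GLY", atom_name = "CA",
                         x = coords[, 1], y = coords[, 2], z = coords[, 3],
                         stringsAsFactors = FALSE),
    ligands = list(), waters = data.frame(), lattice = NULL),
    class = "structure_model")
}

test_that("superposition of a model onto itself is the identity", {
  set.seed(10)
  m <- make_model(matrix(rnorm(60, sd = 5), 20, 3))
  out <- superpose_to_reference(m, m)
  expect_equal(out$result$rotation, diag(3), tolerance = 1e-9)
  expect_equal(out$result$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(out$result$rmsd, 0, tolerance = 1e-9)
  expect_equal(out$result$n_matched, 20L)
})

test_that("superposition recovers a constructed rotation + shift", {
  set.seed(11)
  ref_coords <- matrix(rnorm(60, sd = 5), 20, 3)
  ref <- make_model(ref_coords)
  # rotate 90 degrees about z and shift
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- make_model(sweep(ref_coords %*% t(R), 2, c(10, -4, 7), `+`))
  out <- superpose_to_reference(moved, ref)
  expect_lt(out$result$rmsd, 1e-6)
  expect_equal(as.matrix(out$model$protein[, c("x", "y", "z")]),
               ref_coords, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("residue renumbering removes that pair from the matching", {
  set.seed(12)
  coords <- matrix(rnorm(60, sd = 5), 20, 3)
  ref <- make_model(coords)
  m2 <- make_model(coords, resno = c(1:19, 99L))
  out <- superpose_to_reference(m2, ref)
  expect_equal(out$result$n_matched, 19L)
  few <- make_model(coords[1:2, ], resno = 98:99)
  expect_error(superpose_to_reference(few, ref), "at least 3")
})

test_that("superposition carries ligand atoms along", {
  set.seed(13)
  coords <- matrix(rnorm(60, sd = 5), 20, 3)
  ref <- make_model(coords)
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  tr <- function(x) sweep(x %*% t(R), 2, c(10, -4, 7), `+`)
  lig_orig <- matrix(rnorm(15), 5, 3)
  moved <- make_model(tr(coords))
  moved$ligands <- list(conformer(tr(lig_orig), rep("C", 5), "lig", "crystal"))
  out <- superpose_to_reference(moved, ref)
  expect_equal(out$model$ligands[[1]]$coords, lig_orig,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("pocket centers: single atom, equal masses, mass weighting", {
  expect_equal(pocket_center(matrix(c(1, 2, 3), 1, 3), "C"), c(1, 2, 3))
  two <- rbind(c(0, 0, 0), c(0, 0, 2))
  expect_equal(pocket_center(two, c("C", "C")), c(0, 0, 1))
  # C at origin, O at (0,0,1.6): com_z = 16.00/(12.01+16.00) * 1.6 = 0.914
  co <- rbind(c(0, 0, 0), c(0, 0, 1.6))
  expect_equal(pocket_center(co, c("C", "O"))[3], 0.914, tolerance = 1e-3)
  expect_equal(pocket_center(co, mode = "centroid")[3], 0.8)
  expect_error(pocket_center(matrix(numeric(), 0, 3), "C"), "No atoms")
})

test_that("pocket assignment uses an inclusive any-atom radius rule", {
  pockets <- pocket_set(c("A", "G"), rbind(c(0, 0, 0), c(8, 0, 0)), radius = 5)
  at49 <- conformer(matrix(c(0, 4.9, 0), 1, 3), "C", "l1", "crystal")
  expect_equal(assign_pockets(at49, pockets), "A")
  at51 <- conformer(matrix(c(0, 5.1, 0), 1, 3), "C", "l2", "crystal")
  expect_equal(assign_pockets(at51, pockets), character())
  # elongated fixture reaching both pseudo-atoms 8 A apart
  span <- conformer(rbind(c(-4.5, 0, 0), c(4.5, 0, 0)), rep("C", 2),
                    "l3", "crystal")
  expect_setequal(assign_pockets(span, pockets), c("A", "G"))
  # centroid mode only looks at the centroid (here at the A pseudo-atom)
  expect_equal(assign_pockets(span, pockets, mode = "centroid"), "A")
})

test_that("pocket assignment is invariant under a joint rigid transform", {
  centers <- rbind(c(0, 0, 0), c(8, 0, 0))
  lig <- rbind(c(4, 0, 0), c(5.5, 0, 0))
  labels0 <- assign_pockets(conformer(lig, c("C", "C"), "l", "crystal"),
                            pocket_set(c("A", "G"), centers))
  tc <- rigid_transform(rbind(centers, lig))
  labels1 <- assign_pockets(conformer(tc[3:4, ], c("C", "C"), "l", "crystal"),
                            pocket_set(c("A", "G"), tc[1:2, ]))
  expect_identical(labels0, labels1)
})

test_that("binder classification covers all four outcomes", {
  expect_equal(classify_binder(list(c("A"), c("A"))), "orthosteric_only")
  expect_equal(classify_binder(list(c("A"), c("G"))), "both")
  expect_equal(classify_binder(list(c("E"))), "peripheral_only")
  expect_equal(classify_binder(list(character(), character())), "unassigned")
  expect_equal(classify_binder(list(c("A", "G"))), "both")
  expect_error(classify_binder(list()), "No copies")
})

test_that("toy crystal pocket recovery and classification are exact", {
  tc <- toy_crystal()
  labs <- lapply(tc$model$ligands, assign_pockets, pockets = tc$pockets)
  got <- vapply(labs, paste, character(1), collapse = ",")
  expect_identical(got, tc$truth$expected)
  ids <- vapply(tc$model$ligands, `[[`, character(1), "molecule_id")
  for (lid in unique(ids)) {
    expect_identical(classify_binder(labs[ids == lid]),
                     tc$truth$binder_class[match(lid, tc$truth$ligand_id)],
                     info = lid)
  }
})

test_that("pocket CSV round trip preserves definitions", {
  ps <- pocket_set(c("A", "E"), rbind(c(1, 2, 3), c(4, 5, 6)), radius = c(5, 4))
  path <- tempfile(fileext = ".csv")
  write_pocket_csv(ps, path)
  back <- read_pocket_csv(path)
  expect_equal(back$label, ps$label)
  expect_equal(back$radius, ps$radius)
  expect_error(pocket_set(c("A", "A"), rbind(c(0, 0, 0), c(1, 1, 1))), "unique")
  expect_error(pocket_set("A", matrix(0, 1, 3), radius = 0), "positive")
})
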