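test_that("lattice construction validates cell and operators", {
  expect_error(crystal_lattice(c(-10, 10, 10, 90, 90, 90)), "positive")
  expect_error(crystal_lattice(c(10, 10, 10, 90, 190, 90)), "angles")
  lat <- crystal_lattice(c(10, 20, 30, 90, 90, 90), "P1")
  expect_equal(length(lat$operators), 1L)
  # orthogonalization round trip
  x <- matrix(c(1.2, 3.4, 5.6, 7.8, 9.1, 2.3), 2, 3, byrow = TRUE)
  expect_equal(fragspace:::frac_to_cart(lat, fragspace:::cart_to_frac(lat, x)),
               x, tolerance = 1e-12)
  # triclinic round trip
  tri <- crystal_lattice(c(11, 13, 17, 83, 97, 105), "P1")
  expect_equal(fragspace:::frac_to_cart(tri, fragspace:::cart_to_frac(tri, x)),
               x, tolerance = 1e-9)
})

test_that("packaged space groups form closed operator sets", {
  for (sg in c("P1", "P2", "P21", "C2", "P212121", "P21212", "P43212")) {
    ops <- spacegroup_operators(sg)
    expect_equal(ops[[1]]$R, diag(3), info = sg)
    # closure: composing any two operators lands on an operator
    # (modulo integer lattice translations)
    for (a in ops) for (b in ops) {
      Rc <- a$R %*% b$R
      tc <- as.numeric(a$R %*% b$t + a$t) %% 1
      hit <- any(vapply(ops, function(o) {
        isTRUE(all.equal(o$R, Rc)) &&
          isTRUE(all.equal(o$t %% 1, tc, tolerance = 1e-9))
      }, logical(1)))
      expect_true(hit, info = sg)
    }
  }
  expect_error(spacegroup_operators("X99"), "not in the packaged")
})

test_that("CRYST1 parsing reproduces the written cell", {
  line <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                  40, 50, 60, 90, 95.5, 90, "P 21", 2)
  lat <- lattice_from_cryst1(line)
  expect_equal(lat$cell, c(40, 50, 60, 90, 95.5, 90))
  expect_equal(lat$spacegroup, "P21")
  expect_equal(length(lat$operators), 2L)
})

test_that("symmetry expansion finds periodic images and respects the cutoff", {
  lat <- crystal_lattice(c(10, 50, 50, 90, 90, 90), "P1")
  protein <- matrix(c(0.5, 25, 25), 1, 3)
  ligand <- matrix(c(9.5, 25, 25), 1, 3)
  mates <- expand_symmetry(protein, lat, ligand, cutoff = 6)
  expect_equal(length(mates), 1L)
  expect_equal(mates[[1]]$shift, c(1L, 0L, 0L))
  expect_equal(mates[[1]]$min_dist, 1, tolerance = 1e-9)
  # the asymmetric unit itself (identity, zero shift) is never a mate
  near <- expand_symmetry(protein, lat, matrix(c(1.5, 25, 25), 1, 3), cutoff = 6)
  expect_false(any(vapply(near, function(m) m$op == 1L && all(m$shift == 0L),
                          logical(1))))
  expect_equal(length(expand_symmetry(protein, lat, ligand, cutoff = 0)), 0L)
  far <- crystal_lattice(c(100, 100, 100, 90, 90, 90), "P1")
  expect_equal(length(expand_symmetry(matrix(c(50, 50, 50), 1, 3), far,
                                      matrix(c(20, 20, 20), 1, 3), 6)), 0L)
})

test_that("identity operator reproduces coordinates exactly", {
  lat <- crystal_lattice(c(23, 31, 47, 90, 103, 90), "P21")
  x <- matrix(rnorm(30, sd = 8), 10, 3)
  f <- fragspace:::cart_to_frac(lat, x)
  id <- lat$operators[[1]]
  back <- fragspace:::frac_to_cart(lat, t(id$R %*% t(f)) +
                                   matrix(id$t, 10, 3, byrow = TRUE))
  expect_equal(back, x, tolerance = 1e-9)
})

test_that("a larger cutoff yields a superset of mates", {
  lat <- crystal_lattice(c(15, 15, 15, 90, 90, 90), "P21")
  set.seed(20)
  protein <- matrix(runif(60, 0, 15), 20, 3)
  ligand <- matrix(c(14, 7, 7, 13, 8, 8), 2, 3, byrow = TRUE)
  key <- function(m) paste(m$op, paste(m$shift, collapse = ","))
  small <- vapply(expand_symmetry(protein, lat, ligand, 4), key, character(1))
  large <- vapply(expand_symmetry(protein, lat, ligand, 8), key, character(1))
  expect_true(all(small %in% large))
})

test_that("lattice-proximal flag: direct rule, ties, monotonicity", {
  lig <- matrix(c(0, 0, 0), 1, 3)
  asym <- matrix(c(3, 0, 0), 1, 3)
  mate_near <- structure(list(op = 2L, shift = c(0L, 0L, 0L),
                              coords = matrix(c(-2, 0, 0), 1, 3),
                              min_dist = 2), class = "symmetry_mate")
  mate_far <- structure(list(op = 2L, shift = c(1L, 0L, 0L),
                             coords = matrix(c(-9, 0, 0), 1, 3),
                             min_dist = 9), class = "symmetry_mate")
  expect_false(flag_lattice_proximal(lig, asym, list()))
  expect_false(flag_lattice_proximal(lig, asym, list(mate_far)))
  expect_true(flag_lattice_proximal(lig, asym, list(mate_near)))
  # monotone: adding mates can only turn false into true
  expect_true(flag_lattice_proximal(lig, asym, list(mate_far, mate_near)))
  # equidistant tie resolves to the asymmetric unit
  mate_tie <- structure(list(op = 2L, shift = c(0L, 0L, 0L),
                             coords = matrix(c(-3, 0, 0), 1, 3),
                             min_dist = 3), class = "symmetry_mate")
  expect_false(flag_lattice_proximal(lig, asym, list(mate_tie)))
})

test_that("toy crystal lattice-proximal fraction matches construction", {
  tc <- toy_crystal()
  prot <- as.matrix(tc$model$protein[, c("x", "y", "z")])
  flags <- vapply(tc$model$ligands, function(cf) {
    mates <- expand_symmetry(prot, tc$lattice, cf$coords, cutoff = 6)
    flag_lattice_proximal(cf$coords, prot, mates)
  }, logical(1))
  expect_identical(flags, tc$truth$lattice_proximal)
  expect_equal(mean(flags), mean(tc$truth$lattice_proximal))
})

test_that("surface partition: enclosure, isolation, mirror symmetry", {
  lig <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(-1.4, 0, 0))
  el <- rep("C", 3)
  shell <- fragspace:::sphere_points(200) * 8
  sp_all <- surface_partition(lig, el, list(cage = shell))
  expect_equal(sp_all$percent[sp_all$entity == "cage"], 100, tolerance = 1e-9)
  expect_equal(sp_all$percent[sp_all$entity == "unassigned"], 0)
  # isolated ligand: everything unassigned
  far_wall <- matrix(c(50, 50, 50), 1, 3)
  sp_iso <- surface_partition(lig, el, list(wall = far_wall))
  expect_equal(sp_iso$percent[sp_iso$entity == "unassigned"], 100)
  # mirror fixture: two identical walls
  wall <- as.matrix(expand.grid(x = 4, y = seq(-4, 4, 1), z = seq(-4, 4, 1)))
  wall2 <- wall; wall2[, 1] <- -4
  sp <- surface_partition(lig, el, list(right = wall, left = wall2))
  p <- sp$percent[sp$entity %in% c("right", "left")]
  expect_lte(abs(p[1] - p[2]), 4)
  # percentages sum to at most 100 and are non-negative
  expect_true(all(sp$percent >= 0))
  expect_lte(sum(sp$percent), 100 + 1e-9)
  expect_error(surface_partition(matrix(numeric(), 0, 3), character(),
                                 list(w = far_wall)), "Zero-area")
})

test_that("surface partition is invariant under a joint rigid transform", {
  lig <- rbind(c(0, 0, 0), c(1.4, 0.3, 0), c(-1.2, -0.4, 0.5))
  wall <- as.matrix(expand.grid(x = 4, y = seq(-3, 3, 1.5), z = seq(-3, 3, 1.5)))
  sp0 <- surface_partition(lig, rep("C", 3), list(w = wall))
  tc <- rigid_transform(rbind(lig, wall))
  sp1 <- surface_partition(tc[1:3, ], rep("C", 3), list(w = tc[-(1:3), ]))
  expect_equal(sp0$percent, sp1$percent, tolerance = 0.5)
})

test_that("polar contacts follow the distance-only criteria", {
  g <- molgraph("NCC(=O)[O-]")
  entity <- data.frame(
    element = c("O", "O", "C", "N"),
    x = c(2.9, 4.0, 1.0, 30.0), y = c(0, 0, 0, 3), z = 0,
    resid = c("SER", "SER", "ALA", "LYS"),
    atom_name = c("OG", "OG", "CB", "NZ"), stringsAsFactors = FALSE)
  # coordinates in graph atom order: amine N at the origin, the charged
  # carboxylate oxygen near LYS NZ, everything else out of range
  coords <- matrix(20, g$n_atoms, 3)
  coords[which(g$element == "N"), ] <- c(0, 0, 0)
  coords[which(g$charge == -1L), ] <- c(30, 6.2, 0)  # 3.2 A from NZ
  lig <- conformer(coords, g$element, "gly", "crystal",
                   resolved_mask = rep(TRUE, g$n_atoms), graph = g)
  pc <- polar_contacts(lig, entity)
  # amine N at origin: entity O at 2.9 -> hbond; O at 4.0 -> none (3.5 cutoff)
  n_idx <- which(g$element == "N")
  expect_equal(sum(pc$contacts$ligand_atom == n_idx &
                   pc$contacts$type == "hbond"), 1L)
  # C...C pairs never count
  expect_false(any(pc$contacts$partner_atom == 3))
  # charged carboxylate oxygen 3.2 A from LYS NZ -> salt bridge flagged
  expect_equal(pc$n_saltbridges, 1L)
})

test_that("crystal contact report covers every ligand copy of the toy crystal", {
  tc <- toy_crystal()
  rep_df <- crystal_contact_report(tc$model, n_points = 240L)
  expect_setequal(unique(rep_df$copy_id),
                  vapply(tc$model$ligands, `[[`, character(1), "copy_id"))
  # the interface ligand reports a mate entity with nonzero surface share
  l04 <- rep_df[rep_df$ligand == "L04", ]
  expect_true(any(grepl("^mate", l04$entity)))
  expect_true(all(l04$lattice_proximal))
  mate_share <- sum(l04$surface_percent[grepl("^mate", l04$entity)])
  expect_gt(mate_share, 0)
  # non-interface ligands are not lattice-proximal
  expect_false(any(rep_df$lattice_proximal[rep_df$ligand != "L04"]))
})
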