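test_that("Fsp3 and FC_stereo match hand counts on the worked examples", {
  expect_equal(fsp3("CC"), 1)
  expect_equal(fsp3("c1ccccc1"), 0)
  expect_equal(fsp3("Cc1ccccc1"), 1 / 7)
  expect_equal(fc_stereo("C[C@H](N)C(=O)O"), 1 / 3)
  expect_equal(fc_stereo("c1ccccc1"), 0)
  expect_equal(fc_stereo("C1CCCCC1"), 0)
  expect_warning(v <- fsp3("O=S(=O)(O)O"), "no carbon")
  expect_equal(v, 0)
})

test_that("FC_stereo counts only carbons and never exceeds the sp3-capable set", {
  for (s in c("C[C@H](N)C(=O)O", "CC1CCCO1", "OC(=O)c1ccccc1O",
              "N[C@@H]1C[C@H](O)C[C@@H](N)C1")) {
    mg <- molgraph(s)
    expect_true(all(mg$element[mg$stereocenter] == "C"))
    expect_lte(fc_stereo(mg), 1)
  }
})

test_that("spatial score reproduces the published implementation", {
  # frozen oracle values from the reference SPS implementation
  probes <- c(
    "Oc1ccccc1" = 60, "COc1ccccc1" = 69, "Nc1ccccc1" = 60, "CC(=O)N" = 25,
    "CN(C)C=O" = 34, "CSc1ccccc1" = 73, "CCO" = 18, "CCOCC" = 42,
    "CC=C" = 13, "C/C=C/C" = 38, "C1CCC=CC1" = 128, "CC(N)C(=O)O" = 82,
    "OC(=O)c1ccccc1O" = 92, "c1ccncc1" = 48, "c1cc[nH]c1" = 40,
    "O=[N+]([O-])c1ccccc1" = 80, "C[N+](C)(C)C" = 60, "CS(C)(=O)=O" = 58,
    "CSC" = 18, "C=Cc1ccccc1" = 68, "C1CCOC1" = 120, "C1COCCN1" = 144)
  for (s in names(probes)) {
    expect_equal(spatial_score(s)$sps, unname(probes[s]), info = s)
  }
})

test_that("spatial score basics: methane, benzene, normalization, invariance", {
  expect_equal(spatial_score("C")$sps, 0)   # no heavy neighbors
  expect_equal(spatial_score("C")$nsps, 0)
  sc <- spatial_score("c1ccccc1")
  expect_equal(sc$sps, 48)
  expect_equal(sc$nsps, 8)
  # nsps = sps / heavy atoms exactly
  for (s in c("CCO", "Cc1ccccc1", "C1CCOC1")) {
    v <- spatial_score(s)
    expect_equal(v$nsps, v$sps / molgraph(s)$n_atoms)
  }
  # invariance under atom reordering
  expect_equal(spatial_score("c1ccccc1C")$sps, spatial_score("Cc1ccccc1")$sps)
})

test_that("descriptor panel equals the independent brute-force oracle", {
  tab <- read.csv(test_path("descriptor_oracle.csv"), stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 50L)
  for (i in seq_len(nrow(tab))) {
    mg <- molgraph(tab$smiles[i])
    no <- mg$element %in% c("N", "O")
    expect_equal(suppressWarnings(fsp3(mg)), tab$fsp3[i], info = tab$smiles[i])
    expect_equal(suppressWarnings(fc_stereo(mg)), tab$fc_stereo[i],
                 info = tab$smiles[i])
    expect_equal(length(mg$aromatic_rings), tab$nar[i], info = tab$smiles[i])
    expect_equal(sum(no), tab$hba[i], info = tab$smiles[i])
    expect_equal(sum(no & mg$nH >= 1L), tab$hbd[i], info = tab$smiles[i])
    expect_equal(n_rotatable_bonds(mg), tab$nrb[i], info = tab$smiles[i])
  }
})

test_that("physchem panel populates all seven values", {
  p <- physchem_panel("c1ccccc1")
  expect_equal(p$nar, 1L)
  expect_equal(p$hbd, 0L)
  expect_equal(p$nrb, 0L)
  expect_true(is.finite(p$logp) && is.finite(p$tpsa))
  expect_equal(physchem_panel("O")$mw, 18.02, tolerance = 1e-2)
  expect_equal(physchem_panel("c1ccc2ccccc2c1")$nar, 2L)
})

test_that("rule-of-three bounds are inclusive and configurable", {
  v <- physchem_panel("c1ccccc1")
  expect_true(ro3_compliance(v))
  big <- list(mw = 450, hbd = 1, hba = 2, logp = 2, nrb = 1, tpsa = 30)
  expect_false(ro3_compliance(big))
  boundary <- list(mw = 300, hbd = 3, hba = 3, logp = 3, nrb = 3, tpsa = 60)
  expect_true(ro3_compliance(boundary))
  expect_false(ro3_compliance(boundary, bounds = list(mw = 299)))
})

test_that("compliance fraction counts boundary values as passing", {
  expect_equal(compliance_fraction(c(0.5, 0.3, 0.42), 0.42), 2 / 3)
  expect_equal(compliance_fraction(c(0.1, 0.2), 0.42), 0)
  expect_equal(compliance_fraction(c(0.5, 0.6), 0.42), 1)
  expect_error(compliance_fraction(numeric(), 0.42), "Empty")
})

test_that("NP likeness orders natural-product-like above synthetic-like", {
  tab <- np_contribution_table()
  sugar <- np_likeness("OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O", tab)
  biphenyl <- np_likeness("c1ccc(-c2ccccc2)cc1", tab)
  expect_gt(sugar, biphenyl)
  menthol <- np_likeness("CC(C)C1CCC(C)CC1O", tab)
  quinazoline <- np_likeness("Nc1ncnc2ccccc12", tab)
  expect_gt(menthol, quinazoline)
  # size normalization: two disconnected copies score the same
  expect_equal(np_likeness("CCO.CCO", tab), np_likeness("CCO", tab))
  expect_error(np_likeness("CCO", tab[0, ]), "Empty")
})

test_that("descriptor table produces one complete row per molecule", {
  recs <- list(make_record("Cc1ccccc1", "tol", "fragments"),
               make_record("OC(=O)c1ccccc1O", "sal", "fragments"))
  tab <- descriptor_table(recs)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("mw", "hba", "hbd", "logp", "nrb", "tpsa", "nar", "fsp3",
                    "fc_stereo", "sps", "nsps", "np_likeness",
                    "ro3_compliant") %in% names(tab)))
  expect_false(anyNA(tab$logp))
  expect_equal(tab$nsps, tab$sps / c(7, 10))
})
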