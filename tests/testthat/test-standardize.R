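test_that("standardization disconnects metals, desalts and neutralizes", {
  expect_equal(standardize_molecule("CC(=O)[O-].[Na+]")$smiles_canonical,
               "CC(=O)O")
  expect_equal(standardize_molecule("c1ccccc1")$smiles_canonical, "c1ccccc1")
  # largest organic component wins over a bigger inorganic one
  r <- standardize_molecule("CCO.[Na+].[Cl-]")
  expect_equal(r$smiles_canonical, standardize_molecule("CCO")$smiles_canonical)
  # permanent cation untouched, counter-ion dropped
  expect_equal(standardize_molecule("C[N+](C)(C)C.[Cl-]")$smiles_canonical,
               "C[N+](C)(C)C")
  # internal zwitterion partner (nitro) stays charged
  expect_match(standardize_molecule("O=[N+]([O-])c1ccccc1")$smiles_canonical,
               "\\[N\\+\\]")
})

test_that("standardization is idempotent on canonical strings", {
  inputs <- c("CC(=O)[O-].[Na+]", "[NH3+]CC(=O)[O-]", "Cc1ccccc1",
              "OC(=O)c1ccccc1O", "C[C@H](N)C(=O)O")
  for (s in inputs) {
    once <- standardize_molecule(s)$smiles_canonical
    twice <- standardize_molecule(once)$smiles_canonical
    expect_identical(twice, once)
  }
})

test_that("unparseable and all-inorganic inputs are rejected with context", {
  expect_error(standardize_molecule("][", id = "bad1"), "bad1")
  expect_error(standardize_molecule("[Na+].[Cl-]", id = "salt1"),
               "No organic component")
})

test_that("deduplication keys on canonical SMILES within a source tag", {
  recs <- list(make_record("Cc1ccccc1", id = "a", source_tag = "fragments"),
               make_record("c1ccccc1C", id = "b", source_tag = "fragments"),
               make_record("Cc1ccccc1", id = "c", source_tag = "pdb_ligands"))
  out <- dedupe_records(recs)
  expect_length(out, 2L)
  expect_setequal(vapply(out, `[[`, character(1), "id"), c("a", "c"))
})

test_that("ligand efficiency follows the 1.37 scaling", {
  expect_equal(ligand_efficiency(6, 20), 0.411)
  expect_equal(ligand_efficiency(0, 15), 0)
  expect_equal(ligand_efficiency(6, 40), ligand_efficiency(6, 20) / 2)
  expect_error(ligand_efficiency(5, 0), "heavy_atoms")
})

test_that("activity curation applies confidence and pChEMBL/LE rules", {
  # 6 records enumerated by hand: 2 pass by pChEMBL only (26 heavy atoms
  # keeps LE = 1.37*pChEMBL/26 below 0.3), 1 by LE only, 1 by both,
  # 1 fails both thresholds, 1 fails the confidence requirement -> 4 kept
  chain26 <- strrep("C", 26)
  recs <- list(
    make_record(chain26, "p1", "chembl_kinase", pchembl = 5.5, confidence = 9L),
    make_record(paste0("O", strrep("C", 25)), "p2", "chembl_kinase",
                pchembl = 5.0, confidence = 9L),  # boundary pChEMBL inclusive
    make_record("CCO", "le1", "chembl_kinase", pchembl = 4.0, confidence = 9L),
    make_record("CC(=O)O", "both1", "chembl_kinase", pchembl = 6.0, confidence = 9L),
    make_record(paste0("N", strrep("C", 25)), "f1", "chembl_kinase",
                pchembl = 4.0, confidence = 9L),
    make_record("Clc1ccccc1", "f2", "chembl_kinase", pchembl = 6.0, confidence = 8L))
  out <- curate_activity_dataset(recs)
  expect_setequal(vapply(out, `[[`, character(1), "id"),
                  c("p1", "p2", "le1", "both1"))
  expect_length(curate_activity_dataset(list()), 0L)
})

test_that("curation is a monotone subset operation", {
  recs <- lapply(seq_len(8L), function(i) {
    make_record(c("Cc1ccccc1", "CCO", "CC(=O)O", "c1ccncc1")[(i %% 4) + 1L],
                id = paste0("r", i), source_tag = "chembl_kinase",
                pchembl = 3 + i * 0.5, confidence = 9L)
  })
  loose <- curate_activity_dataset(recs, pchembl_min = 4, le_min = 0.2)
  tight <- curate_activity_dataset(recs, pchembl_min = 6, le_min = 2.5)
  expect_lte(length(tight), length(loose))
  expect_true(all(vapply(tight, `[[`, character(1), "smiles_canonical") %in%
                  vapply(loose, `[[`, character(1), "smiles_canonical")))
})

test_that("file readers round-trip SMILES, SDF and activity tables", {
  smi_path <- tempfile(fileext = ".smi")
  writeLines(c("Cc1ccccc1\ttol", "CCO\tethanol"), smi_path)
  recs <- read_smiles_file(smi_path, source_tag = "user")
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$id, "tol")
  expect_equal(recs[[2]]$smiles_canonical, "CCO")

  csv_path <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("a", "b"), smiles = c("CCO", "CC(=O)[O-].[Na+]"),
                       pchembl = c(5.5, 6.0), confidence = c(9L, 9L),
                       source_tag = "chembl_kinase"),
            csv_path, row.names = FALSE)
  arecs <- read_activity_csv(csv_path)
  expect_length(arecs, 2L)
  expect_equal(arecs[[1]]$pchembl, 5.5)
  cur <- curate_activity_dataset(arecs)
  expect_length(cur, 2L)
  expect_equal(cur[[2]]$smiles_canonical, "CC(=O)O")  # standardized on the way

  sdf_path <- tempfile(fileext = ".sdf")
  writeLines(fragspace:::ob_to_sdf(c("Cc1ccccc1", "CCO")), sdf_path)
  srecs <- read_sdf_molecules(sdf_path, standardize = FALSE)
  expect_length(srecs, 2L)
  expect_equal(srecs[[2]]$smiles_canonical, "CCO")
})
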