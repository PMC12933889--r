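#' @title Molecule standardization and activity-based curation
#' @description Reading, standardizing, deduplicating and curating molecule
#'   collections. Standardization mirrors the common database preparation
#'   protocol: covalent metal-organic bonds are disconnected (the metal is
#'   discarded), the largest organic component is kept (desalting), charges
#'   are neutralized where chemically possible, and the result is
#'   canonicalized. Curation applies the kinase-bioactivity filter: assay
#'   confidence 9 together with pChEMBL >= 5 and/or ligand efficiency >= 0.3.
#' @name standardize
NULL

#' Construct a molecule record
#'
#' A molecule record ties a standardized structure to its identifiers and
#' optional activity annotations. `source_tag` labels the collection a record
#' belongs to (e.g. `fragments`, `pdb_ligands`, `chembl_kinase`,
#' `chembl_pka`, `approved_pki`, `oral_drugs`, `np_parents`, `user`).
#'
#' @param smiles_canonical canonical SMILES (single organic component).
#' @param id record identifier.
#' @param smiles_raw structure string as read.
#' @param source_tag dataset label.
#' @param pchembl optional unitless activity value (-log10 molar).
#' @param assay_confidence optional integer assay confidence score.
#' @param approval_year optional integer.
#' @param graph optional pre-built [molgraph()].
#' @return object of class `mol_record`.
#' @export
molecule_record <- function(smiles_canonical, id = NA_character_,
                            smiles_raw = smiles_canonical,
                            source_tag = "user", pchembl = NA_real_,
                            assay_confidence = NA_integer_,
                            approval_year = NA_integer_, graph = NULL) {
  if (is.null(graph)) graph <- molgraph(smiles_canonical, canonicalize = FALSE)
  structure(list(
    id = id,
    smiles_raw = smiles_raw,
    smiles_canonical = smiles_canonical,
    source_tag = source_tag,
    pchembl = pchembl,
    assay_confidence = assay_confidence,
    heavy_atom_count = graph$n_atoms,
    approval_year = approval_year,
    graph = graph
  ), class = "mol_record")
}

#' @export
print.mol_record <- function(x, ...) {
  cat("<mol_record>", if (!is.na(x$id)) x$id else "", x$smiles_canonical,
      sprintf("[%s, %d heavy atoms]\n", x$source_tag, x$heavy_atom_count))
  invisible(x)
}

#' Standardize one raw structure string
#'
#' Applies, in order: metal disconnection (metal atoms are removed, not
#' preserved), desalting to the largest organic component, charge
#' neutralization (protonatable anions gain a proton, deprotonatable cations
#' lose one; permanent cations such as quaternary nitrogen and internal
#' zwitterion partners such as the nitro group are left untouched), and
#' canonicalization.
#'
#' @param raw a structure string (SMILES), possibly multi-component.
#' @param id record identifier used in error messages.
#' @param source_tag dataset label for the returned record.
#' @param pchembl,assay_confidence,approval_year optional annotations carried
#'   into the record.
#' @return a `mol_record` whose `smiles_canonical` is the standardized form.
#' @examples
#' \dontrun{
#' standardize_molecule("CC(=O)[O-].[Na+]")$smiles_canonical  # "CC(=O)O"
#' }
#' @export
standardize_molecule <- function(raw, id = NA_character_, source_tag = "user",
                                 pchembl = NA_real_,
                                 assay_confidence = NA_integer_,
                                 approval_year = NA_integer_) {
  mg <- tryCatch(molgraph(raw), error = function(e) {
    stop("Unparseable structure", if (!is.na(id)) paste0(" [", id, "]"),
         ": ", raw, call. = FALSE)
  })
  # 1. metal disconnection: drop metal atoms together with their bonds
  keep <- which(!(mg$element %in% METALS))
  if (!length(keep)) {
    stop("No organic component", if (!is.na(id)) paste0(" [", id, "]"),
         ": ", raw, call. = FALSE)
  }
  parts <- molgraph_parts(mg, keep)
  # 2. desalting: largest component containing at least one carbon
  g <- igraph::make_empty_graph(length(keep), directed = FALSE)
  if (nrow(parts$bonds)) {
    g <- igraph::add_edges(g, rbind(parts$bonds$a1, parts$bonds$a2))
  }
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  organic <- vapply(seq_along(sizes), function(ci) {
    any(parts$element[comp == ci] == "C")
  }, logical(1))
  if (!any(organic)) {
    stop("No organic component", if (!is.na(id)) paste0(" [", id, "]"),
         ": ", raw, call. = FALSE)
  }
  best <- which(organic)[which.max(sizes[organic])]
  sub <- molgraph_parts(mg, keep[comp == best])
  # 3. neutralization on the retained component
  sub <- neutralize_charges(sub)
  # 4. canonicalize and rebuild
  can <- parts_to_smiles(sub)
  molecule_record(can, id = id, smiles_raw = raw, source_tag = source_tag,
                  pchembl = pchembl, assay_confidence = assay_confidence,
                  approval_year = approval_year)
}

# Neutralize charges where a proton can be added or removed. Heuristics:
#  * anions on N/O/S gain a proton unless bonded to a positively charged
#    atom (nitro, N-oxide and friends stay zwitterionic);
#  * cations on N/O/S lose a proton when they carry one (quaternary
#    nitrogen has none and is untouched).
# Hydrogen counts are implicit in the connection table, so adjusting the
# formal charge is sufficient.
neutralize_charges <- function(parts) {
  n <- length(parts$element)
  if (!n) return(parts)
  bondsum <- numeric(n); deg <- integer(n)
  adj <- vector("list", n)
  if (nrow(parts$bonds)) for (k in seq_len(nrow(parts$bonds))) {
    a <- parts$bonds$a1[k]; b <- parts$bonds$a2[k]; o <- parts$bonds$order[k]
    bondsum[a] <- bondsum[a] + o; bondsum[b] <- bondsum[b] + o
    deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  for (i in seq_len(n)) {
    q <- parts$charge[i]
    if (q == 0L || !(parts$element[i] %in% c("N", "O", "S"))) next
    if (q < 0L) {
      nb <- adj[[i]]
      if (length(nb) && any(parts$charge[nb] > 0L)) next  # internal zwitterion
      parts$charge[i] <- q + 1L
    } else if (q > 0L) {
      v <- default_valence(parts$element[i], q, bondsum[i])
      nH <- v - bondsum[i]
      if (nH >= 1) parts$charge[i] <- q - 1L  # has a proton to give up
    }
  }
  parts
}

#' Ligand efficiency
#'
#' `LE = scale * pActivity / heavy_atoms`, the standard free-energy-per-atom
#' measure with `scale = 1.37` kcal/mol per log unit at 300 K.
#'
#' @param pchembl non-negative activity value (-log10 molar).
#' @param heavy_atoms heavy-atom count (>= 1).
#' @param scale kcal/mol per log unit; default 1.37.
#' @return LE in kcal/mol per heavy atom.
#' @examples
#' ligand_efficiency(6, 20)  # 0.411
#' @export
ligand_efficiency <- function(pchembl, heavy_atoms, scale = 1.37) {
  if (any(heavy_atoms < 1, na.rm = TRUE)) {
    stop("heavy_atoms must be >= 1", call. = FALSE)
  }
  if (any(pchembl < 0, na.rm = TRUE)) stop("pchembl must be >= 0", call. = FALSE)
  scale * pchembl / heavy_atoms
}

#' Deduplicate records on canonical SMILES within a source tag
#'
#' @param records list of `mol_record`.
#' @return list with duplicates removed (first occurrence kept).
#' @export
dedupe_records <- function(records) {
  if (!length(records)) return(records)
  key <- vapply(records, function(r) paste(r$source_tag, r$smiles_canonical),
                character(1))
  records[!duplicated(key)]
}

#' Curate an activity-annotated molecule set
#'
#' Keeps records measured at the required assay confidence whose pChEMBL
#' value or ligand efficiency clears the threshold (inclusive OR, boundaries
#' inclusive), then standardizes and deduplicates. Records lacking the needed
#' annotations are dropped; the number dropped is reported via `message()`.
#'
#' @param records list of `mol_record` carrying `pchembl` and
#'   `assay_confidence`.
#' @param pchembl_min minimum pChEMBL (default 5.0).
#' @param le_min minimum ligand efficiency (default 0.3).
#' @param confidence_required required assay confidence score (default 9).
#' @param le_scale scale constant for [ligand_efficiency()].
#' @return curated list of `mol_record`.
#' @export
curate_activity_dataset <- function(records, pchembl_min = 5.0, le_min = 0.3,
                                    confidence_required = 9L,
                                    le_scale = 1.37) {
  if (!length(records)) return(records)
  annotated <- vapply(records, function(r) {
    !is.na(r$pchembl) && !is.na(r$assay_confidence)
  }, logical(1))
  if (any(!annotated)) {
    message(sum(!annotated), " record(s) dropped for missing activity annotations")
  }
  records <- records[annotated]
  keep <- vapply(records, function(r) {
    if (r$assay_confidence != confidence_required) return(FALSE)
    le <- ligand_efficiency(r$pchembl, r$heavy_atom_count, scale = le_scale)
    r$pchembl >= pchembl_min || le >= le_min
  }, logical(1))
  out <- lapply(records[keep], function(r) {
    standardize_molecule(r$smiles_raw, id = r$id, source_tag = r$source_tag,
                         pchembl = r$pchembl,
                         assay_confidence = r$assay_confidence,
                         approval_year = r$approval_year)
  })
  dedupe_records(out)
}

#' Read molecules from a SMILES file
#'
#' One molecule per line, optionally followed by a tab- or space-separated
#' identifier. Lines failing to parse raise an error naming the offending
#' record unless `skip_failures` is set.
#'
#' @param path file path.
#' @param source_tag dataset label applied to all records.
#' @param standardize run [standardize_molecule()] on each entry (default)?
#' @param skip_failures drop unparseable lines with a message instead of
#'   erroring.
#' @return list of `mol_record`.
#' @export
read_smiles_file <- function(path, source_tag = "user", standardize = TRUE,
                             skip_failures = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  ok <- logical(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    smi <- f[1L]
    id <- if (length(f) > 1L) f[2L] else sprintf("mol%04d", i)
    rec <- tryCatch({
      if (standardize) standardize_molecule(smi, id = id, source_tag = source_tag)
      else molecule_record(ob_canonical(smi), id = id, smiles_raw = smi,
                           source_tag = source_tag)
    }, error = function(e) if (skip_failures) NULL else stop(e))
    if (!is.null(rec)) { out[[i]] <- rec; ok[i] <- TRUE }
  }
  if (any(!ok)) message(sum(!ok), " record(s) skipped as unparseable")
  out[ok]
}

#' Read molecules from an SDF file
#'
#' @param path SDF file path.
#' @param source_tag dataset label.
#' @param standardize run the standardizer on each entry (default)?
#' @return list of `mol_record`.
#' @export
read_sdf_molecules <- function(path, source_tag = "user", standardize = TRUE) {
  sdf <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdf)
  out <- vector("list", length(sdf))
  lines <- ob_run(readLines(path, warn = FALSE), "sdf", "can")
  lines <- lines[nzchar(trimws(lines))]
  smis <- vapply(strsplit(lines, "[ \t]+"), `[`, character(1), 1L)
  if (length(smis) != length(sdf)) {
    stop("SDF conversion returned ", length(smis), " records for ",
         length(sdf), " molecules in ", path)
  }
  for (i in seq_along(smis)) {
    out[[i]] <- if (standardize) {
      standardize_molecule(smis[i], id = ids[i], source_tag = source_tag)
    } else {
      molecule_record(ob_canonical(smis[i]), id = ids[i], smiles_raw = smis[i],
                      source_tag = source_tag)
    }
  }
  out
}

#' Read an activity table (CSV) into molecule records
#'
#' Expected columns: `id`, `smiles`, `pchembl`, `confidence`, `source_tag`
#' (extra columns ignored; missing annotation columns filled with `NA`).
#'
#' @param path CSV file path.
#' @param standardize run the standardizer on each entry? Off by default:
#'   curation standardizes after filtering.
#' @return list of `mol_record`.
#' @export
read_activity_csv <- function(path, standardize = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "smiles") %in% names(df))) {
    stop("Activity CSV needs at least columns 'id' and 'smiles'")
  }
  getcol <- function(nm, default) if (nm %in% names(df)) df[[nm]] else default
  pch <- getcol("pchembl", rep(NA_real_, nrow(df)))
  conf <- getcol("confidence", rep(NA_integer_, nrow(df)))
  tag <- getcol("source_tag", rep("user", nrow(df)))
  lapply(seq_len(nrow(df)), function(i) {
    if (standardize) {
      standardize_molecule(df$smiles[i], id = df$id[i], source_tag = tag[i],
                           pchembl = pch[i], assay_confidence = as.integer(conf[i]))
    } else {
      molecule_record(ob_canonical(df$smiles[i]), id = df$id[i],
                      smiles_raw = df$smiles[i], source_tag = tag[i],
                      pchembl = pch[i], assay_confidence = as.integer(conf[i]))
    }
  })
}

#' Tabulate a list of molecule records
#'
#' @param records list of `mol_record`.
#' @return data.frame (one row per record, graph column omitted).
#' @export
records_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(id = r$id, smiles_canonical = r$smiles_canonical,
               source_tag = r$source_tag, pchembl = r$pchembl,
               assay_confidence = r$assay_confidence,
               heavy_atom_count = r$heavy_atom_count,
               approval_year = r$approval_year,
               stringsAsFactors = FALSE)
  }))
}
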