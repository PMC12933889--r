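#' @title OpenBabel command-line interface helpers
#' @description Internal wrappers around the `obabel` binary, used for SMILES
#'   canonicalization, SMILES -> SDF conversion, 3D coordinate generation and
#'   the octanol/water partition and polar-surface-area estimators. All
#'   chemistry-specific analysis (descriptors, scaffolds, fingerprints, shape)
#'   is implemented in this package on top of the molecular graphs obtained
#'   here.
#' @name openbabel
#' @keywords internal
NULL

ob_binary <- function() {
  bin <- Sys.which("obabel")
  if (!nzchar(bin)) {
    stop("OpenBabel ('obabel') was not found on PATH; it is required for ",
         "structure parsing and canonicalization.", call. = FALSE)
  }
  bin
}

#' Run obabel on a character vector of input records
#'
#' @param input character vector (e.g. SMILES lines), written to a temp file.
#' @param informat,outformat OpenBabel format codes ("smi", "can", "sdf", ...).
#' @param args extra command-line arguments.
#' @return character vector of output lines.
#' @keywords internal
ob_run <- function(input, informat, outformat, args = character()) {
  fin <- tempfile(fileext = paste0(".", informat))
  fout <- tempfile(fileext = paste0(".", outformat))
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(input, fin)
  res <- suppressWarnings(system2(
    ob_binary(),
    c(shQuote(fin), paste0("-i", informat), paste0("-o", outformat),
      "-O", shQuote(fout), args),
    stdout = FALSE, stderr = TRUE
  ))
  if (!file.exists(fout)) {
    stop("obabel conversion failed: ", paste(res, collapse = " "), call. = FALSE)
  }
  readLines(fout, warn = FALSE)
}

#' Canonical (aromatic) SMILES via OpenBabel
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` for unparseable input.
#' @keywords internal
ob_canonical <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character())
  # tag records so that parse failures (dropped records) can be located
  ids <- sprintf("rec%06d", seq_len(n))
  out <- ob_run(paste(smiles, ids, sep = "\t"), "smi", "can")
  out <- out[nzchar(trimws(out))]
  parts <- strsplit(out, "[ \t]+")
  got <- vapply(parts, function(p) p[length(p)], character(1))
  can <- vapply(parts, function(p) p[1L], character(1))
  res <- rep(NA_character_, n)
  res[match(got, ids)] <- can
  res
}

#' Convert SMILES to SDF text blocks (2D-less connection tables)
#'
#' Atom order in the SDF follows the atom order of the input SMILES, which
#' this package relies on to align aromaticity flags parsed from the SMILES
#' with the connection table.
#'
#' @param smiles character vector.
#' @param gen3d generate 3D coordinates (rule-based + force field)?
#' @return character vector: one concatenated SDF text, records separated by
#'   `$$$$`.
#' @keywords internal
ob_to_sdf <- function(smiles, gen3d = FALSE) {
  args <- if (gen3d) "--gen3d" else character()
  ob_run(smiles, "smi", "sdf", args)
}

#' OpenBabel physicochemical property estimates
#'
#' Returns the atom-contribution logP and topological polar surface area
#' computed by OpenBabel for each molecule.
#'
#' @param smiles character vector.
#' @return data.frame with columns `logp`, `tpsa`.
#' @keywords internal
ob_logp_tpsa <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(data.frame(logp = numeric(), tpsa = numeric()))
  ids <- sprintf("rec%06d", seq_len(n))
  out <- ob_run(paste(smiles, ids, sep = "\t"), "smi", "smi",
                c("--append", shQuote("logP TPSA")))
  out <- out[nzchar(trimws(out))]
  logp <- rep(NA_real_, n); tpsa <- rep(NA_real_, n)
  for (line in out) {
    f <- strsplit(trimws(line), "[ \t]+")[[1]]
    # layout: smiles id logP TPSA
    if (length(f) >= 4L) {
      i <- match(f[2L], ids)
      if (!is.na(i)) {
        logp[i] <- as.numeric(f[3L])
        tpsa[i] <- as.numeric(f[4L])
      }
    }
  }
  data.frame(logp = logp, tpsa = tpsa)
}
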