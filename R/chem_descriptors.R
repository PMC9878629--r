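# Per-molecule descriptors: 166-bit MACCS structural fingerprints and the
# six drug-likeness molecular properties.

# Rotatable bond: single, non-ring bond between two non-terminal atoms,
# excluding bonds to triple-bonded (e.g. nitrile/alkyne) atoms.
.RTB_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' MACCS keys fingerprints
#'
#' Computes the public 166-bit MACCS substructure-key fingerprint for each
#' molecule. Each bit records the presence or absence of one predefined
#' structural feature; identical structures always give identical bit
#' vectors. Fingerprints are intended to be computed on cleaned,
#' stereo-stripped structures (see [clean_and_deduplicate()]).
#'
#' @param smiles character vector of SMILES strings.
#' @return binary integer matrix, one row per molecule, exactly 166 columns
#'   (`MACCS1` ... `MACCS166`). Row names follow `names(smiles)` if set.
#' @export
maccs_fingerprint <- function(smiles) {
  if (!length(smiles)) stop("no molecules supplied")
  ids <- names(smiles) %||% paste0("mol_", seq_along(smiles))
  sdf <- tryCatch(smiles_to_sdf(smiles, ids),
                  error = function(e) stop("unparseable SMILES input: ",
                                           conditionMessage(e)))
  if (length(sdf) != length(smiles)) stop("unparseable SMILES input")
  fp <- ChemmineR::fingerprintOB(sdf, "MACCS")
  m <- methods::slot(fp, "fpma")[, 1:166, drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- list(ids, paste0("MACCS", 1:166))
  m
}

#' Six drug-likeness molecular properties
#'
#' Computes, per molecule: hydrogen bond donors (`HBD`), hydrogen bond
#' acceptors (`HBA`, N+O-style acceptor count), octanol/water partition
#' coefficient (`LogP`, Wildman-Crippen atomic contributions), molecular
#' weight (`MW`, g/mol), topological polar surface area (`TPSA`, Ertl
#' contributions, squared angstroms), and number of rotatable bonds (`RTB`,
#' single non-ring bonds between non-terminal atoms).
#'
#' @param smiles character vector of SMILES strings.
#' @return data.frame with columns `id`, `HBD`, `HBA`, `LogP`, `MW`,
#'   `TPSA`, `RTB`, one row per molecule in input order.
#' @export
property_vector <- function(smiles) {
  if (!length(smiles)) stop("no molecules supplied")
  ids <- names(smiles) %||% paste0("mol_", seq_along(smiles))
  sdf <- tryCatch(smiles_to_sdf(smiles, ids),
                  error = function(e) stop("unparseable SMILES input: ",
                                           conditionMessage(e)))
  if (length(sdf) != length(smiles)) stop("unparseable SMILES input")
  pr <- ChemmineR::propOB(sdf)
  rtb <- ChemmineR::smartsSearchOB(sdf, .RTB_SMARTS, uniqueMatches = TRUE)
  data.frame(id = ids,
             HBD = as.integer(pr$HBD),
             HBA = as.integer(pr$HBA1),
             LogP = pr$logP,
             MW = pr$MW,
             TPSA = pr$TPSA,
             RTB = as.integer(rtb),
             stringsAsFactors = FALSE)
}

#' Property matrix of a library
#'
#' Convenience wrapper returning the numeric 6-column matrix used by the
#' distance and embedding functions, rows in library record order.
#'
#' @param lib a cleaned [chem_library()].
#' @return numeric matrix with columns `HBD`, `HBA`, `LogP`, `MW`, `TPSA`,
#'   `RTB`, row names = record ids.
#' @export
property_matrix <- function(lib) {
  stopifnot(inherits(lib, "ChemLibrary"))
  pv <- property_vector(stats::setNames(lib$records$smiles, lib$records$id))
  m <- as.matrix(pv[, c("HBD", "HBA", "LogP", "MW", "TPSA", "RTB")])
  rownames(m) <- pv$id
  m
}

#' Write a fingerprint matrix as id + bitstring lines
#'
#' @param fp matrix from [maccs_fingerprint()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fp, path) {
  bits <- apply(fp, 1, paste, collapse = "")
  writeLines(paste(rownames(fp), bits, sep = "\t"), path)
  invisible(path)
}
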