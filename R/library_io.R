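# Reading, cleaning, and deduplicating chemical libraries.

#' Create a chemical library object
#'
#' A `ChemLibrary` is a named, ordered collection of molecule records, each
#' holding an identifier and a SMILES string. Libraries read from disk are
#' not yet deduplicated; pass them through [clean_and_deduplicate()] before
#' any diversity analysis.
#'
#' @param name library name tag.
#' @param id character vector of record identifiers.
#' @param smiles character vector of SMILES strings (same length as `id`).
#' @return A `ChemLibrary` object: a list with elements `name` and `records`
#'   (a data.frame with columns `id`, `smiles`, `source`).
#' @export
chem_library <- function(name, id, smiles) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            length(id) == length(smiles))
  if (length(smiles) < 1L) stop("a ChemLibrary needs at least one record")
  id <- as.character(id)
  id[!nzchar(id) | is.na(id)] <- sprintf("%s_%05d", name,
                                         which(!nzchar(id) | is.na(id)))
  structure(
    list(name = name,
         records = data.frame(id = id, smiles = as.character(smiles),
                              source = name, stringsAsFactors = FALSE)),
    class = "ChemLibrary")
}

#' @export
print.ChemLibrary <- function(x, ...) {
  cat(sprintf("<ChemLibrary> %s: %d records\n", x$name, nrow(x$records)))
  print(utils::head(x$records, 5))
  if (nrow(x$records) > 5) cat("...\n")
  invisible(x)
}

#' @export
length.ChemLibrary <- function(x) nrow(x$records)

#' Read a chemical library from an SDF or SMILES file
#'
#' SMILES files hold one molecule per line as `SMILES [id]` (whitespace
#' separated); blank lines and lines starting with `#` are ignored. SDF files
#' are parsed as V2000 records. Entries that fail to parse are skipped with a
#' warning; a file with no parseable entry is an error.
#'
#' @param path file path.
#' @param format `"smiles"` or `"sdf"`.
#' @param name library name tag; defaults to the file name without extension.
#' @return A [chem_library()] object with one record per parsed entry, in
#'   file order, not yet deduplicated.
#' @seealso [clean_and_deduplicate()]
#' @export
read_library <- function(path, format = c("smiles", "sdf"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty library file: ", path)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))

  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("no molecule entries in ", path)
    tok <- strsplit(lines, "[[:space:]]+")
    smiles <- vapply(tok, `[[`, character(1), 1L)
    id <- vapply(tok, function(t) if (length(t) >= 2) t[2] else NA_character_,
                 character(1))
    ok <- is_valid_smiles(smiles)
    if (!any(ok)) stop("no parseable molecule in ", path)
    if (any(!ok)) {
      warning(sprintf("skipped %d unparseable entr%s in %s",
                      sum(!ok), if (sum(!ok) == 1) "y" else "ies", path))
    }
    id <- ifelse(is.na(id), sprintf("%s_%05d", name, seq_along(smiles)), id)
    lib <- chem_library(name, id[ok], smiles[ok])
    attr(lib, "n_unparseable") <- sum(!ok)
    return(lib)
  }

  # SDF: read records, convert each to SMILES (per record, so that one
  # malformed block does not take down its neighbours).
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                  error = function(e) stop("cannot read SDF file ", path,
                                           ": ", conditionMessage(e)))
  if (length(sdf) == 0) stop("no molecule entries in ", path)
  valid <- tryCatch(ChemmineR::validSDF(sdf), error = function(e)
    rep(TRUE, length(sdf)))
  ids <- ChemmineR::sdfid(sdf)
  smiles <- rep(NA_character_, length(sdf))
  for (i in which(valid)) {
    smiles[i] <- tryCatch({
      s <- ChemmineR::sdf2smiles(sdf[i])
      as.character(as.character(s)[1])
    }, error = function(e) NA_character_)
  }
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) stop("no parseable molecule in ", path)
  if (any(!ok)) {
    warning(sprintf("skipped %d unparseable SDF record%s in %s",
                    sum(!ok), if (sum(!ok) == 1) "" else "s", path))
  }
  ids <- ifelse(is.na(ids) | !nzchar(ids),
                sprintf("%s_%05d", name, seq_along(smiles)), ids)
  lib <- chem_library(name, ids[ok], smiles[ok])
  attr(lib, "n_unparseable") <- sum(!ok)
  lib
}

#' Clean and deduplicate a chemical library
#'
#' Applies the standard preprocessing contract for diversity analysis:
#' stereochemistry descriptors are removed (the analysis disregards
#' stereochemistry), each molecule is reduced to its largest covalently
#' connected fragment (salt/solvent stripping; ties broken by molecular
#' weight), structures are canonicalized, and records with identical
#' canonical SMILES are collapsed to the first occurrence.
#'
#' @param lib a [chem_library()] object.
#' @return A list with elements `library` (the cleaned `ChemLibrary`) and
#'   `report` (a `CleaningReport` with counts `n_input`, `n_unparseable`,
#'   `n_duplicates_removed`, `n_output`).
#' @export
clean_and_deduplicate <- function(lib) {
  stopifnot(inherits(lib, "ChemLibrary"))
  smi <- lib$records$smiles
  n_input <- length(smi)
  if (n_input < 1L) stop("library has no records")

  smi <- strip_stereo(smi)
  has_frag <- grepl(".", smi, fixed = TRUE)
  smi[has_frag] <- vapply(smi[has_frag], largest_fragment, character(1),
                          USE.NAMES = FALSE)
  can <- ob_canonical(smi)
  ok <- !is.na(can)
  n_unparseable <- sum(!ok)
  if (!any(ok)) stop("no record of '", lib$name, "' survived cleaning")
  can <- can[ok]
  ids <- lib$records$id[ok]
  dup <- duplicated(can)
  n_duplicates <- sum(dup)
  out <- chem_library(lib$name, ids[!dup], can[!dup])
  report <- structure(
    list(n_input = n_input,
         n_unparseable = n_unparseable,
         n_duplicates_removed = n_duplicates,
         n_output = nrow(out$records)),
    class = "CleaningReport")
  stopifnot(report$n_output ==
              report$n_input - report$n_unparseable - report$n_duplicates_removed)
  list(library = out, report = report)
}

#' @export
print.CleaningReport <- function(x, ...) {
  cat(sprintf(
    "<CleaningReport> input %d | unparseable %d | duplicates removed %d | output %d\n",
    x$n_input, x$n_unparseable, x$n_duplicates_removed, x$n_output))
  invisible(x)
}

#' Write a cleaned library as a SMILES list file
#'
#' One `canonical_smiles<TAB>id` line per record.
#'
#' @param lib a `ChemLibrary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_smiles_library <- function(lib, path) {
  stopifnot(inherits(lib, "ChemLibrary"))
  writeLines(paste(lib$records$smiles, lib$records$id, sep = "\t"), path)
  invisible(path)
}
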