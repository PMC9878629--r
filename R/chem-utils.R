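# Internal helpers around the Open Babel backend (ChemmineR/ChemmineOB).
# All molecule handling in the package funnels through these functions.

# MDL molfile legacy charge codes <-> formal charge
.CHG_FROM_CODE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)

.DEFAULT_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                      F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L)

#' @noRd
strip_stereo <- function(smiles) {
  # SMILES grammar uses '@' only for tetrahedral chirality (inside brackets)
  # and '/', '\' only for double-bond configuration, so textual removal is
  # an exact stereo-stripping operation.
  gsub("@", "", gsub("[/\\\\]", "", smiles), fixed = TRUE)
}

# Canonicalize SMILES through Open Babel. Batch conversion stops at the
# first unparseable entry, so fall back to per-element conversion (NA for
# failures) whenever the batch output does not line up.
#' @noRd
ob_canonical <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  one <- function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) ""
    )
    out <- strsplit(out, "\n", fixed = TRUE)[[1]]
    if (!length(out)) return(NA_character_)
    val <- sub("\t.*$", "", trimws(out[1]))
    if (!nzchar(val)) NA_character_ else val
  }
  batch <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "CAN", paste(smiles, collapse = "\n"))),
    error = function(e) ""
  )
  lines <- strsplit(batch, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == n) {
    out <- sub("\t.*$", "", trimws(lines))
    out[!nzchar(out)] <- NA_character_
    return(out)
  }
  vapply(smiles, one, character(1), USE.NAMES = FALSE)
}

#' @noRd
is_valid_smiles <- function(smiles) {
  !is.na(ob_canonical(smiles))
}

# Parse SMILES into an SDFset; input must already be validated.
#' @noRd
smiles_to_sdf <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("mol_", seq_along(smiles))
  ChemmineR::smiles2sdf(stats::setNames(smiles, ids))
}

# Lightweight molecular graph (elements, formal charges, bond list) from one
# SDF record. Hydrogens are implicit in Open Babel molfile output.
#' @noRd
mol_graph <- function(sdf1) {
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  el <- sub("_.*", "", rownames(ab))
  code <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else rep(0L, nrow(ab))
  chg <- rep(0L, length(code))
  nz <- code != 0L
  chg[nz] <- .CHG_FROM_CODE[as.character(code[nz])]
  chg[is.na(chg)] <- 0L
  bonds <- if (nrow(bb) > 0) {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  } else {
    matrix(integer(0), 0, 3)
  }
  list(el = el, chg = chg, bonds = bonds)
}

# Serialize a molecular graph as a V2000 molblock (single SDF record).
# Coordinates are irrelevant for our use (canonical SMILES generation).
#' @noRd
build_molblock <- function(el, chg, bonds) {
  n <- length(el)
  nb <- nrow(bonds)
  hdr <- c("", " scafdiv", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                0, 0, 0, el)
  bd <- if (nb > 0) sprintf("%3d%3d%3d  0", bonds[, 1], bonds[, 2], bonds[, 3])
        else character(0)
  ich <- which(chg != 0L)
  chgl <- if (length(ich)) {
    sprintf("M  CHG%3d%s", length(ich),
            paste(sprintf("%4d%4d", ich, chg[ich]), collapse = ""))
  } else character(0)
  paste(c(hdr, at, bd, chgl, "M  END", "$$$$"), collapse = "\n")
}

# Canonical SMILES for a vector of self-built molblocks (all valid by
# construction, so batch conversion is safe).
#' @noRd
molblocks_to_smiles <- function(molblocks) {
  if (!length(molblocks)) return(character(0))
  out <- ChemmineOB::convertFormat("SDF", "CAN",
                                   paste(molblocks, collapse = "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != length(molblocks)) {
    stop("internal error: molblock batch conversion misaligned")
  }
  sub("\t.*$", "", trimws(lines))
}

# Heavy-atom count and molecular weight of each '.'-separated SMILES
# fragment; used for the largest-fragment rule.
#' @noRd
largest_fragment <- function(smiles) {
  if (!grepl(".", smiles, fixed = TRUE)) return(smiles)
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  ok <- is_valid_smiles(frags)
  if (!any(ok)) return(smiles)  # ring closures across '.'; keep as a whole
  frags <- frags[ok]
  # suppress the no-bond complaint for single-atom (counter-ion) fragments
  sdf <- tryCatch(suppressWarnings(smiles_to_sdf(frags)),
                  error = function(e) NULL)
  if (is.null(sdf) || length(sdf) != length(frags)) return(smiles)
  natoms <- vapply(seq_along(frags), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    sum(sub("_.*", "", rownames(ab)) != "H")
  }, integer(1))
  best <- which(natoms == max(natoms))
  if (length(best) > 1L) {  # tie: larger molecular weight
    mw <- tryCatch(ChemmineR::propOB(sdf[best])$MW, error = function(e) NULL)
    if (!is.null(mw)) best <- best[which.max(mw)] else best <- best[1]
  }
  frags[best[1]]
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
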